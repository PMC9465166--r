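test_that("compound tables are read with validation and a rejects list", {
  path <- tmp_file(c("id,smiles,label",
                     "a,CCO,active",
                     "b,c1ccccc1,active",
                     "c,CCN,inactive"))
  cs <- read_compound_table(path, quiet = TRUE)
  counts <- compound_counts(cs)
  expect_equal(counts$n_active, 2L)
  expect_equal(counts$n_inactive, 1L)
  expect_equal(counts$n_rejected, 0L)

  # unparseable structure and bad label are rejected with reasons, not dropped
  path2 <- tmp_file(c("id,smiles,label",
                      "a,CCO,active",
                      "b,C1CC,active",        # unmatched ring bond
                      "c,CCN,maybe"))
  cs2 <- read_compound_table(path2, quiet = TRUE)
  rej <- attr(cs2, "rejects")
  expect_equal(nrow(cs2), 1L)
  expect_equal(sort(rej$id), c("b", "c"))
  expect_match(rej$reason[rej$id == "b"], "unparseable")
  expect_match(rej$reason[rej$id == "c"], "label")

  # duplicate ids are rejected
  cs3 <- compound_set(data.frame(id = c("x", "x"), smiles = c("CC", "CCC"),
                                 label = "active"), quiet = TRUE)
  expect_equal(nrow(cs3), 1L)
  expect_match(attr(cs3, "rejects")$reason, "duplicate")

  expect_error(read_compound_table(tmp_file(c("id,label", "a,active"))),
               class = "herbscreen_config_error")
  expect_error(read_compound_table(tmp_file("id,smiles,label")),
               class = "herbscreen_data_error")
})

test_that("delimiter auto-detection handles comma, tab and semicolon", {
  for (d in c(",", "\t", ";")) {
    path <- tmp_file(c(paste("id", "smiles", "label", sep = d),
                       paste("a", "CCO", "active", sep = d),
                       paste("b", "CC", "inactive", sep = d)))
    cs <- read_compound_table(path, quiet = TRUE)
    expect_equal(cs$id, c("a", "b"))
  }
})

test_that("herb tables normalize terms and flag records without channels", {
  df <- rbind(
    make_herb_df("Chuan Xiong", natures = "Warm", flavors = "pungent",
                 channels = "liver| Gall Bladder |pericardium"),
    make_herb_df("No Channel", natures = "cold", flavors = "bitter",
                 channels = "", status = "non-hepatoprotective")
  )
  ht <- herb_table(df)
  expect_setequal(ht$terms[[1]],
                  c("warm", "pungent", "liver", "gall bladder", "pericardium"))
  expect_true(ht$clusterable[1])
  expect_false(ht$clusterable[2])   # retained but not clusterable

  expect_error(herb_table(rbind(df, df[1, ])), "duplicate",
               class = "herbscreen_data_error")
  bad <- make_herb_df("X", natures = "tepid", flavors = "sweet",
                      channels = "liver")
  expect_error(herb_table(bad), "tepid", class = "herbscreen_data_error")
  # a term from the wrong family is also diagnosed
  bad2 <- make_herb_df("Y", natures = "sweet", flavors = "", channels = "liver")
  expect_error(herb_table(bad2), class = "herbscreen_data_error")
})

test_that("domain tables round-trip through write and read", {
  cs <- make_compounds(c("CCO", "c1ccccc1", "CCN"),
                       c("active", "active", "inactive"))
  p1 <- tempfile(fileext = ".csv")
  write_compound_table(cs, p1)
  cs2 <- read_compound_table(p1, quiet = TRUE)
  expect_equal(cs2$id, cs$id)
  expect_equal(cs2$smiles, cs$smiles)
  expect_equal(as.character(cs2$label), as.character(cs$label))

  ht <- herb_table(rbind(
    make_herb_df("A", "warm", "sweet|sour", "liver|kidney"),
    make_herb_df("B", "cold", "bitter", "", status = "undetermined")))
  p2 <- tempfile(fileext = ".csv")
  write_herb_table(ht, p2)
  ht2 <- read_herb_table(p2)
  expect_equal(ht2$name, ht$name)
  expect_equal(ht2$terms, ht$terms)
  expect_equal(as.character(ht2$status), as.character(ht$status))

  ed <- edge_table(data.frame(herb = c("A", "A", "B"),
                              ingredient = c("i1", "i2", "i1")))
  p3 <- tempfile(fileext = ".csv")
  write_edge_table(ed, p3)
  expect_equal(read_edge_table(p3), ed, ignore_attr = TRUE)
})

test_that("edge tables collapse duplicates and check the registry", {
  expect_message(
    ed <- edge_table(data.frame(herb = c("A", "A"), ingredient = c("I1", "i1 "))),
    "duplicate")
  expect_equal(nrow(ed), 1L)        # ids normalized before dedup
  expect_equal(ed$ingredient, "i1")
  expect_error(edge_table(data.frame(herb = "A", ingredient = "zz"),
                          registry = c("i1", "i2")),
               class = "herbscreen_data_error")
})

test_that("Kennard-Stone picks the most distant points first", {
  s <- kennard_stone_split(matrix(c(0, 1, 10), ncol = 1),
                           rep("a", 3), ratio = 2 / 3)
  expect_setequal(s$train_ids, c("1", "3"))  # {0, 10} are the extreme pair
  expect_equal(s$test_ids, "2")

  # all-identical points: deterministic tie-break by input order
  s2 <- kennard_stone_split(matrix(0, 5, 2), rep("a", 5), ratio = 0.8)
  expect_equal(s2$train_ids, c("1", "2", "3", "4"))
  expect_equal(s2$test_ids, "5")
})

test_that("stratified split keeps per-class proportions within one sample", {
  set.seed(99)
  for (sizes in list(c(673, 214), c(50, 23), c(11, 7))) {
    n <- sum(sizes)
    x <- matrix(rnorm(n * 3), n, 3)
    y <- rep(c("active", "inactive"), sizes)
    s <- kennard_stone_split(x, y, ratio = 0.8)
    for (k in seq_along(sizes)) {
      n_train <- s$classes$n_train[s$classes$class == c("active", "inactive")[k]]
      expect_lte(abs(n_train / sizes[k] - 0.8), 1 / sizes[k])
    }
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    expect_setequal(c(s$train_ids, s$test_ids), as.character(seq_len(n)))
  }
  # the published 4:1 split sizes arise from these class totals
  s <- kennard_stone_split(matrix(rnorm(887 * 2), 887, 2),
                           rep(c("pos", "neg"), c(673, 214)), ratio = 0.8)
  expect_equal(sort(unname(unlist(
    s$classes[, c("n_train", "n_test")]))), sort(c(538, 135, 171, 43)))
})

test_that("Kennard-Stone selection is stable under row permutation", {
  set.seed(7)
  x <- matrix(rnorm(40 * 4), 40, 4)  # continuous: distances a.s. distinct
  y <- rep(c("a", "b"), each = 20)
  ids <- sprintf("s%02d", 1:40)
  s1 <- kennard_stone_split(x, y, 0.75, ids = ids)
  perm <- sample(40)
  s2 <- kennard_stone_split(x[perm, ], y[perm], 0.75, ids = ids[perm])
  expect_setequal(s1$train_ids, s2$train_ids)
})

test_that("Kennard-Stone rejects degenerate inputs", {
  expect_error(kennard_stone_split(matrix(c(1, NA), 2, 1), c("a", "a")),
               class = "herbscreen_data_error")
  expect_error(kennard_stone_split(matrix(1:3, 3, 1), c("a", "a", "b")),
               class = "herbscreen_data_error")
  expect_error(kennard_stone_split(matrix(1:4, 4, 1), rep("a", 4), ratio = 1.2),
               class = "herbscreen_config_error")
})
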