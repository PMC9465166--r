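test_that("property encoding sets exactly the herb's term bits", {
  ht <- herb_table(rbind(
    make_herb_df("Chuan Xiong", natures = "warm", flavors = "pungent",
                 channels = "liver|gall bladder|pericardium"),
    make_herb_df("All", natures = paste(c("cold", "hot", "warm", "cool",
                                          "neutral"), collapse = "|"),
                 flavors = paste(c("pungent", "bitter", "sweet", "sour",
                                   "salty", "astringent", "tasteless"),
                                 collapse = "|"),
                 channels = paste(property_vocabulary()[13:24],
                                  collapse = "|")),
    make_herb_df("Empty", natures = "", flavors = "", channels = "",
                 status = "undetermined")))
  pm <- encode_properties(ht)
  bits <- as.matrix(pm[, property_vocabulary()])
  on1 <- property_vocabulary()[bits[1, ] == 1]
  expect_setequal(on1, c("warm", "pungent", "liver", "gall bladder",
                         "pericardium"))
  expect_equal(sum(bits[1, ]), 5)
  expect_equal(unname(bits[2, ]), rep(1L, 24))
  expect_equal(unname(bits[3, ]), rep(0L, 24))
  expect_equal(attr(pm, "invalid"), "Empty")
})

test_that("frequency summaries count herbs per category and report overlap", {
  ht <- herb_table(rbind(
    make_herb_df("A", "warm", "sweet", "liver", category = "antipyretics"),
    make_herb_df("B", "cold", "bitter", "lung", category = "antipyretics"),
    make_herb_df("C", "warm", "sour", "kidney", category = "tonifying medicinal")))
  fs <- frequency_summary(ht, "category")
  expect_equal(fs$n[fs$category == "antipyretics"], 2L)

  toxic <- herb_table(rbind(
    make_herb_df("B", "cold", "bitter", "lung",
                 status = "non-hepatoprotective"),
    make_herb_df("D", "hot", "pungent", "spleen",
                 status = "non-hepatoprotective")))
  fs2 <- frequency_summary(ht, "term", other = toxic)
  expect_equal(attr(fs2, "overlap"), "B")
  expect_equal(fs2$n[fs2$term == "warm"], 2L)
  expect_error(frequency_summary(ht[0, ]), class = "herbscreen_data_error")
})

test_that("chi-squared contrast matches hand-computed 2x2 statistics", {
  mk_group <- function(n, flavors) {
    herb_table(do.call(rbind, lapply(seq_len(n), function(i) {
      make_herb_df(paste0("h", flavors, i), natures = "warm",
                   flavors = flavors, channels = "liver")
    })))
  }
  sweet <- encode_properties(mk_group(50, "sweet"))
  bitter <- encode_properties(mk_group(50, "bitter"))
  pf <- chi_squared_contrast(sweet, bitter, mode = "per_feature")
  # 50/0 vs 0/50 on the sweet bit: X2 = 100 uncorrected, 96.04 with Yates
  expect_equal(pf$statistic[pf$term == "sweet"], 100)
  expect_lt(pf$p[pf$term == "sweet"], 1e-20)
  pf_y <- chi_squared_contrast(sweet, bitter, mode = "per_feature",
                               correct = TRUE)
  expect_equal(pf_y$statistic[pf_y$term == "sweet"], 96.04)
  # terms identical in both groups carry no signal (warm is universal here)
  expect_equal(pf$statistic[pf$term == "warm"], 0)
  expect_equal(pf$p[pf$term == "warm"], 1)
  expect_true(all(pf$p_adj >= pf$p - 1e-12, na.rm = TRUE))

  # identical (proportional) profiles give omnibus statistic exactly 0
  om <- chi_squared_contrast(sweet, sweet, mode = "omnibus")
  expect_equal(om$statistic, 0)
  expect_equal(om$p, 1)
})

test_that("omnibus contrast controls its level under the null", {
  draw_group <- function(n, seed) {
    set.seed(seed)
    m <- matrix(as.integer(matrix(runif(n * 24), n) < 0.3), n, 24,
                dimnames = list(NULL, property_vocabulary()))
    m[, "liver"] <- 1L  # keep every column total positive
    out <- dplyr::bind_cols(tibble::tibble(name = paste0("h", seed, "_",
                                                         seq_len(n))),
                            tibble::as_tibble(as.data.frame(m)))
    class(out) <- c("property_matrix", class(out))
    out
  }
  ps <- vapply(1:40, function(s) {
    chi_squared_contrast(draw_group(120, 2 * s), draw_group(120, 2 * s + 1),
                         mode = "omnibus")$p
  }, numeric(1))
  # the profile test is conservative under the null (possession counts are
  # not a multinomial table), so the false-positive rate must stay at or
  # below the nominal level
  expect_lte(mean(ps < 0.05), 0.05 + 1e-9)
  # and a genuine contrast is detected with a small p
  a <- draw_group(120, 1)
  b <- draw_group(120, 2)
  b$sweet <- 0L
  b$bitter <- 1L
  expect_lt(chi_squared_contrast(a, b, mode = "omnibus")$p, 0.01)
})

test_that("association rules reproduce the published lift arithmetic", {
  ht <- reconstruct_rule_transactions("sour", 0.0588, 0.7143)
  r <- mine_association_rules(ht)
  sour <- r[vapply(r$antecedent, identical, logical(1), "sour"), ]
  expect_equal(round(100 * sour$support, 2), 5.88)
  expect_equal(round(100 * sour$confidence, 2), 71.43)
  expect_equal(round(sour$lift, 2), 1.48)
  expect_equal(attr(r, "prior"), 123 / 255)
})

test_that("Apriori equals brute-force enumeration on a small vocabulary", {
  set.seed(8)
  terms6 <- c("sweet", "sour", "bitter", "warm", "liver", "kidney")
  n <- 12
  rows <- lapply(seq_len(n), function(i) {
    tt <- sample(terms6, sample(1:4, 1))
    make_herb_df(paste0("h", i),
                 natures = paste(intersect(tt, "warm"), collapse = "|"),
                 flavors = paste(intersect(tt, c("sweet", "sour", "bitter")),
                                 collapse = "|"),
                 channels = paste(intersect(tt, c("liver", "kidney")),
                                  collapse = "|"),
                 status = sample(c("hepatoprotective", "non-hepatoprotective"),
                                 1))
  })
  ht <- herb_table(do.call(rbind, rows))
  min_s <- 0.15; min_c <- 0.5; min_l <- 1.0
  mined <- mine_association_rules(ht, min_s, min_c, min_l, max_antecedent = 3)

  # oracle: every antecedent subset up to size 3, counted directly
  hep <- ht$status == "hepatoprotective"
  prior <- mean(hep)
  expected <- list()
  for (k in 1:3) {
    for (idx in utils::combn(length(terms6), k, simplify = FALSE)) {
      a <- terms6[idx]
      has <- vapply(ht$terms, function(tt) all(a %in% tt), logical(1))
      if (!any(has)) next
      supp <- sum(has & hep) / nrow(ht)
      conf <- sum(has & hep) / sum(has)
      lift <- conf / prior
      if (supp >= min_s && conf >= min_c && lift >= min_l) {
        expected[[length(expected) + 1]] <-
          list(a = sort(a), supp = supp, conf = conf, lift = lift)
      }
    }
  }
  expect_equal(nrow(mined), length(expected))
  key <- function(a) paste(sort(a), collapse = "|")
  mined_keys <- vapply(mined$antecedent, key, character(1))
  for (e in expected) {
    i <- match(key(e$a), mined_keys)
    expect_false(is.na(i))
    expect_equal(mined$support[i], e$supp)
    expect_equal(mined$confidence[i], e$conf)
    expect_equal(mined$lift[i], e$lift)
  }
})

test_that("rule identities hold on every mined rule", {
  sp <- synthetic_spec(seed = 5, n_herbs = 400)
  ht <- generate_herbs(sp)
  r <- mine_association_rules(ht, min_support = 0.02, min_confidence = 0.3,
                              min_lift = 0, max_antecedent = 2)
  expect_gt(nrow(r), 0)
  prior <- attr(r, "prior")
  n <- attr(r, "n_transactions")
  expect_true(all(r$support <= r$confidence + 1e-12))
  expect_true(all(r$support > 0))
  expect_equal(r$lift * prior, r$confidence)
  # support * n / confidence recovers the integer antecedent count
  expect_equal(round(r$support * n / r$confidence), r$n_antecedent)
  # sorted by confidence desc then support desc
  expect_true(all(diff(r$confidence) <= 1e-12 |
                    diff(r$support) <= 1e-12))
  expect_error(mine_association_rules(ht, min_support = 1.5),
               class = "herbscreen_config_error")
})

test_that("planted rule confidence is recovered at large n", {
  sp <- synthetic_spec(seed = 9, n_herbs = 5000,
                       planted_rules = list(list(antecedent = "sour",
                                                 confidence = 0.714,
                                                 base_rate = 0.48)))
  ht <- generate_herbs(sp)
  r <- mine_association_rules(ht, min_support = 0.01, min_confidence = 0.4,
                              min_lift = 0, max_antecedent = 1)
  sour <- r[vapply(r$antecedent, identical, logical(1), "sour"), ]
  expect_equal(sour$confidence, 0.714, tolerance = 0.03 / 0.714)
})

test_that("without planted structure, lifts concentrate near one", {
  sp <- synthetic_spec(seed = 21, n_herbs = 2000, planted_rules = list(),
                       separation = 0)
  ht <- generate_herbs(sp)
  r <- mine_association_rules(ht, min_support = 0.03, min_confidence = 0,
                              min_lift = 0, max_antecedent = 1)
  expect_gt(nrow(r), 5)
  salty <- r[vapply(r$antecedent, identical, logical(1), "salty"), ]
  expect_equal(salty$lift, 1, tolerance = 0.1)
  expect_lte(median(abs(r$lift - 1)), 0.1)
})

test_that("cluster classification follows branch composition", {
  # well-separated blobs: hepatoprotective herbs all sweet/liver/kidney,
  # non-hepatoprotective all bitter/pungent/spleen
  mk <- function(tag, n, flavors, channels, status) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      make_herb_df(paste0(tag, i), natures = "", flavors = flavors,
                   channels = channels, status = status)
    }))
  }
  ref <- herb_table(rbind(
    mk("P", 20, "sweet", "liver|kidney", "hepatoprotective"),
    mk("T", 20, "bitter|pungent", "spleen", "non-hepatoprotective")))
  cand <- herb_table(mk("U", 1, "sweet", "liver|kidney", "undetermined"))
  asg <- cluster_classify(ref, cand)
  expect_equal(asg$verdict[asg$name == "U1"], "hepatoprotective-like")
  comp <- glance(asg)
  expect_equal(sum(comp$n_hepato), 20)
  expect_equal(sum(comp$n_non_hepato), 20)

  # determinism and the name-clash guard
  asg2 <- cluster_classify(ref, cand)
  expect_identical(tibble::as_tibble(asg), tibble::as_tibble(asg2))
  expect_error(cluster_classify(ref, herb_table(mk("P", 1, "sweet", "liver",
                                                   "undetermined"))),
               class = "herbscreen_data_error")
})

test_that("candidates from a planted population get that population's verdict", {
  hits <- vapply(1:3, function(s) {
    sp <- synthetic_spec(seed = s, n_herbs = 200, n_undetermined = 20,
                         separation = 1)
    ht <- generate_herbs(sp)
    ref <- ht[ht$status != "undetermined", ]
    hep_like <- attr(ht, "planted_hepatolike")
    cand <- ht[ht$status == "undetermined", ]
    asg <- cluster_classify(ref, cand)
    ca <- asg[asg$role == "candidate", ]
    correct <- (ca$name %in% hep_like) ==
      (ca$verdict == "hepatoprotective-like")
    mean(correct)
  }, numeric(1))
  expect_true(all(hits >= 18 / 20))
})

test_that("rule matching is antecedent subset inclusion", {
  rules <- reference_screen_rules()
  expect_equal(match_rules_to_herb(c("sweet", "kidney", "liver", "warm"),
                                   rules), c(1L, 2L, 4L))
  expect_equal(match_rules_to_herb(c("bitter", "lung"), rules), integer(0))
  # three-rule herb profile: sweet+warm+stomach+sour hits 2, 3 and 5
  expect_setequal(match_rules_to_herb(c("sweet", "warm", "stomach", "sour"),
                                      rules), c(2L, 3L, 5L))
})

test_that("association rules serialize with 2 dp percentages", {
  r <- reference_screen_rules()
  path <- tempfile(fileext = ".csv")
  write_association_rules(r, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$support_pct, c(10.59, 6.67, 5.88, 5.49, 6.67))
  expect_equal(back$lift, c(1.44, 1.53, 1.48, 1.38, 1.36))
  expect_equal(back$antecedent[3], "sour")
})
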