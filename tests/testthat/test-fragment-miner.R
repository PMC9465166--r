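test_that("miner configuration is validated", {
  expect_error(miner_config(min_lr = 1), class = "herbscreen_config_error")
  expect_error(miner_config(min_freq = 0), class = "herbscreen_config_error")
  expect_error(miner_config(min_atoms = 1), class = "herbscreen_config_error")
  expect_error(miner_config(max_atoms = 1), class = "herbscreen_config_error")
  expect_equal(miner_config()$min_lr, 10)
})

test_that("fragment generation cuts acyclic single bonds, rings intact", {
  cs <- make_compounds("CCc1ccccc1", "active")
  fr <- generate_fragments(cs, miner_config(min_atoms = 2, max_atoms = 8))
  # two acyclic cuts: benzene ring, ring+CH2, ethyl and the intact parent
  expect_setequal(fr$pattern, c("c1ccccc1", "Cc1ccccc1", "CC", "CCc1ccccc1"))
  expect_equal(fr$n_heavy_atoms[fr$pattern == "CC"], 2L)

  # methane has no bond to cut and falls below min_atoms
  expect_equal(nrow(generate_fragments(make_compounds("C", "active"),
                                       miner_config())), 0L)

  # duplicated molecules add nothing: fragment set is dedup-idempotent
  cs2 <- make_compounds(rep("CCc1ccccc1", 3), rep("active", 3))
  fr2 <- generate_fragments(cs2, miner_config(min_atoms = 2, max_atoms = 8))
  expect_setequal(fr2$pattern, fr$pattern)

  # double bonds are never cut: acetone yields no 2-atom C-C fragment,
  # the C=O unit stays intact
  fr3 <- generate_fragments(make_compounds("CC(=O)C", "active"),
                            miner_config(min_atoms = 2, max_atoms = 4))
  expect_true("C=O" %in% unlist(lapply(fr3$pattern, identity)) ||
                "CC=O" %in% fr3$pattern)
  expect_false("CO" %in% fr3$pattern)
})

test_that("likelihood-ratio arithmetic matches the published alert table", {
  expect_equal(alert_statistics(45, 0, 536, 171)$lr, Inf)
  expect_equal(alert_statistics(45, 0, 536, 171)$precision_pct, 100)
  # the five finite-LR alerts, class totals implied by the printed ratios
  finite <- list(c(41, 1, 13.08, 97.62), c(39, 1, 12.44, 97.50),
                 c(77, 2, 12.28, 97.47), c(33, 1, 10.53, 97.06),
                 c(65, 2, 10.37, 97.01))
  for (f in finite) {
    st <- alert_statistics(f[1], f[2], 536, 171)
    expect_equal(round(st$lr, 2), f[3])
    expect_equal(round(st$precision_pct, 2), f[4])
  }
  st <- alert_statistics(30, 3, 100, 100)
  expect_equal(st$lr, 10)
  # nothing matched: LR flagged undefined rather than fabricated
  expect_true(is.na(alert_statistics(0, 0, 10, 10)$lr))
})

test_that("likelihood ratio is monotone in the occurrence counts", {
  set.seed(4)
  for (i in 1:25) {
    P <- sample(50:500, 1); N <- sample(20:200, 1)
    tp <- sample(1:P, 1); fp <- sample(1:N, 1)
    lr <- alert_statistics(tp, fp, P, N)$lr
    if (tp < P) expect_gte(alert_statistics(tp + 1, fp, P, N)$lr, lr)
    expect_lte(alert_statistics(tp, fp + 1, P, N)$lr, lr)
  }
})

test_that("fragment scoring counts compounds once each", {
  cs <- make_compounds(
    c("CCO", "CCCO", "OCCO", "c1ccccc1", "CCN"),
    c("active", "active", "active", "inactive", "inactive"))
  r <- score_fragment("CCO", cs)
  expect_equal(r$tp, 3L)     # OCCO matches twice but counts once
  expect_equal(r$fp, 0L)
  expect_equal(r$lr, Inf)
  expect_setequal(attr(r, "matched_ids"), c("c01", "c02", "c03"))

  r2 <- score_fragment("CCN", cs)
  expect_equal(c(r2$tp, r2$fp), c(0L, 1L))
  expect_equal(r2$precision_pct, 0)
})

test_that("mined alerts agree with brute-force SMARTS counting on small sets", {
  # independent oracle: enumerate fragments, count by Open Babel SMARTS on
  # the full set, apply thresholds/ranking/subset filter directly
  smis <- c("CCc1ccccc1", "CCCc1ccccc1", "CCc1ccccc1C", "OCCc1ccccc1",
            "CCCCO", "CCOC", "c1ccncc1CC", "CC(C)c1ccccc1",
            "C1CCCCC1CC", "C1CCCCC1CCC",
            "CCN", "CCCN", "c1ccccc1N", "OCCN", "CCOCC", "CNCC")
  labs <- rep(c("active", "inactive"), c(10, 6))
  cs <- make_compounds(smis, labs)
  cfg <- miner_config(min_lr = 2, min_freq = 3, min_atoms = 2, max_atoms = 9)

  frags <- generate_fragments(cs, cfg)
  oracle <- do.call(rbind, lapply(frags$pattern, function(p) {
    sc <- score_fragment(p, cs)
    cbind(tibble::tibble(pattern = p,
                         n_heavy_atoms = frags$n_heavy_atoms[
                           frags$pattern == p]),
          sc[, c("tp", "fp", "lr", "precision_pct")],
          tibble::tibble(ids = list(sort(attr(sc, "matched_ids")[
            startsWith(attr(sc, "matched_ids"), "c0") |
              startsWith(attr(sc, "matched_ids"), "c1")]))))
  }))
  act_ids <- cs$id[cs$label == "active"]
  oracle$act <- lapply(oracle$ids, intersect, act_ids)
  pass <- oracle[lengths(oracle$act) >= cfg$min_freq &
                   (is.infinite(oracle$lr) | oracle$lr >= cfg$min_lr), ]
  pass <- pass[order(-is.infinite(pass$lr),
                     -ifelse(is.infinite(pass$lr), pass$tp, pass$lr),
                     -pass$tp, pass$n_heavy_atoms, pass$pattern), ]
  keep <- rep(TRUE, nrow(pass))
  for (i in seq_len(nrow(pass))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (keep[j] && all(pass$act[[i]] %in% pass$act[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  expected <- pass[keep, c("pattern", "tp", "fp", "lr", "precision_pct")]

  mined <- mine_alerts(cs, cfg)
  expect_equal(tibble::as_tibble(mined)[, c("pattern", "tp", "fp", "lr",
                                            "precision_pct")],
               tibble::as_tibble(expected), ignore_attr = TRUE)
})

test_that("a planted motif is recovered as the top alert with infinite LR", {
  sp <- synthetic_spec(seed = 17, n_active = 90, n_inactive = 45,
                       planted_alerts = list(list(motif = "FC(F)F",
                                                  penetrance = 1 / 3,
                                                  leak = 0)))
  cs <- generate_compounds(sp)
  carriers <- cs$id[cs$label == "active" & grepl("F", cs$smiles, fixed = TRUE)]
  al <- mine_alerts(cs, miner_config(min_lr = 10, min_freq = 10))
  expect_gte(nrow(al), 1)
  expect_equal(al$lr[1], Inf)
  top_matched <- attr(al, "matched_ids")[[al$pattern[1]]]
  expect_setequal(top_matched, carriers)

  # matching consistency: each rule's pattern matches all its recorded ids
  for (i in seq_len(nrow(al))) {
    sc <- score_fragment(al$pattern[i], cs)
    expect_true(all(attr(al, "matched_ids")[[al$pattern[i]]] %in%
                      attr(sc, "matched_ids")))
  }
  # every emitted rule satisfies the thresholds
  expect_true(all(al$tp >= 10))
  expect_true(all(is.infinite(al$lr) | al$lr >= 10))
})

test_that("identical actives and inactives yield no alert", {
  smis <- c("CCO", "CCc1ccccc1", "CCCN", "C1CCCCC1", "CCOC",
            "CC(C)O", "c1ccccc1O", "CCCCC", "CCNC", "COc1ccccc1")
  cs <- make_compounds(c(smis, smis), rep(c("active", "inactive"), each = 10))
  expect_warning(al <- mine_alerts(cs, miner_config(min_lr = 10, min_freq = 2)),
                 "no fragment")
  expect_equal(nrow(al), 0L)
})

test_that("alert rules serialize with thresholds and an inf literal", {
  cs <- make_compounds(
    c(rep("CCc1ccccc1", 4), "CCO", rep("CCN", 2), "CCOC"),
    rep(c("active", "inactive"), each = 4))
  al <- mine_alerts(cs, miner_config(min_lr = 2, min_freq = 2, max_atoms = 8))
  path <- tempfile(fileext = ".csv")
  write_alert_rules(al, path)
  lines <- readLines(path)
  expect_match(lines[1], "min_lr=2")
  expect_true(any(grepl(",inf,", lines)))
  expect_true(file.exists(paste0(path, ".matches.csv")))
})
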