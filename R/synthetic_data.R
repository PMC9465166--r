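# Synthetic study generators. The defaults define the package's standard
# desk-scale study conditions: ~700 active / 200 inactive compounds with a
# planted trifluoromethyl alert, ~250 reference herbs whose flavor-activity
# associations are planted at stated confidence, two dozen undetermined
# candidate herbs half of which are drawn from the hepatoprotective
# property population, and a bipartite edge list in which designated
# candidates are enriched (>= 15) in active ingredients.

#' Synthetic study specification
#'
#' @param seed Integer seed; fully determines every generated table.
#' @param n_active,n_inactive Compound counts (defaults 700 / 200).
#' @param planted_alerts List of alerts, each
#'   `list(motif = <SMILES>, penetrance = <fraction of actives carrying
#'   it>, leak = <fraction of inactives>)`.
#' @param n_herbs Number of reference herbs with determined status
#'   (default 250).
#' @param planted_rules List of property-activity associations, each
#'   `list(antecedent = <term>, confidence = <target P(hepatoprotective |
#'   term)>, base_rate = <hepatoprotective prior>)`; single-term
#'   antecedents are calibrated exactly, multi-term associations emerge
#'   from the population separation.
#' @param n_undetermined Undetermined candidate herbs (default 24), half
#'   drawn from the hepatoprotective property population.
#' @param n_candidate_herbs Hepatoprotective-like candidates additionally
#'   enriched in active ingredients (default 8).
#' @param planted_degree Active-ingredient count planted on designated
#'   candidates (default 15).
#' @param background_degree_max Maximum active-ingredient count of
#'   non-designated undetermined herbs (default 5).
#' @param separation Property-population separation in \[0, 1\] (default
#'   0.8); 0 makes the two status populations identical.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1,
                           n_active = 700, n_inactive = 200,
                           planted_alerts = list(list(motif = "FC(F)F",
                                                      penetrance = 2 / 7,
                                                      leak = 0)),
                           n_herbs = 250,
                           planted_rules = list(list(antecedent = "sour",
                                                     confidence = 0.714,
                                                     base_rate = 0.482)),
                           n_undetermined = 24,
                           n_candidate_herbs = 8,
                           planted_degree = 15,
                           background_degree_max = 5,
                           separation = 0.8) {
  for (al in planted_alerts) {
    if (al$penetrance < 0 || al$penetrance > 1 || al$leak < 0 || al$leak > 1) {
      hs_config_error("penetrance and leak must be in [0, 1]")
    }
  }
  seenA <- list()
  for (r in planted_rules) {
    if (r$confidence < 0 || r$confidence > 1 ||
        r$base_rate <= 0 || r$base_rate >= 1) {
      hs_config_error("rule confidence in [0,1], base_rate in (0,1)")
    }
    key <- paste(sort(r$antecedent), collapse = "|")
    if (!is.null(seenA[[key]]) && seenA[[key]] != r$confidence) {
      hs_config_error("inconsistent confidence targets for antecedent {%s}", key)
    }
    seenA[[key]] <- r$confidence
    if (!all(r$antecedent %in% property_vocabulary())) {
      hs_config_error("rule antecedent terms must be in the 24-term vocabulary")
    }
  }
  structure(list(seed = seed, n_active = n_active, n_inactive = n_inactive,
                 planted_alerts = planted_alerts, n_herbs = n_herbs,
                 planted_rules = planted_rules,
                 n_undetermined = n_undetermined,
                 n_candidate_herbs = n_candidate_herbs,
                 planted_degree = planted_degree,
                 background_degree_max = background_degree_max,
                 separation = separation),
            class = "synthetic_spec")
}

# Concatenation-safe SMILES grammar pieces: every piece starts and ends on
# an atom with a free valence, so pasting pieces yields a valid molecule.
HS_GRAMMAR <- c("CC", "CCC", "CCO", "CCN", "C(C)C", "c1ccccc1",
                "C1CCCCC1", "c1ccncc1", "CC(=O)", "COC", "CC(=O)O",
                "c1ccc(cc1)")

#' Generate a synthetic labelled compound set
#'
#' Molecules are assembled from a small concatenation-safe SMILES grammar
#' (rings, chains, common substituents); each planted alert motif is
#' appended to active scaffolds at its penetrance and to inactive
#' scaffolds at its leak rate. All emitted SMILES parse.
#'
#' @param spec A [synthetic_spec()].
#' @return A [compound_set()].
#' @export
generate_compounds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (al in spec$planted_alerts) {
    if (is.null(parse_molecule(al$motif))) {
      hs_config_error("planted motif '%s' is not a valid structure", al$motif)
    }
  }
  set.seed(spec$seed)
  build <- function(n, rates) {
    vapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      smi <- paste(sample(HS_GRAMMAR, k, replace = TRUE), collapse = "")
      for (ai in seq_along(spec$planted_alerts)) {
        if (runif(1) < rates[ai]) {
          smi <- paste0(smi, spec$planted_alerts[[ai]]$motif)
        }
      }
      smi
    }, character(1))
  }
  act <- build(spec$n_active,
               vapply(spec$planted_alerts, `[[`, numeric(1), "penetrance"))
  inact <- build(spec$n_inactive,
                 vapply(spec$planted_alerts, `[[`, numeric(1), "leak"))
  compound_set(tibble::tibble(
    id = c(sprintf("act_%04d", seq_len(spec$n_active)),
           sprintf("inact_%04d", seq_len(spec$n_inactive))),
    smiles = c(act, inact),
    label = rep(c("active", "inactive"), c(spec$n_active, spec$n_inactive))
  ), quiet = TRUE)
}

# Per-status Bernoulli marginals over the 24 terms implementing the
# population separation and the planted single-term rule calibration:
# p(term | non-hep) = leak, p(term | hep) = leak * odds^(1/|A|) with
# odds = (c/(1-c)) * ((1-b)/b).
herb_marginals <- function(spec) {
  vocab <- property_vocabulary()
  base <- 0.15
  sep <- spec$separation
  p_hep <- stats::setNames(rep(base, length(vocab)), vocab)
  p_non <- p_hep
  hep_sig <- c("sweet", "warm", "liver", "kidney")
  non_sig <- c("bitter", "pungent", "cold", "spleen", "large intestine")
  p_hep[hep_sig] <- 0.5 + 0.35 * sep
  p_non[hep_sig] <- 0.5 - 0.35 * sep
  p_hep[non_sig] <- 0.5 - 0.35 * sep
  p_non[non_sig] <- 0.5 + 0.35 * sep
  for (r in spec$planted_rules) {
    a <- length(r$antecedent)
    odds <- (r$confidence / (1 - r$confidence)) *
      ((1 - r$base_rate) / r$base_rate)
    leak <- 0.10
    ph <- min(0.95, leak * odds^(1 / a))
    p_hep[r$antecedent] <- ph
    p_non[r$antecedent] <- leak
  }
  list(hep = p_hep, non = p_non)
}

#' Generate a synthetic herb table
#'
#' Reference herbs receive a status at the planted base rate and property
#' bits drawn independently given status from calibrated marginals, so
#' each planted single-term rule's empirical confidence converges to its
#' target as the table grows. Undetermined candidate herbs are drawn from
#' the hepatoprotective or non-hepatoprotective property population
#' (half/half); the hepatoprotective-like ones are named in attribute
#' `"planted_hepatolike"`. Every herb gets at least one nature-or-flavor
#' bit and at least one channel, so all records are clusterable.
#'
#' @param spec A [synthetic_spec()].
#' @return A `herb_table`.
#' @export
generate_herbs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  marg <- herb_marginals(spec)
  prior <- if (length(spec$planted_rules) > 0) {
    spec$planted_rules[[1]]$base_rate
  } else 0.482
  vocab <- property_vocabulary()

  draw <- function(is_hep) {
    p <- if (is_hep) marg$hep else marg$non
    bits <- runif(length(vocab)) < p
    names(bits) <- vocab
    if (!any(bits[c(HS_NATURES, HS_FLAVORS)])) {
      bits[sample(HS_FLAVORS, 1)] <- TRUE
    }
    if (!any(bits[HS_CHANNELS])) bits[sample(HS_CHANNELS, 1)] <- TRUE
    vocab[bits]
  }
  cat_hep <- c("antipyretics", "tonifying medicinal",
               "blood-activating stasis-removing drugs", "diaphoretics")
  cat_other <- c("qi-regulating drugs", "digestants", "astringent medicinal",
                 "warming interior drugs")

  n_ref <- spec$n_herbs
  status <- ifelse(runif(n_ref) < prior, "hepatoprotective",
                   "non-hepatoprotective")
  ref_terms <- lapply(status == "hepatoprotective", draw)
  ref_cat <- ifelse(status == "hepatoprotective",
                    sample(cat_hep, n_ref, replace = TRUE),
                    sample(c(cat_hep, cat_other), n_ref, replace = TRUE))

  n_u <- spec$n_undetermined
  u_hep_like <- rep(c(TRUE, FALSE), length.out = n_u)
  u_terms <- lapply(u_hep_like, draw)
  u_names <- sprintf("cand_%02d", seq_len(n_u))

  fam_cell <- function(tt, f) paste(intersect(f, tt), collapse = "|")
  tbl <- tibble::tibble(
    name = c(sprintf("herb_%03d", seq_len(n_ref)), u_names),
    category = c(ref_cat, sample(c(cat_hep, cat_other), n_u, replace = TRUE)),
    natures = vapply(c(ref_terms, u_terms), fam_cell, character(1), HS_NATURES),
    flavors = vapply(c(ref_terms, u_terms), fam_cell, character(1), HS_FLAVORS),
    channels = vapply(c(ref_terms, u_terms), fam_cell, character(1), HS_CHANNELS),
    status = c(status, rep("undetermined", n_u))
  )
  out <- herb_table(tbl)
  attr(out, "planted_hepatolike") <- u_names[u_hep_like]
  out
}

#' Generate a synthetic herb-ingredient edge list
#'
#' Designated candidate herbs (the first `n_candidate_herbs` of the
#' hepatoprotective-like undetermined herbs) are connected to at least
#' `planted_degree` distinct active ingredients; the remaining undetermined
#' herbs get at most `background_degree_max`; hepatoprotective reference
#' herbs get a moderate number so the hepatoprotective network is
#' non-trivial. No duplicate pairs are emitted.
#'
#' @param spec A [synthetic_spec()].
#' @param compounds The [generate_compounds()] output (source of active
#'   ingredient ids).
#' @param herbs The [generate_herbs()] output.
#' @return An edge tibble ([edge_table()]); the designated candidates are
#'   in attribute `"designated"`.
#' @export
generate_edges <- function(spec, compounds, herbs) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  active_ids <- compounds$id[compounds$label == "active"]
  if (spec$planted_degree > length(active_ids)) {
    hs_config_error("planted_degree (%d) exceeds the number of active ingredients (%d)",
                    spec$planted_degree, length(active_ids))
  }
  hep_like <- attr(herbs, "planted_hepatolike") %||% character(0)
  if (spec$n_candidate_herbs > length(hep_like)) {
    hs_config_error("n_candidate_herbs exceeds the hepatoprotective-like pool")
  }
  designated <- hep_like[seq_len(spec$n_candidate_herbs)]
  undet <- herbs$name[herbs$status == "undetermined"]
  hep_ref <- herbs$name[herbs$status == "hepatoprotective"]

  rows <- list()
  add <- function(herb, k) {
    if (k > 0) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        herb = herb, ingredient = sample(active_ids, k))
    }
  }
  extra <- min(5L, length(active_ids) - spec$planted_degree)
  for (h in designated) {
    add(h, spec$planted_degree + sample(0:extra, 1))
  }
  for (h in setdiff(undet, designated)) {
    add(h, sample(0:spec$background_degree_max, 1))
  }
  for (h in hep_ref) add(h, sample(1:10, 1))
  out <- edge_table(dplyr::bind_rows(rows))
  attr(out, "designated") <- designated
  out
}

#' Write the three synthetic inputs to a directory
#'
#' Emits `compounds.csv`, `herbs.csv` and `edges.csv` in exactly the
#' dialects the package readers consume.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- generate_compounds(spec)
  herbs <- generate_herbs(spec)
  edges <- generate_edges(spec, compounds, herbs)
  paths <- c(compounds = file.path(dir, "compounds.csv"),
             herbs = file.path(dir, "herbs.csv"),
             edges = file.path(dir, "edges.csv"))
  write_compound_table(compounds, paths["compounds"])
  write_herb_table(herbs, paths["herbs"])
  write_edge_table(edges, paths["edges"])
  invisible(paths)
}
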