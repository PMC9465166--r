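# Descriptor matrix construction behind a pluggable provider contract, and
# two-stage feature selection: shadow-feature relevance selection followed
# by Pearson-correlation pruning.

#' Compute a molecular descriptor matrix
#'
#' A *descriptor provider* is any function that maps one parsed molecule to
#' a fixed-length named numeric vector with stable feature names; the
#' provider is a contract, so an external 2D descriptor program can be
#' plugged in by wrapping its output table with
#' [descriptor_provider_table()]. Compounds on which the provider fails are
#' moved to a rejects attribute with the failure reason; sporadic missing
#' values are imputed by the feature median (logged).
#'
#' @param compounds A [compound_set()].
#' @param provider A provider function (default [descriptor_provider_graph()]).
#' @return A tibble of class `descriptor_matrix`: column `id` plus one
#'   numeric column per feature, attributes `zero_variance` (feature names
#'   with no variation), `imputed` (tibble of imputed cells) and `rejects`.
#' @export
compute_descriptors <- function(compounds, provider = descriptor_provider_graph()) {
  stopifnot(inherits(compounds, "compound_set"))
  mols <- compound_molecules(compounds)
  rows <- vector("list", nrow(compounds))
  reject <- character(0)
  for (i in seq_len(nrow(compounds))) {
    v <- tryCatch(provider(mols[[i]], compounds$id[i]),
                  error = function(e) conditionMessage(e))
    if (!is.numeric(v)) {
      reject <- c(reject, stats::setNames(as.character(v), compounds$id[i]))
      rows[[i]] <- NULL
    } else {
      rows[[i]] <- v
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  feat_names <- names(rows[keep][[1]])
  m <- do.call(rbind, rows[keep])
  colnames(m) <- feat_names

  imputed <- tibble::tibble(id = character(0), feature = character(0),
                            value = double(0))
  for (j in seq_len(ncol(m))) {
    miss <- which(!is.finite(m[, j]))
    if (length(miss) > 0) {
      med <- median(m[is.finite(m[, j]), j])
      m[miss, j] <- med
      imputed <- dplyr::bind_rows(imputed, tibble::tibble(
        id = compounds$id[keep][miss], feature = feat_names[j], value = med))
    }
  }
  if (nrow(imputed) > 0) {
    inform(sprintf("descriptors: median-imputed %d value(s)", nrow(imputed)))
  }
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(id = compounds$id[keep]), out)
  attr(out, "zero_variance") <- feat_names[apply(m, 2, function(z) sd(z) == 0)]
  attr(out, "imputed") <- imputed
  attr(out, "rejects") <- tibble::tibble(id = names(reject),
                                         reason = unname(reject))
  class(out) <- c("descriptor_matrix", class(out))
  out
}

#' Built-in descriptor providers
#'
#' `descriptor_provider_graph()` computes a deterministic 2D descriptor set
#' from the molecular graph alone (element counts, bond-order counts, ring
#' and branching statistics, simple estimated properties) - small but
#' sufficient to drive feature selection and classification.
#' `descriptor_provider_toy()` returns just atom counts, handy in examples.
#' `descriptor_provider_table(path)` adapts a pre-computed descriptor table
#' (delimited text, `id` column plus numeric columns), the route to use for
#' full-size external 2D descriptor sets.
#'
#' @return A provider function for [compute_descriptors()].
#' @export
descriptor_provider_graph <- function() {
  halogens <- c("F", "Cl", "Br", "I")
  function(mol, id = NULL) {
    if (is.null(mol)) stop("structure not parsed")
    el <- mol$elem
    bo <- mol$bonds$order
    deg <- tabulate(c(mol$bonds$a, mol$bonds$b), nbins = length(el))
    g <- mol_igraph(mol)
    n_ring_bonds <- if (length(bo) > 0) {
      length(bo) - length(igraph::bridges(g))
    } else 0L
    mw_tab <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904)
    c(
      n_atoms = length(el),
      n_bonds = length(bo),
      n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
      n_S = sum(el == "S"), n_halogen = sum(el %in% halogens),
      n_hetero = sum(el != "C"),
      n_single = sum(bo == 1), n_double = sum(bo == 2),
      n_triple = sum(bo == 3),
      n_ring_bonds = n_ring_bonds,
      n_rings = length(bo) - length(el) + igraph::count_components(g),
      n_branch = sum(deg >= 3),
      n_terminal = sum(deg == 1),
      max_degree = max(deg, 0),
      mean_degree = if (length(deg)) mean(deg) else 0,
      mw = sum(mw_tab[el], na.rm = TRUE),
      frac_hetero = sum(el != "C") / max(1, length(el)),
      frac_ring = n_ring_bonds / max(1, length(bo))
    )
  }
}

#' @rdname descriptor_provider_graph
#' @export
descriptor_provider_toy <- function() {
  function(mol, id = NULL) {
    if (is.null(mol)) stop("structure not parsed")
    # aromatic atoms from the kekulized graph: atoms on non-bridge bonds
    # that alternate single/double (approximated as ring atoms with a
    # double bond); adequate for toy examples
    g <- mol_igraph(mol)
    ring_bond <- rep(FALSE, nrow(mol$bonds))
    if (nrow(mol$bonds) > 0) {
      br <- igraph::bridges(g)
      ring_bond[-as.integer(br)] <- TRUE
      if (length(br) == 0) ring_bond[] <- TRUE
    }
    arom_atoms <- unique(c(mol$bonds$a[ring_bond & mol$bonds$order == 2],
                           mol$bonds$b[ring_bond & mol$bonds$order == 2]))
    c(n_atoms = length(mol$elem), n_aromatic_atoms = length(arom_atoms))
  }
}

#' @rdname descriptor_provider_graph
#' @param path Delimited text file with an `id` column and numeric
#'   descriptor columns.
#' @param delim Field delimiter (auto-detected when `NULL`).
#' @export
descriptor_provider_table <- function(path, delim = NULL) {
  tab <- read_delim_auto(path, delim)
  if (!"id" %in% names(tab)) hs_config_error("descriptor table needs an 'id' column")
  num <- as.matrix(as.data.frame(lapply(tab[setdiff(names(tab), "id")],
                                        as.numeric)))
  rownames(num) <- tab$id
  function(mol, id = NULL) {
    if (is.null(id) || !id %in% rownames(num)) {
      stop("compound id not present in descriptor table")
    }
    num[id, ]
  }
}

# Matrix accessor: numeric part of a descriptor_matrix.
descr_values <- function(x) {
  as.matrix(tibble::as_tibble(x)[setdiff(names(x), "id")])
}

#' Shadow-feature relevance selection
#'
#' Selects features relevant to a binary outcome with a shadow-feature
#' scheme: each iteration appends a permuted copy of every feature, fits a
#' random-forest importance, and scores a *hit* for every real feature whose
#' importance exceeds the best shadow importance. After each iteration a
#' two-sided binomial test at level `alpha` on the accumulated hit count
#' confirms features that beat the shadows significantly more often than
#' chance and rejects those that lose significantly; features still
#' undecided at `max_iter` are resolved by comparing their median importance
#' to the median best-shadow importance. Every feature's decision is
#' recorded in the returned provenance table.
#'
#' @param x A `descriptor_matrix` (or plain data frame with an `id` column).
#' @param y Binary labels aligned with rows of `x` (factor or character).
#' @param alpha Significance level for the binomial decisions (default 0.05).
#' @param max_iter Maximum shadow iterations (default 100).
#' @param seed Integer seed; fixed seed gives an identical mask.
#' @param ntree Trees per forest (default 500).
#' @return A tibble of class `feature_mask` with columns `feature`,
#'   `decision` (`kept-by-relevance` / `dropped-shadow`), `importance`
#'   (median importance across iterations) and `hits`/`trials`.
#' @export
select_relevant <- function(x, y, alpha = 0.05, max_iter = 100, seed = 1,
                            ntree = 500) {
  m <- descr_values(x)
  y <- as.factor(as.character(y))
  if (nlevels(y) != 2) hs_data_error("y must be binary; found %d level(s)", nlevels(y))
  if (ncol(m) < 2) hs_config_error("need at least 2 features")
  # drop zero-variance columns up front (they carry no importance signal)
  zv <- apply(m, 2, function(z) sd(z) == 0)
  feats <- colnames(m)[!zv]
  mm <- m[, !zv, drop = FALSE]
  p <- ncol(mm)

  set.seed(seed)
  hits <- stats::setNames(rep(0L, p), feats)
  trials <- 0L
  imp_hist <- matrix(NA_real_, nrow = max_iter, ncol = p,
                     dimnames = list(NULL, feats))
  shadow_hist <- rep(NA_real_, max_iter)
  decision <- stats::setNames(rep(NA_character_, p), feats)

  for (iter in seq_len(max_iter)) {
    open <- is.na(decision)
    if (!any(open)) break
    sh <- apply(mm, 2, sample)
    colnames(sh) <- paste0(".shadow.", feats)
    fit <- randomForest::randomForest(cbind(mm, sh), y, ntree = ntree,
                                      importance = TRUE)
    # z-scored permutation importance (mean accuracy decrease / SD)
    imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
    best_shadow <- max(imp[paste0(".shadow.", feats)])
    real <- imp[feats]
    imp_hist[iter, ] <- real
    shadow_hist[iter] <- best_shadow
    trials <- trials + 1L
    hits <- hits + as.integer(real > best_shadow)
    # Bonferroni over all tested features, so the familywise false
    # confirm/reject rate stays at alpha
    alpha_adj <- alpha / p
    for (f in feats[open]) {
      pv <- binom.test(hits[[f]], trials, 0.5)$p.value
      if (pv < alpha_adj) {
        decision[[f]] <- if (hits[[f]] > trials / 2) "kept-by-relevance"
                         else "dropped-shadow"
      }
    }
  }
  # tentative resolution by median importance vs median best-shadow
  med_shadow <- median(shadow_hist, na.rm = TRUE)
  med_imp <- apply(imp_hist, 2, median, na.rm = TRUE)
  tent <- is.na(decision)
  decision[tent] <- ifelse(med_imp[tent] > med_shadow,
                           "kept-by-relevance", "dropped-shadow")

  out <- tibble::tibble(
    feature = colnames(m),
    decision = ifelse(colnames(m) %in% feats,
                      decision[colnames(m)], "dropped-zero-variance"),
    importance = ifelse(colnames(m) %in% feats,
                        med_imp[colnames(m)], 0),
    hits = ifelse(colnames(m) %in% feats, hits[colnames(m)], NA_integer_),
    trials = trials
  )
  class(out) <- c("feature_mask", class(out))
  out
}

#' Prune correlated features
#'
#' Among every pair of kept features with absolute Pearson correlation above
#' `r_max`, drops the member with the lower relevance importance (ties by
#' feature name order). Zero-variance features, for which the correlation is
#' undefined, are dropped first with their own provenance tag. Implemented
#' greedily in descending-importance order, which guarantees all retained
#' pairwise correlations are at most `r_max`.
#'
#' @param x The `descriptor_matrix` the mask was computed on.
#' @param mask A `feature_mask` from [select_relevant()].
#' @param r_max Maximum allowed absolute Pearson correlation (default 0.90).
#' @return An updated `feature_mask`; dropped features carry decisions
#'   `dropped-correlated-with <feature>` or `dropped-zero-variance`.
#' @export
prune_correlated <- function(x, mask, r_max = 0.90) {
  stopifnot(inherits(mask, "feature_mask"))
  kept <- mask$feature[mask$decision == "kept-by-relevance"]
  if (length(kept) == 0) hs_config_error("mask keeps no features")
  m <- descr_values(x)[, kept, drop = FALSE]
  zv <- colnames(m)[apply(m, 2, function(z) sd(z) == 0)]
  mask$decision[mask$feature %in% zv] <- "dropped-zero-variance"
  kept <- setdiff(kept, zv)

  imp <- stats::setNames(mask$importance, mask$feature)[kept]
  ord <- kept[order(-imp, kept)]
  cm <- suppressWarnings(cor(m[, ord, drop = FALSE]))
  retained <- character(0)
  for (f in ord) {
    clash <- retained[abs(cm[f, retained]) > r_max]
    if (length(clash) > 0) {
      mask$decision[mask$feature == f] <-
        paste0("dropped-correlated-with ", clash[1])
    } else {
      retained <- c(retained, f)
    }
  }
  attr(mask, "r_max") <- r_max
  mask
}

#' @rdname prune_correlated
#' @param mask A `feature_mask`.
#' @return `mask_kept()` returns the kept feature names in original order.
#' @export
mask_kept <- function(mask) {
  mask$feature[mask$decision == "kept-by-relevance"]
}
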