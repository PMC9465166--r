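#' Stratified Kennard-Stone train/test split
#'
#' Splits samples into training and test sets with the Kennard-Stone
#' max-min distance algorithm, run independently within each class so that
#' both classes keep the target train fraction (the standard design when a
#' QSAR data set is strongly imbalanced). Features are standardized (zero
#' mean, unit variance per column, computed on the full data) before
#' Euclidean distances are taken, so descriptors on different scales
#' contribute comparably. Within a class the first two training picks are
#' the mutually most distant pair; each subsequent pick maximizes its
#' minimum distance to the already-selected set. Ties are broken by lowest
#' input index, which makes the split deterministic and permutation-stable
#' whenever all pairwise distances are distinct.
#'
#' @param x Numeric matrix or data frame (samples x features), no missing
#'   values.
#' @param labels Binary class vector (factor, character or logical), one per
#'   row of `x`; each class must have at least 2 members.
#' @param ratio Target train fraction in (0, 1); default 0.8 (a 4:1 split).
#' @param ids Optional sample identifiers; defaults to row numbers as
#'   character.
#' @return A list of class `ks_split` with `train_ids`, `test_ids`, `ratio`
#'   and a per-class summary tibble `classes`.
#' @examples
#' x <- matrix(c(0, 1, 10), ncol = 1)
#' kennard_stone_split(x, c("a", "a", "a"), ratio = 2 / 3)$train_ids
#' @export
kennard_stone_split <- function(x, labels, ratio = 0.8, ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) hs_data_error("feature matrix contains missing values")
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1) {
    hs_config_error("ratio must be a single number in (0, 1)")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    hs_config_error("labels length (%d) != rows of x (%d)", length(labels), nrow(x))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  ids <- as.character(ids)

  # standardize globally; constant columns contribute 0, not NaN
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")

  train <- character(0)
  summaries <- list()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2) {
      hs_data_error("class '%s' has fewer than 2 members", cl)
    }
    n_train <- round(ratio * length(idx))
    n_train <- max(2L, min(length(idx) - 1L, n_train))
    sel <- ks_select(xs[idx, , drop = FALSE], n_train)
    train <- c(train, ids[idx[sel]])
    summaries[[cl]] <- tibble::tibble(
      class = cl, n = length(idx), n_train = n_train,
      n_test = length(idx) - n_train
    )
  }
  structure(
    list(train_ids = train, test_ids = setdiff(ids, train), ratio = ratio,
         classes = dplyr::bind_rows(summaries)),
    class = "ks_split"
  )
}

# Core max-min selection on one class; returns selected row indices.
ks_select <- function(xs, n_train) {
  n <- nrow(xs)
  d <- as.matrix(dist(xs))
  # seed: mutually most distant pair, lowest indices on ties
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (nrow(best) == 0) best <- matrix(c(1L, 2L), ncol = 2) # all-identical points
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1, ])
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_train) {
    mind[sel] <- -Inf
    cand <- which(mind == max(mind))[1] # lowest index on ties
    sel <- c(sel, cand)
    mind <- pmin(mind, d[, cand])
  }
  sort(sel)
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split (train fraction %.3g): %d train / %d test\n",
              x$ratio, length(x$train_ids), length(x$test_ids)))
  print(x$classes)
  invisible(x)
}
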