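# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per fold with the fold's own confusion counts at threshold 0.5
#' (the headline metrics pool the folds; see [glance.hs_cv()]).
#'
#' @param x An `hs_cv` object.
#' @param ... Unused.
#' @return A tibble with columns `fold`, `n`, `tp`, `fn`, `tn`, `fp`, `acc`.
#' @export
tidy.hs_cv <- function(x, ...) {
  x$scores |>
    dplyr::mutate(pred = .data$score >= 0.5) |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      tp = sum(.data$pred & .data$active),
      fn = sum(!.data$pred & .data$active),
      tn = sum(!.data$pred & !.data$active),
      fp = sum(.data$pred & !.data$active),
      acc = (.data$tp + .data$tn) / .data$n,
      .groups = "drop"
    )
}

#' @rdname tidy.hs_cv
#' @export
glance.hs_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(learner = x$spec$name, k = x$k, seed = x$seed),
    tibble::as_tibble(x$metrics)
  )
}

#' Tidy a feature mask
#'
#' @param x A `feature_mask`.
#' @param ... Unused.
#' @return The provenance tibble (`feature`, `decision`, `importance`).
#' @export
tidy.feature_mask <- function(x, ...) {
  tibble::as_tibble(x)[, c("feature", "decision", "importance")]
}

#' @rdname tidy.feature_mask
#' @export
glance.feature_mask <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_kept = sum(x$decision == "kept-by-relevance"),
    n_dropped_shadow = sum(x$decision == "dropped-shadow"),
    n_dropped_correlated = sum(startsWith(x$decision, "dropped-correlated")),
    n_dropped_zero_variance = sum(x$decision == "dropped-zero-variance")
  )
}

#' Tidy cluster assignments
#'
#' @param x A `cluster_assignments` tibble.
#' @param ... Unused.
#' @return `tidy()`: the assignment tibble; `glance()`: one row per branch
#'   with its reference composition.
#' @export
tidy.cluster_assignments <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.cluster_assignments
#' @export
glance.cluster_assignments <- function(x, ...) {
  attr(x, "branch_composition")
}
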