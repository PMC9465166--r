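# Herb-level analysis: 24-bit drug-property encoding, frequency summaries,
# chi-squared contrast between hepatoprotective and non-hepatoprotective
# herbs, Apriori association rules with the hepatoprotection consequent,
# and hierarchical-cluster branch classification.

#' Encode herb drug properties as 24-bit vectors
#'
#' Bit i is 1 iff the i-th vocabulary term (order of
#' [property_vocabulary()]) is among the herb's terms. An all-zero vector
#' (no nature and no flavor) is flagged invalid.
#'
#' @param herbs A `herb_table` (or any tibble with `name` and a `terms`
#'   list column).
#' @return A tibble of class `property_matrix`: `name` plus one 0/1 integer
#'   column per vocabulary term; attribute `invalid` names herbs with
#'   neither a nature nor a flavor bit set.
#' @export
encode_properties <- function(herbs) {
  vocab <- property_vocabulary()
  bits <- vapply(herbs$terms, function(tt) as.integer(vocab %in% tt),
                 integer(length(vocab)))
  m <- t(bits)
  colnames(m) <- vocab
  out <- dplyr::bind_cols(tibble::tibble(name = herbs$name),
                          tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
  nf <- c(HS_NATURES, HS_FLAVORS)
  attr(out, "invalid") <- herbs$name[rowSums(m[, nf, drop = FALSE]) == 0]
  class(out) <- c("property_matrix", class(out))
  out
}

prop_values <- function(x) {
  as.matrix(tibble::as_tibble(x)[property_vocabulary()])
}

#' Frequency summaries of herbs by category or property term
#'
#' Counts herbs per group and status. With `group_by = "category"` it
#' reproduces efficacy-category frequency analysis (which Pharmacopoeia
#' classes are rich in hepatoprotective herbs); with a property family it
#' counts term possession. The `overlap` attribute lists herbs carrying
#' both a hepatoprotective and a non-hepatoprotective annotation when a
#' second table is supplied.
#'
#' @param herbs A `herb_table`.
#' @param group_by `"category"` or `"term"`.
#' @param other Optional second `herb_table` (e.g. a hepatotoxic herb
#'   list); the overlap of names is reported in attribute `"overlap"`.
#' @return A tibble of counts, sorted by descending frequency within
#'   status.
#' @export
frequency_summary <- function(herbs, group_by = c("category", "term"),
                              other = NULL) {
  group_by <- match.arg(group_by)
  if (nrow(herbs) == 0) hs_data_error("empty herb table")
  if (group_by == "category") {
    out <- herbs |>
      dplyr::count(.data$status, .data$category, name = "n") |>
      dplyr::arrange(.data$status, dplyr::desc(.data$n))
  } else {
    long <- tibble::tibble(
      status = rep(herbs$status, lengths(herbs$terms)),
      term = unlist(herbs$terms, use.names = FALSE)
    )
    out <- long |>
      dplyr::count(.data$status, .data$term, name = "n") |>
      dplyr::arrange(.data$status, dplyr::desc(.data$n))
  }
  if (!is.null(other)) {
    attr(out, "overlap") <- intersect(herbs$name, other$name)
  }
  out
}

#' Chi-squared contrast of drug properties between herb groups
#'
#' `mode = "omnibus"` builds the 2 x 24 table of per-term possession counts
#' (hepatoprotective vs non-hepatoprotective group) and tests homogeneity
#' of the two property profiles with one chi-squared statistic.
#' `mode = "per_feature"` tests each of the 24 terms in its own 2 x 2 table
#' (possessing vs not, by group) and reports raw and
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param hepato,non_hepato `property_matrix` objects (or 0/1 matrices with
#'   vocabulary columns) for the two groups.
#' @param mode `"omnibus"` or `"per_feature"`.
#' @param correct Apply the Yates continuity correction in the 2 x 2 tests
#'   (default `FALSE`).
#' @return For omnibus: a one-row tibble `statistic`, `df`, `p`. For
#'   per-feature: a tibble with one row per term (`term`, `statistic`,
#'   `df`, `p`, `p_adj`). Expected cell counts below 1 attach a warning
#'   but still return the result.
#' @export
chi_squared_contrast <- function(hepato, non_hepato,
                                 mode = c("omnibus", "per_feature"),
                                 correct = FALSE) {
  mode <- match.arg(mode)
  a <- prop_values(hepato)
  b <- prop_values(non_hepato)
  if (nrow(a) == 0 || nrow(b) == 0) hs_data_error("both groups must be non-empty")
  ca <- colSums(a)
  cb <- colSums(b)
  if (mode == "omnibus") {
    tab <- rbind(hepato = ca, non_hepato = cb)
    keep <- colSums(tab) > 0
    res <- suppressWarnings(chisq.test(tab[, keep, drop = FALSE],
                                       correct = FALSE))
    if (any(res$expected < 1)) {
      warn("omnibus chi-squared: expected cell count below 1")
    }
    tibble::tibble(statistic = unname(res$statistic),
                   df = unname(res$parameter), p = res$p.value)
  } else {
    rows <- lapply(seq_along(ca), function(j) {
      tab <- rbind(c(ca[j], nrow(a) - ca[j]), c(cb[j], nrow(b) - cb[j]))
      if (any(colSums(tab) == 0)) {
        # term possessed by everyone or no one in both groups: no contrast
        return(tibble::tibble(term = property_vocabulary()[j], statistic = 0,
                              df = 1, p = 1))
      }
      if (all(rowSums(tab) > 0)) {
        res <- suppressWarnings(chisq.test(tab, correct = correct))
        if (any(res$expected < 1)) {
          warn(sprintf("term '%s': expected cell count below 1",
                       property_vocabulary()[j]))
        }
        tibble::tibble(term = property_vocabulary()[j],
                       statistic = unname(res$statistic),
                       df = unname(res$parameter), p = res$p.value)
      } else {
        tibble::tibble(term = property_vocabulary()[j],
                       statistic = NA_real_, df = NA_real_, p = NA_real_)
      }
    })
    out <- dplyr::bind_rows(rows)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out
  }
}

#' Mine drug-property association rules for hepatoprotection
#'
#' Apriori with a fixed consequent: frequent property-term itemsets are
#' grown level-wise with the anti-monotone support bound applied to the
#' rule support P(antecedent and hepatoprotective), and a rule
#' `antecedent => hepatoprotection` is emitted when it passes the support,
#' confidence and lift thresholds with antecedent size at most
#' `max_antecedent`. Lift is confidence divided by the hepatoprotective
#' prior. Rules are sorted by confidence then support, descending, and
#' numbered in that order.
#'
#' @param herbs A `herb_table`; herbs with status `undetermined` are
#'   excluded from the transaction set.
#' @param min_support Minimum rule support as a fraction (default 0.05).
#' @param min_confidence Minimum confidence (default 0.65).
#' @param min_lift Minimum lift (default 1).
#' @param max_antecedent Maximum antecedent size (default 3).
#' @return A tibble of class `association_rules`: `id`, `antecedent` (list
#'   column), `support`, `confidence`, `lift`, `n_antecedent`, `n_joint`;
#'   attribute `prior` is the hepatoprotective prior used for lift.
#' @export
mine_association_rules <- function(herbs, min_support = 0.05,
                                   min_confidence = 0.65, min_lift = 1,
                                   max_antecedent = 3) {
  if (min_support > 1 || min_confidence > 1) {
    hs_config_error("support/confidence thresholds are fractions <= 1")
  }
  known <- herbs[herbs$status != "undetermined", ]
  if (nrow(known) == 0) hs_data_error("no herbs with a determined status")
  n <- nrow(known)
  hep <- known$status == "hepatoprotective"
  prior <- sum(hep) / n
  items <- sort(unique(unlist(known$terms, use.names = FALSE)))
  # transaction incidence: herbs x items
  inc <- vapply(items, function(t) {
    vapply(known$terms, function(tt) t %in% tt, logical(1))
  }, logical(n))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = n)
  min_count <- ceiling(min_support * n - 1e-9)

  # level-wise expansion on joint (antecedent & hepatoprotective) support
  joint_count <- function(cols) sum(rowSums(inc[, cols, drop = FALSE]) ==
                                      length(cols) & hep)
  ante_count <- function(cols) sum(rowSums(inc[, cols, drop = FALSE]) ==
                                     length(cols))
  frontier <- lapply(which(vapply(seq_along(items), function(j) {
    joint_count(j) >= min_count
  }, logical(1))), identity)
  rules <- list()
  level <- 1
  while (length(frontier) > 0 && level <= max_antecedent) {
    for (cols in frontier) {
      nj <- joint_count(cols)
      na <- ante_count(cols)
      conf <- nj / na
      supp <- nj / n
      lift <- conf / prior
      if (supp >= min_support && conf >= min_confidence && lift >= min_lift) {
        rules[[length(rules) + 1]] <- tibble::tibble(
          antecedent = list(items[cols]), support = supp, confidence = conf,
          lift = lift, n_antecedent = na, n_joint = nj)
      }
    }
    if (level == max_antecedent) break
    # candidate generation: extend each frequent set by a larger item index
    nxt <- list()
    seen <- character(0)
    for (cols in frontier) {
      for (j in seq_along(items)) {
        if (j <= max(cols)) next
        cand <- c(cols, j)
        key <- paste(cand, collapse = "-")
        if (key %in% seen) next
        seen <- c(seen, key)
        if (joint_count(cand) >= min_count) nxt[[length(nxt) + 1]] <- cand
      }
    }
    frontier <- nxt
    level <- level + 1
  }
  out <- if (length(rules) > 0) dplyr::bind_rows(rules) else
    tibble::tibble(antecedent = list(), support = double(),
                   confidence = double(), lift = double(),
                   n_antecedent = integer(), n_joint = integer())
  out <- out[order(-out$confidence, -out$support,
                   vapply(out$antecedent, paste, character(1),
                          collapse = "|")), ]
  out <- dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(out))), out)
  attr(out, "prior") <- prior
  attr(out, "n_transactions") <- n
  class(out) <- c("association_rules", class(out))
  out
}

#' Classify herbs by hierarchical-cluster branch
#'
#' Reference herbs (known hepatoprotective / non-hepatoprotective status)
#' and candidate herbs are clustered jointly on the Euclidean distance
#' between their 24-bit property vectors; the tree is cut into `k_cut`
#' branches. A branch - and every candidate in it - is called
#' *hepatoprotective-like* when the fraction of hepatoprotective reference
#' herbs in the branch exceeds the global reference prior, so the verdict
#' is determined solely by branch composition.
#'
#' @param reference A `herb_table` with determined statuses (both must be
#'   present), or a `property_matrix` with a `status` column.
#' @param candidates A `herb_table` of herbs to classify; names must not
#'   collide with reference names.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`, Ward linkage on Euclidean distances).
#' @param k_cut Number of branches to cut the tree into (default 2).
#' @return A tibble of class `cluster_assignments`: `name`, `role`
#'   (`reference`/`candidate`), `status`, `branch`, `verdict`
#'   (`hepatoprotective-like` / `non-hepatoprotective-like`), plus a
#'   `branch_composition` attribute tabulating reference statuses per
#'   branch. The fitted tree is attached as attribute `"hclust"`.
#' @export
cluster_classify <- function(reference, candidates, linkage = "ward.D2",
                             k_cut = 2) {
  clash <- intersect(reference$name, candidates$name)
  if (length(clash) > 0) {
    hs_data_error("candidate name(s) already in reference: %s",
                  paste(clash, collapse = ", "))
  }
  ref_status <- as.character(reference$status)
  if (!all(c("hepatoprotective", "non-hepatoprotective") %in% ref_status)) {
    hs_data_error("reference must contain both statuses")
  }
  pm_ref <- if (inherits(reference, "property_matrix")) reference else
    encode_properties(reference)
  pm_cand <- if (inherits(candidates, "property_matrix")) candidates else
    encode_properties(candidates)
  x <- rbind(prop_values(pm_ref), prop_values(pm_cand))
  rownames(x) <- c(pm_ref$name, pm_cand$name)
  hc <- hclust(dist(x), method = linkage)
  branch <- cutree(hc, k = k_cut)

  is_ref <- seq_len(nrow(x)) <= nrow(pm_ref)
  prior <- mean(ref_status == "hepatoprotective")
  comp <- lapply(seq_len(k_cut), function(b) {
    st <- ref_status[branch[is_ref] == b]
    tibble::tibble(branch = b,
                   n_hepato = sum(st == "hepatoprotective"),
                   n_non_hepato = sum(st == "non-hepatoprotective"))
  })
  comp <- dplyr::bind_rows(comp)
  comp$frac_hepato <- with(comp, ifelse(n_hepato + n_non_hepato == 0,
                                        NA_real_,
                                        n_hepato / (n_hepato + n_non_hepato)))
  branch_verdict <- ifelse(!is.na(comp$frac_hepato) &
                             comp$frac_hepato > prior,
                           "hepatoprotective-like", "non-hepatoprotective-like")
  out <- tibble::tibble(
    name = rownames(x),
    role = ifelse(is_ref, "reference", "candidate"),
    status = c(ref_status, rep("undetermined", nrow(pm_cand))),
    branch = unname(branch),
    verdict = branch_verdict[branch]
  )
  attr(out, "branch_composition") <- comp
  attr(out, "prior") <- prior
  attr(out, "hclust") <- hc
  class(out) <- c("cluster_assignments", class(out))
  out
}

#' Match association rules to a herb
#'
#' A rule matches iff its antecedent term set is a subset of the herb's
#' property terms.
#'
#' @param terms Character vector of a herb's property terms (or a one-row
#'   `herb_table`).
#' @param rules An `association_rules` tibble.
#' @return Integer vector of matching rule ids.
#' @export
match_rules_to_herb <- function(terms, rules) {
  if (is.data.frame(terms)) terms <- terms$terms[[1]]
  terms <- normalize_terms(terms)
  hit <- vapply(rules$antecedent, function(a) all(a %in% terms), logical(1))
  rules$id[hit]
}

#' Write association rules as delimited text
#'
#' Columns `id`, `antecedent` (`|`-joined), `support_pct`,
#' `confidence_pct`, `lift`, percentages rounded to 2 decimal places (the
#' internal values are unrounded).
#'
#' @param rules An `association_rules` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_rules <- function(rules, path) {
  out <- tibble::tibble(
    id = rules$id,
    antecedent = vapply(rules$antecedent, paste, character(1), collapse = "|"),
    support_pct = round(100 * rules$support, 2),
    confidence_pct = round(100 * rules$confidence, 2),
    lift = round(rules$lift, 2)
  )
  readr::write_csv(out, path)
  invisible(path)
}
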