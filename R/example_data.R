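# Curated example data from the TCM hepatoprotection literature: the five
# drug-property association rules reported for hepatoprotective herbs, and
# the 26 candidate herbs that passed a published material-basis screen of
# the public TCM ingredient databases, with their active-ingredient counts,
# matched rules and final drug-property verdicts. These tables let the
# screening arithmetic be exercised and demonstrated without any database
# access.

#' Published drug-property association rules for hepatoprotection
#'
#' Five association rules relating drug-property terms to herb
#' hepatoprotection, mined from a literature-curated reference set of 123
#' hepatoprotective and 132 non-hepatoprotective TCMs (support >= 5%,
#' confidence >= 65%, lift > 1).
#'
#' @return An `association_rules`-style tibble: `id`, `antecedent` (list
#'   column), `support`, `confidence`, `lift` (fractions / ratio as
#'   published, 2 dp).
#' @export
reference_screen_rules <- function() {
  raw <- readr::read_csv(system.file("extdata", "hepatoprotection_rules.csv",
                                     package = "herbscreen"),
                         show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(
    id = as.integer(raw$id),
    antecedent = lapply(strsplit(raw$antecedent, "|", fixed = TRUE),
                        normalize_terms),
    support = raw$support_pct / 100,
    confidence = raw$confidence_pct / 100,
    lift = raw$lift
  )
  attr(out, "prior") <- reference_screen_population()[["hepatoprotective"]] /
    sum(reference_screen_population())
  class(out) <- c("association_rules", class(out))
  out
}

#' @rdname reference_screen_rules
#' @details `reference_screen_population()` gives the reference set sizes
#'   behind the rules (123 hepatoprotective, 132 non-hepatoprotective
#'   herbs), whose ratio is the prior used for lift.
#' @export
reference_screen_population <- function() {
  c(hepatoprotective = 123L, `non-hepatoprotective` = 132L)
}

#' Published candidate herbs rich in hepatoprotective ingredients
#'
#' The 26 TCMs found to contain at least 15 hepatoprotective ingredients in
#' a screen of the public TCM ingredient databases, with their
#' active-ingredient counts, the ids of the [reference_screen_rules()] they
#' match, whether they could be placed by the drug-property cluster model
#' (one herb lacks channel-tropism information), and the final screen
#' verdict (12 herbs passed both filters).
#'
#' @return A tibble: `herb`, `n_active_ingredients`, `matched_rules` (list
#'   column of integer rule ids), `assessable`, `screened`.
#' @export
reference_screen_candidates <- function() {
  raw <- readr::read_csv(system.file("extdata",
                                     "hepatoprotection_candidates.csv",
                                     package = "herbscreen"),
                         show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    herb = raw$name,
    n_active_ingredients = as.integer(raw$n_active_ingredients),
    matched_rules = lapply(raw$matched_rules, function(x) {
      if (is.na(x) || !nzchar(x)) integer(0)
      else as.integer(strsplit(x, "|", fixed = TRUE)[[1]])
    }),
    assessable = raw$assessable,
    screened = raw$screened
  )
}

#' Reconstruct a transaction table reproducing one published rule
#'
#' Builds a herb table whose mined rule for the given antecedent has
#' exactly the published support and confidence: the joint and antecedent
#' counts are recovered from the printed percentages over the reference
#' population, and filler herbs carry a neutral term so the population
#' size and hepatoprotective prior are preserved. Used to re-derive the
#' published lift values through the mining code itself.
#'
#' @param antecedent Character vector of antecedent terms.
#' @param support,confidence Published fractions.
#' @param population Named counts as in [reference_screen_population()].
#' @return A `herb_table` of `sum(population)` herbs.
#' @export
reconstruct_rule_transactions <- function(antecedent, support, confidence,
                                          population = reference_screen_population()) {
  n <- sum(population)
  n_hep <- population[["hepatoprotective"]]
  joint <- round(support * n)
  ante <- round(joint / confidence)
  if (joint > n_hep || ante < joint) {
    hs_config_error("inconsistent support/confidence for n = %d", n)
  }
  ante_cell <- paste(antecedent, collapse = "|")
  fam <- function(terms, f) paste(intersect(f, terms), collapse = "|")
  mk <- function(k, terms, status, tag) {
    if (k == 0) return(NULL)
    tibble::tibble(
      name = sprintf("%s_%03d", tag, seq_len(k)),
      category = "unspecified",
      natures = fam(terms, HS_NATURES),
      flavors = fam(terms, HS_FLAVORS),
      channels = fam(terms, HS_CHANNELS),
      status = status
    )
  }
  filler <- c("tasteless", "heart")
  tbl <- dplyr::bind_rows(
    mk(joint, antecedent, "hepatoprotective", "ah"),
    mk(ante - joint, antecedent, "non-hepatoprotective", "an"),
    mk(n_hep - joint, filler, "hepatoprotective", "fh"),
    mk(n - ante - (n_hep - joint), filler, "non-hepatoprotective", "fn")
  )
  herb_table(tbl)
}
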