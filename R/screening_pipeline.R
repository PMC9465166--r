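# End-to-end screen: material basis (herbs rich in hepatoprotective
# ingredients) AND drug property (clustered with the hepatoprotective
# herbs). Rule hits are reported as supporting evidence only; they do not
# gate the final call.

#' Screen configuration
#'
#' Collects every threshold of the herb-level screen. Defaults follow the
#' package's standard study conditions: degree threshold 15 (inclusive),
#' Ward clustering cut into 2 branches, association rules at support 5%,
#' confidence 65%, lift > 1.
#'
#' @param min_count Material-basis threshold (inclusive, default 15).
#' @param linkage,k_cut Clustering linkage and branch count (see
#'   [cluster_classify()]).
#' @param min_support,min_confidence,min_lift,max_antecedent Association
#'   rule thresholds (see [mine_association_rules()]).
#' @param seed Integer seed recorded in the report provenance.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_count = 15, linkage = "ward.D2", k_cut = 2,
                          min_support = 0.05, min_confidence = 0.65,
                          min_lift = 1, max_antecedent = 3, seed = 1) {
  structure(list(min_count = min_count, linkage = linkage, k_cut = k_cut,
                 min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift, max_antecedent = max_antecedent,
                 seed = seed),
            class = "screen_config")
}

#' Run the two-level herb screen
#'
#' Pipeline: build the undetermined herb-ingredient network, count each
#' herb's active ingredients, keep herbs at or above the degree threshold,
#' classify the survivors against the reference herbs by cluster branch,
#' match the mined association rules, and intersect: a herb is *screened*
#' iff it passes the degree filter and is hepatoprotective-like by drug
#' property. Candidates lacking channel-tropism information (or absent
#' from the herb table) cannot be placed by the cluster model and are
#' reported as unassessable, never silently dropped.
#'
#' @param edges Herb-ingredient edge tibble ([edge_table()]).
#' @param active_ingredients Character vector of hepatoprotective
#'   ingredient ids.
#' @param herbs A `herb_table` containing the reference herbs (determined
#'   status) and, ideally, the candidate herbs' properties.
#' @param config A [screen_config()].
#' @param rules Optional pre-mined `association_rules`; mined from the
#'   reference herbs when `NULL`.
#' @return A tibble of class `candidate_report`: `herb`,
#'   `n_active_ingredients`, `assessable`, `verdict`, `matched_rules`
#'   (list column of rule ids), `screened`, `category`. Attribute
#'   `provenance` records every threshold; `assignments` and `rules` carry
#'   the intermediate objects.
#' @export
run_screen <- function(edges, active_ingredients, herbs,
                       config = screen_config(), rules = NULL) {
  stopifnot(inherits(config, "screen_config"))
  hepato_herbs <- herbs$name[herbs$status == "hepatoprotective"]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("screen stage '%s' failed: %s", name, conditionMessage(e)),
            class = "herbscreen_stage_error")
    })
  }
  nets <- stage("build_networks",
                build_networks(edges, active_ingredients, hepato_herbs))
  deg <- stage("ingredient_degree", ingredient_degree(nets$undetermined))
  cand <- stage("filter_candidates", filter_candidates(deg, config$min_count))

  reference <- herbs[herbs$status != "undetermined", ]
  if (is.null(rules)) {
    rules <- stage("mine_association_rules", mine_association_rules(
      herbs, min_support = config$min_support,
      min_confidence = config$min_confidence, min_lift = config$min_lift,
      max_antecedent = config$max_antecedent))
  }

  cand_rows <- herbs[match(cand$herb, herbs$name), ]
  assessable <- !is.na(cand_rows$name) & cand_rows$clusterable
  assignments <- NULL
  verdict <- rep(NA_character_, nrow(cand))
  if (any(assessable)) {
    assignments <- stage("cluster_classify", cluster_classify(
      reference, cand_rows[assessable, ], linkage = config$linkage,
      k_cut = config$k_cut))
    cand_assign <- assignments[assignments$role == "candidate", ]
    verdict[assessable] <- cand_assign$verdict[match(cand$herb[assessable],
                                                     cand_assign$name)]
  }
  matched <- lapply(seq_len(nrow(cand)), function(i) {
    if (is.na(cand_rows$name[i])) return(integer(0))
    match_rules_to_herb(cand_rows$terms[[i]], rules)
  })
  out <- tibble::tibble(
    herb = cand$herb,
    n_active_ingredients = cand$n_active_ingredients,
    assessable = assessable,
    verdict = verdict,
    matched_rules = matched,
    screened = assessable & !is.na(verdict) &
      verdict == "hepatoprotective-like",
    category = cand_rows$category
  )
  attr(out, "provenance") <- unclass(config)
  attr(out, "assignments") <- assignments
  attr(out, "rules") <- rules
  attr(out, "degrees") <- deg
  class(out) <- c("candidate_report", class(out))
  out
}

#' Count association-rule hits over a set of herbs
#'
#' Sums the number of matched rules over the named herbs - the post-hoc
#' evidence check that screened candidates carry the hepatoprotection
#' rules more often than the rejected ones.
#'
#' @param herb_names Character vector of herb names.
#' @param annotations A `candidate_report`, or any tibble with a `herb`
#'   column and a `matched_rules` list column, or a named list of rule-id
#'   vectors.
#' @return Total rule-hit count (integer).
#' @export
count_rule_hits <- function(herb_names, annotations) {
  if (is.data.frame(annotations)) {
    ann <- stats::setNames(annotations$matched_rules, annotations$herb)
  } else {
    ann <- annotations
  }
  missing <- setdiff(herb_names, names(ann))
  if (length(missing) > 0) {
    hs_data_error("no annotation for herb(s): %s",
                  paste(missing, collapse = ", "))
  }
  sum(lengths(ann[herb_names]))
}

#' Render a candidate report
#'
#' Deterministic output mirroring the candidate table layout: name, active
#' ingredient count, matched rule ids (comma-joined), verdict and final
#' screen flag, preceded by `#`-prefixed provenance headers (delimited
#' format) or a bold provenance line (markdown).
#'
#' @param report A `candidate_report`.
#' @param path Output path.
#' @param format `"delimited"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("delimited", "markdown")) {
  format <- match.arg(format)
  prov <- attr(report, "provenance")
  prov_txt <- paste(names(prov), unlist(prov), sep = "=", collapse = " ")
  rules_txt <- vapply(report$matched_rules, paste, character(1),
                      collapse = ", ")
  verdict <- ifelse(is.na(report$verdict), "unassessable", report$verdict)
  if (format == "delimited") {
    lines <- c(paste0("# ", prov_txt),
               "herb,n_active_ingredients,matched_rules,verdict,screened",
               paste(report$herb, report$n_active_ingredients,
                     gsub(", ", ";", rules_txt), verdict, report$screened,
                     sep = ","))
  } else {
    lines <- c(paste0("**screen provenance:** ", prov_txt), "",
               "| Herb | Active ingredients | Rules | Verdict | Screened |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %s | %s | %s |", report$herb,
                       report$n_active_ingredients, rules_txt, verdict,
                       ifelse(report$screened, "yes", "no")))
  }
  writeLines(lines, path)
  invisible(path)
}
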