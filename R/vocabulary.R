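#' The 24-term TCM drug-property vocabulary
#'
#' TCM theory describes every herb by a *nature* (cold, hot, warm, cool, or
#' neutral), one or more *flavors* (pungent, bitter, sweet, sour, salty,
#' astringent, tasteless) and the *channels* (meridians) it enters. The
#' package encodes the three families as a fixed-order 24-bit vector; these
#' constants define the canonical term order used everywhere.
#'
#' @return `property_vocabulary()` returns a character vector of all 24 terms
#'   in encoding order; `property_families()` a tibble with columns `term`
#'   and `family` (`nature`, `flavor`, `channel`).
#' @examples
#' property_vocabulary()
#' @export
property_vocabulary <- function() {
  c(HS_NATURES, HS_FLAVORS, HS_CHANNELS)
}

HS_NATURES <- c("cold", "hot", "warm", "cool", "neutral")
HS_FLAVORS <- c("pungent", "bitter", "sweet", "sour", "salty", "astringent",
                "tasteless")
HS_CHANNELS <- c("liver", "lung", "stomach", "spleen", "kidney", "heart",
                 "large intestine", "gall bladder", "bladder",
                 "small intestine", "pericardium", "triple energizer")

#' @rdname property_vocabulary
#' @export
property_families <- function() {
  tibble::tibble(
    term = property_vocabulary(),
    family = rep(c("nature", "flavor", "channel"), c(5L, 7L, 12L))
  )
}

# Normalize free-text property terms: trim, collapse internal whitespace,
# lowercase. Returns the normalized terms; unknown terms are the caller's
# problem to diagnose (they know the row).
normalize_terms <- function(terms) {
  terms <- tolower(trimws(terms))
  terms <- gsub("[[:space:]]+", " ", terms)
  terms[nzchar(terms)]
}

# Split a |-separated multi-valued cell into normalized terms.
split_terms <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  normalize_terms(strsplit(cell, "|", fixed = TRUE)[[1]])
}
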