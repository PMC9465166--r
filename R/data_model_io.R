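# Readers and domain tables: labelled compound sets, herb records with
# drug-property terms, and herb-ingredient edge lists. All readers return
# tibbles; rows that fail validation are collected on a "rejects" attribute,
# never silently dropped.

#' Read a labelled compound table
#'
#' Reads a delimited text file with columns `id`, `smiles`, `label` into a
#' validated compound set. Each SMILES is parsed (Open Babel); rows whose
#' structure cannot be parsed, whose label is not `active`/`inactive`, or
#' whose id duplicates an earlier row are routed to a rejects table attached
#' as `attr(x, "rejects")` with a `reason` column.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) auto-detects among
#'   comma, tab and semicolon.
#' @param quiet Suppress the ingest summary message.
#' @return A tibble of class `compound_set` with columns `id`, `smiles`,
#'   `label` (factor `active`/`inactive`) and `canonical`; attributes
#'   `rejects` (tibble) and counts available via [compound_counts()].
#' @seealso [compound_set()] to build one from an in-memory data frame.
#' @export
read_compound_table <- function(path, delim = NULL, quiet = FALSE) {
  raw <- read_delim_auto(path, delim)
  need <- c("id", "smiles", "label")
  if (!all(need %in% names(raw))) {
    hs_config_error("compound table must have columns %s; found: %s",
                    paste(need, collapse = ", "),
                    paste(names(raw), collapse = ", "))
  }
  if (nrow(raw) == 0) hs_data_error("compound table '%s' has no data rows", path)
  compound_set(raw, quiet = quiet)
}

#' Build a compound set from a data frame
#'
#' @param data Data frame with columns `id`, `smiles`, `label`.
#' @param quiet Suppress the ingest summary message.
#' @return See [read_compound_table()].
#' @export
compound_set <- function(data, quiet = FALSE) {
  data <- tibble::as_tibble(data)[, c("id", "smiles", "label")]
  data$id <- as.character(data$id)
  data$smiles <- as.character(data$smiles)
  lab <- tolower(trimws(as.character(data$label)))
  reason <- rep(NA_character_, nrow(data))
  bad_label <- !lab %in% c("active", "inactive")
  reason[bad_label] <- sprintf("label '%s' not in {active, inactive}",
                               data$label[bad_label])
  dup <- duplicated(data$id)
  reason[dup & is.na(reason)] <- "duplicate id"
  parsed <- parse_molecules(data$smiles)
  unparsed <- vapply(parsed, is.null, logical(1))
  reason[unparsed & is.na(reason)] <- "unparseable SMILES"
  keep <- is.na(reason)
  out <- data[keep, ]
  out$label <- factor(lab[keep], levels = c("active", "inactive"))
  out$canonical <- vapply(parsed[keep], function(m) m$canonical, character(1))
  rejects <- data[!keep, ]
  rejects$reason <- reason[!keep]
  attr(out, "rejects") <- rejects
  attr(out, "molecules") <- parsed[keep]
  class(out) <- c("compound_set", class(out))
  if (!quiet) {
    inform(sprintf(
      "compound set: %d kept (%d active, %d inactive), %d rejected",
      nrow(out), sum(out$label == "active"), sum(out$label == "inactive"),
      nrow(rejects)))
  }
  out
}

#' @rdname compound_set
#' @param x A `compound_set`.
#' @export
compound_counts <- function(x) {
  stopifnot(inherits(x, "compound_set"))
  tibble::tibble(
    n = nrow(x),
    n_active = sum(x$label == "active"),
    n_inactive = sum(x$label == "inactive"),
    n_rejected = nrow(attr(x, "rejects") %||% tibble::tibble())
  )
}

# Parsed molecule list aligned with compound rows (internal).
compound_molecules <- function(x) {
  mols <- attr(x, "molecules")
  if (is.null(mols)) mols <- parse_molecules(x$smiles)
  mols
}

#' Read a herb table with drug-property terms
#'
#' Reads a delimited file with columns `name`, `category`, `natures`,
#' `flavors`, `channels`, `status`. Multi-valued cells are `|`-separated.
#' Terms are normalized (case, whitespace) and validated against the 24-term
#' drug-property vocabulary ([property_vocabulary()]); an unknown term is a
#' data error naming the term and the row. Herbs without any channel-tropism
#' term are retained but flagged `clusterable = FALSE`, since the
#' drug-property cluster model cannot place them.
#'
#' @inheritParams read_compound_table
#' @return A tibble of class `herb_table` with columns `name`, `category`,
#'   `terms` (list column of normalized property terms), `status` (factor
#'   `hepatoprotective` / `non-hepatoprotective` / `undetermined`) and
#'   `clusterable`.
#' @export
read_herb_table <- function(path, delim = NULL) {
  raw <- read_delim_auto(path, delim)
  need <- c("name", "category", "natures", "flavors", "channels", "status")
  if (!all(need %in% names(raw))) {
    hs_config_error("herb table must have columns %s; found: %s",
                    paste(need, collapse = ", "),
                    paste(names(raw), collapse = ", "))
  }
  herb_table(raw)
}

#' @rdname read_herb_table
#' @param data Data frame with the herb-table columns.
#' @export
herb_table <- function(data) {
  data <- tibble::as_tibble(data)
  dup <- unique(data$name[duplicated(data$name)])
  if (length(dup) > 0) {
    hs_data_error("duplicate herb name(s): %s", paste(dup, collapse = ", "))
  }
  vocab <- property_vocabulary()
  fam <- list(natures = HS_NATURES, flavors = HS_FLAVORS,
              channels = HS_CHANNELS)
  terms <- vector("list", nrow(data))
  channel_n <- integer(nrow(data))
  for (i in seq_len(nrow(data))) {
    tt <- character(0)
    for (col in names(fam)) {
      cell <- split_terms(as.character(data[[col]][i]))
      bad <- setdiff(cell, vocab)
      if (length(bad) > 0) {
        hs_data_error("unknown property term '%s' in column '%s', row %d (%s)",
                      bad[1], col, i, data$name[i])
      }
      wrong <- setdiff(cell, fam[[col]])
      if (length(wrong) > 0) {
        hs_data_error("term '%s' is not a valid %s entry (row %d, %s)",
                      wrong[1], sub("s$", "", col), i, data$name[i])
      }
      if (col == "channels") channel_n[i] <- length(cell)
      tt <- c(tt, cell)
    }
    terms[[i]] <- unique(tt)
  }
  status <- tolower(trimws(as.character(data$status)))
  okst <- c("hepatoprotective", "non-hepatoprotective", "undetermined")
  if (!all(status %in% okst)) {
    hs_data_error("status values must be in {%s}; offending: %s",
                  paste(okst, collapse = ", "),
                  paste(unique(setdiff(status, okst)), collapse = ", "))
  }
  out <- tibble::tibble(
    name = as.character(data$name),
    category = as.character(data$category),
    terms = terms,
    status = factor(status, levels = okst),
    clusterable = channel_n > 0
  )
  class(out) <- c("herb_table", class(out))
  out
}

#' Read a herb-ingredient edge list
#'
#' @inheritParams read_compound_table
#' @param registry Optional character vector of known ingredient ids; edges
#'   whose ingredient is absent are a data error.
#' @return A tibble with columns `herb`, `ingredient`; duplicate pairs are
#'   collapsed (count reported via message).
#' @export
read_edge_table <- function(path, delim = NULL, registry = NULL) {
  raw <- read_delim_auto(path, delim)
  need <- c("herb", "ingredient")
  if (!all(need %in% names(raw))) {
    hs_config_error("edge list must have columns %s", paste(need, collapse = ", "))
  }
  edge_table(raw, registry = registry)
}

#' @rdname read_edge_table
#' @param data Data frame with columns `herb` and `ingredient`.
#' @export
edge_table <- function(data, registry = NULL) {
  out <- tibble::tibble(herb = as.character(data$herb),
                        ingredient = normalize_ingredient(data$ingredient))
  ndup <- sum(duplicated(out))
  out <- dplyr::distinct(out)
  if (ndup > 0) inform(sprintf("edge list: collapsed %d duplicate pair(s)", ndup))
  if (!is.null(registry)) {
    missing <- setdiff(out$ingredient, normalize_ingredient(registry))
    if (length(missing) > 0) {
      hs_data_error("edge list ingredient(s) not in registry: %s",
                    paste(head(missing, 5), collapse = ", "))
    }
  }
  out
}

# Ingredient identity convention: trimmed, lowercased names/ids.
normalize_ingredient <- function(x) tolower(trimws(as.character(x)))

#' Write the domain tables back to delimited text
#'
#' Round-trip companions to the readers: writing then reading is the
#' identity on fields (term order inside multi-valued cells follows the
#' vocabulary order).
#'
#' @param x Object to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x)[, c("id", "smiles", "label")], path)
  invisible(path)
}

#' @rdname write_compound_table
#' @export
write_herb_table <- function(x, path) {
  fam <- list(natures = HS_NATURES, flavors = HS_FLAVORS, channels = HS_CHANNELS)
  cells <- lapply(fam, function(f) {
    vapply(x$terms, function(tt) paste(intersect(f, tt), collapse = "|"),
           character(1))
  })
  out <- tibble::tibble(name = x$name, category = x$category,
                        natures = cells$natures, flavors = cells$flavors,
                        channels = cells$channels,
                        status = as.character(x$status))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_compound_table
#' @export
write_edge_table <- function(x, path) {
  readr::write_csv(x[, c("herb", "ingredient")], path)
  invisible(path)
}

# Delimiter auto-detection among comma / tab / semicolon on the header line.
read_delim_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) hs_config_error("file not found: %s", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    counts <- c("," = lengths(regmatches(header, gregexpr(",", header))),
                "\t" = lengths(regmatches(header, gregexpr("\t", header))),
                ";" = lengths(regmatches(header, gregexpr(";", header))))
    delim <- names(counts)[which.max(counts)]
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}
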