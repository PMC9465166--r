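# Structural-alert mining: fragments are generated by recursively breaking
# the acyclic single bonds of each active molecule (rings are never opened),
# scored by the likelihood ratio
#     LR = (tp / P) / (fp / N)
# with P and N the active/inactive class totals and tp/fp the number of
# compounds of each class containing the fragment (a compound counts once
# regardless of match multiplicity), and filtered by minimum LR and minimum
# frequency. A fragment present in no inactive has LR = +Inf and sorts above
# every finite LR.
#
# Matching is Open Babel SMARTS substructure search. Two provable shortcuts
# keep mining fast: a fragment obtained by cutting a molecule is by
# construction a substructure of it (definite hit), and a fragment whose
# element counts exceed a molecule's cannot match it (definite miss); only
# the residual pairs go to the SMARTS engine.

#' Miner configuration
#'
#' @param min_lr Minimum likelihood ratio (default 10; must exceed 1).
#' @param min_freq Minimum number of active compounds containing the
#'   fragment (default 10).
#' @param min_atoms,max_atoms Heavy-atom bounds for generated fragments
#'   (defaults 2 and 18).
#' @param extraction_mode `"score_all"` (score every fragment, then drop
#'   rules whose matched active set is a subset of an already-accepted
#'   rule's) or `"iterative_cover"` (after accepting a rule, remove the
#'   actives it matches and rescore until nothing passes the thresholds).
#' @return A list of class `miner_config`.
#' @export
miner_config <- function(min_lr = 10, min_freq = 10, min_atoms = 2,
                         max_atoms = 18,
                         extraction_mode = c("score_all", "iterative_cover")) {
  extraction_mode <- match.arg(extraction_mode)
  if (min_lr <= 1) hs_config_error("min_lr must be > 1")
  if (min_freq < 1) hs_config_error("min_freq must be >= 1")
  if (min_atoms < 2) hs_config_error("min_atoms must be >= 2")
  if (max_atoms < min_atoms) hs_config_error("max_atoms < min_atoms")
  structure(list(min_lr = min_lr, min_freq = min_freq, min_atoms = min_atoms,
                 max_atoms = max_atoms, extraction_mode = extraction_mode),
            class = "miner_config")
}

#' Likelihood-ratio statistics for one fragment
#'
#' The arithmetic core of alert scoring: given occurrence counts and class
#' totals, returns the likelihood ratio (`+Inf` when `fp == 0`) and the
#' precision percentage `100 * tp / (tp + fp)`.
#'
#' @param tp,fp Occurrence counts among actives / inactives.
#' @param n_active,n_inactive Class totals (P and N).
#' @return A one-row tibble with `tp`, `fp`, `lr`, `precision_pct`.
#' @examples
#' alert_statistics(41, 1, 536, 171) # lr 13.08, precision 97.62
#' @export
alert_statistics <- function(tp, fp, n_active, n_inactive) {
  if (n_active < 1 || n_inactive < 1) {
    hs_data_error("both class totals must be >= 1")
  }
  lr <- if (tp + fp == 0) NA_real_
        else if (fp == 0) Inf
        else (tp / n_active) / (fp / n_inactive)
  tibble::tibble(
    tp = as.integer(tp), fp = as.integer(fp), lr = lr,
    precision_pct = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  )
}

#' Generate candidate fragments from the active molecules
#'
#' Recursively breaks every acyclic single bond of each active molecule
#' (ring systems stay intact), keeps connected fragments within the
#' configured heavy-atom bounds, and deduplicates by canonical SMILES.
#'
#' @param compounds A [compound_set()].
#' @param config A [miner_config()].
#' @return A tibble of class `fragment_set` with columns `pattern`
#'   (canonical SMILES, usable as SMARTS), `n_heavy_atoms`, `n_sources`
#'   (number of distinct active structures the fragment was generated from).
#' @export
generate_fragments <- function(compounds, config = miner_config()) {
  idx <- frag_match_index(compounds, config)
  frags <- idx$fragments
  out <- tibble::tibble(pattern = frags$pattern,
                        n_heavy_atoms = frags$n_heavy_atoms,
                        n_sources = frags$n_sources)
  class(out) <- c("fragment_set", class(out))
  out
}

#' Score one fragment against a compound set
#'
#' Counts the active (`tp`) and inactive (`fp`) compounds containing the
#' fragment by SMARTS substructure matching and derives the likelihood
#' ratio and precision via [alert_statistics()].
#'
#' @param pattern Fragment expression (SMARTS; a fragment SMILES works).
#' @param compounds A [compound_set()].
#' @return A one-row tibble `pattern`, `tp`, `fp`, `lr`, `precision_pct`;
#'   the matched compound ids are attached as attribute `"matched_ids"`.
#' @export
score_fragment <- function(pattern, compounds) {
  stopifnot(inherits(compounds, "compound_set"))
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(compounds$canonical, compounds$id)))
  hits <- smarts_hits(sdfset, pattern) > 0
  tp <- sum(hits & compounds$label == "active")
  fp <- sum(hits & compounds$label == "inactive")
  st <- alert_statistics(tp, fp, sum(compounds$label == "active"),
                         sum(compounds$label == "inactive"))
  out <- dplyr::bind_cols(tibble::tibble(pattern = pattern), st)
  attr(out, "matched_ids") <- compounds$id[hits]
  out
}

#' Mine structural alerts
#'
#' Generates all fragments from the actives, scores them, discards those
#' failing the frequency or likelihood-ratio thresholds and ranks the
#' survivors (infinite LR first, then LR descending, occurrences
#' descending, fewer heavy atoms, canonical form). In `score_all` mode a
#' redundancy filter then drops any rule whose matched active set is a
#' subset of an already-accepted rule's; in `iterative_cover` mode the
#' matched actives of each accepted rule are removed and scoring repeats.
#'
#' @inheritParams generate_fragments
#' @return A tibble of class `alert_rules` with columns `id`, `pattern`,
#'   `n_heavy_atoms`, `tp`, `fp`, `lr`, `precision_pct`; attributes
#'   `matched_ids` (named list of matched active ids per rule) and
#'   `config`. Empty (with a warning) when nothing passes the thresholds.
#' @export
mine_alerts <- function(compounds, config = miner_config()) {
  P <- sum(compounds$label == "active")
  N <- sum(compounds$label == "inactive")
  if (P < 1 || N < 1) hs_data_error("both classes must be non-empty")
  idx <- frag_match_index(compounds, config)
  scored <- idx$fragments
  scored$tp <- as.integer(lengths(idx$matched_active_ids))
  scored$fp <- as.integer(idx$matched_inactive_n)
  st <- alert_statistics_vec(scored$tp, scored$fp, P, N)
  scored$lr <- st$lr
  scored$precision_pct <- st$precision_pct

  if (config$extraction_mode == "score_all") {
    pass <- scored$tp >= config$min_freq &
      (is.infinite(scored$lr) | (!is.na(scored$lr) &
                                   scored$lr >= config$min_lr))
    ranked <- rank_rules(scored[pass, ])
    accepted <- list()
    accepted_sets <- list()
    for (i in seq_len(nrow(ranked))) {
      ids <- idx$matched_active_ids[[ranked$pattern[i]]]
      redundant <- any(vapply(accepted_sets, function(s) all(ids %in% s),
                              logical(1)))
      if (!redundant) {
        accepted[[length(accepted) + 1]] <- ranked[i, ]
        accepted_sets[[length(accepted_sets) + 1]] <- ids
      }
    }
    rules <- dplyr::bind_rows(accepted)
    matched <- accepted_sets
  } else {
    remaining <- idx$active_ids
    rules <- list()
    matched <- list()
    repeat {
      live <- scored
      live$tp <- vapply(live$pattern, function(p) {
        length(intersect(idx$matched_active_ids[[p]], remaining))
      }, integer(1))
      st <- alert_statistics_vec(live$tp, live$fp, P, N)
      live$lr <- st$lr
      live$precision_pct <- st$precision_pct
      live <- live[live$tp >= config$min_freq &
                     (is.infinite(live$lr) | live$lr >= config$min_lr), ]
      if (nrow(live) == 0) break
      top <- rank_rules(live)[1, ]
      rules[[length(rules) + 1]] <- top
      hit <- intersect(idx$matched_active_ids[[top$pattern]], remaining)
      matched[[length(matched) + 1]] <- hit
      remaining <- setdiff(remaining, hit)
      if (length(remaining) == 0) break
    }
    rules <- dplyr::bind_rows(rules)
  }

  if (is.null(rules) || nrow(rules) == 0) {
    warn("no fragment passed the LR/frequency thresholds; empty rule set")
    rules <- tibble::tibble(id = integer(), pattern = character(),
                            n_heavy_atoms = integer(), tp = integer(),
                            fp = integer(), lr = double(),
                            precision_pct = double())
  } else {
    rules <- dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(rules))),
                              rules[, c("pattern", "n_heavy_atoms", "tp",
                                        "fp", "lr", "precision_pct")])
  }
  names(matched) <- rules$pattern[seq_along(matched)]
  attr(rules, "matched_ids") <- matched
  attr(rules, "config") <- config
  attr(rules, "class_totals") <- c(n_active = P, n_inactive = N)
  class(rules) <- c("alert_rules", class(rules))
  rules
}

alert_statistics_vec <- function(tp, fp, P, N) {
  lr <- ifelse(tp + fp == 0, NA_real_,
               ifelse(fp == 0, Inf, (tp / P) / (fp / N)))
  tibble::tibble(lr = lr,
                 precision_pct = ifelse(tp + fp == 0, NA_real_,
                                        100 * tp / (tp + fp)))
}

# threshold filter + canonical rule ordering
rank_rules <- function(tbl) {
  ord <- order(-is.infinite(tbl$lr),
               -ifelse(is.infinite(tbl$lr), tbl$tp, tbl$lr),
               -tbl$tp, tbl$n_heavy_atoms, tbl$pattern)
  tbl[ord, ]
}

# --- matching machinery ----------------------------------------------------

# Build the fragment/molecule match index:
#   structures: unique canonical SMILES with per-class multiplicities
#   fragments:  deduplicated fragments from the active structures
#   matched_active_ids / matched per structure, computed exactly
frag_match_index <- function(compounds, config) {
  stopifnot(inherits(compounds, "compound_set"))
  mols <- compound_molecules(compounds)
  canon <- compounds$canonical
  uniq <- unique(canon)
  mol_of <- mols[match(uniq, canon)]
  act_ids <- split(compounds$id[compounds$label == "active"],
                   canon[compounds$label == "active"])
  inact_ids <- split(compounds$id[compounds$label == "inactive"],
                     canon[compounds$label == "inactive"])
  is_active_struct <- uniq %in% names(act_ids)

  # enumerate cut fragments per unique structure (aromaticity perceived on
  # the parent and inherited by its fragments, rings being kept intact)
  frag_graphs <- list()
  frag_owner <- integer(0)
  struct_frag <- vector("list", length(uniq)) # canonical patterns per structure
  struct_arom <- vector("list", length(uniq))
  for (si in seq_along(uniq)) {
    struct_arom[[si]] <- perceive_aromatic(mol_of[[si]]$sdf, mol_of[[si]])
    sets <- cut_fragment_graphs(mol_of[[si]], config$min_atoms,
                                config$max_atoms, arom = struct_arom[[si]])
    if (length(sets) > 0) {
      frag_graphs <- c(frag_graphs, sets)
      frag_owner <- c(frag_owner, rep(si, length(sets)))
    }
  }
  frag_canon <- canonical_from_graphs(frag_graphs)
  ok <- !is.na(frag_canon)
  frag_canon <- frag_canon[ok]
  frag_graphs <- frag_graphs[ok]
  frag_owner <- frag_owner[ok]
  for (si in seq_along(uniq)) {
    struct_frag[[si]] <- unique(frag_canon[frag_owner == si])
  }

  # fragment universe: fragments generated from active structures
  from_active <- frag_owner %in% which(is_active_struct)
  pat <- unique(frag_canon[from_active])
  first <- match(pat, frag_canon)
  fragments <- tibble::tibble(
    pattern = pat,
    n_heavy_atoms = vapply(frag_graphs[first],
                           function(g) length(g$elem), integer(1)),
    n_sources = vapply(pat, function(p) {
      length(unique(frag_owner[from_active & frag_canon == p]))
    }, integer(1))
  )
  fragments <- fragments[order(fragments$pattern), ]

  # element counts
  struct_elem <- lapply(mol_of, function(m) element_counts(m$elem))
  frag_elem <- lapply(frag_graphs[match(fragments$pattern, frag_canon)],
                      function(g) element_counts(g$elem))

  # membership matrix fragment x structure, resolved exactly
  contains <- matrix(NA, nrow = nrow(fragments), ncol = length(uniq),
                     dimnames = list(fragments$pattern, NULL))
  for (si in seq_along(uniq)) {
    contains[, si] <- fragments$pattern %in% struct_frag[[si]]
    contains[!contains[, si], si] <- NA # not yet known
  }
  for (fi in seq_len(nrow(fragments))) {
    unknown <- which(is.na(contains[fi, ]))
    if (length(unknown) == 0) next
    compat <- vapply(unknown, function(si) {
      elements_compatible(frag_elem[[fi]], struct_elem[[si]])
    }, logical(1))
    contains[fi, unknown[!compat]] <- FALSE
  }
  # residual pairs -> labelled subgraph-monomorphism verification
  residual <- which(is.na(contains), arr.ind = TRUE)
  if (nrow(residual) > 0) {
    first_graph <- frag_graphs[match(fragments$pattern, frag_canon)]
    tgt_g <- vector("list", length(uniq))
    pat_g <- vector("list", nrow(fragments))
    for (r in seq_len(nrow(residual))) {
      fi <- residual[r, 1]
      si <- residual[r, 2]
      if (is.null(pat_g[[fi]])) {
        fg <- first_graph[[fi]]
        pat_g[[fi]] <- match_graph(fg$elem, fg$bonds, fg$arom_atom,
                                   fg$arom_bond)
      }
      if (is.null(tgt_g[[si]])) {
        m <- mol_of[[si]]
        ar <- struct_arom[[si]]
        tgt_g[[si]] <- match_graph(m$elem, m$bonds, ar$atom, ar$bond)
      }
      contains[fi, si] <- subgraph_match(pat_g[[fi]], tgt_g[[si]])
    }
  }

  matched_active_ids <- lapply(seq_len(nrow(fragments)), function(fi) {
    sel <- which(contains[fi, ] & is_active_struct)
    unlist(act_ids[uniq[sel]], use.names = FALSE)
  })
  names(matched_active_ids) <- fragments$pattern
  matched_inactive_n <- vapply(seq_len(nrow(fragments)), function(fi) {
    sel <- which(contains[fi, ] & uniq %in% names(inact_ids))
    length(unlist(inact_ids[uniq[sel]], use.names = FALSE))
  }, integer(1))

  list(fragments = fragments,
       matched_active_ids = matched_active_ids,
       matched_inactive_n = matched_inactive_n,
       active_ids = compounds$id[compounds$label == "active"])
}

# Enumerate the connected fragments of one molecule obtainable by cutting
# acyclic single bonds. Non-cuttable bonds (ring bonds, double/triple bonds)
# are contracted into blocks; the blocks form a tree whose connected
# subtrees are exactly the fragments. Returns a list of graphs
# list(elem=, bonds=) within the heavy-atom bounds.
cut_fragment_graphs <- function(mol, min_atoms, max_atoms, arom = NULL) {
  n <- length(mol$elem)
  bonds <- mol$bonds
  g <- mol_igraph(mol)
  cuttable <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    br <- as.integer(igraph::bridges(g))
    cuttable[br] <- bonds$order[br] == 1
  }
  # blocks: components after removing cuttable bonds
  gk <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (any(!cuttable)) {
    gk <- igraph::add_edges(gk, as.vector(rbind(bonds$a[!cuttable],
                                                bonds$b[!cuttable])))
  }
  block <- igraph::components(gk)$membership
  nb <- max(block)
  block_atoms <- split(seq_len(n), block)
  block_size <- lengths(block_atoms)
  # block tree adjacency from cuttable bonds
  adj <- vector("list", nb)
  for (i in which(cuttable)) {
    u <- block[bonds$a[i]]; v <- block[bonds$b[i]]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  subsets <- connected_subtrees(adj, nb, block_size, max_atoms)
  out <- list()
  for (s in subsets) {
    atoms <- sort(unlist(block_atoms[s], use.names = FALSE))
    na <- length(atoms)
    if (na < min_atoms || na > max_atoms) next
    keep <- which(bonds$a %in% atoms & bonds$b %in% atoms)
    remap <- match(seq_len(n), atoms)
    out[[length(out) + 1]] <- list(
      elem = mol$elem[atoms],
      bonds = list(a = remap[bonds$a[keep]], b = remap[bonds$b[keep]],
                   order = bonds$order[keep]),
      arom_atom = if (is.null(arom)) rep(FALSE, na) else arom$atom[atoms],
      arom_bond = if (is.null(arom)) rep(FALSE, length(keep)) else
        arom$bond[keep]
    )
  }
  out
}

# ESU-style enumeration of connected subtrees of the block tree, pruned by
# cumulative atom count.
connected_subtrees <- function(adj, n, sizes, max_atoms) {
  res <- list()
  recurse <- function(S, size, ext, root) {
    res[[length(res) + 1]] <<- S
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      if (size + sizes[w] <= max_atoms) {
        nbr <- adj[[w]]
        newext <- c(ext, setdiff(nbr[nbr > root], c(S, ext, w)))
        recurse(c(S, w), size + sizes[w], newext, root)
      }
    }
  }
  for (r in seq_len(n)) {
    if (sizes[r] <= max_atoms) {
      nbr <- adj[[r]]
      recurse(r, sizes[r], unique(nbr[nbr > r]), r)
    }
  }
  res
}

#' Write mined alert rules to delimited text
#'
#' Columns `id`, `pattern`, `tp`, `fp`, `lr` (the literal `inf` for an
#' infinite likelihood ratio), `precision_pct`; the thresholds used are
#' recorded in `#`-prefixed header lines. A sidecar file
#' `<path>.matches.csv` lists the matched active ids per rule.
#'
#' @param rules An `alert_rules` tibble from [mine_alerts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alert_rules <- function(rules, path) {
  cfg <- attr(rules, "config")
  hdr <- sprintf("# min_lr=%s min_freq=%s mode=%s", cfg$min_lr, cfg$min_freq,
                 cfg$extraction_mode)
  lr_txt <- ifelse(is.infinite(rules$lr), "inf",
                   formatC(rules$lr, digits = 4, format = "fg"))
  lines <- c(hdr, "id,pattern,tp,fp,lr,precision_pct",
             paste(rules$id, rules$pattern, rules$tp, rules$fp, lr_txt,
                   sprintf("%.2f", rules$precision_pct), sep = ","))
  writeLines(lines, path)
  m <- attr(rules, "matched_ids")
  side <- tibble::tibble(
    pattern = rep(names(m), lengths(m)),
    id = unlist(m, use.names = FALSE)
  )
  readr::write_csv(side, paste0(path, ".matches.csv"))
  invisible(path)
}
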