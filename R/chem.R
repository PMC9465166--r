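# Chemistry layer: SMILES parsing, canonicalization, molecular graphs and
# substructure matching, built on ChemmineR/ChemmineOB (Open Babel).
#
# A parsed molecule is a plain list:
#   elem      character vector of element symbols, one per heavy atom
#   bonds     tibble(a, b, order) with 1-based atom indices (kekulized orders)
#   canonical canonical SMILES (Open Babel "can" format)
#   sdf       the ChemmineR::SDF object (kept for SMARTS matching)

parse_molecule <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) return(NULL)
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  if (nrow(ab) == 0) return(NULL)
  elem <- sub("_.*$", "", rownames(ab))
  if (!is.null(bb) && !is.matrix(bb)) bb <- matrix(bb, nrow = 1)
  bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
    tibble::tibble(a = integer(), b = integer(), order = integer())
  } else {
    tibble::tibble(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  can <- canonical_from_graph(elem, bonds)
  if (is.na(can)) return(NULL)
  list(elem = elem, bonds = bonds, canonical = can, sdf = sdf1)
}

# Parse a vector of SMILES, memoizing on the raw string. Returns a list the
# same length as `smiles` with NULL entries for unparseable structures.
parse_molecules <- function(smiles) {
  uniq <- unique(smiles)
  parsed <- lapply(uniq, parse_molecule)
  names(parsed) <- uniq
  parsed[smiles]
}

# Serialize a (fragment) graph to a minimal V2000 molfile. Open Babel infers
# implicit hydrogens at the free valences left by cut bonds, which is exactly
# the convention used when writing fragment SMILES.
v2000_text <- function(elem, bonds, name = "frag") {
  n_a <- length(elem)
  n_b <- length(bonds$a)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b)
  atoms <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    elem
  )
  bl <- if (n_b > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a, bonds$b, bonds$order)
  } else {
    character(0)
  }
  paste(c(name, "  herbscreen", "", counts, atoms, bl, "M  END", "$$$$"),
        collapse = "\n")
}

# Canonical SMILES of one graph; NA if Open Babel cannot interpret it.
canonical_from_graph <- function(elem, bonds) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", v2000_text(elem, bonds)),
    error = function(e) NA_character_
  )
  if (is.na(out) || !nzchar(out)) return(NA_character_)
  strip_smiles_line(out)[1]
}

# Batched canonicalization of many graphs (one Open Babel call per chunk).
# graphs: list of list(elem=, bonds=). Returns a character vector.
canonical_from_graphs <- function(graphs, chunk = 200L) {
  if (length(graphs) == 0) return(character(0))
  out <- character(length(graphs))
  idx <- split(seq_along(graphs), ceiling(seq_along(graphs) / chunk))
  for (ii in idx) {
    txt <- paste(vapply(graphs[ii], function(g) {
      v2000_text(g$elem, g$bonds)
    }, character(1)), collapse = "\n")
    res <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", txt),
                    error = function(e) NA_character_)
    lines <- if (is.na(res)) rep(NA_character_, length(ii)) else
      strip_smiles_line(res)
    if (length(lines) != length(ii)) {
      # fall back to one-by-one on any surprise
      lines <- vapply(graphs[ii], function(g) {
        canonical_from_graph(g$elem, g$bonds)
      }, character(1))
    }
    out[ii] <- lines
  }
  out
}

strip_smiles_line <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  sub("[\t ].*$", "", lines)
}

# Count SMARTS matches of `pattern` in each molecule of an SDFset;
# returns integer vector (number of unique matches, 0 = no match).
smarts_hits <- function(sdfset, pattern) {
  if (length(sdfset) == 0) return(integer(0))
  res <- tryCatch(
    ChemmineR::smartsSearchOB(sdfset, pattern, uniqueMatches = TRUE),
    error = function(e) rep(NA_integer_, length(sdfset))
  )
  as.integer(res)
}

# Element count table for a molecule / fragment: named integer vector.
element_counts <- function(elem) {
  tab <- table(elem)
  stats::setNames(as.integer(tab), names(tab))
}

# TRUE if fragment element counts fit inside the molecule's.
elements_compatible <- function(frag_counts, mol_counts) {
  all(names(frag_counts) %in% names(mol_counts)) &&
    all(frag_counts <= mol_counts[names(frag_counts)])
}

# Aromatic perception via ChemmineR ring analysis on the kekulized SDF:
# atoms and bonds lying on an aromatic ring are flagged, so two different
# kekulizations of the same ring compare equal during matching.
perceive_aromatic <- function(sdf, mol) {
  n <- length(mol$elem)
  out <- list(atom = rep(FALSE, n), bond = rep(FALSE, nrow(mol$bonds)))
  if (nrow(mol$bonds) == 0) return(out)
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(rr) || length(rr$RINGS) == 0) return(out)
  bond_key <- paste(pmin(mol$bonds$a, mol$bonds$b),
                    pmax(mol$bonds$a, mol$bonds$b))
  for (k in seq_along(rr$RINGS)) {
    if (!isTRUE(rr$AROMATIC[[k]])) next
    idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
    out$atom[idx] <- TRUE
    ring_pairs <- paste(pmin(idx, c(idx[-1], idx[1])),
                        pmax(idx, c(idx[-1], idx[1])))
    out$bond[bond_key %in% ring_pairs] <- TRUE
  }
  out
}

# Vertex-labelled match graph: bonds become subdivision vertices labelled by
# order (aromatic ring bonds get one shared label), so LAD monomorphism
# with label domains implements substructure matching with atom and bond
# type constraints.
match_graph <- function(elem, bonds, atom_arom, bond_arom) {
  na <- length(elem)
  nb <- length(bonds$a)
  lab <- c(paste0(elem, ifelse(atom_arom, ":ar", "")),
           if (nb > 0) paste0("B", ifelse(bond_arom, "ar", bonds$order)))
  g <- igraph::make_empty_graph(na + nb, directed = FALSE)
  if (nb > 0) {
    g <- igraph::add_edges(g, as.vector(rbind(
      c(bonds$a, na + seq_len(nb)),
      c(na + seq_len(nb), bonds$b))))
  }
  structure(list(g = g, lab = lab,
                 index = split(seq_along(lab), lab),
                 counts = table(lab)),
            class = "hs_match_graph")
}

# TRUE iff the pattern graph embeds in the target graph (label-preserving
# injective monomorphism). A label-multiset prefilter rejects impossible
# embeddings before the LAD search runs.
subgraph_match <- function(pat, tgt) {
  pc <- pat$counts
  tc <- tgt$counts
  if (!all(names(pc) %in% names(tc)) || any(pc > tc[names(pc)])) return(FALSE)
  doms <- tgt$index[pat$lab]
  igraph::subgraph_isomorphic(pat$g, tgt$g, method = "lad", induced = FALSE,
                              domains = doms)
}

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = length(mol$elem), directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, as.vector(rbind(mol$bonds$a, mol$bonds$b)))
  }
  g
}
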