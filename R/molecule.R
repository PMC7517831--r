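#' @importFrom methods as
NULL

# ---- light molecule representation ------------------------------------------
#
# A Molecule is a list(atoms, bonds, id):
#   atoms: data.frame(element, x, y, z, charge, explicit_h)
#   bonds: data.frame(a1, a2, order) with order 1/2/3 and 4 = aromatic
# built from ChemmineR SDF objects so every reader shares one code path.

#' Convert a ChemmineR SDF to a Molecule
#'
#' @param sdf a `ChemmineR::SDF` object.
#' @param id compound id.
#' @return An object of class `Molecule`.
#' @export
as_molecule <- function(sdf, id = "mol") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_[0-9]+$", "", rownames(ab))
  # MDL old-style charge codes (field 5 of the atom line, ChemmineR column
  # "C6"): 1..3 => +3..+1, 5..7 => -1..-3
  code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, nrow(ab))
  charge <- ifelse(code == 0, 0, 4 - code)
  atoms <- data.frame(
    element = toupper(elem),
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    charge = as.integer(charge),
    stringsAsFactors = FALSE
  )
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, id = id), class = "Molecule")
  mol$atoms$explicit_h <- count_explicit_h(mol)
  mol
}

#' Read molecules from an SDF file or string
#'
#' @param x path to an SDF file, or a character scalar holding SDF text.
#' @return named list of `Molecule` objects.
#' @export
read_molecules_sdf <- function(x) {
  if (length(x) == 1 && !file.exists(x) && grepl("\n", x)) {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf))
    writeLines(x, tf)
    x <- tf
  }
  sdfset <- ChemmineR::read.SDFset(x)
  ids <- ChemmineR::sdfid(sdfset)
  ids[is.na(ids) | ids == ""] <- paste0("mol", which(is.na(ids) | ids == ""))
  ids <- make.unique(ids)
  out <- lapply(seq_along(sdfset), function(i) as_molecule(sdfset[[i]], ids[i]))
  names(out) <- ids
  out
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("Molecule %s: %d atoms (%d heavy), %d bonds\n", x$id,
              nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds)))
  invisible(x)
}

heavy_idx <- function(mol) which(mol$atoms$element != "H")

mol_xyz <- function(mol, idx = seq_len(nrow(mol$atoms))) {
  as.matrix(mol$atoms[idx, c("x", "y", "z")])
}

count_explicit_h <- function(mol) {
  nh <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds) == 0) return(nh)
  ish <- mol$atoms$element == "H"
  for (r in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[r]; b <- mol$bonds$a2[r]
    if (ish[b]) nh[a] <- nh[a] + 1L
    if (ish[a]) nh[b] <- nh[b] + 1L
  }
  nh
}

# Total (explicit + implicit) hydrogens per atom, from standard valences.
# Aromatic bonds (order 4) count 1.5; the per-atom sum is rounded.
total_h_count <- function(mol) {
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1, BR = 1, I = 1, B = 3)
  deg <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (r in seq_len(nrow(mol$bonds))) {
      deg[mol$bonds$a1[r]] <- deg[mol$bonds$a1[r]] + ord[r]
      deg[mol$bonds$a2[r]] <- deg[mol$bonds$a2[r]] + ord[r]
    }
  }
  el <- mol$atoms$element
  v <- valence[el]
  v[is.na(v)] <- 0
  # effective valence: N+ 4, O- 1 (charge adds for N/O); C ions lose a bond
  chg <- mol$atoms$charge
  v_eff <- v + ifelse(el == "C", -abs(chg), chg)
  imp <- pmax(0, round(v_eff - deg))
  # explicit hydrogens already count in deg; imp is the implicit remainder
  ifelse(el == "H", 0L, mol$atoms$explicit_h + imp)
}

mol_graph <- function(mol, heavy_only = TRUE) {
  idx <- if (heavy_only) heavy_idx(mol) else seq_len(nrow(mol$atoms))
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  b <- mol$bonds
  keep <- !is.na(remap[b$a1]) & !is.na(remap[b$a2])
  el <- cbind(remap[b$a1[keep]], remap[b$a2[keep]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::V(g)$element <- mol$atoms$element[idx]
  igraph::V(g)$orig <- idx
  igraph::E(g)$order <- mol$bonds$order[keep]
  g
}

# Simple rings of length 3..max_len among heavy atoms, as lists of original
# atom indices. DFS-based; molecules handled here are small.
find_rings <- function(mol, max_len = 7) {
  g <- mol_graph(mol, heavy_only = TRUE)
  n <- igraph::vcount(g)
  if (n == 0) return(list())
  adj <- igraph::as_adj_list(g)
  rings <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in as.integer(adj[[last]])) {
      if (nb == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < max_len && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  # keep minimal rings only: drop rings that are unions of smaller ones
  rings <- rings[order(lengths(rings))]
  minimal <- list()
  for (r in rings) {
    contained <- any(vapply(minimal, function(m) all(m %in% r), logical(1)))
    sz_ok <- length(r) <= max_len
    if (!contained && sz_ok) minimal[[length(minimal) + 1]] <- r
  }
  orig <- igraph::V(g)$orig
  lapply(minimal, function(r) orig[r])
}

# Aromatic iff every ring bond has MDL order 4, or the ring is a 6-ring of
# C/N with alternating single/double bonds (kekulized aromatic).
ring_is_aromatic <- function(mol, ring) {
  n <- length(ring)
  ords <- integer(n)
  for (i in seq_len(n)) {
    a <- ring[i]; b <- ring[(i %% n) + 1]
    hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
                   (mol$bonds$a1 == b & mol$bonds$a2 == a))
    if (length(hit) == 0) return(FALSE)
    ords[i] <- mol$bonds$order[hit[1]]
  }
  if (all(ords == 4)) return(TRUE)
  el <- mol$atoms$element[ring]
  if (n == 6 && all(el %in% c("C", "N")) &&
      sum(ords == 1) == 3 && sum(ords == 2) == 3 &&
      all(abs(diff(c(ords, ords[1]))) == 1)) {
    return(TRUE)
  }
  FALSE
}

# ---- SMILES helpers (OpenBabel-backed) --------------------------------------

#' Canonicalize SMILES strings
#'
#' Canonical form via OpenBabel; unparseable entries return `NA` (with a
#' warning) rather than failing the batch.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  out <- vapply(smiles, function(s) {
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
      error = function(e) ""
    )
    res <- sub("[\t\n ].*$", "", res)
    if (!nzchar(res)) NA_character_ else res
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " SMILES failed to parse and were marked NA")
  }
  out
}

#' Parse SMILES into Molecule objects (2D, no coordinates guaranteed)
#' @param smiles character vector.
#' @param ids compound ids.
#' @return named list of `Molecule`s; unparseable entries are dropped with a warning.
#' @export
smiles_to_molecules <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  ok <- !is.na(canonical_smiles(smiles))
  if (!all(ok)) warning(sum(!ok), " unparseable SMILES dropped")
  smiles <- smiles[ok]; ids <- ids[ok]
  sdf <- ChemmineR::smiles2sdf(smiles)
  out <- lapply(seq_along(smiles), function(i) as_molecule(sdf[[i]], ids[i]))
  names(out) <- ids
  out
}

#' Embed a 3D conformer for a SMILES string
#'
#' Deterministic 3D coordinate generation (OpenBabel `gen3D`, which also adds
#' explicit hydrogens). One conformer per molecule; screening at higher
#' conformational resolution should supply multi-conformer SDF input instead.
#'
#' @param smiles single SMILES string.
#' @param id compound id.
#' @return a `Molecule` with 3D coordinates.
#' @export
embed_conformer <- function(smiles, id = "mol") {
  sdf_txt <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(smiles, "\t", id, "\n"),
    options = data.frame(names = "gen3D", args = "best")
  )
  read_molecules_sdf(sdf_txt)[[1]]
}

#' ECFP4 fingerprints for a set of SMILES
#'
#' Hashed circular fingerprints (radius 2) computed by OpenBabel, returned as
#' a logical matrix (compounds x bits) for Tanimoto arithmetic.
#'
#' @param smiles character vector.
#' @param ids row names.
#' @return logical matrix.
#' @export
fingerprint_matrix <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  sdf <- suppressWarnings({ChemmineR::cid(sdf) <- ids; sdf})
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  m <- methods::slot(fp, "fpma") == 1
  rownames(m) <- ids
  m
}

#' Tanimoto distance between fingerprint rows
#' @param m logical fingerprint matrix.
#' @param i,j row indices or names.
#' @return numeric distance in \[0, 1\] (1 - Tanimoto similarity).
#' @export
tanimoto_distance <- function(m, i, j) {
  a <- m[i, ]; b <- m[j, ]
  un <- sum(a | b)
  if (un == 0) return(0)
  1 - sum(a & b) / un
}
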