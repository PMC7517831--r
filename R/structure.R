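#' Read a receptor-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records with [bio3d::read.pdb()] and splits the
#' structure into protein atoms and the designated bound ligand. Alternate
#' conformations keep altloc ' ' or 'A'. Resolution is taken from the
#' `REMARK   2 RESOLUTION.` record when present, else `NA` (it can also be
#' supplied explicitly, which wins).
#'
#' @param path PDB file path.
#' @param ligand_resname het-group residue name (e.g. `"LIG"`, `"ATP"`)
#'   designating the bound ligand.
#' @param ligand_chain optional chain of the ligand copy to use; default takes
#'   all matching het atoms.
#' @param structure_id identifier; defaults to the file name without extension.
#' @param resolution optional resolution in Angstrom, overriding the header.
#' @return An object of class `ParsedStructure`: list with `structure_id`,
#'   `atoms` (data.frame: atom_name, element, residue_number, residue_name,
#'   chain, x, y, z), `ligand_atoms` (same schema) and `resolution`.
#' @export
read_complex_pdb <- function(path, ligand_resname, ligand_chain = NULL,
                             structure_id = NULL, resolution = NULL) {
  if (missing(ligand_resname) || is.null(ligand_resname)) {
    stop("read_complex_pdb: a ligand residue name must be designated")
  }
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]+$", "", basename(path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", " ", "A"), , drop = FALSE]

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- element_from_atom_name(at$elety)
  } else {
    miss <- is.na(elem) | elem == ""
    elem[miss] <- element_from_atom_name(at$elety[miss])
  }
  df <- data.frame(
    atom_name = at$elety, element = toupper(elem),
    residue_number = at$resno, residue_name = at$resid, chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    record = at$type, stringsAsFactors = FALSE
  )
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("read_complex_pdb: non-finite coordinates in ", path)
  }
  is_lig <- df$residue_name == ligand_resname
  if (!is.null(ligand_chain)) is_lig <- is_lig & df$chain == ligand_chain
  lig <- df[is_lig, , drop = FALSE]
  if (nrow(lig) == 0) {
    stop("read_complex_pdb: designated ligand '", ligand_resname,
         "' not found in ", path)
  }
  prot <- df[!is_lig & df$record == "ATOM", , drop = FALSE]

  if (is.null(resolution)) resolution <- parse_pdb_resolution(path)

  structure(
    list(structure_id = structure_id, atoms = prot, ligand_atoms = lig,
         resolution = resolution),
    class = "ParsedStructure"
  )
}

#' Read a receptor-only PDB file (no designated ligand)
#'
#' Same parsing as [read_complex_pdb()] but without a bound ligand; the
#' result can serve as the receptor argument of [generate_models()].
#'
#' @inheritParams read_complex_pdb
#' @return a `ParsedStructure` with empty `ligand_atoms`.
#' @export
read_receptor_pdb <- function(path, structure_id = NULL, resolution = NULL) {
  if (is.null(structure_id)) structure_id <- sub("\\.[^.]+$", "", basename(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", " ", "A"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- element_from_atom_name(at$elety)
  } else {
    miss <- is.na(elem) | elem == ""
    elem[miss] <- element_from_atom_name(at$elety[miss])
  }
  df <- data.frame(
    atom_name = at$elety, element = toupper(elem),
    residue_number = at$resno, residue_name = at$resid, chain = at$chain,
    x = at$x, y = at$y, z = at$z, record = at$type, stringsAsFactors = FALSE
  )
  if (is.null(resolution)) resolution <- parse_pdb_resolution(path)
  structure(
    list(structure_id = structure_id, atoms = df[df$record == "ATOM", , drop = FALSE],
         ligand_atoms = df[0, , drop = FALSE], resolution = resolution),
    class = "ParsedStructure"
  )
}

parse_pdb_resolution <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(hit) == 0) return(NA_real_)
  tail_part <- sub(".*RESOLUTION\\.", "", hit[1])
  m <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
  if (length(m) == 0) NA_real_ else as.numeric(m)
}

element_from_atom_name <- function(name) {
  # PDB atom names: element is the alphabetic prefix after stripping digits;
  # two-letter elements (FE, CL, BR, ZN, MG, NA, ...) are left intact by
  # bio3d's elesy so this fallback only needs the common organic set.
  first <- toupper(substr(gsub("^[0-9]+", "", name), 1, 1))
  first
}

#' Extract the ligand-binding site of a complex
#'
#' A protein residue belongs to the binding site iff any of its heavy atoms
#' lies within `radius` of any ligand heavy atom. Hydrogens are ignored on
#' both sides of the distance test. Residues are keyed by `chain_resno` and
#' site C-alpha coordinates are returned in residue-key order.
#'
#' @param structure a `ParsedStructure`.
#' @param radius extraction radius in Angstrom (default 10).
#' @return An object of class `BindingSite`: list with `structure_id`,
#'   `residues` (ordered keys), `ca_coords` (named matrix, one row per site
#'   residue that has a C-alpha), `all_atom_coords` and `resolution`.
#' @export
extract_binding_site <- function(structure, radius = 10) {
  stopifnot(inherits(structure, "ParsedStructure"))
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  lig <- structure$ligand_atoms
  lig <- lig[lig$element != "H", , drop = FALSE]
  if (nrow(lig) == 0) stop("extract_binding_site: ligand has no heavy atoms")
  prot <- structure$atoms
  heavy <- prot[prot$element != "H", , drop = FALSE]

  pk <- residue_key(heavy$chain, heavy$residue_number)
  pxyz <- as.matrix(heavy[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  # nearest ligand heavy atom per protein heavy atom
  d2min <- min_sq_dist_to_set(pxyz, lxyz)
  in_site <- d2min <= radius^2
  keys <- sort(unique(pk[in_site]))
  if (length(keys) == 0) {
    stop("extract_binding_site: empty site at radius ", radius,
         " A for ", structure$structure_id)
  }

  all_k <- residue_key(prot$chain, prot$residue_number)
  site_atoms <- prot[all_k %in% keys, , drop = FALSE]
  ca <- site_atoms[site_atoms$atom_name == "CA" & site_atoms$element == "C", , drop = FALSE]
  ca_keys <- residue_key(ca$chain, ca$residue_number)
  ord <- order(ca_keys)
  ca_coords <- as.matrix(ca[ord, c("x", "y", "z")])
  rownames(ca_coords) <- ca_keys[ord]

  structure(
    list(structure_id = structure$structure_id, residues = keys,
         ca_coords = ca_coords,
         all_atom_coords = as.matrix(site_atoms[, c("x", "y", "z")]),
         resolution = structure$resolution),
    class = "BindingSite"
  )
}

residue_key <- function(chain, resno) {
  chain[is.na(chain) | chain == ""] <- "_"
  sprintf("%s_%05d", chain, resno)
}

# Row-wise minimum squared distance from points a (n x 3) to set b (m x 3).
min_sq_dist_to_set <- function(a, b) {
  # chunked to bound the n x m distance matrix
  n <- nrow(a)
  out <- numeric(n)
  step <- max(1L, floor(2e6 / max(1L, nrow(b))))
  for (i0 in seq(1L, n, by = step)) {
    idx <- i0:min(n, i0 + step - 1L)
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), `+`) -
      2 * a[idx, , drop = FALSE] %*% t(b)
    out[idx] <- apply(d2, 1, min)
  }
  pmax(out, 0)
}

#' Pairwise binding-site RMSD matrix
#'
#' For every pair of sites, superposes the C-alpha atoms of their shared
#' residues (intersection of residue keys, at least 3 required) with
#' [superpose()] and records the post-fit RMSD.
#'
#' @param sites list of `BindingSite` objects.
#' @return An object of class `DistanceMatrix`: list with `ids` and `values`
#'   (symmetric matrix, zero diagonal, Angstrom).
#' @export
rmsd_matrix <- function(sites) {
  if (length(sites) < 2) stop("rmsd_matrix: need at least 2 sites")
  ids <- vapply(sites, function(s) s$structure_id, character(1))
  if (anyDuplicated(ids)) stop("rmsd_matrix: duplicate structure ids")
  n <- length(sites)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sites[[i]]$ca_coords
      b <- sites[[j]]$ca_coords
      shared <- intersect(rownames(a), rownames(b))
      if (length(shared) < 3) {
        stop("rmsd_matrix: sites ", ids[i], " and ", ids[j],
             " share only ", length(shared), " residues (< 3)")
      }
      sp <- superpose(a[shared, , drop = FALSE], b[shared, , drop = FALSE])
      m[i, j] <- m[j, i] <- sp$rmsd
    }
  }
  structure(list(ids = ids, values = m), class = "DistanceMatrix")
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration of the RMSD matrix, as used to group an
#' ensemble of binding-site conformations into types. Node heights follow the
#' ultrametric convention (leaf-to-node height = merge distance / 2), so two
#' leaves at distance d merge at height d/2 and the cophenetic distance
#' between them is d.
#'
#' @param dm a `DistanceMatrix` (or symmetric matrix with dimnames).
#' @return An object of class `ClusterTree`: list with `hclust` (the
#'   agglomeration), `phylo` (an [ape] tree with ultrametric edge lengths),
#'   `heights` (merge heights, d/2 scale) and `ids`.
#' @export
upgma_tree <- function(dm) {
  m <- if (inherits(dm, "DistanceMatrix")) dm$values else as.matrix(dm)
  if (!isSymmetric(unname(m), tol = 1e-9)) stop("upgma_tree: matrix not symmetric")
  if (any(diag(m) != 0)) stop("upgma_tree: diagonal must be zero")
  if (any(m < 0)) stop("upgma_tree: negative distances")
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  phy <- ape::as.phylo(hc)   # edge lengths on the d/2 ultrametric scale
  structure(
    list(hclust = hc, phylo = phy, heights = hc$height / 2, ids = hc$labels),
    class = "ClusterTree"
  )
}

#' Serialize a ClusterTree to Newick
#' @param tree a `ClusterTree`.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @export
tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ClusterTree"))
  if (is.null(path)) ape::write.tree(tree$phylo) else ape::write.tree(tree$phylo, file = path)
}

#' Cut the tree into k clusters and pick per-cluster representatives
#'
#' Cuts the UPGMA tree at the lowest height giving exactly `k` groups and
#' returns, for each group, the member with the best (numerically smallest)
#' resolution; ties break by lexicographic structure id. Output rows follow
#' cluster order (order of first appearance among the leaves).
#'
#' @param tree a `ClusterTree`.
#' @param k number of clusters, 1..n_leaves (default 8).
#' @param resolutions named numeric vector, resolution in Angstrom per id.
#' @return data.frame with columns `structure_id`, `cluster`, `resolution`.
#' @export
select_representatives <- function(tree, k = 8, resolutions) {
  stopifnot(inherits(tree, "ClusterTree"))
  ids <- tree$ids
  if (k < 1 || k > length(ids)) stop("k must be in 1..", length(ids))
  missing_res <- setdiff(ids, names(resolutions))
  if (length(missing_res) > 0) {
    stop("select_representatives: missing resolution for: ",
         paste(missing_res, collapse = ", "))
  }
  grp <- stats::cutree(tree$hclust, k = k)
  # renumber clusters by first appearance in leaf order
  first <- tapply(seq_along(ids), grp, min)
  relabel <- rank(first)
  grp <- as.integer(relabel[as.character(grp)])

  out <- lapply(sort(unique(grp)), function(g) {
    members <- ids[grp == g]
    res <- resolutions[members]
    best <- members[order(res, members)][1]
    data.frame(structure_id = best, cluster = g,
               resolution = unname(resolutions[best]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a DistanceMatrix as TSV
#' @param dm a `DistanceMatrix`.
#' @param path output file.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "DistanceMatrix"))
  df <- data.frame(id = dm$ids, dm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
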