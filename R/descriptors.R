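# Drug-likeness descriptors and the Lipinski/Veber filter.

#' Physicochemical descriptors for drug-likeness filtering
#'
#' Molecular weight, logP (OpenBabel atom-contribution estimator) and TPSA
#' come from the chemistry toolkit; the Lipinski hydrogen-bond counts use
#' the classic definitions (donors = OH + NH count, acceptors = N + O count)
#' and rotatable bonds are counted on the package's own molecular graph:
#' single acyclic bonds between two non-terminal heavy atoms, amide C-N
#' excluded. Descriptor provenance matters because absolute logP differs
#' across estimators; the estimator used is recorded in the output attribute.
#'
#' @param smiles character vector.
#' @param ids compound ids.
#' @return data.frame with `compound_id`, `mw`, `logp`, `hbd`, `hba`,
#'   `rotatable_bonds`, `tpsa`.
#' @export
mol_descriptors <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  sdf <- suppressWarnings({ChemmineR::cid(sdf) <- ids; sdf})
  pr <- ChemmineR::propOB(sdf)
  mols <- lapply(seq_along(smiles), function(i) as_molecule(sdf[[i]], ids[i]))
  hba <- vapply(mols, function(m) sum(m$atoms$element %in% c("N", "O")), integer(1))
  rot <- vapply(mols, count_rotatable_bonds, integer(1))
  out <- data.frame(
    compound_id = ids,
    mw = pr$MW, logp = pr$logP, hbd = pr$HBD, hba = hba,
    rotatable_bonds = rot, tpsa = pr$TPSA,
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- "MW/logP/TPSA/HBD: OpenBabel; HBA (N+O) and rotatable bonds: ensembleVS graph"
  out
}

# Rotatable bonds: order-1 bonds, not in a ring, both ends heavy atoms with
# >= 2 heavy neighbors (non-terminal), amide C-N excluded.
count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(0L)
  el <- mol$atoms$element
  heavy_deg <- integer(nrow(mol$atoms))
  for (r in seq_len(nrow(b))) {
    if (el[b$a1[r]] != "H" && el[b$a2[r]] != "H") {
      heavy_deg[b$a1[r]] <- heavy_deg[b$a1[r]] + 1L
      heavy_deg[b$a2[r]] <- heavy_deg[b$a2[r]] + 1L
    }
  }
  ring_atoms <- find_rings(mol, max_len = 12)
  in_ring_bond <- function(a, bb) {
    any(vapply(ring_atoms, function(r) {
      ra <- match(a, r); rb <- match(bb, r)
      !is.na(ra) && !is.na(rb)
    }, logical(1)))
  }
  is_amide <- function(a, bb) {
    # C(=O)-N in either direction
    pair_amide <- function(cc, nn) {
      if (el[cc] != "C" || el[nn] != "N") return(FALSE)
      dbl_o <- b[(b$a1 == cc | b$a2 == cc) & b$order == 2, , drop = FALSE]
      any(el[ifelse(dbl_o$a1 == cc, dbl_o$a2, dbl_o$a1)] == "O")
    }
    pair_amide(a, bb) || pair_amide(bb, a)
  }
  n <- 0L
  for (r in seq_len(nrow(b))) {
    a <- b$a1[r]; bb <- b$a2[r]
    if (b$order[r] != 1) next
    if (el[a] == "H" || el[bb] == "H") next
    if (heavy_deg[a] < 2 || heavy_deg[bb] < 2) next
    if (in_ring_bond(a, bb)) next
    if (is_amide(a, bb)) next
    n <- n + 1L
  }
  n
}

#' Lipinski/Veber drug-likeness filter
#'
#' Pass iff MW <= 500, logP <= 5, HBD <= 5, HBA <= 10 (Lipinski) and
#' rotatable bonds <= 10, TPSA <= 140 A^2 (Veber). The strict default allows
#' zero Lipinski violations; `max_lipinski_violations = 1` reproduces the
#' permissive variant of some screening tools.
#'
#' @param smiles character vector (or a data.frame with `compound_id` and
#'   `smiles`).
#' @param ids compound ids.
#' @param max_lipinski_violations allowed Lipinski rule violations (default 0).
#' @return data.frame with per-rule logical flags, `n_lipinski_violations`
#'   and overall `pass`; unparseable molecules are excluded and reported via
#'   the `excluded` attribute.
#' @export
lipinski_veber_filter <- function(smiles, ids = NULL, max_lipinski_violations = 0) {
  if (is.data.frame(smiles)) {
    ids <- smiles$compound_id
    smiles <- smiles$smiles
  }
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  ok <- !is.na(suppressWarnings(canonical_smiles(smiles)))
  excluded <- ids[!ok]
  if (length(excluded) > 0) {
    message(length(excluded), " unparseable molecules excluded from the filter")
  }
  d <- mol_descriptors(smiles[ok], ids[ok])
  d$mw_ok <- d$mw <= 500
  d$logp_ok <- d$logp <= 5
  d$hbd_ok <- d$hbd <= 5
  d$hba_ok <- d$hba <= 10
  d$rotb_ok <- d$rotatable_bonds <= 10
  d$tpsa_ok <- d$tpsa <= 140
  d$n_lipinski_violations <- 4L - (d$mw_ok + d$logp_ok + d$hbd_ok + d$hba_ok)
  d$pass <- d$n_lipinski_violations <= max_lipinski_violations &
    d$rotb_ok & d$tpsa_ok
  attr(d, "excluded") <- excluded
  d
}
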