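# benchmark_builder: labeled active/decoy validation sets.

#' Deduplicate compound records by canonical structure
#'
#' Collapses records sharing a canonical SMILES to one record, keeping the
#' earliest id (input order). Unparseable structures are dropped and counted.
#'
#' @param records data.frame with at least `compound_id` and `smiles`;
#'   optional `label` and activity columns are carried through.
#' @return data.frame of survivors with a `canonical` column; attributes
#'   `n_dropped_unparseable` and `n_merged_duplicates`.
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records), all(c("compound_id", "smiles") %in% names(records)))
  can <- suppressWarnings(canonical_smiles(records$smiles))
  bad <- is.na(can)
  if (any(bad)) {
    message(sum(bad), " unparseable structures dropped during deduplication")
  }
  rec <- records[!bad, , drop = FALSE]
  rec$canonical <- can[!bad]
  keep <- !duplicated(rec$canonical)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_unparseable") <- sum(bad)
  attr(out, "n_merged_duplicates") <- nrow(rec) - nrow(out)
  out
}

#' MaxMin diversity selection
#'
#' Greedy maximum-diversity picking on ECFP4 fingerprints with Tanimoto
#' distance: the seeded first pick, then repeatedly the candidate farthest
#' (max-min distance) from the current selection. Ties break by lexicographic
#' compound id. Output order is pick order.
#'
#' @param library data.frame with `compound_id` and `smiles`.
#' @param n number of compounds to select.
#' @param seed integer seed for the first pick.
#' @return data.frame of the selected rows, in pick order.
#' @export
diverse_select <- function(library, n, seed = 1) {
  stopifnot(is.data.frame(library), n >= 1)
  if (n > nrow(library)) {
    stop("diverse_select: n (", n, ") exceeds library size (", nrow(library), ")")
  }
  if (n == nrow(library)) return(library)
  fp <- fingerprint_matrix(library$smiles, library$compound_id)
  fpn <- fp * 1L
  popcnt <- rowSums(fpn)

  set.seed(seed)
  first <- sample.int(nrow(library), 1)
  picked <- integer(n)
  picked[1] <- first
  # min distance from each candidate to the picked set, updated incrementally
  mind <- tanimoto_row(fpn, popcnt, first)
  mind[first] <- -Inf
  ids <- library$compound_id
  for (k in seq_len(n - 1)) {
    best <- which(mind == max(mind))
    if (length(best) > 1) best <- best[order(ids[best])][1]
    picked[k + 1] <- best
    d <- tanimoto_row(fpn, popcnt, best)
    mind <- pmin(mind, d)
    mind[best] <- -Inf
  }
  out <- library[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Tanimoto distance from every row of fp to row i (vectorized).
tanimoto_row <- function(fpn, popcnt, i) {
  inter <- as.numeric(fpn %*% fpn[i, ])
  un <- popcnt + popcnt[i] - inter
  d <- 1 - ifelse(un == 0, 1, inter / un)
  d
}

#' Build the labeled validation set
#'
#' Removes actives (by canonical structure) from the candidate library,
#' diversity-selects `ratio` decoys per active, and labels both groups
#' (1 = inhibitor, 0 = non-inhibitor).
#'
#' @param actives data.frame of known actives (`compound_id`, `smiles`).
#' @param library data.frame of candidate decoys.
#' @param ratio decoys per active (default 20).
#' @param seed seed for the diversity pick.
#' @return An object of class `ValidationSet`: list with `actives`, `decoys`
#'   (both with `label` columns), `ratio`, `seed`.
#' @export
build_validation_set <- function(actives, library, ratio = 20, seed = 1) {
  actives <- deduplicate(actives)
  library <- deduplicate(library)
  library <- library[!(library$canonical %in% actives$canonical) &
                       !(library$compound_id %in% actives$compound_id), , drop = FALSE]
  n_decoy <- ratio * nrow(actives)
  if (n_decoy > nrow(library)) {
    stop("build_validation_set: library too small; need ", n_decoy,
         " decoys, have ", nrow(library), " (short by ", n_decoy - nrow(library), ")")
  }
  decoys <- diverse_select(library, n_decoy, seed = seed)
  actives$label <- 1L
  decoys$label <- 0L
  structure(
    list(actives = actives, decoys = decoys, ratio = ratio, seed = seed),
    class = "ValidationSet"
  )
}

#' @export
print.ValidationSet <- function(x, ...) {
  cat(sprintf("ValidationSet: %d actives, %d decoys (ratio 1:%d, seed %d)\n",
              nrow(x$actives), nrow(x$decoys), x$ratio, x$seed))
  invisible(x)
}

#' Flatten a ValidationSet to one labeled data.frame
#' @param vs a `ValidationSet`.
#' @return data.frame with `compound_id`, `smiles`, `label`.
#' @export
validation_table <- function(vs) {
  stopifnot(inherits(vs, "ValidationSet"))
  cols <- c("compound_id", "smiles", "label")
  rbind(vs$actives[, cols], vs$decoys[, cols])
}
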