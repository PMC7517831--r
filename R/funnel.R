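# funnel_cli: tiered screening funnel
#   stage 1: top n1 by aggregated docking score (lower = better)
#   stage 2: top n2 of stage 1 by best pharmacophore fit value (higher = better)
#   stage 3: top n3 of stage 2 by NB score (higher = better)
#   stage 4: Lipinski/Veber survivors of stage 3, ranked by NB score

#' Funnel configuration
#'
#' @param n1,n2,n3 stage survivor counts (defaults 10000 / 2000 / 100;
#'   must be non-increasing).
#' @param docking_rule cross-structure aggregation: `"best"` (minimum score,
#'   default), `"mean"` or `"rank_sum"`.
#' @param fit_rule cross-model aggregation of fit values: `"best"` (maximum,
#'   default) or `"mean"`.
#' @param apply_filter run the drug-likeness stage (default `TRUE`).
#' @param max_lipinski_violations passed to [lipinski_veber_filter()].
#' @return a `FunnelConfig` list.
#' @export
funnel_config <- function(n1 = 10000, n2 = 2000, n3 = 100,
                          docking_rule = c("best", "mean", "rank_sum"),
                          fit_rule = c("best", "mean"),
                          apply_filter = TRUE, max_lipinski_violations = 0) {
  if (!(n1 >= n2 && n2 >= n3 && n3 > 0)) {
    stop("funnel_config: need n1 >= n2 >= n3 > 0")
  }
  structure(
    list(n1 = n1, n2 = n2, n3 = n3,
         docking_rule = match.arg(docking_rule),
         fit_rule = match.arg(fit_rule),
         apply_filter = apply_filter,
         max_lipinski_violations = max_lipinski_violations),
    class = "FunnelConfig"
  )
}

#' Deterministic top-n selection
#'
#' Best `n` ids by score. `direction = "lower"` treats smaller scores as
#' better (docking), `"higher"` larger (fit, NB). Ties — including ties that
#' straddle the cutoff — break by lexicographic compound id, so the output
#' is bit-identical across runs.
#'
#' @param ids character vector.
#' @param scores numeric vector aligned with `ids`.
#' @param n number to keep.
#' @param direction `"lower"` or `"higher"`.
#' @return character vector of selected ids, best first.
#' @export
top_n <- function(ids, scores, n, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(n > 0, length(ids) == length(scores))
  if (n > length(ids)) {
    warning("top_n: n (", n, ") exceeds input size (", length(ids), "); returning all")
    n <- length(ids)
  }
  key <- if (direction == "lower") scores else -scores
  ord <- order(key, ids)
  ids[ord[seq_len(n)]]
}

#' Aggregate a compound's docking scores across structures
#'
#' @param sm a `ScoreMatrix`.
#' @param rule `"best"` (minimum of non-missing), `"mean"`, or `"rank_sum"`
#'   (sum of per-column ranks, missing cells getting the worst rank + 1).
#' @return named numeric vector (lower = better under every rule); compounds
#'   with all scores missing are excluded with a message.
#' @export
aggregate_docking <- function(sm, rule = c("best", "mean", "rank_sum")) {
  rule <- match.arg(rule)
  stopifnot(inherits(sm, "ScoreMatrix"))
  m <- sm$scores
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " compounds with no docking score excluded from aggregation")
  }
  m <- m[!all_missing, , drop = FALSE]
  ids <- sm$compound_id[!all_missing]
  agg <- switch(
    rule,
    best = do.call(pmin, c(as.data.frame(m), na.rm = TRUE)),
    mean = rowMeans(m, na.rm = TRUE),
    rank_sum = {
      rk <- apply(m, 2, function(col) {
        r <- rank(col, ties.method = "average", na.last = "keep")
        r[is.na(r)] <- sum(!is.na(col)) + 1
        r
      })
      rowSums(rk)
    }
  )
  stats::setNames(as.numeric(agg), ids)
}

# best (max) or mean fit value per compound across the selected models
aggregate_fits <- function(fits, rule = c("best", "mean")) {
  rule <- match.arg(rule)
  fun <- if (rule == "best") max else mean
  agg <- tapply(fits$fit_value, fits$compound_id, fun)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Run the tiered screening funnel
#'
#' @param sm a `ScoreMatrix` over the screening library.
#' @param fits fit-value data.frame (`compound_id`, `model_id`, `fit_value`);
#'   compounds absent from it are treated as fit 0 (no pharmacophore match).
#' @param nb_model a trained `NBModel` applied to the per-compound descriptor
#'   rows (docking columns + fit columns it was trained on).
#' @param library optional data.frame (`compound_id`, `smiles`) for the
#'   drug-likeness stage; required when `config$apply_filter`.
#' @param config a `FunnelConfig`.
#' @return An object of class `FunnelResult`: per-stage survivor data.frames
#'   (`stage1`..`stage4`), `final` ranked list and a `log` of counts and cut
#'   scores.
#' @export
run_funnel <- function(sm, fits, nb_model, library = NULL,
                       config = funnel_config()) {
  stopifnot(inherits(sm, "ScoreMatrix"), inherits(config, "FunnelConfig"))
  log <- list()

  # stage 1: docking
  agg <- aggregate_docking(sm, config$docking_rule)
  if (length(agg) == 0) stop("run_funnel: stage 1 produced no compounds")
  s1 <- top_n(names(agg), unname(agg), config$n1, "lower")
  log$stage1 <- list(n_in = length(agg), n_out = length(s1),
                     cut_score = max(agg[s1]), rule = config$docking_rule)

  # stage 2: pharmacophore fit (only stage-1 survivors are consulted)
  fits_s1 <- fits[fits$compound_id %in% s1, , drop = FALSE]
  fit_by_id <- aggregate_fits(fits_s1, config$fit_rule)
  f1 <- stats::setNames(rep(0, length(s1)), s1)
  hit <- intersect(s1, names(fit_by_id))
  f1[hit] <- fit_by_id[hit]
  s2 <- top_n(names(f1), unname(f1), config$n2, "higher")
  if (length(s2) == 0) stop("run_funnel: stage 2 produced no compounds")
  log$stage2 <- list(n_in = length(s1), n_out = length(s2),
                     cut_score = min(f1[s2]), rule = config$fit_rule)

  # stage 3: NB re-scoring
  dm <- assemble_matrix(
    scores = subset_score_matrix(sm, s2),
    fits = fits[fits$compound_id %in% s2, , drop = FALSE]
  )
  nb <- score_nb(nb_model, pad_columns(dm, nb_model$columns))
  s3 <- top_n(names(nb), unname(nb), config$n3, "higher")
  if (length(s3) == 0) stop("run_funnel: stage 3 produced no compounds")
  log$stage3 <- list(n_in = length(s2), n_out = length(s3), cut_score = min(nb[s3]))

  # stage 4: drug-likeness
  if (config$apply_filter) {
    if (is.null(library)) stop("run_funnel: drug-likeness stage needs the library")
    lib3 <- library[match(s3, library$compound_id), , drop = FALSE]
    if (anyNA(lib3$smiles)) stop("run_funnel: library lacks SMILES for stage-3 survivors")
    flt <- lipinski_veber_filter(lib3, max_lipinski_violations = config$max_lipinski_violations)
    s4 <- flt$compound_id[flt$pass]
    s4 <- s4[order(-nb[s4], s4)]
    log$stage4 <- list(n_in = length(s3), n_out = length(s4), filter = flt)
  } else {
    s4 <- s3
    flt <- NULL
    log$stage4 <- list(n_in = length(s3), n_out = length(s3), filter = NULL)
  }

  structure(
    list(
      stage1 = data.frame(compound_id = s1, docking = unname(agg[s1])),
      stage2 = data.frame(compound_id = s2, fit = unname(f1[s2])),
      stage3 = data.frame(compound_id = s3, nb_score = unname(nb[s3])),
      stage4 = data.frame(compound_id = s4, nb_score = unname(nb[s4])),
      final = data.frame(rank = seq_along(s4), compound_id = s4,
                         nb_score = unname(nb[s4])),
      log = log, config = config
    ),
    class = "FunnelResult"
  )
}

#' @export
print.FunnelResult <- function(x, ...) {
  cat("Screening funnel:\n")
  cat(sprintf("  stage 1 (docking, %s): %d -> %d\n", x$log$stage1$rule,
              x$log$stage1$n_in, x$log$stage1$n_out))
  cat(sprintf("  stage 2 (fit, %s):     %d -> %d\n", x$log$stage2$rule,
              x$log$stage2$n_in, x$log$stage2$n_out))
  cat(sprintf("  stage 3 (NB):          %d -> %d\n", x$log$stage3$n_in, x$log$stage3$n_out))
  cat(sprintf("  stage 4 (drug-like):   %d -> %d\n", x$log$stage4$n_in, x$log$stage4$n_out))
  invisible(x)
}

subset_score_matrix <- function(sm, ids) {
  keep <- sm$compound_id %in% ids
  score_matrix(sm$compound_id[keep], sm$scores[keep, , drop = FALSE], sm$columns)
}

# make sure the descriptor matrix has every model column (all-NA when absent,
# e.g. no compound in the subset matched a given pharmacophore model)
pad_columns <- function(dm, columns) {
  x <- dm$x
  missing_cols <- setdiff(columns, colnames(x))
  if (length(missing_cols) > 0) {
    x <- cbind(x, matrix(NA_real_, nrow(x), length(missing_cols),
                         dimnames = list(NULL, missing_cols)))
  }
  rownames(x) <- dm$compound_id
  x[, columns, drop = FALSE]
}
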