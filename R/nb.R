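# nb_fusion: Laplacian-corrected naive Bayes over docking scores + fit values.
#
# Each continuous descriptor column is discretized into equal-frequency bins
# (plus a reserved bin for missing values: failure to dock is informative).
# Each (column, bin) event F gets the Laplacian-corrected log-likelihood
# weight w_F = ln((A + 1) / (B * p + 1)), where A = actives showing F,
# B = all training rows showing F and p = active base rate. This is the
# K = 1/p virtual-sample stabilisation of the naive Bayes likelihood ratio:
# with no observations the weight is ln(1/1) = 0, and a feature present at
# exactly the base rate (A = B p) is also weightless. A compound's score is
# the sum of its per-column weights.

#' Assemble the descriptor matrix for NB training
#'
#' Row-aligns selected docking-score columns and per-model fit values by
#' compound id. Compounds missing a docking score keep the missing marker
#' (`NA`); compounds with every column missing are dropped with a message.
#'
#' @param scores a `ScoreMatrix` (or `NULL`).
#' @param fits fit-value data.frame from [fit_table()] (or `NULL`).
#' @param chosen_columns character vector of `<structure>.<mode>` column keys
#'   to keep from the score matrix (default: all).
#' @param chosen_models model ids to keep from the fit table (default: all).
#' @param labels named 0/1 vector (names = compound ids) or data.frame with
#'   `compound_id` and `label`; may be `NULL` for a scoring-only matrix.
#' @return An object of class `DescriptorMatrix`: list with `compound_id`,
#'   `x` (numeric matrix), `label` (or `NULL`) and `provenance`.
#' @export
assemble_matrix <- function(scores = NULL, fits = NULL, chosen_columns = NULL,
                            chosen_models = NULL, labels = NULL) {
  blocks <- list()
  if (!is.null(scores)) {
    stopifnot(inherits(scores, "ScoreMatrix"))
    keep <- if (is.null(chosen_columns)) colnames(scores$scores) else chosen_columns
    missing_cols <- setdiff(keep, colnames(scores$scores))
    if (length(missing_cols) > 0) {
      stop("assemble_matrix: unknown score columns: ", paste(missing_cols, collapse = ", "))
    }
    b <- scores$scores[, keep, drop = FALSE]
    rownames(b) <- scores$compound_id
    blocks$docking <- b
  }
  if (!is.null(fits)) {
    keep <- if (is.null(chosen_models)) unique(fits$model_id) else chosen_models
    missing_m <- setdiff(keep, unique(fits$model_id))
    if (length(missing_m) > 0) {
      stop("assemble_matrix: unknown model ids: ", paste(missing_m, collapse = ", "))
    }
    f <- fits[fits$model_id %in% keep, , drop = FALSE]
    ids <- sort(unique(f$compound_id))
    b <- matrix(NA_real_, length(ids), length(keep),
                dimnames = list(ids, paste0("fit.", keep)))
    b[cbind(match(f$compound_id, ids), match(paste0("fit.", f$model_id), colnames(b)))] <-
      f$fit_value
    blocks$fits <- b
  }
  if (length(blocks) == 0) stop("assemble_matrix: no inputs")
  all_ids <- sort(unique(unlist(lapply(blocks, rownames))))
  x <- do.call(cbind, lapply(blocks, function(b) {
    out <- matrix(NA_real_, length(all_ids), ncol(b),
                  dimnames = list(all_ids, colnames(b)))
    out[rownames(b), ] <- b
    out
  }))
  colnames(x) <- unname(unlist(lapply(blocks, colnames)))

  empty <- rowSums(!is.na(x)) == 0
  if (any(empty)) {
    message(sum(empty), " compounds with all descriptors missing were dropped")
    x <- x[!empty, , drop = FALSE]
    all_ids <- all_ids[!empty]
  }

  lab <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) labels <- stats::setNames(labels$label, labels$compound_id)
    lab <- unname(labels[all_ids])
    if (anyNA(lab)) stop("assemble_matrix: ", sum(is.na(lab)), " rows lack a label")
  }
  structure(
    list(compound_id = all_ids, x = x, label = lab,
         provenance = list(columns = colnames(x))),
    class = "DescriptorMatrix"
  )
}

#' Equal-frequency binning scheme
#'
#' Per-column quantile cut points from the training rows (missing values
#' excluded; duplicate quantiles merged). Constant columns collapse to a
#' single bin with a warning.
#'
#' @param matrix a `DescriptorMatrix` or numeric matrix.
#' @param n_bins target bins per column (default 10, minimum 2).
#' @return An object of class `BinningScheme`: named list of strictly
#'   increasing cut-point vectors.
#' @export
fit_bins <- function(matrix, n_bins = 10) {
  if (inherits(matrix, "DescriptorMatrix")) matrix <- matrix$x
  stopifnot(n_bins >= 2)
  cuts <- lapply(seq_len(ncol(matrix)), function(j) {
    v <- matrix[, j]
    v <- v[!is.na(v)]
    if (length(unique(v)) <= 1) {
      warning("column ", colnames(matrix)[j], " is constant; single bin")
      return(numeric(0))
    }
    q <- stats::quantile(v, probs = seq_len(n_bins - 1) / n_bins,
                         type = 7, names = FALSE)
    unique(q)
  })
  names(cuts) <- colnames(matrix)
  structure(cuts, class = "BinningScheme")
}

# Bin index per value: 1..(k+1) for finite values, 0L for missing.
bin_values <- function(values, cuts) {
  idx <- findInterval(values, cuts, left.open = TRUE) + 1L
  idx[is.na(values)] <- 0L
  idx
}

#' Train the Laplacian-corrected naive Bayes classifier
#'
#' @param matrix a labeled `DescriptorMatrix` (both classes present).
#' @param scheme a `BinningScheme` from [fit_bins()]; default fits one with
#'   `n_bins` bins.
#' @param n_bins bins used when `scheme` is `NULL`.
#' @return An object of class `NBModel`: `base_rate`, `scheme`, `weights`
#'   (per column: data.frame bin / A / B / w) and training metadata.
#' @export
train_nb <- function(matrix, scheme = NULL, n_bins = 10) {
  stopifnot(inherits(matrix, "DescriptorMatrix"))
  y <- matrix$label
  if (is.null(y)) stop("train_nb: matrix has no labels")
  if (length(unique(y)) < 2) stop("train_nb: single-class training set")
  if (is.null(scheme)) scheme <- fit_bins(matrix, n_bins = n_bins)
  p <- mean(y == 1)
  weights <- lapply(colnames(matrix$x), function(col) {
    bins <- bin_values(matrix$x[, col], scheme[[col]])
    tab_all <- table(factor(bins, levels = 0:(length(scheme[[col]]) + 1)))
    tab_act <- table(factor(bins[y == 1], levels = 0:(length(scheme[[col]]) + 1)))
    A <- as.numeric(tab_act); B <- as.numeric(tab_all)
    data.frame(bin = as.integer(names(tab_all)), A = A, B = B,
               w = log((A + 1) / (B * p + 1)))
  })
  names(weights) <- colnames(matrix$x)
  structure(
    list(base_rate = p, scheme = scheme, weights = weights,
         columns = colnames(matrix$x),
         n_train = length(y), n_active = sum(y == 1)),
    class = "NBModel"
  )
}

#' @export
print.NBModel <- function(x, ...) {
  cat(sprintf("NBModel: %d columns, base rate %.4f, %d training rows\n",
              length(x$columns), x$base_rate, x$n_train))
  invisible(x)
}

#' Score compounds with a trained NB model
#'
#' Rows are binned under the model's frozen scheme (missing values to the
#' missing bin); the score is the sum of the per-column bin weights. Bins
#' never seen in training contribute `ln(1/1) = 0`.
#'
#' @param model an `NBModel`.
#' @param matrix a `DescriptorMatrix` (or numeric matrix with the model's
#'   columns).
#' @return named numeric vector of scores.
#' @export
score_nb <- function(model, matrix) {
  stopifnot(inherits(model, "NBModel"))
  ids <- NULL
  if (inherits(matrix, "DescriptorMatrix")) {
    ids <- matrix$compound_id
    matrix <- matrix$x
  } else {
    ids <- rownames(matrix)
  }
  missing_cols <- setdiff(model$columns, colnames(matrix))
  if (length(missing_cols) > 0) {
    stop("score_nb: matrix lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  s <- numeric(nrow(matrix))
  for (col in model$columns) {
    bins <- bin_values(matrix[, col], model$scheme[[col]])
    wt <- model$weights[[col]]
    w <- wt$w[match(bins, wt$bin)]
    w[is.na(w)] <- 0   # bin never seen in training
    s <- s + w
  }
  if (!is.null(ids)) names(s) <- ids
  s
}

#' Rank-based ROC AUC (Mann-Whitney, midrank ties)
#'
#' @param scores numeric vector (higher = more active-like).
#' @param labels 0/1 vector.
#' @return An object of class `ROCResult`: `auc`, `curve` (FPR/TPR points),
#'   `n_active`, `n_decoy`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: need both classes")
  r <- rank(scores)   # midranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1); fp <- cumsum(labels[ord] == 0)
  # collapse tied thresholds
  keep <- c(diff(scores[ord]) != 0, TRUE)
  curve <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  structure(list(auc = auc, curve = curve, n_active = n1, n_decoy = n0),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC AUC = %.4f (%d actives vs %d decoys)\n",
              x$auc, x$n_active, x$n_decoy))
  invisible(x)
}

#' Stratified cross-validated NB AUC
#'
#' The apparent (train = test) AUC flatters a classifier; this refits the NB
#' model on stratified folds and reports the held-out AUC.
#'
#' @param matrix a labeled `DescriptorMatrix`.
#' @param n_bins bins per column.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `auc` (held-out), `fold_auc`.
#' @export
nb_cv_auc <- function(matrix, n_bins = 10, folds = 5, seed = 1) {
  stopifnot(inherits(matrix, "DescriptorMatrix"))
  y <- matrix$label
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  scores <- numeric(length(y))
  fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    trm <- structure(list(compound_id = matrix$compound_id[tr],
                          x = matrix$x[tr, , drop = FALSE], label = y[tr],
                          provenance = matrix$provenance),
                     class = "DescriptorMatrix")
    mdl <- train_nb(trm, n_bins = n_bins)
    scores[!tr] <- score_nb(mdl, matrix$x[!tr, , drop = FALSE])
    fold_auc[f] <- roc_auc(scores[!tr], y[!tr])$auc
  }
  list(auc = roc_auc(scores, y)$auc, fold_auc = fold_auc)
}

#' Serialize an NB model to JSON
#' @param model an `NBModel`.
#' @param path output file.
#' @export
write_nb_json <- function(model, path) {
  payload <- list(
    base_rate = model$base_rate,
    n_train = model$n_train, n_active = model$n_active,
    columns = model$columns,
    scheme = lapply(model$scheme, as.numeric),
    weights = model$weights
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read an NB model from JSON
#' @param path JSON file from [write_nb_json()].
#' @return an `NBModel`.
#' @export
read_nb_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(base_rate = p$base_rate,
         scheme = structure(lapply(p$scheme, as.numeric), class = "BinningScheme"),
         weights = lapply(p$weights, as.data.frame),
         columns = p$columns, n_train = p$n_train, n_active = p$n_active),
    class = "NBModel"
  )
}
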