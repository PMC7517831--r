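# score_matrix: docking-score ingestion and the two docking validation powers.

#' Construct a ScoreMatrix
#'
#' A compounds x (structure, mode) table of docking scores in kcal/mol
#' (lower = better). Missing cells stay `NA` and are never imputed.
#'
#' @param compound_id character vector.
#' @param scores numeric matrix or data.frame, one column per
#'   (structure, mode) pair.
#' @param columns data.frame with `structure_id` and `mode` (`"SP"`/`"XP"`),
#'   one row per score column. Column names are `<structure>.<mode>`.
#' @return An object of class `ScoreMatrix`.
#' @export
score_matrix <- function(compound_id, scores, columns) {
  scores <- as.matrix(scores)
  stopifnot(nrow(columns) == ncol(scores),
            all(c("structure_id", "mode") %in% names(columns)))
  key <- paste(columns$structure_id, columns$mode, sep = ".")
  if (anyDuplicated(key)) stop("score_matrix: duplicate (structure, mode) columns")
  colnames(scores) <- key
  rownames(scores) <- NULL
  structure(
    list(compound_id = as.character(compound_id), scores = scores,
         columns = columns),
    class = "ScoreMatrix"
  )
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d compounds x %d (structure, mode) columns; %d missing cells\n",
              length(x$compound_id), ncol(x$scores), sum(is.na(x$scores))))
  invisible(x)
}

#' Load per-structure docking score tables
#'
#' Accepts either one long-format file (columns `compound_id`, `structure_id`,
#' `mode`, `score`) or several per-column files (columns `compound_id`,
#' `score`) whose (structure, mode) keys are given alongside. Duplicate
#' (compound, column) entries keep the better (lower) score; the number of
#' such collisions is reported with a message.
#'
#' @param paths character vector of CSV/TSV paths.
#' @param structure_id,mode required when `paths` are per-column files;
#'   recycled along `paths`.
#' @return a `ScoreMatrix`.
#' @export
load_scores <- function(paths, structure_id = NULL, mode = NULL) {
  long <- list()
  for (i in seq_along(paths)) {
    df <- data.table::fread(paths[i], data.table = FALSE)
    if (all(c("structure_id", "mode", "score") %in% names(df))) {
      long[[i]] <- df[, c("compound_id", "structure_id", "mode", "score")]
    } else if (all(c("compound_id", "score") %in% names(df))) {
      if (is.null(structure_id) || is.null(mode)) {
        stop("load_scores: per-column file ", paths[i],
             " needs structure_id and mode arguments")
      }
      sid <- rep_len(structure_id, length(paths))[i]
      md <- rep_len(mode, length(paths))[i]
      long[[i]] <- data.frame(compound_id = df$compound_id, structure_id = sid,
                              mode = md, score = df$score)
    } else {
      stop("load_scores: unrecognized schema in ", paths[i])
    }
  }
  long <- do.call(rbind, long)
  long$key <- paste(long$structure_id, long$mode, sep = ".")
  dup <- duplicated(long[, c("compound_id", "key")]) |
    duplicated(long[, c("compound_id", "key")], fromLast = TRUE)
  if (any(dup)) {
    n_extra <- sum(duplicated(long[, c("compound_id", "key")]))
    message(n_extra, " duplicate (compound, column) entries resolved by keeping the lower score")
    long <- long[order(long$compound_id, long$key, long$score), ]
    long <- long[!duplicated(long[, c("compound_id", "key")]), ]
  }
  ids <- sort(unique(long$compound_id))
  keys <- unique(long$key)
  cols <- unique(long[, c("structure_id", "mode", "key")])
  cols <- cols[match(keys, cols$key), ]
  m <- matrix(NA_real_, length(ids), length(keys), dimnames = list(NULL, keys))
  m[cbind(match(long$compound_id, ids), match(long$key, keys))] <- long$score
  score_matrix(ids, m, cols[, c("structure_id", "mode")])
}

# ---- pose RMSD --------------------------------------------------------------

#' Heavy-atom pose RMSD, optionally symmetry-corrected
#'
#' RMSD between a docked pose and the reference pose of the same molecule in
#' the same (receptor) frame — no re-superposition, matching re-docking
#' practice. With `symmetry = TRUE` the minimum over all graph automorphisms
#' of the heavy-atom molecular graph (element-colored, VF2) is returned, so
#' e.g. a benzene ring rotated by 60 degrees scores 0.
#'
#' @param ref_pose,test_pose `Molecule` objects with identical heavy-atom
#'   topology (same molecule).
#' @param symmetry correct for automorphisms (default `TRUE`).
#' @param max_automorphisms safety cap on enumeration.
#' @return An object of class `PoseComparison`: list with `rmsd`,
#'   `mapping_used` (test-atom index per ref atom, heavy-atom numbering) and
#'   `symmetry_corrected`.
#' @export
pose_rmsd <- function(ref_pose, test_pose, symmetry = TRUE,
                      max_automorphisms = 10000) {
  stopifnot(inherits(ref_pose, "Molecule"), inherits(test_pose, "Molecule"))
  ih <- heavy_idx(ref_pose); jh <- heavy_idx(test_pose)
  if (length(ih) != length(jh)) {
    stop("pose_rmsd: heavy-atom counts differ (", length(ih), " vs ", length(jh), ")")
  }
  if (!identical(sort(ref_pose$atoms$element[ih]), sort(test_pose$atoms$element[jh]))) {
    stop("pose_rmsd: element multisets differ; not the same molecule")
  }
  a <- mol_xyz(ref_pose, ih)
  b <- mol_xyz(test_pose, jh)

  if (!symmetry) {
    if (!identical(ref_pose$atoms$element[ih], test_pose$atoms$element[jh])) {
      stop("pose_rmsd: without symmetry correction atoms must be in the same order")
    }
    return(structure(list(rmsd = rmsd_inplace(a, b),
                          mapping_used = seq_len(nrow(a)),
                          symmetry_corrected = FALSE),
                     class = "PoseComparison"))
  }

  g1 <- mol_graph(ref_pose, heavy_only = TRUE)
  g2 <- mol_graph(test_pose, heavy_only = TRUE)
  col1 <- as.integer(factor(igraph::V(g1)$element,
                            levels = sort(unique(ref_pose$atoms$element[ih]))))
  col2 <- as.integer(factor(igraph::V(g2)$element,
                            levels = sort(unique(ref_pose$atoms$element[ih]))))
  maps <- igraph::graph.get.isomorphisms.vf2(g1, g2,
                                             vertex.color1 = col1,
                                             vertex.color2 = col2)
  if (length(maps) == 0) stop("pose_rmsd: molecular graphs are not isomorphic")
  if (length(maps) > max_automorphisms) {
    stop("pose_rmsd: ", length(maps), " automorphisms exceed the cap")
  }
  best <- Inf; best_map <- NULL
  for (mp in maps) {
    perm <- as.integer(mp)
    r <- rmsd_inplace(a, b[perm, , drop = FALSE])
    if (r < best) { best <- r; best_map <- perm }
  }
  structure(list(rmsd = best, mapping_used = best_map, symmetry_corrected = TRUE),
            class = "PoseComparison")
}

#' Scoring-power report from re-dock pose comparisons
#'
#' A docking setup has scoring power for a structure when the re-docked pose
#' reproduces the crystallographic conformation within the RMSD threshold
#' (2.0 Angstrom by convention, inclusive).
#'
#' @param rmsds named numeric vector (or list of `PoseComparison`) of re-dock
#'   RMSDs per structure/mode.
#' @param threshold pass threshold in Angstrom (default 2.0).
#' @return data.frame with `id`, `rmsd`, `pass`; attribute `fraction_passing`.
#' @export
scoring_power <- function(rmsds, threshold = 2.0) {
  if (is.list(rmsds)) {
    rmsds <- vapply(rmsds, function(p) p$rmsd, numeric(1))
  }
  if (length(rmsds) == 0) stop("scoring_power: empty input")
  stopifnot(threshold > 0)
  ids <- names(rmsds)
  if (is.null(ids)) ids <- paste0("pose", seq_along(rmsds))
  out <- data.frame(id = ids, rmsd = unname(rmsds),
                    pass = unname(rmsds) <= threshold)
  attr(out, "fraction_passing") <- mean(out$pass)
  out
}

#' Screening power: Welch t-test between active and decoy score distributions
#'
#' Two-sided Welch two-sample t-test (Welch-Satterthwaite degrees of
#' freedom) on docking scores of actives vs decoys. Missing scores are
#' excluded with a message. Two groups that are both constant and identical
#' give t = 0, p = 1 with a warning.
#'
#' @param scores_active,scores_decoy numeric vectors.
#' @param structure_id,mode optional identifiers carried into the result.
#' @return An object of class `ScreeningPowerResult`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, group means and sizes.
#' @export
screening_power <- function(scores_active, scores_decoy,
                            structure_id = NA_character_, mode = NA_character_) {
  na_a <- sum(is.na(scores_active)); na_d <- sum(is.na(scores_decoy))
  if (na_a + na_d > 0) {
    message(na_a + na_d, " missing scores excluded from the t-test")
  }
  a <- scores_active[!is.na(scores_active)]
  d <- scores_decoy[!is.na(scores_decoy)]
  if (length(a) < 2 || length(d) < 2) {
    stop("screening_power: each group needs at least 2 non-missing scores")
  }
  res <- tryCatch(
    stats::t.test(a, d, var.equal = FALSE),
    error = function(e) {
      if (grepl("essentially constant", conditionMessage(e)) &&
          isTRUE(all.equal(mean(a), mean(d)))) {
        warning("zero variance with identical means; reporting t = 0, p = 1")
        list(statistic = c(t = 0), parameter = c(df = length(a) + length(d) - 2),
             p.value = 1)
      } else if (grepl("essentially constant", conditionMessage(e))) {
        # constant groups with different means: infinitely significant
        warning("zero variance with different means; reporting p = 0")
        list(statistic = c(t = sign(mean(a) - mean(d)) * Inf),
             parameter = c(df = length(a) + length(d) - 2), p.value = 0)
      } else {
        stop(e)
      }
    }
  )
  structure(
    list(structure_id = structure_id, mode = mode,
         t_statistic = unname(res$statistic),
         degrees_of_freedom = unname(res$parameter),
         p_value = res$p.value,
         mean_active = mean(a), mean_decoy = mean(d),
         n_active = length(a), n_decoy = length(d)),
    class = "ScreeningPowerResult"
  )
}

#' @export
print.ScreeningPowerResult <- function(x, ...) {
  cat(sprintf("Screening power %s/%s: t = %.3f, df = %.1f, p = %.3g (n = %d vs %d)\n",
              x$structure_id, x$mode, x$t_statistic, x$degrees_of_freedom,
              x$p_value, x$n_active, x$n_decoy))
  invisible(x)
}

#' Choose the docking mode per structure
#'
#' Per structure, keeps the precision mode (SP or XP) whose score
#' distributions separate actives from decoys more strongly, i.e. the smaller
#' t-test p-value; ties go to XP (the higher-precision mode). The reading of
#' "higher P-value" as higher significance is switchable.
#'
#' @param results named list per structure, each a list with elements `SP`
#'   and/or `XP` of class `ScreeningPowerResult`.
#' @param prefer `"smaller_p"` (default: stronger separation wins) or
#'   `"larger_p"` (literal larger p-value wins).
#' @return data.frame with `structure_id`, `mode`, `p_value`.
#' @export
choose_mode <- function(results, prefer = c("smaller_p", "larger_p")) {
  prefer <- match.arg(prefer)
  rows <- lapply(names(results), function(sid) {
    r <- results[[sid]]
    have <- intersect(c("SP", "XP"), names(r)[!vapply(r, is.null, logical(1))])
    if (length(have) == 0) stop("choose_mode: no modes for ", sid)
    if (length(have) == 1) {
      warning("choose_mode: only ", have, " available for ", sid)
      pick <- have
    } else {
      p_sp <- r$SP$p_value; p_xp <- r$XP$p_value
      if (p_sp == p_xp) {
        pick <- "XP"
      } else if (prefer == "smaller_p") {
        pick <- if (p_xp < p_sp) "XP" else "SP"
      } else {
        pick <- if (p_xp > p_sp) "XP" else "SP"
      }
    }
    data.frame(structure_id = sid, mode = pick, p_value = r[[pick]]$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Table-style power report across structures and modes
#'
#' @param power named list per structure with `SP`/`XP`
#'   `ScreeningPowerResult`s.
#' @param redock named numeric or NULL: re-dock RMSD per `<structure>.<mode>`.
#' @param threshold scoring-power pass threshold (Angstrom).
#' @return data.frame, one row per (structure, mode).
#' @export
power_report <- function(power, redock = NULL, threshold = 2.0) {
  rows <- list()
  for (sid in names(power)) {
    for (md in intersect(c("SP", "XP"), names(power[[sid]]))) {
      r <- power[[sid]][[md]]
      key <- paste(sid, md, sep = ".")
      rr <- if (!is.null(redock) && key %in% names(redock)) redock[[key]] else NA_real_
      rows[[key]] <- data.frame(
        structure_id = sid, mode = md, t = r$t_statistic,
        df = r$degrees_of_freedom, p_value = r$p_value,
        redock_rmsd = rr, pass = if (is.na(rr)) NA else rr <= threshold,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
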