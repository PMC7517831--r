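# pharmacophore: receptor-complemented ("complex-based") pharmacophore models.
#
# Feature types follow the common six-letter alphabet:
#   HBA (A) hydrogen-bond acceptor   HBD (D) donor
#   HYD (H) hydrophobic              NI  (N) negative ionizable
#   PI  (P) positive ionizable       RA  (R) ring aromatic

FEATURE_LETTERS <- c(HBA = "A", HBD = "D", HYD = "H", NI = "N", PI = "P", RA = "R")

feature_frame <- function(type = character(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), tolerance = 1.6, weight = 1) {
  data.frame(type = type, x = x, y = y, z = z,
             tolerance = rep_len(tolerance, length(type)),
             weight = rep_len(weight, length(type)),
             stringsAsFactors = FALSE)
}

#' Perceive pharmacophoric features of a 3D molecule
#'
#' Rule-based typing on the molecular graph and conformer coordinates:
#' \describe{
#'   \item{HBD}{N or O carrying at least one hydrogen; point at the heavy atom.}
#'   \item{HBA}{N or O with non-positive formal charge; point at the atom.}
#'   \item{HYD}{centroid of each connected group of two or more apolar
#'     carbons (carbons bonded only to carbon or hydrogen).}
#'   \item{RA}{centroid of each aromatic ring (plus its unit normal).}
#'   \item{NI}{negatively charged group centroid (a carboxylate O collapses
#'     to the COO group centroid).}
#'   \item{PI}{positively charged atom position.}
#' }
#'
#' @param mol a `Molecule` with 3D coordinates.
#' @param tolerance default feature tolerance (Angstrom).
#' @param weight default feature weight.
#' @return data.frame of features (`type`, `x`, `y`, `z`, `tolerance`,
#'   `weight`), with ring normals in attribute `normals`.
#' @export
perceive_features <- function(mol, tolerance = 1.6, weight = 1) {
  stopifnot(inherits(mol, "Molecule"))
  at <- mol$atoms
  nh <- total_h_count(mol)
  res <- list()
  normals <- list()

  add <- function(type, xyz) {
    res[[length(res) + 1]] <<- c(type = type, as.list(xyz))
  }

  # neighbor table over all atoms
  nbrs <- vector("list", nrow(at))
  if (nrow(mol$bonds) > 0) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[r]; b <- mol$bonds$a2[r]
      nbrs[[a]] <- c(nbrs[[a]], b); nbrs[[b]] <- c(nbrs[[b]], a)
    }
  }

  is_no <- at$element %in% c("N", "O")
  for (i in which(is_no)) {
    if (nh[i] >= 1) add("HBD", c(x = at$x[i], y = at$y[i], z = at$z[i]))
    if (at$charge[i] <= 0) add("HBA", c(x = at$x[i], y = at$y[i], z = at$z[i]))
  }

  # hydrophobic groups: connected apolar-carbon components of size >= 2
  apolar <- vapply(seq_len(nrow(at)), function(i) {
    at$element[i] == "C" &&
      all(at$element[nbrs[[i]]] %in% c("C", "H")) && at$charge[i] == 0
  }, logical(1))
  if (any(apolar)) {
    idx <- which(apolar)
    g <- igraph::graph_from_edgelist(matrix(integer(0), 0, 2), directed = FALSE)
    g <- igraph::add_vertices(g, length(idx))
    el <- mol$bonds[mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx, c("a1", "a2")]
    if (nrow(el) > 0) {
      g <- igraph::add_edges(g, t(cbind(match(el$a1, idx), match(el$a2, idx))))
    }
    comp <- igraph::components(g)$membership
    for (cmp in unique(comp)) {
      members <- idx[comp == cmp]
      if (length(members) >= 2) {
        add("HYD", c(x = mean(at$x[members]), y = mean(at$y[members]),
                     z = mean(at$z[members])))
      }
    }
  }

  # aromatic rings
  for (ring in find_rings(mol)) {
    if (ring_is_aromatic(mol, ring)) {
      ctr <- colMeans(mol_xyz(mol, ring))
      add("RA", c(x = ctr[1], y = ctr[2], z = ctr[3]))
      v1 <- mol_xyz(mol, ring[2]) - mol_xyz(mol, ring[1])
      v2 <- mol_xyz(mol, ring[3]) - mol_xyz(mol, ring[1])
      nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
               v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])
      normals[[length(res)]] <- nrm / sqrt(sum(nrm^2))
    }
  }

  # ionizable groups
  for (i in which(at$charge < 0)) {
    members <- i
    if (at$element[i] == "O") {
      cs <- nbrs[[i]][at$element[nbrs[[i]]] == "C"]
      if (length(cs) == 1) {
        sib_o <- setdiff(nbrs[[cs]][at$element[nbrs[[cs]]] == "O"], i)
        if (length(sib_o) >= 1) members <- c(cs, i, sib_o)  # carboxylate
      }
    }
    add("NI", c(x = mean(at$x[members]), y = mean(at$y[members]),
                z = mean(at$z[members])))
  }
  for (i in which(at$charge > 0)) {
    if (at$element[i] != "H") {
      add("PI", c(x = at$x[i], y = at$y[i], z = at$z[i]))
    }
  }

  if (length(res) == 0) return(feature_frame())
  df <- do.call(rbind, lapply(res, function(r) {
    data.frame(type = r$type, x = r$x, y = r$y, z = r$z, stringsAsFactors = FALSE)
  }))
  df$tolerance <- tolerance
  df$weight <- weight
  attr(df, "normals") <- normals
  df
}

#' Letter code of a feature set
#' @param features feature data.frame (or a `PharmacophoreModel`).
#' @return sorted letter-code string, e.g. `"ADHN"`.
#' @export
feature_code <- function(features) {
  if (inherits(features, "PharmacophoreModel")) features <- features$features
  paste(sort(FEATURE_LETTERS[features$type]), collapse = "")
}

# ---- receptor complementation ----------------------------------------------

default_interaction_thresholds <- function() {
  list(hbond = 3.5, hydrophobic = 4.5, ionic = 5.5)
}

receptor_partner_atoms <- function(receptor) {
  at <- receptor$atoms
  heavy <- at[at$element != "H", , drop = FALSE]
  polar <- heavy[heavy$element %in% c("N", "O"), , drop = FALSE]
  apolar <- heavy[heavy$element == "C", , drop = FALSE]
  neg <- heavy[(heavy$residue_name == "ASP" & heavy$atom_name %in% c("OD1", "OD2")) |
                 (heavy$residue_name == "GLU" & heavy$atom_name %in% c("OE1", "OE2")) |
                 heavy$atom_name == "OXT", , drop = FALSE]
  pos <- heavy[(heavy$residue_name == "LYS" & heavy$atom_name == "NZ") |
                 (heavy$residue_name == "ARG" &
                    heavy$atom_name %in% c("NE", "NH1", "NH2")), , drop = FALSE]
  list(polar = as.matrix(polar[, c("x", "y", "z")]),
       apolar = as.matrix(apolar[, c("x", "y", "z")]),
       negative = as.matrix(neg[, c("x", "y", "z")]),
       positive = as.matrix(pos[, c("x", "y", "z")]))
}

# Keep only ligand features with a complementary receptor environment.
complement_features <- function(features, receptor,
                                thresholds = default_interaction_thresholds()) {
  part <- receptor_partner_atoms(receptor)
  keep <- logical(nrow(features))
  why <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    p <- matrix(as.numeric(features[i, c("x", "y", "z")]), 1, 3)
    ty <- features$type[i]
    ok <- switch(
      ty,
      HBD = nrow(part$polar) > 0 &&
        min_sq_dist_to_set(p, part$polar) <= thresholds$hbond^2,
      HBA = nrow(part$polar) > 0 &&
        min_sq_dist_to_set(p, part$polar) <= thresholds$hbond^2,
      HYD = nrow(part$apolar) >= 3 &&
        sum(rowSums(sweep(part$apolar, 2, as.numeric(p))^2) <=
              thresholds$hydrophobic^2) >= 3,
      RA = nrow(part$apolar) >= 3 &&
        sum(rowSums(sweep(part$apolar, 2, as.numeric(p))^2) <=
              thresholds$hydrophobic^2) >= 3,
      NI = nrow(part$positive) > 0 &&
        min_sq_dist_to_set(p, part$positive) <= thresholds$ionic^2,
      PI = nrow(part$negative) > 0 &&
        min_sq_dist_to_set(p, part$negative) <= thresholds$ionic^2,
      FALSE
    )
    keep[i] <- isTRUE(ok)
    if (!keep[i]) {
      why[i] <- sprintf("%s at (%.1f, %.1f, %.1f): no receptor complement within threshold",
                        ty, p[1], p[2], p[3])
    }
  }
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- why[!keep]
  out
}

# ---- model construction ------------------------------------------------------

new_pharmacophore_model <- function(features, model_id, source_id = NA_character_,
                                    selectivity = NA_real_, auc = NA_real_) {
  stopifnot(nrow(features) >= 3)
  structure(
    list(model_id = model_id, features = features,
         selectivity_score = selectivity, auc = auc, source = source_id),
    class = "PharmacophoreModel"
  )
}

#' @export
print.PharmacophoreModel <- function(x, ...) {
  cat(sprintf("PharmacophoreModel %s [%s]: %d features, selectivity %.3f, AUC %s\n",
              x$model_id, feature_code(x), nrow(x$features), x$selectivity_score,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Generate complex-based pharmacophore models from a receptor-ligand complex
#'
#' Ligand features are perceived, filtered to those with a complementary
#' receptor environment (H-bond partner within `thresholds$hbond`, at least 3
#' apolar receptor atoms within `thresholds$hydrophobic` of a HYD/RA
#' centroid, oppositely charged receptor group within `thresholds$ionic`),
#' and all feature subsets of size `>= min_features` are scored for
#' selectivity against a background library. The `top_m` models by
#' selectivity are returned (ties: fewer features, then lexicographic letter
#' code).
#'
#' @param receptor a `ParsedStructure`.
#' @param ligand a `Molecule` with 3D coordinates (the bound pose).
#' @param background background library for selectivity scoring: list of
#'   `Molecule`s or of feature data.frames.
#' @param min_features minimum model size (default 3).
#' @param top_m number of models to return (default 10).
#' @param thresholds interaction distance thresholds (Angstrom).
#' @param tolerance,weight feature defaults.
#' @param max_complemented cap on complemented features entering subset
#'   enumeration; the nearest-complement features are kept if exceeded.
#' @param min_background minimum background size (default 50).
#' @return list of `PharmacophoreModel`s, ordered by decreasing selectivity.
#' @export
generate_models <- function(receptor, ligand, background,
                            min_features = 3, top_m = 10,
                            thresholds = default_interaction_thresholds(),
                            tolerance = 1.6, weight = 1,
                            max_complemented = 12, min_background = 50) {
  feats <- perceive_features(ligand, tolerance = tolerance, weight = weight)
  comp <- complement_features(feats, receptor, thresholds)
  if (nrow(comp) > max_complemented) comp <- comp[seq_len(max_complemented), , drop = FALSE]
  if (nrow(comp) < min_features) {
    stop("generate_models: only ", nrow(comp), " receptor-complemented features (need ",
         min_features, "). Rejected: ",
         paste(attr(comp, "rejected"), collapse = "; "))
  }
  n <- nrow(comp)
  subsets <- list()
  for (k in min_features:n) {
    cmb <- utils::combn(n, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  cand <- lapply(seq_along(subsets), function(i) {
    f <- comp[subsets[[i]], , drop = FALSE]
    m <- new_pharmacophore_model(f, model_id = sprintf("%s_m%03d", receptor$structure_id, i),
                                 source_id = receptor$structure_id)
    m$selectivity_score <- selectivity_score(m, background, min_background = min_background)
    m
  })
  sel <- vapply(cand, function(m) m$selectivity_score, numeric(1))
  sizes <- vapply(cand, function(m) nrow(m$features), numeric(1))
  codes <- vapply(cand, feature_code, character(1))
  ord <- order(-sel, sizes, codes)
  out <- cand[ord[seq_len(min(top_m, length(cand)))]]
  # stable model ids in rank order
  for (i in seq_along(out)) {
    out[[i]]$model_id <- sprintf("%s_r%02d_%s", receptor$structure_id, i,
                                 feature_code(out[[i]]))
  }
  out
}

#' Empirical-rarity selectivity score
#'
#' A model is selective when few background molecules can match it:
#' `score = -log10(max(m, 0.5) / N)` with `m` the number of background
#' molecules attaining `fit_value > 0` and `N` the background size. A model
#' matched by everything scores 0; rarer matches score higher, with the 0.5
#' floor keeping never-matched models finite.
#'
#' @param model a `PharmacophoreModel`.
#' @param background list of `Molecule`s or feature data.frames.
#' @param min_background minimum background size (default 50).
#' @return numeric selectivity score.
#' @export
selectivity_score <- function(model, background, min_background = 50) {
  n <- length(background)
  if (n == 0) stop("selectivity_score: empty background")
  if (n < min_background) {
    stop("selectivity_score: background has ", n, " molecules (need >= ",
         min_background, ")")
  }
  m <- sum(vapply(background, function(b) {
    fit_value(b, model)$fit_value > 0
  }, logical(1)))
  -log10(max(m, 0.5) / n)
}

# ---- fit values -------------------------------------------------------------

as_feature_conformers <- function(x) {
  if (inherits(x, "Molecule")) return(list(perceive_features(x)))
  if (is.data.frame(x)) return(list(x))
  if (is.list(x)) {
    return(lapply(x, function(el) {
      if (inherits(el, "Molecule")) perceive_features(el) else el
    }))
  }
  stop("fit_value: cannot interpret molecule input")
}

#' Fit value of a molecule against a pharmacophore model
#'
#' Over all conformers and all type-compatible injective assignments of
#' molecule features to ALL model features, the matched centers are
#' superposed (Kabsch) and per-feature displacements `d_f` computed. An
#' assignment is valid iff every `d_f <= tolerance_f`; its fit is
#' `sum_f weight_f * (1 - d_f / tolerance_f)` (or the squared-displacement
#' variant). The best valid assignment wins; with none, `matched = FALSE`
#' and fit 0.
#'
#' @param molecule a `Molecule`, a feature data.frame, or a list of either
#'   (conformers).
#' @param model a `PharmacophoreModel` (at most 8 features).
#' @param displacement `"linear"` (default) or `"squared"` penalty form.
#' @param compound_id id carried into the result.
#' @return An object of class `FitResult`: `compound_id`, `model_id`,
#'   `fit_value`, `matched`, `mapping` (molecule-feature row per model
#'   feature), `conformer`.
#' @export
fit_value <- function(molecule, model, displacement = c("linear", "squared"),
                      compound_id = NULL) {
  displacement <- match.arg(displacement)
  stopifnot(inherits(model, "PharmacophoreModel"))
  mf <- model$features
  if (nrow(mf) > 8) stop("fit_value: model exceeds the 8-feature cap")
  confs <- as_feature_conformers(molecule)
  if (is.null(compound_id)) {
    compound_id <- if (inherits(molecule, "Molecule")) molecule$id else "mol"
  }

  best <- list(fit = -Inf, mapping = NULL, conformer = NA_integer_)
  model_xyz <- as.matrix(mf[, c("x", "y", "z")])
  for (ci in seq_along(confs)) {
    lf <- confs[[ci]]
    if (is.null(lf) || nrow(lf) == 0) next
    lig_xyz <- as.matrix(lf[, c("x", "y", "z")])
    for (asn in enumerate_assignments(mf$type, lf$type)) {
      pts <- lig_xyz[asn, , drop = FALSE]
      sp <- superpose(model_xyz, pts)
      fitted <- apply_superposition(sp, pts)
      d <- sqrt(rowSums((fitted - model_xyz)^2))
      if (all(d <= mf$tolerance + 1e-9)) {
        fit <- if (displacement == "linear") {
          sum(mf$weight * (1 - d / mf$tolerance))
        } else {
          sum(mf$weight * (1 - (d / mf$tolerance)^2))
        }
        if (fit > best$fit) best <- list(fit = fit, mapping = asn, conformer = ci)
      }
    }
  }
  matched <- is.finite(best$fit)
  structure(
    list(compound_id = compound_id, model_id = model$model_id,
         fit_value = if (matched) max(best$fit, 0) else 0,
         matched = matched, mapping = best$mapping, conformer = best$conformer),
    class = "FitResult"
  )
}

# All injective assignments of molecule features (types `lig`) onto every
# model feature (types `mod`), as integer vectors indexed by model feature.
enumerate_assignments <- function(mod, lig, cap = 50000) {
  n <- length(mod)
  out <- list()
  recurse <- function(i, used, acc) {
    if (length(out) >= cap) return()
    if (i > n) {
      out[[length(out) + 1]] <<- acc
      return()
    }
    for (j in which(lig == mod[i])) {
      if (!(j %in% used)) recurse(i + 1, c(used, j), c(acc, j))
    }
  }
  recurse(1, integer(0), integer(0))
  out
}

#' Fit-value table of many molecules against many models
#'
#' @param molecules named list (ids) of `Molecule`s / feature frames /
#'   conformer lists.
#' @param models list of `PharmacophoreModel`s.
#' @param displacement penalty form passed to [fit_value()].
#' @return data.frame `compound_id`, `model_id`, `fit_value`, `matched`.
#' @export
fit_table <- function(molecules, models, displacement = "linear") {
  ids <- names(molecules)
  if (is.null(ids)) ids <- paste0("cmp", seq_along(molecules))
  rows <- list()
  for (i in seq_along(molecules)) {
    for (m in models) {
      fr <- fit_value(molecules[[i]], m, displacement = displacement,
                      compound_id = ids[i])
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = fr$compound_id, model_id = fr$model_id,
        fit_value = fr$fit_value, matched = fr$matched, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Discrimination AUC of a pharmacophore model
#'
#' Uses the model's fit values as a ranking score for the active class and
#' computes the rank-based (Mann-Whitney) AUC with midrank ties. Models with
#' AUC > 0.7 are flagged acceptable.
#'
#' @param model a `PharmacophoreModel`.
#' @param molecules list of molecules/feature frames (the validation set).
#' @param labels 0/1 vector aligned with `molecules`.
#' @return list with `auc`, `acceptable` (AUC > 0.7) and `fits`.
#' @export
model_auc <- function(model, molecules, labels) {
  if (length(unique(labels)) < 2) stop("model_auc: need both classes")
  fits <- vapply(molecules, function(m) fit_value(m, model)$fit_value, numeric(1))
  auc <- roc_auc(fits, labels)$auc
  list(auc = auc, acceptable = auc > 0.7, fits = fits)
}

#' Serialize pharmacophore models to JSON
#' @param models list of `PharmacophoreModel`s.
#' @param path output file.
#' @export
write_models_json <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(model_id = m$model_id, source = m$source,
         code = feature_code(m),
         selectivity_score = m$selectivity_score, auc = m$auc,
         features = m$features)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
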