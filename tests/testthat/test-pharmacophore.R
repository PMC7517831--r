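test_that("benzene perceives exactly one aromatic ring and one hydrophobic group", {
  f <- perceive_features(benzene_molecule())
  expect_equal(sum(f$type == "RA"), 1)
  expect_equal(sum(f$type == "HYD"), 1)
  expect_equal(sum(f$type %in% c("HBD", "HBA")), 0)
  # both centered at the ring centroid
  expect_equal(unname(unlist(f[f$type == "RA", c("x", "y", "z")])), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("methanol's oxygen both donates and accepts", {
  xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-0.6, 0.8, 0))
  bonds <- data.frame(a1 = c(1, 1), a2 = c(2, 3), order = 1L)
  meoh <- make_molecule(c("O", "C", "H"), xyz, bonds)
  f <- perceive_features(meoh)
  expect_equal(sum(f$type == "HBD"), 1)
  expect_equal(sum(f$type == "HBA"), 1)
  # both at the oxygen
  expect_equal(f$x[f$type == "HBD"], 0)
})

test_that("acetate carries one negative-ionizable feature at the carboxylate centroid", {
  xyz <- rbind(c(-1.5, 0, 0), c(0, 0, 0), c(0.6, 1.05, 0), c(0.6, -1.05, 0))
  bonds <- data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1L, 2L, 1L))
  ace <- make_molecule(c("C", "C", "O", "O"), xyz, bonds,
                       charge = c(0L, 0L, 0L, -1L))
  f <- perceive_features(ace)
  expect_equal(sum(f$type == "NI"), 1)
  ni <- f[f$type == "NI", ]
  expect_equal(c(ni$x, ni$y, ni$z), colMeans(xyz[2:4, ]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the deprotonated oxygen is not a donor
  expect_equal(sum(f$type == "HBD"), 0)
})

test_that("receptor complementation applies the distance thresholds feature by feature", {
  mk_cx <- function(d_hbd) {
    toy_complex_spec(data.frame(type = "HBD", partner_dist = d_hbd),
                     decoy_atoms = 0)
  }
  near <- make_toy_complex(mk_cx(3.0))
  far <- make_toy_complex(mk_cx(4.0))
  expect_true("HBD" %in% near$expected_types)
  expect_false("HBD" %in% far$expected_types)

  for (cx in list(near, far)) {
    pdb <- tempfile(fileext = ".pdb"); sdf <- tempfile(fileext = ".sdf")
    writeLines(cx$receptor_pdb, pdb); writeLines(cx$ligand_sdf, sdf)
    rec <- read_receptor_pdb(pdb)
    lig <- read_molecules_sdf(sdf)[[1]]
    comp <- ensembleVS:::complement_features(perceive_features(lig), rec)
    expect_setequal(comp$type, cx$expected_types)
  }
})

test_that("model generation returns the top 10 of all subsets, ordered by selectivity", {
  # toy complex with exactly 5 complemented features
  spec <- toy_complex_spec(
    data.frame(type = c("HBA", "HYD", "NI", "PI", "HYD"),
               partner_dist = c(3.0, 4.0, 5.0, 5.0, 4.2)),
    decoy_atoms = 4, seed = 2
  )
  cx <- make_toy_complex(spec)
  expect_length(cx$expected_types, 5)

  pdb <- tempfile(fileext = ".pdb"); sdf <- tempfile(fileext = ".sdf")
  writeLines(cx$receptor_pdb, pdb); writeLines(cx$ligand_sdf, sdf)
  rec <- read_receptor_pdb(pdb)
  lig <- read_molecules_sdf(sdf)[[1]]
  bg <- random_background(60, seed = 31)

  models <- generate_models(rec, lig, bg, min_features = 3, top_m = 10)
  expect_length(models, 10)
  expect_true(all(vapply(models, function(m) nrow(m$features) >= 3, logical(1))))

  # oracle: brute-force re-scoring of all C(5,3)+C(5,4)+C(5,5) = 16 subsets
  comp <- ensembleVS:::complement_features(perceive_features(lig), rec)
  expect_equal(nrow(comp), 5)
  subsets <- unlist(lapply(3:5, function(k) utils::combn(5, k, simplify = FALSE)),
                    recursive = FALSE)
  expect_length(subsets, 16)
  oracle <- lapply(subsets, function(s) {
    m <- ensembleVS:::new_pharmacophore_model(comp[s, , drop = FALSE], "o")
    list(sel = selectivity_score(m, bg), size = length(s),
         code = feature_code(m))
  })
  sel <- vapply(oracle, `[[`, numeric(1), "sel")
  size <- vapply(oracle, `[[`, numeric(1), "size")
  code <- vapply(oracle, `[[`, character(1), "code")
  ord <- order(-sel, size, code)[1:10]
  expect_equal(vapply(models, function(m) m$selectivity_score, numeric(1)),
               sel[ord], tolerance = 1e-12)
  expect_equal(vapply(models, feature_code, character(1)), code[ord])

  # deterministic total order: a second run is identical
  models2 <- generate_models(rec, lig, bg, min_features = 3, top_m = 10)
  expect_identical(lapply(models, `[[`, "features"),
                   lapply(models2, `[[`, "features"))
})

test_that("too few complemented features is an explanatory error", {
  spec <- toy_complex_spec(data.frame(type = c("HBA", "HYD"),
                                      partner_dist = c(5.0, 6.0)),
                           decoy_atoms = 0)
  cx <- make_toy_complex(spec)
  pdb <- tempfile(fileext = ".pdb"); sdf <- tempfile(fileext = ".sdf")
  writeLines(cx$receptor_pdb, pdb); writeLines(cx$ligand_sdf, sdf)
  expect_error(
    generate_models(read_receptor_pdb(pdb), read_molecules_sdf(sdf)[[1]],
                    random_background(60, 1)),
    "complemented features"
  )
})

test_that("selectivity score follows the rarity formula with its 0.5 floor", {
  model <- make_model(c("HBA", "HBD", "HYD"),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  # background where every molecule matches exactly (features coincide)
  match_all <- replicate(60, model$features, simplify = FALSE)
  expect_equal(selectivity_score(model, match_all), 0)

  # background where nothing can match (wrong types entirely)
  no_match <- replicate(1000, data.frame(type = "PI", x = 0, y = 0, z = 0,
                                         tolerance = 1.6, weight = 1),
                        simplify = FALSE)
  expect_equal(selectivity_score(model, no_match), -log10(0.5 / 1000),
               tolerance = 1e-12)

  # planted background: exactly 10 matchers among 1000 -> score 2.0
  planted <- c(replicate(10, model$features, simplify = FALSE),
               replicate(990, data.frame(type = "PI", x = 0, y = 0, z = 0,
                                         tolerance = 1.6, weight = 1),
                         simplify = FALSE))
  expect_equal(selectivity_score(model, planted), 2.0, tolerance = 1e-12)

  expect_error(selectivity_score(model, list()), "empty")
  expect_error(selectivity_score(model, match_all[1:10]), "need >= 50")
})

test_that("a molecule coinciding with the model attains fit = sum of weights", {
  model <- make_model(c("HBA", "HBD", "HYD"),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                      weight = c(1, 2, 0.5))
  fr <- fit_value(model$features, model)
  expect_true(fr$matched)
  expect_equal(fr$fit_value, 3.5, tolerance = 1e-9)
})

test_that("displacement exactly at tolerance gives fit 0 but matched TRUE", {
  tol <- 1.6
  # equilateral triangle centered at the origin: radial expansion preserves
  # the centroid and leaves the optimal rotation at identity, so after
  # superposition every feature sits exactly tol from its model center
  r <- 5
  ang <- c(0, 2, 4) * pi / 3
  xyz <- cbind(r * cos(ang), r * sin(ang), 0)
  model <- make_model(c("HBA", "HBD", "HYD"), xyz, tolerance = tol)

  # pure translation is removed by the fit
  f <- model$features
  f$z <- f$z + tol
  fr0 <- fit_value(f, model)
  expect_equal(fr0$fit_value, sum(f$weight), tolerance = 1e-9)

  # radial expansion by exactly tol
  g <- model$features
  g[, c("x", "y", "z")] <- xyz * (r + tol) / r
  frt <- fit_value(g, model)
  expect_true(frt$matched)
  expect_equal(frt$fit_value, 0, tolerance = 1e-6)
})

test_that("fit value equals the exhaustive assignment-and-conformer oracle", {
  model <- make_model(c("HBA", "HBA", "HYD"),
                      rbind(c(0, 0, 0), c(3.4, 0, 0), c(1.5, 2.8, 0)),
                      tolerance = 1.6)
  # 4-feature molecule (3 HBA + 1 HYD), two conformers
  set.seed(131)
  conf <- lapply(1:2, function(ci) {
    data.frame(type = c("HBA", "HBA", "HBA", "HYD"),
               x = c(0.2, 3.1, 5.0, 1.4) + stats::rnorm(4, sd = 0.2),
               y = c(-0.1, 0.3, 1.0, 2.9) + stats::rnorm(4, sd = 0.2),
               z = stats::rnorm(4, sd = 0.2),
               tolerance = 1.6, weight = 1)
  })
  fr <- fit_value(conf, model)

  # oracle: brute force over both conformers and all injective assignments
  best <- 0; any_match <- FALSE
  mxyz <- as.matrix(model$features[, c("x", "y", "z")])
  for (cf in conf) {
    hba_idx <- which(cf$type == "HBA"); hyd_idx <- which(cf$type == "HYD")
    for (p in all_perms(hba_idx)) {
      for (h in hyd_idx) {
        asn <- c(p[1], p[2], h)   # model features 1, 2 are HBA, 3 is HYD
        pts <- as.matrix(cf[asn, c("x", "y", "z")])
        sp <- superpose(mxyz, pts)
        d <- sqrt(rowSums((apply_superposition(sp, pts) - mxyz)^2))
        if (all(d <= 1.6 + 1e-9)) {
          any_match <- TRUE
          best <- max(best, sum(1 - d / 1.6))
        }
      }
    }
  }
  expect_equal(fr$matched, any_match)
  expect_equal(fr$fit_value, max(best, 0), tolerance = 1e-9)
})

test_that("fit value is invariant under rigid motion of the conformer", {
  model <- make_model(c("HBA", "HBD", "HYD", "RA"),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(2, 2, 2)))
  set.seed(141)
  f <- model$features
  f[, c("x", "y", "z")] <- f[, c("x", "y", "z")] +
    matrix(stats::rnorm(12, sd = 0.3), 4, 3)
  base <- fit_value(f, model)$fit_value
  for (s in 1:4) {
    set.seed(s)
    rot <- rotation_xyz(stats::runif(1, 0, pi), stats::runif(1, 0, pi),
                        stats::runif(1, 0, pi))
    g <- f
    g[, c("x", "y", "z")] <-
      sweep(as.matrix(f[, c("x", "y", "z")]) %*% t(rot), 2, stats::rnorm(3, sd = 5), `+`)
    expect_equal(fit_value(g, model)$fit_value, base, tolerance = 1e-6)
  }
  # fit never exceeds the weight sum
  expect_lte(base, sum(model$features$weight))
})

test_that("removing a model feature can only widen the matching set", {
  full <- make_model(c("HBA", "HBD", "HYD", "NI"),
                     rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(3, 3, 0)))
  reduced <- ensembleVS:::new_pharmacophore_model(full$features[1:3, ], "red")
  bg <- random_background(80, seed = 151)
  m_full <- sum(vapply(bg, function(b) fit_value(b, full)$fit_value > 0, logical(1)))
  m_red <- sum(vapply(bg, function(b) fit_value(b, reduced)$fit_value > 0, logical(1)))
  expect_gte(m_red, m_full)
  expect_gte(selectivity_score(full, bg), selectivity_score(reduced, bg))
})

test_that("model AUC flags discriminating models through the 0.7 gate", {
  model <- make_model(c("HBA", "HBD", "HYD"),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  set.seed(161)
  actives <- lapply(1:15, function(i) {
    f <- model$features
    f[, c("x", "y", "z")] <- f[, c("x", "y", "z")] + matrix(stats::rnorm(9, sd = 0.2), 3, 3)
    f
  })
  decoys <- random_background(30, seed = 162)
  res <- model_auc(model, c(actives, decoys), c(rep(1, 15), rep(0, 30)))
  expect_gt(res$auc, 0.7)
  expect_true(res$acceptable)
  expect_error(model_auc(model, actives, rep(1, 15)), "both classes")
})
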