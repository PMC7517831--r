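test_that("descriptor assembly row-aligns docking and fit blocks with missing markers", {
  sm <- score_matrix(c("c1", "c2", "c3"),
                     cbind(c(-9, -8, NA), c(-7, NA, -6)),
                     data.frame(structure_id = c("S1", "S2"), mode = "XP"))
  fits <- data.frame(compound_id = rep(c("c1", "c2", "c3"), 2),
                     model_id = rep(c("m1", "m2"), each = 3),
                     fit_value = c(2, 1, 0, 3, 0, 1), matched = TRUE)
  dm <- assemble_matrix(scores = sm, fits = fits)
  expect_equal(ncol(dm$x), 4)  # 2 structures x 1 mode + 2 models
  expect_true(is.na(dm$x["c2", "S2.XP"]))
  expect_equal(unname(dm$x["c1", "fit.m2"]), 3)
})

test_that("the AUC > 0.7 gate on a synthetic model table matches hand selection", {
  # analogue of a per-model discrimination table: keep the models over 0.7
  model_table <- data.frame(
    model_id = c("1Q4L_D", "4NM3_D", "3L1S_D", "2OW3_D", "4B7T_D"),
    auc = c(0.711, 0.502, 0.657, 0.709, 0.567)
  )
  gate <- model_table$model_id[model_table$auc > 0.7]
  expect_equal(gate, c("1Q4L_D", "2OW3_D"))

  fits <- data.frame(compound_id = rep(c("c1", "c2"), 5),
                     model_id = rep(model_table$model_id, each = 2),
                     fit_value = stats::runif(10), matched = TRUE)
  dm <- assemble_matrix(fits = fits, chosen_models = gate)
  expect_equal(colnames(dm$x), c("fit.1Q4L_D", "fit.2OW3_D"))
})

test_that("compounds with every descriptor missing are dropped with a message", {
  sm <- score_matrix(c("c1", "c2"), cbind(c(-9, NA)),
                     data.frame(structure_id = "S1", mode = "XP"))
  expect_message(dm <- assemble_matrix(scores = sm), "dropped")
  expect_equal(dm$compound_id, "c1")
  expect_error(assemble_matrix(scores = sm, chosen_columns = "nope.XP"), "unknown")
})

test_that("equal-frequency cuts land on deciles and handle constant columns", {
  m <- cbind(a = as.numeric(1:100))
  sch <- fit_bins(m, n_bins = 10)
  expect_equal(sch$a, as.numeric(stats::quantile(1:100, seq(0.1, 0.9, 0.1), names = FALSE)))

  mc <- cbind(k = rep(5, 50))
  expect_warning(schc <- fit_bins(mc, n_bins = 10), "constant")
  expect_length(schc$k, 0)  # single bin

  # skewed sample: each of 5 bins holds 20% of rows (within rounding)
  set.seed(171)
  v <- stats::rexp(1000)
  sch5 <- fit_bins(cbind(x = v), n_bins = 5)
  bins <- ensembleVS:::bin_values(v, sch5$x)
  counts <- table(bins)
  expect_true(all(abs(counts - 200) <= 1))
})

test_that("NB weights match the hand-computed Laplacian-corrected form on an 8-row table", {
  # two columns, two bins each; hand-traceable counts
  x <- cbind(d = c(-9, -8.5, -8, -7.5, -6, -5.5, -5, -4.5),
             f = c(3, 1, 3, 1, 3, 1, 1, 1))
  dm <- structure(list(compound_id = paste0("c", 1:8), x = x,
                       label = c(1, 1, 1, 0, 0, 0, 0, 0),
                       provenance = list()), class = "DescriptorMatrix")
  scheme <- structure(list(d = -7.0, f = 2), class = "BinningScheme")
  model <- train_nb(dm, scheme = scheme)
  p <- 3 / 8
  expect_equal(model$base_rate, p)

  # column d, bin 1 (<= -7): rows 1-4, actives 1-3 -> A=3, B=4
  wd <- model$weights$d
  expect_equal(wd$w[wd$bin == 1], log((3 + 1) / (4 * p + 1)), tolerance = 1e-12)
  # column d, bin 2 (> -7): rows 5-8, actives 0 -> A=0, B=4
  expect_equal(wd$w[wd$bin == 2], log(1 / (4 * p + 1)), tolerance = 1e-12)
  # column f, bin 1 (<= 2): rows {2,4,6,7,8}, actives {2} -> A=1, B=5
  wf <- model$weights$f
  expect_equal(wf$w[wf$bin == 1], log((1 + 1) / (5 * p + 1)), tolerance = 1e-12)
  # column f, bin 2: rows {1,3,5}, actives {1,3} -> A=2, B=3
  expect_equal(wf$w[wf$bin == 2], log((2 + 1) / (3 * p + 1)), tolerance = 1e-12)

  # scoring a row is the sum of its bin weights
  s <- score_nb(model, dm)
  expect_equal(unname(s["c1"]),
               log(4 / (4 * p + 1)) + log(3 / (3 * p + 1)), tolerance = 1e-12)
})

test_that("a feature present at the base rate in every class is weightless", {
  # every row shows the same bin, actives at base rate: A = B * p exactly
  x <- cbind(u = rep(1, 10))
  dm <- structure(list(compound_id = paste0("c", 1:10), x = x,
                       label = c(rep(1, 4), rep(0, 6)), provenance = list()),
                  class = "DescriptorMatrix")
  model <- suppressWarnings(train_nb(dm, n_bins = 2))
  w <- model$weights$u
  expect_equal(w$w[w$B > 0], 0, tolerance = 1e-12)  # ln((4+1)/(10*0.4+1)) = 0
})

test_that("bins never seen in training contribute zero at scoring time", {
  x <- cbind(d = c(1, 2, 3, 4))
  dm <- structure(list(compound_id = paste0("c", 1:4), x = x,
                       label = c(1, 1, 0, 0), provenance = list()),
                  class = "DescriptorMatrix")
  model <- train_nb(dm, n_bins = 2)
  # missing bin (bin 0) never seen in training: A = 0, B = 0 -> w = ln(1/1) = 0
  w0 <- model$weights$d
  expect_equal(w0$w[w0$bin == 0], 0)
  # scoring a row with a missing value adds that zero
  s <- score_nb(model, cbind(d = NA_real_))
  expect_equal(unname(s), 0)
})

test_that("NB scoring equals brute-force lookup-and-sum on random rows", {
  set.seed(181)
  x <- cbind(a = stats::rnorm(200), b = stats::rnorm(200), c = stats::rnorm(200))
  dm <- structure(list(compound_id = sprintf("c%03d", 1:200), x = x,
                       label = rep(c(1, 0), each = 100), provenance = list()),
                  class = "DescriptorMatrix")
  model <- train_nb(dm, n_bins = 5)
  newx <- cbind(a = stats::rnorm(20), b = stats::rnorm(20), c = stats::rnorm(20))
  s <- score_nb(model, newx)

  for (i in 1:20) {
    manual <- 0
    for (col in c("a", "b", "c")) {
      bin <- ensembleVS:::bin_values(newx[i, col], model$scheme[[col]])
      wt <- model$weights[[col]]
      hit <- wt$w[wt$bin == bin]
      manual <- manual + if (length(hit)) hit else 0
    }
    expect_equal(unname(s[i]), manual, tolerance = 1e-12)
  }
})

test_that("training rejects unlabeled or single-class matrices", {
  x <- cbind(a = 1:4)
  dm1 <- structure(list(compound_id = paste0("c", 1:4), x = x, label = NULL,
                        provenance = list()), class = "DescriptorMatrix")
  expect_error(train_nb(dm1), "no labels")
  dm2 <- structure(list(compound_id = paste0("c", 1:4), x = x,
                        label = rep(1, 4), provenance = list()),
                   class = "DescriptorMatrix")
  expect_error(train_nb(dm2), "single-class")
})

test_that("rank AUC handles perfect separation, pure ties and the hand example", {
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(1, 0), 5))$auc, 0.5)
  # hand count: 5 of 6 active-decoy pairs concordant
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6, 0.4), c(1, 1, 0, 1, 0))$auc, 5 / 6)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is complementary under label flip and matches pROC", {
  set.seed(191)
  s <- stats::rnorm(300)
  y <- as.integer(stats::runif(300) < stats::plogis(s))
  if (length(unique(y)) == 2) {
    a1 <- roc_auc(s, y)$auc
    a2 <- roc_auc(s, 1 - y)$auc
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(a1, ref, tolerance = 1e-12)
  }
})

test_that("column shifts change neither binning structure nor AUC", {
  set.seed(201)
  bench <- make_score_benchmark(score_benchmark_spec(
    n_active = 300, n_decoy = 1500,
    columns = data.frame(structure_id = "S1", mode = "XP",
                         mu_active = -9, mu_decoy = -7, sigma = 1),
    seed = 7))
  dm <- assemble_matrix(scores = bench$scores, labels = bench$labels)
  auc1 <- roc_auc(score_nb(train_nb(dm), dm), dm$label)$auc
  dm$x[, 1] <- dm$x[, 1] + 42
  auc2 <- roc_auc(score_nb(train_nb(dm), dm), dm$label)$auc
  expect_equal(auc1, auc2, tolerance = 1e-12)
})

test_that("training and scoring are invariant to row permutation", {
  set.seed(211)
  x <- cbind(a = stats::rnorm(100), b = stats::rnorm(100))
  y <- rep(c(1, 0), 50)
  dm <- structure(list(compound_id = sprintf("c%03d", 1:100), x = x, label = y,
                       provenance = list()), class = "DescriptorMatrix")
  perm <- sample(100)
  dmp <- structure(list(compound_id = dm$compound_id[perm],
                        x = x[perm, ], label = y[perm], provenance = list()),
                   class = "DescriptorMatrix")
  s1 <- score_nb(train_nb(dm), dm)
  s2 <- score_nb(train_nb(dmp), dmp)
  expect_equal(s1[dm$compound_id], s2[dm$compound_id], tolerance = 1e-12)
})

test_that("single-column Gaussian NB converges to the closed-form AUC", {
  # actives ~ N(mu1, s), decoys ~ N(mu0, s): ranking AUC -> Phi(d / sqrt(2))
  bench <- make_score_benchmark(score_benchmark_spec(
    n_active = 10000, n_decoy = 10000,
    columns = data.frame(structure_id = "S1", mode = "XP",
                         mu_active = -9, mu_decoy = -9 + sqrt(2), sigma = 1),
    seed = 17))
  dm <- assemble_matrix(scores = bench$scores, labels = bench$labels)
  model <- train_nb(dm, n_bins = 10)
  auc <- roc_auc(score_nb(model, dm), dm$label)$auc
  expect_equal(auc, stats::pnorm(1), tolerance = 0.02)
})

test_that("NB model JSON serialization round-trips", {
  set.seed(221)
  x <- cbind(a = stats::rnorm(60), b = stats::rnorm(60))
  dm <- structure(list(compound_id = sprintf("c%02d", 1:60), x = x,
                       label = rep(c(1, 0), 30), provenance = list()),
                  class = "DescriptorMatrix")
  model <- train_nb(dm, n_bins = 4)
  f <- tempfile(fileext = ".json")
  write_nb_json(model, f)
  back <- read_nb_json(f)
  expect_equal(back$base_rate, model$base_rate)
  expect_equal(score_nb(back, x), score_nb(model, x), tolerance = 1e-12)
})

test_that("cross-validated AUC is close to but not above the apparent optimum", {
  set.seed(231)
  bench <- make_score_benchmark(score_benchmark_spec(
    n_active = 500, n_decoy = 2500,
    columns = data.frame(structure_id = "S1", mode = "XP",
                         mu_active = -9, mu_decoy = -7, sigma = 1),
    seed = 23))
  dm <- assemble_matrix(scores = bench$scores, labels = bench$labels)
  cv <- nb_cv_auc(dm, folds = 5, seed = 3)
  apparent <- roc_auc(score_nb(train_nb(dm), dm), dm$label)$auc
  expect_gt(cv$auc, 0.8)          # signal survives held-out evaluation
  expect_lt(cv$auc, apparent + 0.02)
})
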