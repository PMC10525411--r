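test_that("feature expansion matches its definitions", {
  X <- cbind(x = c(0, 1, 2))
  fl <- build_features(X, feature_spec("L"))
  expect_equal(ncol(fl$features), 1)
  expect_equal(drop(fl$features), c(0, 0.5, 1))   # (x - min) / (max - min)

  # forward hinge at knot 1: max(0, x - 1) / (2 - 1) = (0, 0, 1)
  Xh <- cbind(x = seq(0, 2, length.out = 21))
  fh <- build_features(Xh, feature_spec("H", n_hinge_knots = 19))
  fwd1 <- fh$features[, "HF.x.1"]
  expect_equal(unname(fwd1[c(1, 11, 21)]), c(0, 0, 1))

  # two covariates, classes {L, Q, P}: 2 + 2 + 1 = 5 columns
  X2 <- cbind(a = rnorm(30), b = rnorm(30))
  f2 <- build_features(X2, feature_spec("LQP"))
  expect_equal(ncol(f2$features), 5)
  expect_true(all(f2$features >= 0 & f2$features <= 1))

  # threshold features are step indicators
  ft <- build_features(Xh, feature_spec("T", n_threshold_knots = 3))
  expect_true(all(ft$features %in% c(0, 1)))

  # constant covariate contributes only its linear column, with a warning
  Xc <- cbind(a = rnorm(20), k = rep(2, 20))
  expect_warning(fc <- build_features(Xc, feature_spec("LQ")), "constant")
  expect_setequal(colnames(fc$features), c("L.a", "L.k", "Q.a"))
})

test_that("a frozen feature map reproduces the training transform on new data", {
  set.seed(5)
  X <- cbind(a = runif(100, -3, 7), b = runif(100, 0, 1000))
  f <- build_features(X, feature_spec("LQHT", n_hinge_knots = 5,
                                      n_threshold_knots = 4))
  f2 <- build_features(X[1:10, ], map = f$map)
  expect_identical(f2$features, f$features[1:10, ])
  expect_error(build_features(cbind(a = 1:5), map = f$map), "missing covariate")
})

test_that("huge regularization shrinks every coefficient to zero", {
  w <- recovery_world(1, n_presence = 60)
  mod <- fit_maxent(w$presence_X, w$background_X, feature_spec("LQ"),
                    rm = 1e6)
  expect_true(all(mod$coefficients == 0))
  pred <- predict(mod, w$background_X, link = "raw")
  expect_lt(diff(range(pred)), 1e-12)           # constant over cells
})

test_that("a high-x presence gradient yields a positive linear coefficient", {
  set.seed(8)
  bg <- cbind(x = runif(1000, 0, 10))
  pres <- cbind(x = 10 - abs(rnorm(100, 0, 1.5)))  # concentrated at high x
  mod <- fit_maxent(pres, bg, feature_spec("L"), rm = 0.5)
  expect_gt(mod$coefficients[["L.x"]], 0)
})

test_that("the penalized fit matches brute-force constrained entropy on a tiny world", {
  # 6 cells, one covariate, linear features, vanishing penalty
  cells <- cbind(x = c(0, 1, 2, 3, 4, 5))
  presence <- cbind(x = c(3, 4, 4, 5, 5, 5, 2, 4, 3, 5))
  mod <- suppressWarnings( # 6 background cells by construction
    fit_maxent(presence, cells, feature_spec("L"), rm = 1e-4, tol = 1e-10))
  gibbs_p <- predict(mod, cells, link = "raw")
  f_scaled <- build_features(cells, map = mod$map)$features
  target <- colMeans(build_features(presence, map = mod$map)$features)
  oracle_p <- brute_force_simplex_entropy(f_scaled, target)
  expect_lt(max(abs(gibbs_p - oracle_p)), 1e-3)
  expect_equal(sum(gibbs_p), 1, tolerance = 1e-8)
})

test_that("raw predictions normalize over the training background; links are monotone", {
  w <- recovery_world(2, n_presence = 120)
  mod <- fit_maxent(w$presence_X, w$background_X, feature_spec("LQH",
                    n_hinge_knots = 8), rm = 1)
  raw <- predict(mod, w$background_X, link = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-8)
  logi <- predict(mod, w$background_X, link = "logistic")
  clog <- predict(mod, w$background_X, link = "cloglog")
  expect_true(all(logi >= 0 & logi <= 1))
  expect_true(all(clog >= 0 & clog <= 1))
  expect_identical(order(raw), order(logi))
  expect_identical(order(raw), order(clog))
  # intercept-free Gibbs density: identical covariates -> identical outputs
  expect_error(predict(mod, w$background_X[, 1:2]), "missing model covariate")
})

test_that("prediction over a stack propagates nodata", {
  w <- recovery_world(3, n_presence = 80)
  mod <- fit_maxent(w$presence_X, w$background_X, feature_spec("LQ"), rm = 1)
  st <- w$stack
  st$layers$bio1$values[1, 1] <- NA
  suit <- predict(mod, st, link = "cloglog")
  expect_s3_class(suit, "raster_grid")
  expect_true(is.na(suit$values[1, 1]))
  expect_true(all(suit$values[-1] >= 0 & suit$values[-1] <= 1, na.rm = TRUE))
})

test_that("AUC equals the brute-force pairwise comparison statistic", {
  sp <- c(0.9, 0.7, 0.5, 0.3)
  sb <- c(0.8, 0.5, 0.2, 0.1)
  pairs <- outer(sp, sb, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(evaluate_auc(sp, sb), mean(pairs))
  expect_equal(evaluate_auc(c(3, 4), c(1, 2)), 1)        # perfect ranking
  expect_equal(evaluate_auc(rep(1, 5), rep(1, 7)), 0.5)  # all ties
  # invariance under strictly monotone transforms
  set.seed(13)
  a <- rnorm(50); b <- rnorm(60)
  expect_equal(evaluate_auc(exp(a), exp(b)), evaluate_auc(a, b))
  expect_equal(evaluate_auc(qlogis(plogis(a)), b), evaluate_auc(a, b))
})

test_that("AICc follows its formula and tuning selects the minimum", {
  k <- 3; lnL <- -100; n <- 50
  expect_equal(2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
               206.5217391304348)
  w <- recovery_world(4, n_presence = 100)
  tr <- tune_maxent(w$presence_X, w$background_X,
                    rm_grid = c(0.5, 1, 2, 4), fc_sets = list("L", "LQ"),
                    n_hinge_knots = 5, n_threshold_knots = 5)
  expect_equal(nrow(tr$candidates), 8)
  expect_equal(min(tr$candidates$delta_AICc), 0)
  expect_equal(tr$candidates$delta_AICc[tr$selected], 0)
  # AICc recomputed from the reported k and lnL
  with(tr$candidates[is.finite(tr$candidates$AICc), ], {
    n <- nrow(w$presence_X)
    expect_equal(AICc, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))
  })
  # single candidate: delta 0 and selected
  tr1 <- tune_maxent(w$presence_X, w$background_X, rm_grid = 1,
                     fc_sets = list("L"))
  expect_equal(nrow(tr1$candidates), 1)
  expect_equal(tr1$selected, 1)
  expect_equal(tr1$candidates$delta_AICc, 0)
})

test_that("more regularization shrinks the model across the tuning grid", {
  for (s in c(4, 5)) {
    w <- recovery_world(s, n_presence = 100)
    fits_lq <- lapply(seq(0.5, 4, 0.5), function(rm)
      fit_maxent(w$presence_X, w$background_X, feature_spec("LQ"), rm = rm))
    ks <- vapply(fits_lq, function(m) sum(m$coefficients != 0), numeric(1))
    expect_true(all(diff(ks) <= 0))
    # with the large hinge dictionary the active set can occasionally swap
    # members, but the penalty-weighted coefficient norm always shrinks as
    # the multiplier grows
    norms <- vapply(seq(0.5, 4, 0.5), function(rm) {
      m <- fit_maxent(w$presence_X, w$background_X,
                      feature_spec("LQH", n_hinge_knots = 6), rm = rm)
      ok <- is.finite(m$penalties)
      sum((m$penalties[ok] / rm) * abs(m$coefficients[ok]))
    }, numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("jackknife gains identify the informative covariate", {
  w <- recovery_world(6, n_presence = 150)
  jk <- jackknife_importance(w$presence_X, w$background_X,
                             feature_spec("LQ"), rm = 1)
  # bio1 drives the virtual species; its with-only gain dominates
  expect_equal(jk$variable[which.max(jk$gain_with_only)], "bio1")
  # full-model gain >= each single-variable gain (nested fits, equal penalty)
  expect_gte(attr(jk, "full_gain"), max(jk$gain_with_only) - 1e-6)

  # duplicated covariate: leaving one copy out costs nothing
  X <- cbind(w$presence_X[, "bio1", drop = FALSE],
             bio1b = w$presence_X[, "bio1"])
  B <- cbind(w$background_X[, "bio1", drop = FALSE],
             bio1b = w$background_X[, "bio1"])
  colnames(X)[1] <- "bio1"
  jk2 <- jackknife_importance(X, B, feature_spec("LQ"), rm = 1)
  full <- attr(jk2, "full_gain")
  expect_lt(max(abs(full - jk2$gain_without)), 0.02)
})

test_that("permutation contributions sum to 100 and favour signal over noise", {
  w <- recovery_world(7, n_presence = 150)
  mod <- fit_maxent(w$presence_X, w$background_X, feature_spec("LQ"), rm = 1)
  pc <- percent_contribution(mod, w$presence_X, w$background_X,
                             permutations = 5, seed = 99)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_true(all(pc >= 0))
  expect_equal(names(which.max(pc)), "bio1")
  # determinism under a fixed seed
  pc2 <- percent_contribution(mod, w$presence_X, w$background_X,
                              permutations = 5, seed = 99)
  expect_identical(pc, pc2)
  # single-covariate model concentrates everything
  mod1 <- fit_maxent(w$presence_X[, "bio1", drop = FALSE],
                     w$background_X[, "bio1", drop = FALSE],
                     feature_spec("LQ"), rm = 1)
  pc1 <- percent_contribution(mod1, w$presence_X[, "bio1", drop = FALSE],
                              w$background_X[, "bio1", drop = FALSE],
                              permutations = 3, seed = 1)
  expect_equal(unname(pc1), 100)
})

test_that("response curves recover a Gaussian optimum and stay in [0,1]", {
  w <- recovery_world(8, n_presence = 250)
  mod <- fit_maxent(w$presence_X, w$background_X, feature_spec("LQ"),
                    rm = 1)
  rc <- response_curve(mod, "bio1", link = "cloglog")
  expect_true(all(rc$suitability >= 0 & rc$suitability <= 1))
  peak <- rc$x[which.max(rc$suitability)]
  rng <- diff(range(w$background_X[, "bio1"]))
  expect_lt(abs(peak - 15), 0.05 * rng)
  expect_error(response_curve(mod, "nope"), "unknown variable")
})

test_that("models serialize to JSON and restore identical predictions", {
  w <- recovery_world(9, n_presence = 100)
  mod <- fit_maxent(w$presence_X, w$background_X,
                    feature_spec("LQH", n_hinge_knots = 6), rm = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(mod, p)
  mod2 <- read_maxent_model(p)
  expect_equal(predict(mod2, w$background_X, link = "cloglog"),
               predict(mod, w$background_X, link = "cloglog"),
               tolerance = 1e-12)
})
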