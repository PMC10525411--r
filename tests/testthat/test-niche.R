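toy_space <- function(R = 4) {
  structure(list(loadings = diag(2), explained_variance = c(0.6, 0.4),
                 center = c(0, 0), scale = c(1, 1),
                 bounds = list(x = c(0, 1), y = c(0, 1)), grid_R = R),
            class = "env_space")
}

toy_grid <- function(z, mask = NULL, R = nrow(z)) {
  z <- z / sum(z)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(z), ncol(z))
  structure(list(z = z, z_raw = z, mask = mask, grid_R = R,
                 bounds = list(x = c(0, 1), y = c(0, 1))),
            class = "occupancy_grid")
}

test_that("background sampling respects extent, latitude limit, and seed", {
  st <- make_climate_stack(grid_spec(20, 20, west = 0, north = 80,
                                     cell_deg = 4), n_vars = 2, seed = 1)
  bg <- sample_background(st, n = 50, lat_limit = 70, seed = 7)
  expect_true(all(abs(bg$latitude) <= 70))
  bg2 <- sample_background(st, n = 50, lat_limit = 70, seed = 7)
  expect_identical(as.data.frame(bg), as.data.frame(bg2))

  # exhaustion: a 5-cell extent cannot yield 8000 points
  ext <- matrix(FALSE, 20, 20); ext[10, 1:5] <- TRUE
  expect_warning(bg3 <- sample_background(st, ext, n = 8000, seed = 1),
                 "eligible")
  expect_equal(nrow(bg3), 5)
})

test_that("environmental space axes are orthonormal, centred, and ordered", {
  set.seed(3)
  n <- 400
  z <- rnorm(n)
  bg1 <- cbind(a = z + rnorm(n, sd = 0.1), b = z + rnorm(n, sd = 0.1),
               c = rnorm(n), d = rnorm(n))
  bg2 <- bg1 + 0.2
  sp <- build_env_space(bg1, bg2)
  expect_equal(crossprod(sp$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  ev <- sp$explained_variance
  expect_true(all(ev > 0 & ev <= 1) && diff(ev) <= 0)
  sc <- env_scores(sp, rbind(bg1, bg2))
  expect_equal(colMeans(sc), c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  # axis 1 loads on the correlated pair (eigen-oracle on the correlation)
  ld1 <- abs(sp$loadings[, 1])
  expect_true(all(ld1[c("a", "b")] > max(ld1[c("c", "d")])))
  eig <- eigen(cor(rbind(bg1, bg2)))$vectors[, 1]
  expect_gt(abs(sum(eig * sp$loadings[, 1])), 0.99)
  expect_error(build_env_space(bg1[, 1:2], bg2[, 1:2]), "3 covariates")
})

test_that("occupancy correction flattens occurrences that mirror the background", {
  set.seed(5)
  n <- 2000
  bg <- cbind(a = runif(n, -1, 1), b = runif(n, -1, 1), c = runif(n, -1, 1))
  occ <- cbind(a = runif(n, -1, 1), b = runif(n, -1, 1), c = runif(n, -1, 1))
  sp <- build_env_space(bg, bg, grid_R = 25)
  z <- occupancy_grid(env_scores(sp, occ), env_scores(sp, bg), sp)
  expect_equal(sum(z$z), 1, tolerance = 1e-8)
  core <- z$z[8:18, 8:18]   # interior of the occupied square
  expect_lt(max(core) / min(core[core > 0]), 2)
})

test_that("a tight occurrence cluster concentrates occupancy mass locally", {
  set.seed(6)
  n <- 1500
  bg <- cbind(a = runif(n, -1, 1), b = runif(n, -1, 1), c = rnorm(n))
  occ <- cbind(a = rnorm(200, 0.6, 0.05), b = rnorm(200, 0.6, 0.05),
               c = rnorm(200, 1, 0.05))
  sp <- build_env_space(bg, bg, grid_R = 50)
  zs <- occupancy_grid(env_scores(sp, occ), env_scores(sp, bg), sp)
  ctr <- colMeans(env_scores(sp, occ))
  gx <- seq(sp$bounds$x[1], sp$bounds$x[2], length.out = 50)
  gy <- seq(sp$bounds$y[1], sp$bounds$y[2], length.out = 50)
  same_quadrant <- outer(sign(gx) == sign(ctr[1]),
                         sign(gy) == sign(ctr[2]), `&`)
  expect_gt(sum(zs$z[same_quadrant]), 0.99)
})

test_that("Schoener's D matches hand-computed cases and is symmetric", {
  z <- matrix(c(0.4, 0.1, 0.3, 0.2), 2, 2)
  expect_equal(schoener_d(toy_grid(z), toy_grid(z)), 1)
  a <- toy_grid(matrix(c(1, 0, 0, 0), 2, 2))
  b <- toy_grid(matrix(c(0, 0, 0.5, 0.5), 2, 2))
  expect_equal(schoener_d(a, b), 0)
  cc <- toy_grid(matrix(c(0.5, 0.5, 0, 0), 2, 2))
  expect_equal(schoener_d(a, cc), 0.5)  # 1 - (0.5 + 0.5)/2
  set.seed(8)
  for (i in 1:10) {
    g1 <- toy_grid(matrix(runif(16), 4, 4))
    g2 <- toy_grid(matrix(runif(16), 4, 4))
    expect_equal(schoener_d(g1, g2), schoener_d(g2, g1))
    expect_gte(schoener_d(g1, g2), 0)
    expect_lte(schoener_d(g1, g2), 1)
  }
  bad <- toy_grid(matrix(runif(25), 5, 5), R = 5)
  expect_error(schoener_d(a, bad), "share a grid")
})

test_that("niche dynamics match the cellwise definitions", {
  # identical grids: no expansion, full stability, no unfilling
  g <- toy_grid(matrix(c(0.4, 0.1, 0.3, 0.2), 2, 2))
  dyn <- niche_dynamics(g, g)
  expect_equal(dyn, list(expansion = 0, stability = 1, unfilling = 0))

  # hand 2x2 case (native mass 0.5/0.5/0/0 vs invaded 0.25/0.25/0.5/0)
  zn <- toy_grid(matrix(c(0.5, 0.5, 0, 0), 2, 2))
  zi <- toy_grid(matrix(c(0.25, 0.25, 0.5, 0), 2, 2))
  dyn2 <- niche_dynamics(zn, zi)
  expect_equal(dyn2$expansion, 0.5)
  expect_equal(dyn2$stability, 0.5)
  expect_equal(dyn2$unfilling, 0)

  # disjoint supports within a shared background
  za <- toy_grid(matrix(c(1, 0, 0, 0), 2, 2))
  zb <- toy_grid(matrix(c(0, 0, 0, 1), 2, 2))
  dyn3 <- niche_dynamics(za, zb)
  expect_equal(dyn3$expansion, 1)
  expect_equal(dyn3$stability, 0)
  expect_equal(dyn3$unfilling, 1)

  # expansion + stability = 1 for random grids
  set.seed(9)
  for (i in 1:10) {
    g1 <- toy_grid(matrix(runif(16) * (runif(16) > 0.4), 4, 4) + 1e-12)
    g2 <- toy_grid(matrix(runif(16) * (runif(16) > 0.4), 4, 4) + 1e-12)
    d <- niche_dynamics(g1, g2)
    expect_equal(d$expansion + d$stability, 1, tolerance = 1e-8)
  }
})

test_that("permutation p-values follow the (k+1)/(reps+1) estimator", {
  w <- shifted_world(11, shift = 0, n_presence = 80, n_bg = 600)
  sp <- build_env_space(w$bg1, w$bg2, grid_R = 40)
  s <- lapply(list(w$occ1, w$occ2, w$bg1, w$bg2),
              function(m) env_scores(sp, m))
  eq <- equivalency_test(s[[1]], s[[2]], s[[3]], s[[4]], sp, reps = 100,
                         seed = 17)
  sim <- similarity_test(s[[1]], s[[2]], s[[3]], s[[4]], sp, reps = 100,
                         seed = 18)
  # p-values are exact multiples of 1/(reps+1), in (0, 1]
  expect_equal(eq$p * 101, round(eq$p * 101))
  expect_equal(sim$p * 101, round(sim$p * 101))
  expect_gt(eq$p, 0); expect_lte(eq$p, 1)
  expect_equal(length(eq$null), 100)
  # the printed-precision cases: 2 of 100 nulls below gives 3/101, and
  # 1 of 100 at/above gives 2/101
  expect_equal((2 + 1) / 101, 0.0297, tolerance = 1e-3)
  expect_equal((1 + 1) / 101, 0.0198, tolerance = 1e-3)
  # determinism under the seed
  eq2 <- equivalency_test(s[[1]], s[[2]], s[[3]], s[[4]], sp, reps = 100,
                          seed = 17)
  expect_identical(eq$null, eq2$null)
  sim2 <- similarity_test(s[[1]], s[[2]], s[[3]], s[[4]], sp, reps = 100,
                          seed = 18)
  expect_identical(sim$null, sim2$null)
})

test_that("conserved niches stay stable; programmed shifts drive expansion", {
  cmp0 <- with(shifted_world(21, shift = 0),
               compare_niches(occ1, occ2, bg1, bg2, grid_R = 60, reps = 10,
                              seed = 1))
  expect_gt(cmp0$stability, 0.8)
  expect_gt(cmp0$D, 0.3)

  cmp4 <- with(shifted_world(21, shift = 4),
               compare_niches(occ1, occ2, bg1, bg2, grid_R = 60, reps = 10,
                              seed = 1))
  expect_gt(cmp4$expansion, 0.5)
  expect_lt(cmp4$D, cmp0$D)
})

test_that("niche reports serialize to JSON and CSV", {
  cmp <- with(shifted_world(31, shift = 1, n_presence = 60, n_bg = 500),
              compare_niches(occ1, occ2, bg1, bg2, grid_R = 30, reps = 5,
                             seed = 2))
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_niche_report(cmp, js, cs)
  rep <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(rep$D, cmp$D)
  expect_equal(rep$expansion + rep$stability, 1, tolerance = 1e-8)
  nulls <- utils::read.csv(cs)
  expect_equal(nrow(nulls), 5)
})
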