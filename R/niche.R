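#' Sample background (pseudo-absence) points from a raster stack
#'
#' Draws up to `n` points uniformly over the data cells of an extent,
#' excluding latitudes beyond `lat_limit`; points are placed at cell
#' centres. If fewer than `n` eligible cells exist, all of them are
#' returned with a warning.
#'
#' @param stack A [layer_stack()]; a cell is eligible only if every layer
#'   has data there.
#' @param extent Optional logical matrix (`n_rows x n_cols`) restricting
#'   the eligible cells, or `NULL` for the whole grid.
#' @param n Number of points (default 8000).
#' @param lat_limit Maximum absolute latitude in degrees (default 70).
#' @param seed Integer seed.
#' @return An `occurrence_table` of background points.
#' @export
sample_background <- function(stack, extent = NULL, n = 8000, lat_limit = 70,
                              seed = 1L) {
  stopifnot(inherits(stack, "layer_stack"))
  spec <- stack$spec
  X <- stack_matrix(stack)
  ok <- rowSums(is.na(X)) == 0L
  lat <- rep(row_centers(spec), times = spec$n_cols)
  lon <- rep(col_centers(spec), each = spec$n_rows)
  ok <- ok & abs(lat) <= lat_limit
  if (!is.null(extent)) {
    stopifnot(is.logical(extent), all(dim(extent) == c(spec$n_rows, spec$n_cols)))
    ok <- ok & as.vector(extent)
  }
  idx <- which(ok)
  if (!length(idx)) stop("extent contains no eligible data cells")
  if (length(idx) < n) {
    warning("only ", length(idx), " eligible cells for ", n,
            " background points; returning all of them")
    pick <- idx
  } else {
    set.seed(seed)
    pick <- sample(idx, n)
  }
  as_occurrence_table(data.frame(longitude = lon[pick], latitude = lat[pick],
                                 source = "background"))
}

#' Build a two-axis environmental space by principal components
#'
#' Covariates are standardized with the pooled mean and standard deviation
#' of both background samples and decomposed by PCA; the first two
#' components define the niche space. Axis bounds cover the pooled scores
#' with 10% padding.
#'
#' @param native_bg,invaded_bg Covariate matrices of the two background
#'   samples (same named columns, >= 3 covariates, >= 10 rows each).
#' @param grid_R Occupancy-grid resolution per axis (default 100).
#' @return An `env_space`: loadings, explained variance, pooled
#'   center/scale, axis bounds, and `grid_R`.
#' @export
build_env_space <- function(native_bg, invaded_bg, grid_R = 100) {
  if (is.data.frame(native_bg)) native_bg <- as.matrix(native_bg)
  if (is.data.frame(invaded_bg)) invaded_bg <- as.matrix(invaded_bg)
  stopifnot(identical(colnames(native_bg), colnames(invaded_bg)))
  if (ncol(native_bg) < 3L) stop("need at least 3 covariates")
  if (nrow(native_bg) < 10L || nrow(invaded_bg) < 10L)
    stop("need at least 10 points per range")
  pooled <- rbind(native_bg, invaded_bg)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, stats::sd)
  if (any(scl == 0)) stop("constant covariate in pooled background")
  pc <- stats::prcomp(pooled, center = ctr, scale. = scl)
  if (ncol(pc$rotation) < 2L || pc$sdev[2] < 1e-12)
    stop("pooled background has rank < 2")
  loadings <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]
  pad <- function(r) r + c(-0.1, 0.1) * diff(r)
  structure(list(
    loadings = loadings,
    explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
    center = ctr, scale = scl,
    bounds = list(x = pad(range(scores[, 1])), y = pad(range(scores[, 2]))),
    grid_R = as.integer(grid_R)),
    class = "env_space")
}

#' Project covariate rows into an environmental space
#'
#' @param space An `env_space`.
#' @param X Covariate matrix with the space's covariates.
#' @return Two-column score matrix (axis 1, axis 2).
#' @export
env_scores <- function(space, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  X <- X[, rownames(space$loadings), drop = FALSE]
  scale(X, center = space$center, scale = space$scale) %*% space$loadings
}

silverman_bw <- function(x) {
  bw <- MASS::bandwidth.nrd(x)
  if (!is.finite(bw) || bw <= 0) bw <- 4 * 1.06 * stats::sd(x) * length(x)^(-1/5)
  if (!is.finite(bw) || bw <= 0) bw <- 1
  bw
}

kde_grid <- function(scores, space, bw = NULL) {
  if (is.null(bw)) bw <- c(silverman_bw(scores[, 1]), silverman_bw(scores[, 2]))
  k <- MASS::kde2d(scores[, 1], scores[, 2], h = bw, n = space$grid_R,
                   lims = c(space$bounds$x, space$bounds$y))
  k$z
}

#' Background-corrected occupancy grid in environmental space
#'
#' Gaussian kernel densities of the occurrences and of the background are
#' evaluated on the space's `R x R` grid (normal-reference bandwidths per
#' axis); the occupancy is the occurrence density divided by the background
#' density where the background is available, zero elsewhere, normalized to
#' sum 1. A cell counts as available background only where the background
#' density exceeds `mask_rel` of its maximum; far KDE tails otherwise
#' amplify without bound under the ratio correction.
#'
#' @param occ_scores,bg_scores Two-column score matrices from
#'   [env_scores()] (>= 5 occurrence rows).
#' @param space An `env_space`.
#' @param mask_rel Relative background-density threshold defining the
#'   available-environment mask (default `1e-4` of the maximum).
#' @return An `occupancy_grid`: list with `z` (corrected, sums to 1),
#'   `z_raw` (uncorrected occurrence density, sums to 1), `mask`
#'   (background availability), and the grid geometry.
#' @export
occupancy_grid <- function(occ_scores, bg_scores, space, mask_rel = 1e-4) {
  stopifnot(inherits(space, "env_space"))
  occ_scores <- as.matrix(occ_scores); bg_scores <- as.matrix(bg_scores)
  if (nrow(occ_scores) < 5L) stop("need at least 5 occurrence scores")
  inx <- occ_scores[, 1] >= space$bounds$x[1] & occ_scores[, 1] <= space$bounds$x[2] &
         occ_scores[, 2] >= space$bounds$y[1] & occ_scores[, 2] <= space$bounds$y[2]
  if (!any(inx))
    stop("all occurrences fall outside the axis bounds; rebuild the env_space")
  zocc <- kde_grid(occ_scores, space)
  zbg <- kde_grid(bg_scores, space)
  correct_occupancy(zocc, zbg, space, mask_rel)
}

# Ratio-correct an occurrence density against a (possibly cached)
# background density. KDE tails below mask_rel of the peak are outside the
# occupied niche / available background; without the floor the correction
# amplifies vanishing densities and the zero-sets behind
# expansion/unfilling vanish.
correct_occupancy <- function(zocc, zbg, space, mask_rel = 1e-4) {
  zocc[zocc < mask_rel * max(zocc)] <- 0
  mask <- zbg > mask_rel * max(zbg)
  z <- matrix(0, nrow(zocc), ncol(zocc))
  z[mask] <- zocc[mask] / zbg[mask]
  if (sum(z) == 0) stop("occupancy has no mass on the background mask")
  z <- z / sum(z)
  z_raw <- if (sum(zocc) > 0) zocc / sum(zocc) else zocc
  structure(list(z = z, z_raw = z_raw, mask = mask, grid_R = space$grid_R,
                 bounds = space$bounds),
            class = "occupancy_grid")
}

same_grid <- function(a, b) {
  a$grid_R == b$grid_R &&
    isTRUE(all.equal(a$bounds$x, b$bounds$x)) &&
    isTRUE(all.equal(a$bounds$y, b$bounds$y))
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over the occupancy cells: 0 for disjoint
#' niches, 1 for identical ones. Symmetric in its arguments.
#'
#' @param z1,z2 [occupancy_grid()]s on the same grid and bounds.
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(z1, z2) {
  stopifnot(inherits(z1, "occupancy_grid"), inherits(z2, "occupancy_grid"))
  if (!same_grid(z1, z2)) stop("occupancy grids do not share a grid")
  1 - 0.5 * sum(abs(z1$z - z2$z))
}

#' Niche equivalency permutation test
#'
#' Pools the two occurrence samples, randomly re-splits them into the
#' original sizes each iteration, recomputes the overlap, and reports the
#' one-sided permutation p-value with the `(k + 1) / (reps + 1)` estimator.
#' The default lower tail asks whether the niches are less equivalent than
#' random re-assignments would make them.
#'
#' @param occ1_scores,occ2_scores Occurrence score matrices.
#' @param bg1_scores,bg2_scores Background score matrices of the two ranges.
#' @param space An `env_space`.
#' @param reps Permutation count (default 100).
#' @param seed Integer seed.
#' @param tail `"lower"` (default) or `"upper"`.
#' @return List: `D_obs`, `p`, `null` (length-`reps` vector), `reps`,
#'   `tail`.
#' @export
equivalency_test <- function(occ1_scores, occ2_scores, bg1_scores, bg2_scores,
                             space, reps = 100, seed = 1L,
                             tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  stopifnot(reps >= 1)
  z1 <- occupancy_grid(occ1_scores, bg1_scores, space)
  z2 <- occupancy_grid(occ2_scores, bg2_scores, space)
  d_obs <- schoener_d(z1, z2)
  pool <- rbind(as.matrix(occ1_scores), as.matrix(occ2_scores))
  n1 <- nrow(as.matrix(occ1_scores))
  # the background densities do not change under re-splits: cache them
  zbg1 <- kde_grid(as.matrix(bg1_scores), space)
  zbg2 <- kde_grid(as.matrix(bg2_scores), space)
  set.seed(seed)
  null <- vapply(seq_len(reps), function(i) {
    pick <- sample.int(nrow(pool), n1)
    za <- correct_occupancy(kde_grid(pool[pick, , drop = FALSE], space),
                            zbg1, space)
    zb <- correct_occupancy(kde_grid(pool[-pick, , drop = FALSE], space),
                            zbg2, space)
    schoener_d(za, zb)
  }, numeric(1))
  k <- if (tail == "lower") sum(null <= d_obs) else sum(null >= d_obs)
  list(D_obs = d_obs, p = (k + 1) / (reps + 1), null = null, reps = reps,
       tail = tail)
}

# Translate an occupancy surface so its centroid lands on a target cell,
# wrapping at the grid edges, then re-mask and renormalize.
shift_occupancy <- function(z, mask, target_rc) {
  R <- nrow(z)
  w <- sum(z)
  cr <- round(sum(row(z) * z) / w); cc <- round(sum(col(z) * z) / w)
  dr <- (target_rc[1] - cr) %% R; dc <- (target_rc[2] - cc) %% R
  zs <- z[((seq_len(R) - 1 - dr) %% R) + 1, ((seq_len(R) - 1 - dc) %% R) + 1]
  zs[!mask] <- 0
  s <- sum(zs)
  if (s > 0) zs / s else zs
}

#' Niche similarity permutation test
#'
#' Each iteration relocates one range's occupancy to a random position
#' within its own background mask (centroid translation with wraparound)
#' and recomputes the overlap; the p-value asks whether the observed
#' overlap exceeds what random placement achieves,
#' `p = (#\{D_null >= D_obs\} + 1) / (reps + 1)`.
#'
#' @inheritParams equivalency_test
#' @param direction Which range is relocated: `"invaded"` (range 2,
#'   default), `"native"`, or `"both"` (the larger of the two one-sided
#'   p-values is reported).
#' @return List: `D_obs`, `p`, `null`, `reps`, `direction`.
#' @export
similarity_test <- function(occ1_scores, occ2_scores, bg1_scores, bg2_scores,
                            space, reps = 100, seed = 1L,
                            direction = c("invaded", "native", "both")) {
  direction <- match.arg(direction)
  stopifnot(reps >= 1)
  z1 <- occupancy_grid(occ1_scores, bg1_scores, space)
  z2 <- occupancy_grid(occ2_scores, bg2_scores, space)
  d_obs <- schoener_d(z1, z2)
  one_side <- function(zfix, zmove, seed) {
    cells <- which(zmove$mask, arr.ind = TRUE)
    set.seed(seed)
    vapply(seq_len(reps), function(i) {
      rc <- cells[sample.int(nrow(cells), 1L), ]
      zs <- shift_occupancy(zmove$z, zmove$mask, rc)
      1 - 0.5 * sum(abs(zfix$z - zs))
    }, numeric(1))
  }
  if (direction == "both") {
    null_a <- one_side(z1, z2, seed)
    null_b <- one_side(z2, z1, seed + 1L)
    p <- max((sum(null_a >= d_obs) + 1) / (reps + 1),
             (sum(null_b >= d_obs) + 1) / (reps + 1))
    return(list(D_obs = d_obs, p = p, null = c(null_a, null_b), reps = reps,
                direction = direction))
  }
  null <- if (direction == "invaded") one_side(z1, z2, seed)
          else one_side(z2, z1, seed)
  list(D_obs = d_obs, p = (sum(null >= d_obs) + 1) / (reps + 1), null = null,
       reps = reps, direction = direction)
}

#' Niche expansion, stability, and unfilling
#'
#' Restricted to the intersection of the two background masks (optionally
#' trimmed to cells above a background-density quantile), the invaded
#' niche mass splits into expansion (cells where the native niche is
#' absent) and stability (cells where it is present); unfilling is the
#' native mass in cells the invaded niche does not occupy. Expansion and
#' stability sum to 1 by construction.
#'
#' @param z_native,z_invaded [occupancy_grid()]s on a shared grid.
#' @param intersection_quantile Quantile in `[0, 1)` of each background
#'   mask's density retained (0 = full shared background, the default).
#' @param bg_native,bg_invaded Optional background density matrices used
#'   only when `intersection_quantile > 0`.
#' @return List: `expansion`, `stability`, `unfilling`.
#' @export
niche_dynamics <- function(z_native, z_invaded, intersection_quantile = 0,
                           bg_native = NULL, bg_invaded = NULL) {
  stopifnot(inherits(z_native, "occupancy_grid"),
            inherits(z_invaded, "occupancy_grid"))
  if (!same_grid(z_native, z_invaded))
    stop("occupancy grids do not share a grid")
  mask <- z_native$mask & z_invaded$mask
  if (intersection_quantile > 0 && !is.null(bg_native) && !is.null(bg_invaded)) {
    thr1 <- stats::quantile(bg_native[bg_native > 0], intersection_quantile)
    thr2 <- stats::quantile(bg_invaded[bg_invaded > 0], intersection_quantile)
    mask <- mask & bg_native >= thr1 & bg_invaded >= thr2
  }
  if (!any(mask)) stop("empty background intersection")
  zn <- z_native$z; zi <- z_invaded$z
  wi <- sum(zi[mask]); wn <- sum(zn[mask])
  if (wi == 0 || wn == 0)
    stop("a niche has no mass on the shared background")
  expansion <- sum(zi[mask & zn == 0]) / wi
  stability <- sum(zi[mask & zn > 0]) / wi
  unfilling <- sum(zn[mask & zi == 0]) / wn
  list(expansion = expansion, stability = stability, unfilling = unfilling)
}

#' Full niche comparison between a native and an invaded range
#'
#' Convenience wrapper running [build_env_space()], [occupancy_grid()],
#' [schoener_d()], both permutation tests, and [niche_dynamics()].
#'
#' @param native_occ_X,invaded_occ_X Covariate matrices at the occurrence
#'   points of each range.
#' @param native_bg_X,invaded_bg_X Covariate matrices of the two
#'   background samples.
#' @param grid_R Occupancy resolution (default 100).
#' @param reps Permutation count (default 100).
#' @param seed Integer seed.
#' @return A `niche_comparison` list: `D`, `p_equivalency`, `p_similarity`,
#'   `expansion`, `stability`, `unfilling`, `reps`, `space`, and the two
#'   occupancy grids.
#' @export
compare_niches <- function(native_occ_X, invaded_occ_X, native_bg_X,
                           invaded_bg_X, grid_R = 100, reps = 100, seed = 1L) {
  space <- build_env_space(native_bg_X, invaded_bg_X, grid_R = grid_R)
  s_occ1 <- env_scores(space, native_occ_X)
  s_occ2 <- env_scores(space, invaded_occ_X)
  s_bg1 <- env_scores(space, native_bg_X)
  s_bg2 <- env_scores(space, invaded_bg_X)
  z1 <- occupancy_grid(s_occ1, s_bg1, space)
  z2 <- occupancy_grid(s_occ2, s_bg2, space)
  eq <- equivalency_test(s_occ1, s_occ2, s_bg1, s_bg2, space, reps = reps,
                         seed = seed)
  sim <- similarity_test(s_occ1, s_occ2, s_bg1, s_bg2, space, reps = reps,
                         seed = seed + 1L)
  dyn <- niche_dynamics(z1, z2)
  structure(list(D = eq$D_obs, p_equivalency = eq$p, p_similarity = sim$p,
                 expansion = dyn$expansion, stability = dyn$stability,
                 unfilling = dyn$unfilling, reps = reps, seed = seed,
                 space = space, z_native = z1, z_invaded = z2,
                 null_equivalency = eq$null, null_similarity = sim$null),
            class = "niche_comparison")
}

#' @export
print.niche_comparison <- function(x, ...) {
  cat(sprintf("<niche_comparison> D=%.3f  p_eq=%.4f  p_sim=%.4f\n",
              x$D, x$p_equivalency, x$p_similarity))
  cat(sprintf("  expansion=%.3f stability=%.3f unfilling=%.3f (reps=%d)\n",
              x$expansion, x$stability, x$unfilling, x$reps))
  invisible(x)
}

#' Write a niche-comparison report
#'
#' @param cmp A `niche_comparison`.
#' @param json_path JSON report path (D, p-values, dynamics, reps, seed).
#' @param null_csv_path Optional CSV of the two null distributions.
#' @return Invisibly, the report list.
#' @export
write_niche_report <- function(cmp, json_path, null_csv_path = NULL) {
  rep <- list(D = cmp$D, p_equivalency = cmp$p_equivalency,
              p_similarity = cmp$p_similarity, expansion = cmp$expansion,
              stability = cmp$stability, unfilling = cmp$unfilling,
              reps = cmp$reps, seed = cmp$seed)
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(null_csv_path))
    utils::write.csv(data.frame(equivalency = cmp$null_equivalency,
                                similarity = cmp$null_similarity),
                     null_csv_path, row.names = FALSE)
  invisible(rep)
}
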