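#' Threshold suitability into PGD / non-PGD
#'
#' Cells with suitability strictly above the cutoff are potential
#' geographic distribution (PGD); cells at or below it are not. The
#' boundary value `p == cutoff` is non-PGD, matching a non-PGD interval
#' closed at the cutoff; set `strict = FALSE` to flip the boundary for
#' sensitivity analysis.
#'
#' @param suitability A [raster_grid()] with values in `[0, 1]`.
#' @param cutoff Suitability threshold (default 0.23).
#' @param strict If `TRUE` (default) PGD requires `p > cutoff`; if
#'   `FALSE`, `p >= cutoff`.
#' @return A `pgd_map`: list with `state` (integer matrix: 1 = PGD,
#'   0 = non-PGD, `NA` = nodata), `spec`, `cutoff`, `strict`.
#' @export
threshold_pgd <- function(suitability, cutoff = 0.23, strict = TRUE) {
  stopifnot(inherits(suitability, "raster_grid"))
  v <- suitability$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  state <- if (strict) (v > cutoff) * 1L else (v >= cutoff) * 1L
  structure(list(state = state, spec = suitability$spec, cutoff = cutoff,
                 strict = strict),
            class = "pgd_map")
}

#' @export
print.pgd_map <- function(x, ...) {
  cat(sprintf("<pgd_map> cutoff=%g: %d PGD / %d non-PGD / %d nodata cells\n",
              x$cutoff, sum(x$state == 1, na.rm = TRUE),
              sum(x$state == 0, na.rm = TRUE), sum(is.na(x$state))))
  invisible(x)
}

#' Spherical cell areas of a geographic grid
#'
#' `area(row) = R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))` with
#' `R = 6371` km; identical across a row, and the full-globe total equals
#' `4 pi R^2` (about 5.10e8 km^2).
#'
#' @param spec A [grid_spec()].
#' @return A [raster_grid()] of km^2 per cell, named `"cell_area"`.
#' @export
cell_areas <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  R <- 6371
  dl <- spec$cell_deg * pi / 180
  top <- spec$north - (seq_len(spec$n_rows) - 1) * spec$cell_deg
  bot <- top - spec$cell_deg
  row_area <- R^2 * dl * (sin(top * pi / 180) - sin(bot * pi / 180))
  raster_grid(matrix(row_area, spec$n_rows, spec$n_cols), spec, "cell_area")
}

#' Per-ecosystem PGD area accounting
#'
#' For each ecosystem, the total area is the sum of cell area times the
#' ecosystem's per-cell fraction over all data cells; the PGD area is the
#' same sum restricted to PGD cells; the proportion is their ratio as a
#' percentage. Areas are reported in km^2 and, matching the conventional
#' table layout, also in units of 1e4 km^2.
#'
#' @param pgd A `pgd_map`.
#' @param fractions An `ecosystem_fractions` on the same grid.
#' @param scenario,period Tags copied into the output rows.
#' @return An `ecosystem_area_table` data frame: `scenario`, `period`,
#'   `ecosystem`, `pgd_area_km2`, `total_area_km2`, `pgd_area_1e4km2`,
#'   `total_area_1e4km2`, `proportion_pct`.
#' @export
ecosystem_pgd_area <- function(pgd, fractions, scenario = "near_current",
                               period = NA_character_) {
  stopifnot(inherits(pgd, "pgd_map"), inherits(fractions, "ecosystem_fractions"))
  if (!spec_equal(pgd$spec, attr(fractions, "spec")))
    stop("PGD map and ecosystem fractions do not share a grid")
  area <- cell_areas(pgd$spec)$values
  is_pgd <- !is.na(pgd$state) & pgd$state == 1L
  rows <- lapply(names(fractions), function(eco) {
    fr <- fractions[[eco]]$values
    ok <- !is.na(fr) & !is.na(pgd$state)
    total <- sum(area[ok] * fr[ok])
    in_pgd <- sum(area[ok & is_pgd] * fr[ok & is_pgd])
    data.frame(scenario = scenario, period = period, ecosystem = eco,
               pgd_area_km2 = in_pgd, total_area_km2 = total,
               pgd_area_1e4km2 = in_pgd / 1e4, total_area_1e4km2 = total / 1e4,
               proportion_pct = if (total > 0) 100 * in_pgd / total else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("ecosystem_area_table", "data.frame"))
}

#' Change map between a reference and a future PGD map
#'
#' Cell states: `gain` (non-PGD to PGD), `loss` (PGD to non-PGD), `stable`
#' (PGD in both), `never` (non-PGD in both); nodata propagates. Gain and
#' loss areas are reported overall and, when ecosystem fractions are
#' given, per ecosystem.
#'
#' @param pgd_ref,pgd_future `pgd_map`s on a shared grid. A cutoff
#'   mismatch triggers a warning recorded in the output.
#' @param fractions Optional `ecosystem_fractions` for per-ecosystem
#'   gain/loss areas.
#' @return A `change_map`: list with `state` (character matrix), `spec`,
#'   `areas` (data frame of gain/loss/stable/never km^2), optional
#'   `ecosystem_areas`, and `cutoff_mismatch`.
#' @export
change_map <- function(pgd_ref, pgd_future, fractions = NULL) {
  stopifnot(inherits(pgd_ref, "pgd_map"), inherits(pgd_future, "pgd_map"))
  if (!spec_equal(pgd_ref$spec, pgd_future$spec))
    stop("PGD maps do not share a grid")
  mismatch <- !isTRUE(all.equal(pgd_ref$cutoff, pgd_future$cutoff))
  if (mismatch)
    warning("cutoff mismatch between PGD maps (", pgd_ref$cutoff, " vs ",
            pgd_future$cutoff, "); recorded in output metadata")
  a <- pgd_ref$state; b <- pgd_future$state
  state <- matrix(NA_character_, nrow(a), ncol(a))
  state[a == 0 & b == 1] <- "gain"
  state[a == 1 & b == 0] <- "loss"
  state[a == 1 & b == 1] <- "stable"
  state[a == 0 & b == 0] <- "never"
  area <- cell_areas(pgd_ref$spec)$values
  tot <- function(lbl) sum(area[!is.na(state) & state == lbl])
  areas <- data.frame(state = c("gain", "loss", "stable", "never"),
                      area_km2 = c(tot("gain"), tot("loss"), tot("stable"),
                                   tot("never")))
  eco_areas <- NULL
  if (!is.null(fractions)) {
    stopifnot(inherits(fractions, "ecosystem_fractions"))
    if (!spec_equal(pgd_ref$spec, attr(fractions, "spec")))
      stop("ecosystem fractions do not share the PGD grid")
    eco_areas <- do.call(rbind, lapply(names(fractions), function(eco) {
      fr <- fractions[[eco]]$values
      g <- !is.na(state) & state == "gain" & !is.na(fr)
      l <- !is.na(state) & state == "loss" & !is.na(fr)
      data.frame(ecosystem = eco,
                 gain_km2 = sum(area[g] * fr[g]),
                 loss_km2 = sum(area[l] * fr[l]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(state = state, spec = pgd_ref$spec, areas = areas,
                 ecosystem_areas = eco_areas, cutoff_mismatch = mismatch),
            class = "change_map")
}

#' Latitudinal suitability profile with fitted peak
#'
#' Aggregates suitability into fixed-width latitude bands, weighting each
#' cell by its spherical area times an ecosystem fraction, then fits a
#' polynomial per hemisphere by least squares with pointwise 95%
#' confidence bands and reports the band centre maximizing the fitted
#' curve. A hemisphere whose fitted curve is flat (range of fitted values
#' below `1e-6`) or has no weighted bands reports an undefined (`NA`)
#' peak.
#'
#' @param suitability A [raster_grid()] of suitability in `[0, 1]`.
#' @param fraction A [raster_grid()] of weights in `[0, 1]` (e.g. an
#'   ecosystem fraction), or `NULL` for uniform weighting.
#' @param band_deg Band width in degrees (default 0.5); bands are
#'   half-open `[lo, hi)` from -90 northward.
#' @param fit_degree Polynomial degree (default 2).
#' @return A `latitude_profile`: data frame (`band_center`,
#'   `mean_suitability`, `weight`, `hemisphere`, `fitted`, `ci_low`,
#'   `ci_high`) with attribute `peaks` = named vector
#'   (`north`, `south`) of peak latitudes.
#' @export
latitudinal_profile <- function(suitability, fraction = NULL, band_deg = 0.5,
                                fit_degree = 2) {
  stopifnot(inherits(suitability, "raster_grid"))
  spec <- suitability$spec
  if (is.null(fraction)) {
    frv <- matrix(1, spec$n_rows, spec$n_cols)
  } else {
    stopifnot(inherits(fraction, "raster_grid"))
    if (!spec_equal(spec, fraction$spec))
      stop("suitability and fraction do not share a grid")
    frv <- fraction$values
    if (any(frv < 0 | frv > 1, na.rm = TRUE))
      stop("fraction values must lie in [0, 1]")
  }
  area <- cell_areas(spec)$values
  lat <- matrix(rep(row_centers(spec), spec$n_cols), spec$n_rows, spec$n_cols)
  ok <- !is.na(suitability$values) & !is.na(frv)
  w <- area * frv
  edges <- seq(-90, 90, by = band_deg)
  band <- findInterval(lat, edges, rightmost.closed = TRUE)
  centers <- edges[-length(edges)] + band_deg / 2
  agg_w <- tapply(w[ok], band[ok], sum)
  agg_sw <- tapply((w * suitability$values)[ok], band[ok], sum)
  prof <- data.frame(band_center = centers, mean_suitability = NA_real_,
                     weight = 0)
  ix <- as.integer(names(agg_w))
  prof$weight[ix] <- agg_w
  pos <- agg_w > 0
  prof$mean_suitability[ix[pos]] <- agg_sw[pos] / agg_w[pos]
  prof$hemisphere <- ifelse(prof$band_center >= 0, "north", "south")
  prof$fitted <- NA_real_; prof$ci_low <- NA_real_; prof$ci_high <- NA_real_
  peaks <- c(north = NA_real_, south = NA_real_)
  for (h in c("north", "south")) {
    rows <- which(prof$hemisphere == h & !is.na(prof$mean_suitability) &
                    prof$weight > 0)
    if (length(rows) <= fit_degree) next
    d <- data.frame(x = abs(prof$band_center[rows]),
                    y = prof$mean_suitability[rows])
    fit <- stats::lm(y ~ poly(x, degree = fit_degree, raw = TRUE), data = d)
    pr <- stats::predict(fit, newdata = d, interval = "confidence",
                         level = 0.95)
    prof$fitted[rows] <- pr[, "fit"]
    prof$ci_low[rows] <- pr[, "lwr"]
    prof$ci_high[rows] <- pr[, "upr"]
    if (diff(range(pr[, "fit"])) >= 1e-6)
      peaks[h] <- prof$band_center[rows[which.max(pr[, "fit"])]]
  }
  structure(prof, peaks = peaks, band_deg = band_deg,
            fit_degree = fit_degree,
            class = c("latitude_profile", "data.frame"))
}

#' Peak latitudes of a profile
#'
#' @param profile A `latitude_profile`.
#' @return Named vector (`north`, `south`); `NA` where undefined.
#' @export
profile_peaks <- function(profile) {
  stopifnot(inherits(profile, "latitude_profile"))
  attr(profile, "peaks")
}
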