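#' Default synthetic world grid
#'
#' A 50 x 50 lattice of 0.5-degree cells spanning longitudes -25 to 0 and
#' latitudes -12.5 to 12.5, so both hemispheres are exercised by
#' latitude-dependent code.
#'
#' @return A [grid_spec()].
#' @export
default_world_spec <- function() {
  grid_spec(50, 50, west = -25, north = 12.5, cell_deg = 0.5)
}

#' Virtual-species configuration
#'
#' @param response_optima Named numeric vector: Gaussian response optimum
#'   per covariate (covariate units).
#' @param response_breadths Named numeric vector of Gaussian SDs (> 0),
#'   same names.
#' @param n_presence Number of presence points to draw (>= 1).
#' @param sampling `"probability_weighted"` (cells drawn with probability
#'   proportional to suitability times cell area) or `"bernoulli"`
#'   (uniformly drawn cells accepted with probability equal to their
#'   suitability).
#' @param seed Integer seed.
#' @return A `virtual_species_config`.
#' @export
virtual_species_config <- function(response_optima, response_breadths,
                                   n_presence = 300,
                                   sampling = c("probability_weighted",
                                                "bernoulli"),
                                   seed = 1L) {
  sampling <- match.arg(sampling)
  stopifnot(length(response_optima) >= 1,
            identical(sort(names(response_optima)),
                      sort(names(response_breadths))))
  if (any(response_breadths <= 0)) stop("response breadths must be positive")
  if (n_presence < 1) stop("n_presence must be >= 1")
  structure(list(response_optima = response_optima,
                 response_breadths = response_breadths,
                 n_presence = as.integer(n_presence), sampling = sampling,
                 seed = as.integer(seed)),
            class = "virtual_species_config")
}

# Separable Gaussian blur with replicated edges; sigma in cells.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], half), v, rep(v[n], half))
    stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  }
  m <- apply(m, 2, blur1)
  t(apply(t(m), 2, blur1))
}

#' Generate a bioclim-like climate layer stack
#'
#' Each layer mixes a latitudinal gradient with spatially smoothed Gaussian
#' noise — `gradient_weight * gradient + (1 - gradient_weight) * noise` —
#' and is rescaled to a target range. Default ranges alternate a
#' temperature-like span (-10..30) and a precipitation-like span (0..3000).
#' Bit-reproducible for a fixed seed.
#'
#' @param spec A [grid_spec()] (default [default_world_spec()]).
#' @param n_vars Number of layers (>= 1), named `bio1`, `bio2`, ...
#' @param seed Integer seed.
#' @param gradient_weight Mixing weight in `[0, 1]` (default 0.6); 1 gives
#'   layers constant along each row.
#' @param noise_smoothing Gaussian blur SD in cells (default 2); larger
#'   values raise spatial autocorrelation.
#' @param ranges Optional list of length-2 target ranges per layer.
#' @return A [layer_stack()].
#' @export
make_climate_stack <- function(spec = default_world_spec(), n_vars = 5,
                               seed = 1L, gradient_weight = 0.6,
                               noise_smoothing = 2, ranges = NULL) {
  if (n_vars < 1) stop("n_vars must be >= 1")
  stopifnot(gradient_weight >= 0, gradient_weight <= 1)
  if (is.null(ranges))
    ranges <- lapply(seq_len(n_vars),
                     function(k) if (k %% 2 == 1) c(-10, 30) else c(0, 3000))
  set.seed(seed)
  lat <- row_centers(spec)
  grad_col <- (lat - min(lat)) / max(diff(range(lat)), 1e-12)
  layers <- lapply(seq_len(n_vars), function(k) {
    # alternate gradient direction so layers are not collinear by design
    g <- if (k %% 2 == 1) grad_col else 1 - grad_col
    G <- matrix(g, spec$n_rows, spec$n_cols)
    noise <- smooth_matrix(matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                                  spec$n_rows, spec$n_cols), noise_smoothing)
    raw <- gradient_weight * G + (1 - gradient_weight) * noise
    r <- range(raw)
    v <- if (diff(r) > 0) (raw - r[1]) / diff(r) else raw * 0
    tgt <- ranges[[k]]
    raster_grid(tgt[1] + v * diff(tgt), spec, paste0("bio", k))
  })
  layer_stack(layers)
}

#' True suitability surface of a virtual species
#'
#' The cellwise product of Gaussian responses
#' `exp(-(x - optimum)^2 / (2 breadth^2))` over the configured covariates;
#' 1 where every optimum is met exactly.
#'
#' @param stack A [layer_stack()] containing every configured covariate.
#' @param config A [virtual_species_config()].
#' @return A [raster_grid()] named `"true_suitability"` with values in
#'   `[0, 1]`.
#' @export
make_true_suitability <- function(stack, config) {
  stopifnot(inherits(stack, "layer_stack"),
            inherits(config, "virtual_species_config"))
  covs <- names(config$response_optima)
  miss <- setdiff(covs, names(stack$layers))
  if (length(miss))
    stop("stack is missing configured covariate(s): ",
         paste(miss, collapse = ", "))
  spec <- stack$spec
  s <- matrix(1, spec$n_rows, spec$n_cols)
  for (v in covs) {
    x <- stack$layers[[v]]$values
    s <- s * exp(-(x - config$response_optima[[v]])^2 /
                   (2 * config$response_breadths[[v]]^2))
  }
  raster_grid(s, spec, "true_suitability")
}

#' Sample presence points from a suitability surface
#'
#' Points are jittered uniformly within their cell so several presences can
#' share a thinning cell, as in real data.
#'
#' @param true_suitability A [raster_grid()] in `[0, 1]`.
#' @param config A [virtual_species_config()] (supplies `n_presence`,
#'   `sampling`, `seed`).
#' @param extent Optional logical matrix restricting eligible cells.
#' @return An `occurrence_table` of `n_presence` points.
#' @export
sample_presences <- function(true_suitability, config, extent = NULL) {
  stopifnot(inherits(true_suitability, "raster_grid"),
            inherits(config, "virtual_species_config"))
  spec <- true_suitability$spec
  suit <- as.vector(true_suitability$values)
  area <- as.vector(cell_areas(spec)$values)
  if (!is.null(extent)) suit[!as.vector(extent)] <- NA
  eligible <- which(is.finite(suit) & suit > 0)
  if (!length(eligible)) stop("suitability is zero everywhere in the extent")
  lat0 <- rep(row_centers(spec), times = spec$n_cols)
  lon0 <- rep(col_centers(spec), each = spec$n_rows)
  set.seed(config$seed)
  n <- config$n_presence
  cells <- if (config$sampling == "probability_weighted") {
    eligible[sample.int(length(eligible), n, replace = TRUE,
                        prob = suit[eligible] * area[eligible])]
  } else {
    picked <- integer(0)
    while (length(picked) < n) {
      cand <- eligible[sample.int(length(eligible), n, replace = TRUE)]
      acc <- stats::runif(n) < suit[cand]
      picked <- c(picked, cand[acc])
    }
    picked[seq_len(n)]
  }
  jx <- stats::runif(n, -0.5, 0.5) * spec$cell_deg
  jy <- stats::runif(n, -0.5, 0.5) * spec$cell_deg
  as_occurrence_table(data.frame(longitude = lon0[cells] + jx,
                                 latitude = lat0[cells] + jy,
                                 source = "simulated"))
}

#' Niche-shift scenario for paired native/invaded ranges
#'
#' @param shift_magnitude Displacement of the invaded range's response
#'   optima, in units of each covariate's SD over the whole grid (>= 0;
#'   0 emulates a conserved niche).
#' @param background_offset Longitudinal gap, in degrees, between the
#'   native (western) and invaded (eastern) halves of the grid
#'   (default 0).
#' @param seed Integer seed.
#' @return A `niche_shift_scenario`.
#' @export
niche_shift_scenario <- function(shift_magnitude = 0, background_offset = 0,
                                 seed = 1L) {
  if (shift_magnitude < 0) stop("shift_magnitude must be >= 0")
  structure(list(shift_magnitude = shift_magnitude,
                 background_offset = background_offset,
                 seed = as.integer(seed)),
            class = "niche_shift_scenario")
}

#' Generate paired native and invaded ranges with a programmed niche shift
#'
#' The grid is split into a western (native) and an eastern (invaded)
#' extent separated by `background_offset` degrees; the invaded species'
#' optima are displaced by `shift_magnitude` grid-wide covariate SDs, and
#' both ranges are sampled from their own true-suitability surface.
#'
#' @param stack A [layer_stack()] of covariates.
#' @param config A [virtual_species_config()] for the native range.
#' @param scenario A [niche_shift_scenario()].
#' @return List: `native` and `invaded` occurrence tables, `native_extent`
#'   and `invaded_extent` logical matrices, `native_config`,
#'   `invaded_config`.
#' @export
make_shifted_ranges <- function(stack, config, scenario) {
  stopifnot(inherits(stack, "layer_stack"),
            inherits(config, "virtual_species_config"),
            inherits(scenario, "niche_shift_scenario"))
  spec <- stack$spec
  gap_cells <- ceiling(scenario$background_offset / spec$cell_deg / 2)
  half <- floor(spec$n_cols / 2)
  col <- matrix(rep(seq_len(spec$n_cols), each = spec$n_rows),
                spec$n_rows, spec$n_cols)
  native_extent <- col <= (half - gap_cells)
  invaded_extent <- col > (half + gap_cells)
  if (!any(native_extent) || !any(invaded_extent))
    stop("background_offset leaves an empty extent")
  sds <- vapply(names(config$response_optima), function(v)
    stats::sd(stack$layers[[v]]$values, na.rm = TRUE), numeric(1))
  inv_optima <- config$response_optima + scenario$shift_magnitude * sds
  inv_config <- virtual_species_config(inv_optima, config$response_breadths,
                                       config$n_presence, config$sampling,
                                       seed = config$seed + 1000L)
  suit_nat <- make_true_suitability(stack, config)
  suit_inv <- make_true_suitability(stack, inv_config)
  list(native = sample_presences(suit_nat, config, native_extent),
       invaded = sample_presences(suit_inv, inv_config, invaded_extent),
       native_extent = native_extent, invaded_extent = invaded_extent,
       native_config = config, invaded_config = inv_config)
}

#' Generate LUH2-style land-use state fractions
#'
#' Per-cell state fractions are drawn from a symmetric Dirichlet over the
#' twelve LUH2-style states (the ten mapped by [luh2_mapping()] plus
#' non-forest primary/secondary natural land), so states sum to 1 in every
#' cell; large concentrations approach uniform compositions.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration parameter (default 1).
#' @return List: `states` (a [layer_stack()] of the twelve state layers)
#'   and `fractions` (the aggregated `ecosystem_fractions`).
#' @export
make_landuse <- function(spec = default_world_spec(), seed = 1L,
                         concentration = 1) {
  stopifnot(inherits(spec, "grid_spec"), concentration > 0)
  states <- c(luh2_mapping()$state, "primn", "secdn")
  n <- spec$n_rows * spec$n_cols
  set.seed(seed)
  g <- matrix(stats::rgamma(n * length(states), shape = concentration),
              nrow = n)
  g <- g / rowSums(g)
  layers <- lapply(seq_along(states), function(j)
    raster_grid(matrix(g[, j], spec$n_rows, spec$n_cols), spec, states[j]))
  st <- layer_stack(layers)
  list(states = st, fractions = aggregate_landuse(st))
}

#' Generate a country first-record table following a logistic invasion curve
#'
#' First-record years are placed at logistic-quantile positions between
#' `start_year` and `end_year` (midpoint and rate controlling the S-curve)
#' with seeded jitter, so the cumulative invaded-country count traces a
#' logistic rise: slow lag, fast spread, saturating equilibrium.
#'
#' @param n_countries Number of countries (>= 1).
#' @param start_year,end_year Calendar bounds (`end_year > start_year`).
#' @param midpoint Inflection year of the logistic curve.
#' @param rate Logistic rate per year (> 0); small rates flatten the curve
#'   toward uniform yearly counts.
#' @param jitter_sd SD of the Gaussian year jitter (default 1).
#' @param seed Integer seed.
#' @return Data frame (`country`, `first_year`), one row per country.
#' @export
make_timeline <- function(n_countries, start_year = 1950, end_year = 2023,
                          midpoint = 1995, rate = 0.15, jitter_sd = 1,
                          seed = 1L) {
  if (end_year <= start_year) stop("end_year must exceed start_year")
  stopifnot(n_countries >= 1, rate > 0)
  set.seed(seed)
  u <- (seq_len(n_countries) - 0.5) / n_countries
  # inverse CDF of the logistic truncated to [start_year, end_year]; as
  # rate -> 0 this tends to uniform yearly counts instead of piling at the
  # bounds
  f_lo <- stats::plogis((start_year - midpoint) * rate)
  f_hi <- stats::plogis((end_year - midpoint) * rate)
  yrs <- midpoint + stats::qlogis(f_lo + u * (f_hi - f_lo)) / rate +
    stats::rnorm(n_countries, sd = jitter_sd)
  yrs <- pmin(pmax(round(yrs), start_year), end_year)
  data.frame(country = sprintf("C%03d", seq_len(n_countries)),
             first_year = as.integer(sort(yrs)),
             stringsAsFactors = FALSE)
}
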