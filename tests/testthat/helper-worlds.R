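# Small synthetic worlds shared across tests. Everything is generated in
# code under fixed seeds; nothing is read from disk.

tiny_spec <- function(n = 10, cell = 1, west = 0, north = 10) {
  grid_spec(n, n, west = west, north = north, cell_deg = cell)
}

# A world where a Gaussian virtual species responds to one gradient-driven
# covariate (bio1, -10..30 with latitude) next to two uninformative,
# spatially smooth noise covariates — the standard parameter-recovery
# design, which keeps the companions uncorrelated with the signal.
recovery_world <- function(seed, n_presence = 200, optimum = 15, breadth = 6) {
  gspec <- grid_spec(40, 40, west = -20, north = 10, cell_deg = 0.5)
  sig <- make_climate_stack(gspec, n_vars = 1, seed = seed,
                            gradient_weight = 0.7, noise_smoothing = 2)
  noise <- make_climate_stack(gspec, n_vars = 2, seed = seed + 500L,
                              gradient_weight = 0, noise_smoothing = 2,
                              ranges = list(c(0, 3000), c(-5, 45)))
  st <- layer_stack(list(
    sig$layers$bio1,
    raster_grid(noise$layers$bio1$values, gspec, "bio2"),
    raster_grid(noise$layers$bio2$values, gspec, "bio3")))
  cfg <- virtual_species_config(c(bio1 = optimum), c(bio1 = breadth),
                                n_presence = n_presence, seed = seed + 1L)
  suit <- make_true_suitability(st, cfg)
  occ <- sample_presences(suit, cfg)
  bg <- sample_background(st, n = 1500, seed = seed + 2L)
  ep <- extract_at_points(st, occ)
  list(stack = st, config = cfg, suit = suit,
       presence_X = ep$values[ep$in_bounds, , drop = FALSE],
       background_X = extract_at_points(st, bg)$values)
}

# Paired native/invaded ranges with a programmed niche shift, plus the
# covariate matrices the niche module consumes.
shifted_world <- function(seed, shift = 0, n_presence = 150, n_bg = 1200,
                          n_vars = 3) {
  st <- make_climate_stack(grid_spec(40, 60, west = -25, north = 10,
                                     cell_deg = 0.5),
                           n_vars = n_vars, seed = seed,
                           gradient_weight = 0.75, noise_smoothing = 2)
  # a sharp single-covariate niche low on the bio1 gradient, so programmed
  # shifts (in grid-SD units) separate the realized niches cleanly
  rng1 <- range(st$layers$bio1$values)
  cfg <- virtual_species_config(
    c(bio1 = rng1[1] + 0.35 * diff(rng1)),
    c(bio1 = 0.12 * diff(rng1)),
    n_presence = n_presence, seed = seed + 1L)
  rng <- make_shifted_ranges(st, cfg,
                             niche_shift_scenario(shift_magnitude = shift,
                                                  seed = seed))
  bg1 <- sample_background(st, rng$native_extent, n = n_bg, lat_limit = 70,
                           seed = seed + 3L)
  bg2 <- sample_background(st, rng$invaded_extent, n = n_bg, lat_limit = 70,
                           seed = seed + 4L)
  grab <- function(tab) {
    e <- extract_at_points(st, tab)
    e$values[e$in_bounds, , drop = FALSE]
  }
  list(stack = st,
       occ1 = grab(rng$native), occ2 = grab(rng$invaded),
       bg1 = grab(bg1), bg2 = grab(bg2))
}
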