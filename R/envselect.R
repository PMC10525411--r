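#' Greedy Pearson-correlation covariate filter
#'
#' Covariates are ranked by descending importance (percent contribution from
#' a preliminary all-covariate fit is the intended score) and scanned in that
#' order: a covariate is kept unless its absolute Pearson correlation with an
#' already-kept covariate exceeds `r_threshold`, so of any highly correlated
#' pair only the larger contributor survives. Fully deterministic; ties in
#' the scores are broken alphabetically by layer name.
#'
#' @param X Numeric matrix of covariate values (samples x layers), with
#'   column names. Pairwise-complete observations are used when `NA`
#'   patterns differ between columns.
#' @param contributions Named numeric vector of importance scores covering
#'   every column of `X`.
#' @param r_threshold Absolute-correlation threshold (default 0.8).
#' @return Character vector of kept layer names, in contribution order;
#'   attributes `dropped` (named by the kept layer that displaced each) and
#'   `constant` (zero-variance layers, whose correlations are defined as 0).
#' @export
correlation_filter <- function(X, contributions, r_threshold = 0.8) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (nrow(X) < 2L) stop("need at least 2 samples per layer")
  if (!all(colnames(X) %in% names(contributions)))
    stop("contributions must cover all layers of X")
  nms <- colnames(X)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  const <- nms[!is.finite(sds) | sds == 0]
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0           # zero-variance layers correlate with nothing
  diag(R) <- 1
  ord <- nms[order(-contributions[nms], nms)]
  kept <- character(0)
  dropped <- character(0)
  for (nm in ord) {
    r_with_kept <- if (length(kept)) abs(R[nm, kept]) else numeric(0)
    if (all(r_with_kept <= r_threshold)) {
      kept <- c(kept, nm)
    } else {
      culprit <- kept[which.max(r_with_kept)]
      dropped[nm] <- culprit
    }
  }
  structure(kept, dropped = dropped, constant = const)
}

#' Default LUH2 state-to-ecosystem mapping
#'
#' Primary and secondary forest make up the forest ecosystem; all annual,
#' perennial, and N-fixing crop states make up cropland; rangeland plus
#' managed pasture make up grassland; the urban state maps to urban.
#'
#' @return Data frame with columns `state`, `ecosystem`.
#' @export
luh2_mapping <- function() {
  data.frame(
    state = c("primf", "secdf", "c3ann", "c4ann", "c3per", "c4per", "c3nfx",
              "range", "pastr", "urban"),
    ecosystem = c("forest", "forest", "cropland", "cropland", "cropland",
                  "cropland", "cropland", "grassland", "grassland", "urban"),
    stringsAsFactors = FALSE)
}

#' Aggregate land-use state fractions into the four ecosystems
#'
#' @param states A [layer_stack()] of per-cell land-use state fractions
#'   (LUH2-style names by default).
#' @param mapping Data frame (`state`, `ecosystem`) assigning each source
#'   layer to one of `forest`, `cropland`, `grassland`, `urban`; defaults
#'   to [luh2_mapping()]. Every mapped state must be present in the stack.
#' @return An `ecosystem_fractions` object: list of four [raster_grid()]s
#'   (`forest`, `cropland`, `grassland`, `urban`), each clipped to `[0, 1]`.
#' @export
aggregate_landuse <- function(states, mapping = luh2_mapping()) {
  stopifnot(inherits(states, "layer_stack"),
            all(c("state", "ecosystem") %in% names(mapping)))
  eco_names <- c("forest", "cropland", "grassland", "urban")
  if (!all(mapping$ecosystem %in% eco_names))
    stop("mapping contains unknown ecosystems: ",
         paste(setdiff(mapping$ecosystem, eco_names), collapse = ", "))
  missing <- setdiff(mapping$state, names(states$layers))
  if (length(missing))
    stop("configuration error: mapped land-use layer(s) missing from stack: ",
         paste(missing, collapse = ", "))
  spec <- states$spec
  out <- lapply(eco_names, function(eco) {
    src <- mapping$state[mapping$ecosystem == eco]
    acc <- matrix(0, spec$n_rows, spec$n_cols)
    for (s in src) acc <- acc + states$layers[[s]]$values
    acc <- pmin(pmax(acc, 0), 1)
    raster_grid(acc, spec, eco)
  })
  names(out) <- eco_names
  structure(out, spec = spec, class = "ecosystem_fractions")
}

#' @export
print.ecosystem_fractions <- function(x, ...) {
  cat("<ecosystem_fractions> forest, cropland, grassland, urban\n")
  print(attr(x, "spec"))
  invisible(x)
}
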