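#' Feature-class specification for the maximum-entropy model
#'
#' @param classes Feature classes as a single string (e.g. `"LQHPT"`) or a
#'   character vector drawn from `L` (linear), `Q` (quadratic), `P`
#'   (pairwise product), `T` (threshold step), `H` (hinge).
#' @param n_hinge_knots Number of hinge knots per covariate (>= 2,
#'   default 50); forward and reverse hinges share them.
#' @param n_threshold_knots Number of threshold knots per covariate
#'   (>= 1, default 50).
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(classes = "LQHPT", n_hinge_knots = 50,
                         n_threshold_knots = 50) {
  if (length(classes) == 1L && nchar(classes) > 1L)
    classes <- strsplit(classes, "")[[1]]
  classes <- unique(toupper(classes))
  if (!length(classes) || !all(classes %in% c("L", "Q", "P", "T", "H")))
    stop("classes must be a non-empty subset of L, Q, P, T, H")
  if (n_hinge_knots < 2) stop("n_hinge_knots must be >= 2")
  if (n_threshold_knots < 1) stop("n_threshold_knots must be >= 1")
  structure(list(classes = classes,
                 n_hinge_knots = as.integer(n_hinge_knots),
                 n_threshold_knots = as.integer(n_threshold_knots)),
            class = "feature_spec")
}

# Normalizers (per-covariate min/max) and knot positions are frozen from a
# reference sample (the background, by convention) so the same transform is
# applied to presences, projection grids, and response-curve sweeps.
make_feature_map <- function(X_ref, spec) {
  stopifnot(is.matrix(X_ref), !is.null(colnames(X_ref)))
  if (any(!is.finite(X_ref))) stop("covariates must be finite for feature building")
  covs <- colnames(X_ref)
  rng <- lapply(covs, function(v) range(X_ref[, v]))
  names(rng) <- covs
  knots <- list()
  if ("H" %in% spec$classes || "T" %in% spec$classes) {
    for (v in covs) {
      if (diff(rng[[v]]) == 0) next
      if ("H" %in% spec$classes) {
        p <- seq_len(spec$n_hinge_knots) / (spec$n_hinge_knots + 1)
        knots[[paste0("H.", v)]] <-
          unique(stats::quantile(X_ref[, v], probs = p, names = FALSE, type = 7))
      }
      if ("T" %in% spec$classes) {
        p <- seq_len(spec$n_threshold_knots) / (spec$n_threshold_knots + 1)
        knots[[paste0("T.", v)]] <-
          unique(stats::quantile(X_ref[, v], probs = p, names = FALSE, type = 7))
      }
    }
  }
  structure(list(spec = spec, covariates = covs, range = rng, knots = knots),
            class = "feature_map")
}

#' Build the feature design matrix
#'
#' Expands a covariate matrix into the model's feature columns. Linear
#' features are min-max scaled to `[0, 1]` over the reference sample;
#' quadratic features are the squared scaled value; product features are
#' pairwise products of scaled values; threshold features are step
#' indicators `1{x > k}`; hinge features are forward `max(0, x - k) /
#' (max - k)` and reverse `max(0, k - x) / (k - min)` ramps. Knots sit at
#' equally spaced quantiles of the reference distribution. A constant
#' covariate contributes only a (zero) linear column, with a warning.
#'
#' @param X Covariate matrix (rows = samples, named columns).
#' @param spec A [feature_spec()]. Ignored when `map` is supplied.
#' @param map Optional frozen `feature_map` (from a previous call or a
#'   fitted model) so new data is expanded identically to the training data.
#' @return List with `features` (design matrix in the reference's `[0, 1]`
#'   scaling), `meta` (data frame: `name`, `class`, `cov1`, `cov2`, `knot`),
#'   and `map` (the frozen feature map).
#' @export
build_features <- function(X, spec = feature_spec(), map = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (is.null(map)) map <- make_feature_map(X, spec)
  spec <- map$spec
  miss <- setdiff(map$covariates, colnames(X))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  X <- X[, map$covariates, drop = FALSE]
  n <- nrow(X)
  cols <- list(); meta <- list()
  add <- function(vals, name, class, cov1, cov2 = NA_character_, knot = NA_real_) {
    cols[[length(cols) + 1L]] <<- vals
    meta[[length(meta) + 1L]] <<- data.frame(
      name = name, class = class, cov1 = cov1, cov2 = cov2, knot = knot,
      stringsAsFactors = FALSE)
  }
  scaled <- matrix(NA_real_, n, length(map$covariates),
                   dimnames = list(NULL, map$covariates))
  const_covs <- character(0)
  for (v in map$covariates) {
    lo <- map$range[[v]][1]; hi <- map$range[[v]][2]
    if (hi > lo) scaled[, v] <- (X[, v] - lo) / (hi - lo)
    else { scaled[, v] <- 0; const_covs <- c(const_covs, v) }
  }
  if (length(const_covs) && length(intersect(spec$classes, c("Q", "H", "T"))))
    warning("constant covariate(s) contribute only a linear feature: ",
            paste(const_covs, collapse = ", "))
  if ("L" %in% spec$classes)
    for (v in map$covariates) add(scaled[, v], paste0("L.", v), "L", v)
  if ("Q" %in% spec$classes)
    for (v in setdiff(map$covariates, const_covs))
      add(scaled[, v]^2, paste0("Q.", v), "Q", v)
  if ("P" %in% spec$classes && length(map$covariates) >= 2L) {
    cv <- map$covariates
    for (i in seq_len(length(cv) - 1L))
      for (j in seq.int(i + 1L, length(cv)))
        add(scaled[, cv[i]] * scaled[, cv[j]],
            paste0("P.", cv[i], ":", cv[j]), "P", cv[i], cv[j])
  }
  if ("T" %in% spec$classes)
    for (v in setdiff(map$covariates, const_covs))
      for (k in map$knots[[paste0("T.", v)]])
        add(as.numeric(X[, v] > k), sprintf("T.%s.%.8g", v, k), "T", v,
            knot = k)
  if ("H" %in% spec$classes)
    for (v in setdiff(map$covariates, const_covs)) {
      lo <- map$range[[v]][1]; hi <- map$range[[v]][2]
      for (k in map$knots[[paste0("H.", v)]]) {
        if (hi > k)
          add(pmax(0, X[, v] - k) / (hi - k), sprintf("HF.%s.%.8g", v, k),
              "H", v, knot = k)
        if (k > lo)
          add(pmax(0, k - X[, v]) / (k - lo), sprintf("HR.%s.%.8g", v, k),
              "H", v, knot = k)
      }
    }
  F <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  colnames(F) <- meta$name
  list(features = F, meta = meta, map = map)
}
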