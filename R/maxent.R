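#' Per-class base regularization table
#'
#' The published MaxEnt defaults interpolate the per-class base penalty on
#' the number of presence samples; the per-feature L1 weight is
#' `rm * base(class, m) * s_j / sqrt(m)` where `s_j` is the feature's
#' standard deviation over the presence sample and `m` the presence count.
#' The table is exposed so it can be inspected or replaced.
#'
#' @return Data frame with columns `class`, `m` (presence count node), and
#'   `base` (penalty at that node); linear interpolation between nodes,
#'   constant beyond them.
#' @export
maxent_reg_table <- function() {
  data.frame(
    class = c(rep("L", 4), rep("Q", 5), rep("P", 5), rep("T", 2), rep("H", 2)),
    m = c(0, 10, 30, 100,
          0, 10, 17, 30, 100,
          0, 10, 17, 30, 100,
          0, 100,
          0, 1),
    base = c(1, 1, 0.2, 0.05,
             1.3, 0.8, 0.5, 0.25, 0.05,
             2.6, 1.6, 0.9, 0.55, 0.05,
             2, 1,
             0.5, 0.5),
    stringsAsFactors = FALSE)
}

base_penalty <- function(class, m, table = maxent_reg_table()) {
  tb <- table[table$class == class, ]
  stats::approx(tb$m, tb$base, xout = m, rule = 2)$y
}

feature_penalties <- function(meta, F_presence, F_all, rm, m,
                              table = maxent_reg_table()) {
  s <- apply(F_presence, 2, stats::sd)
  s_all <- apply(F_all, 2, stats::sd)
  s[!is.finite(s) | s < 1e-8] <- s_all[!is.finite(s) | s < 1e-8]
  beta <- rm * vapply(meta$class, base_penalty, numeric(1), m = m,
                      table = table) * s / sqrt(m)
  beta[!is.finite(beta)] <- Inf  # truly constant features are never selected
  beta
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# FISTA (accelerated proximal gradient with backtracking and restart) on
#   f(b) = -mean(Fp b) + log sum exp(Fb b),   g(b) = sum(beta * |b|)
# Convergence: max |change| < tol or max_iter iterations.
fista_maxent <- function(Fp, Fb, beta, tol = 1e-7, max_iter = 10000L) {
  p <- ncol(Fb)
  mean_fp <- colMeans(Fp)
  fval <- function(b) {
    eta <- drop(Fb %*% b)
    -sum(mean_fp * b) + logsumexp(eta)
  }
  grad <- function(b) {
    eta <- drop(Fb %*% b)
    w <- exp(eta - logsumexp(eta))
    drop(crossprod(Fb, w)) - mean_fp
  }
  prox <- function(z, t) sign(z) * pmax(abs(z) - t * beta, 0)
  pen <- function(b) sum(beta * abs(b))
  b <- numeric(p); y <- b; tk <- 1; step <- 1
  obj_b <- fval(b) + pen(b)
  delta <- Inf; it <- 0L; stall <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f_y <- fval(y); g_y <- grad(y)
    repeat {
      b_new <- prox(y - step * g_y, step)
      d <- b_new - y
      f_new <- fval(b_new)
      if (f_new <= f_y + sum(g_y * d) + sum(d * d) / (2 * step) + 1e-12 ||
          step < 1e-12) break
      step <- step / 2
    }
    obj_new <- f_new + pen(b_new)
    if (obj_new > obj_b + 1e-12) {     # momentum overshoot: restart at b
      y <- b; tk <- 1
      next
    }
    delta <- max(abs(b_new - b))
    # objective improvements at the double-precision noise floor mean the
    # iterate is only rattling; treat a long stall as converged
    stall <- if (obj_b - obj_new < 1e-12) stall + 1L else 0L
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- b_new + ((tk - 1) / t_next) * (b_new - b)
    tk <- t_next
    b <- b_new; obj_b <- obj_new
    step <- step * 2                   # let the step grow back
    if (delta < tol || stall >= 50L) break
  }
  list(coef = b, iterations = it, converged = delta < tol || stall >= 50L)
}

#' Fit a presence-background maximum-entropy model
#'
#' Minimizes the penalized Gibbs objective: the negative log-likelihood of
#' the presence sample under the exponential (Gibbs) density over the
#' background cells, plus an L1 penalty `sum(beta_j * |coef_j|)` with
#' per-feature weights from the sample-size-interpolated class defaults
#' scaled by the regularization multiplier `rm`. Optimization is an
#' accelerated proximal-gradient (FISTA) scheme with backtracking,
#' converging when the largest coefficient change drops below `tol`.
#'
#' @param presence_X,background_X Covariate matrices (named columns; the
#'   background also anchors the feature normalizers and knots).
#' @param spec A [feature_spec()].
#' @param rm Regularization multiplier (> 0), default 1.
#' @param link Default output transform: `"cloglog"` (default),
#'   `"logistic"`, or `"raw"`.
#' @param tol,max_iter Optimizer controls.
#' @param reg_table Per-class base-penalty table, see [maxent_reg_table()].
#' @return A `maxent_model` with coefficients, the frozen feature map,
#'   normalization constant (`alpha`, so raw predictions sum to 1 over the
#'   training background), training entropy, and tuning metadata.
#' @export
fit_maxent <- function(presence_X, background_X, spec = feature_spec(),
                       rm = 1, link = c("cloglog", "logistic", "raw"),
                       tol = 1e-7, max_iter = 10000L,
                       reg_table = maxent_reg_table()) {
  link <- match.arg(link)
  if (is.data.frame(presence_X)) presence_X <- as.matrix(presence_X)
  if (is.data.frame(background_X)) background_X <- as.matrix(background_X)
  stopifnot(is.matrix(presence_X), is.matrix(background_X),
            identical(colnames(presence_X), colnames(background_X)))
  m <- nrow(presence_X)
  if (m == 0L) stop("no presence records")
  if (m < 10L) warning("fewer than 10 presence records; fit may be unstable")
  if (nrow(background_X) < 100L)
    warning("fewer than 100 background samples; fit may be unstable")
  if (!is.finite(rm) || rm <= 0) stop("rm must be positive")
  fb <- build_features(background_X, spec)
  fp <- build_features(presence_X, map = fb$map)
  beta <- feature_penalties(fb$meta, fp$features,
                            rbind(fp$features, fb$features), rm, m,
                            table = reg_table)
  usable <- is.finite(beta)
  fit <- fista_maxent(fp$features[, usable, drop = FALSE],
                      fb$features[, usable, drop = FALSE],
                      beta[usable], tol = tol, max_iter = max_iter)
  coef <- numeric(ncol(fb$features)); names(coef) <- fb$meta$name
  coef[usable] <- fit$coef
  eta_b <- drop(fb$features %*% coef)
  alpha <- -logsumexp(eta_b)
  raw_b <- exp(eta_b + alpha)
  entropy <- -sum(ifelse(raw_b > 0, raw_b * log(raw_b), 0))
  structure(list(
    feature_spec = spec, rm = rm, coefficients = coef, map = fb$map,
    meta = fb$meta, penalties = beta, alpha = alpha, entropy = entropy,
    link = link, covariate_names = colnames(background_X),
    bg_means = colMeans(background_X),
    n_presence = m, n_background = nrow(background_X),
    optimizer = fit[c("iterations", "converged")]),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> FC=%s RM=%g: %d/%d non-zero features over %d covariates\n",
    paste(x$feature_spec$classes, collapse = ""), x$rm,
    sum(x$coefficients != 0), length(x$coefficients),
    length(x$covariate_names)))
  cat(sprintf("  n_presence=%d n_background=%d entropy=%.4f link=%s\n",
              x$n_presence, x$n_background, x$entropy, x$link))
  invisible(x)
}

#' Predict suitability from a fitted maximum-entropy model
#'
#' `raw` is the normalized Gibbs density (sums to 1 over the training
#' background); `logistic` and `cloglog` rescale it through the stored
#' training entropy `H` as `e^H r / (1 + e^H r)` and `1 - exp(-e^H r)`
#' respectively, giving values in `[0, 1]`. The three transforms are
#' strictly monotone in one another, so cell rankings agree.
#'
#' @param object A `maxent_model`.
#' @param newdata Covariate matrix / data frame, or a [layer_stack()]
#'   containing all model covariates (missing cells propagate as `NA`).
#' @param link Output transform; defaults to the model's.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a [raster_grid()] named
#'   `"suitability"` when `newdata` is a stack.
#' @export
predict.maxent_model <- function(object, newdata,
                                 link = c("model", "raw", "logistic", "cloglog"),
                                 ...) {
  link <- match.arg(link)
  if (link == "model") link <- object$link
  if (inherits(newdata, "layer_stack")) {
    miss <- setdiff(object$covariate_names, names(newdata$layers))
    if (length(miss))
      stop("stack is missing model covariate(s): ", paste(miss, collapse = ", "))
    X <- stack_matrix(newdata)[, object$covariate_names, drop = FALSE]
    out <- rep(NA_real_, nrow(X))
    ok <- rowSums(is.na(X)) == 0L
    if (any(ok))
      out[ok] <- predict(object, X[ok, , drop = FALSE], link = link)
    return(raster_grid(matrix(out, newdata$spec$n_rows, newdata$spec$n_cols),
                       newdata$spec, "suitability"))
  }
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  miss <- setdiff(object$covariate_names, colnames(newdata))
  if (length(miss))
    stop("missing model covariate(s): ", paste(miss, collapse = ", "))
  f <- build_features(newdata[, object$covariate_names, drop = FALSE],
                      map = object$map)
  eta <- drop(f$features %*% object$coefficients)
  raw <- exp(eta + object$alpha)
  switch(link,
         raw = raw,
         logistic = {
           z <- exp(object$entropy) * raw
           z / (1 + z)
         },
         cloglog = 1 - exp(-exp(object$entropy) * raw))
}

# Mean log raw presence probability relative to a uniform background:
# the MaxEnt "training gain".
training_gain <- function(model, presence_X) {
  raw <- predict(model, presence_X, link = "raw")
  mean(log(pmax(raw, .Machine$double.xmin))) + log(model$n_background)
}

#' Tune feature classes and regularization multiplier by AICc
#'
#' Fits one candidate per (feature-class set, RM) pair and scores each with
#' the small-sample-corrected AIC: `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`,
#' where `k` counts non-zero coefficients, `n` is the presence count, and
#' `lnL` is the sum of log raw probabilities at the presences. Candidates
#' with `n - k - 1 <= 0` score `+Inf`. The minimum-AICc candidate is
#' selected (`delta_AICc = 0`), ties broken by smaller `k`, then larger RM.
#'
#' @param presence_X,background_X Covariate matrices.
#' @param rm_grid Regularization multipliers (default 0.5 to 4 by 0.5).
#' @param fc_sets List of feature-class strings (default `"LQHPT"` only).
#' @param n_hinge_knots,n_threshold_knots Passed to [feature_spec()].
#' @param keep_models Keep every fitted candidate (default: only the
#'   selected one).
#' @param ... Passed on to [fit_maxent()].
#' @return A `tuning_result`: list with `candidates` (data frame: `fc`,
#'   `rm`, `k`, `lnL`, `AICc`, `delta_AICc`), `selected` (row index), and
#'   `model` (the selected fit).
#' @export
tune_maxent <- function(presence_X, background_X,
                        rm_grid = seq(0.5, 4, by = 0.5),
                        fc_sets = list("LQHPT"),
                        n_hinge_knots = 50, n_threshold_knots = 50,
                        keep_models = FALSE, ...) {
  stopifnot(length(rm_grid) >= 1L, length(fc_sets) >= 1L)
  n <- nrow(presence_X)
  rows <- list(); models <- list()
  for (fc in fc_sets) for (rm in rm_grid) {
    spec <- feature_spec(fc, n_hinge_knots, n_threshold_knots)
    mod <- fit_maxent(presence_X, background_X, spec, rm = rm, ...)
    raw_p <- predict(mod, presence_X, link = "raw")
    lnL <- sum(log(pmax(raw_p, .Machine$double.xmin)))
    k <- sum(mod$coefficients != 0)
    aicc <- if (n - k - 1 <= 0) Inf else 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      fc = paste(spec$classes, collapse = ""), rm = rm, k = k, lnL = lnL,
      AICc = aicc, stringsAsFactors = FALSE)
    models[[length(models) + 1L]] <- mod
  }
  cand <- do.call(rbind, rows)
  if (all(!is.finite(cand$AICc)))
    stop("all candidates have infinite AICc; more presences are needed")
  cand$delta_AICc <- cand$AICc - min(cand$AICc)
  ord <- order(cand$delta_AICc, cand$k, -cand$rm)
  sel <- ord[1]
  structure(list(candidates = cand, selected = sel, model = models[[sel]],
                 models = if (keep_models) models else NULL),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d candidates; selected FC=%s RM=%g (k=%d, AICc=%.2f)\n",
              nrow(x$candidates), x$candidates$fc[x$selected],
              x$candidates$rm[x$selected], x$candidates$k[x$selected],
              x$candidates$AICc[x$selected]))
  invisible(x)
}

#' Area under the ROC curve for presence vs background scores
#'
#' The rank (Mann-Whitney) formulation: the probability that a random
#' presence outscores a random background point, ties counted one half.
#'
#' @param scores_presence,scores_background Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0L || nb == 0L) stop("both score sets must be non-empty")
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Jackknife variable importance
#'
#' Refits the model with each covariate alone and with each covariate left
#' out, reporting the training gain of every fit (gain = mean log raw
#' presence probability minus the log of a uniform background cell's
#' probability).
#'
#' @param presence_X,background_X Covariate matrices (>= 2 covariates).
#' @param spec A [feature_spec()].
#' @param rm Regularization multiplier.
#' @param ... Passed on to [fit_maxent()].
#' @return Data frame (`variable`, `gain_with_only`, `gain_without`) with
#'   the full-model gain as attribute `full_gain`.
#' @export
jackknife_importance <- function(presence_X, background_X,
                                 spec = feature_spec(), rm = 1, ...) {
  if (is.data.frame(presence_X)) presence_X <- as.matrix(presence_X)
  if (is.data.frame(background_X)) background_X <- as.matrix(background_X)
  covs <- colnames(background_X)
  if (length(covs) < 2L) stop("jackknife needs at least 2 covariates")
  gain_for <- function(keep) {
    mod <- fit_maxent(presence_X[, keep, drop = FALSE],
                      background_X[, keep, drop = FALSE], spec, rm = rm, ...)
    training_gain(mod, presence_X[, keep, drop = FALSE])
  }
  full <- gain_for(covs)
  out <- data.frame(
    variable = covs,
    gain_with_only = vapply(covs, function(v) gain_for(v), numeric(1)),
    gain_without = vapply(covs, function(v) gain_for(setdiff(covs, v)),
                          numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "full_gain") <- full
  out
}

#' Permutation percent contribution of each covariate
#'
#' Shuffles one covariate at a time across the pooled presence + background
#' rows, measures the drop in training AUC, averages over permutations,
#' floors negative drops at zero, and normalizes to percentages summing
#' to 100.
#'
#' @param model A fitted `maxent_model`.
#' @param presence_X,background_X The training covariate matrices.
#' @param permutations Number of shuffles per covariate (default 10).
#' @param seed Integer seed making the result reproducible.
#' @return Named numeric vector of percentages (sums to 100).
#' @export
percent_contribution <- function(model, presence_X, background_X,
                                 permutations = 10, seed = 1L) {
  if (is.data.frame(presence_X)) presence_X <- as.matrix(presence_X)
  if (is.data.frame(background_X)) background_X <- as.matrix(background_X)
  covs <- model$covariate_names
  np <- nrow(presence_X)
  pooled <- rbind(presence_X[, covs, drop = FALSE],
                  background_X[, covs, drop = FALSE])
  base_auc <- evaluate_auc(
    predict(model, presence_X, link = "raw"),
    predict(model, background_X, link = "raw"))
  set.seed(seed)
  drops <- vapply(covs, function(v) {
    mean(vapply(seq_len(permutations), function(i) {
      perm <- pooled
      perm[, v] <- perm[sample.int(nrow(perm)), v]
      auc <- evaluate_auc(
        predict(model, perm[seq_len(np), , drop = FALSE], link = "raw"),
        predict(model, perm[-seq_len(np), , drop = FALSE], link = "raw"))
      base_auc - auc
    }, numeric(1)))
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    warning("all permutation drops are zero; reporting a uniform split")
    drops <- rep(1, length(covs))
  }
  100 * drops / sum(drops)
}

#' Response curve of one covariate
#'
#' Sweeps the covariate over its training range while holding every other
#' covariate at its background mean, and evaluates the model through the
#' requested link.
#'
#' @param model A fitted `maxent_model`.
#' @param variable Covariate name.
#' @param n_points Number of sweep points (default 100).
#' @param link Output transform; defaults to the model's.
#' @return Data frame with columns `x` and `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100,
                           link = c("model", "raw", "logistic", "cloglog")) {
  link <- match.arg(link)
  if (!variable %in% model$covariate_names)
    stop("unknown variable: ", variable)
  rng <- model$map$range[[variable]]
  xs <- seq(rng[1], rng[2], length.out = n_points)
  X <- matrix(rep(model$bg_means, each = n_points),
              nrow = n_points,
              dimnames = list(NULL, model$covariate_names))
  X[, variable] <- xs
  data.frame(x = xs, suitability = predict(model, X, link = link))
}

#' Serialize / restore a maximum-entropy model as JSON
#'
#' @param model A `maxent_model`.
#' @param path Output (input) path.
#' @return `write_maxent_model`: `path`, invisibly. `read_maxent_model`:
#'   the restored `maxent_model`.
#' @export
write_maxent_model <- function(model, path) {
  obj <- list(
    format = "invrisk-maxent", version = 1L,
    classes = model$feature_spec$classes,
    n_hinge_knots = model$feature_spec$n_hinge_knots,
    n_threshold_knots = model$feature_spec$n_threshold_knots,
    rm = model$rm, link = model$link, alpha = model$alpha,
    entropy = model$entropy, covariate_names = model$covariate_names,
    bg_means = as.list(model$bg_means),
    range = model$map$range, knots = model$map$knots,
    coefficients = as.list(model$coefficients),
    n_presence = model$n_presence, n_background = model$n_background)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "invrisk-maxent"))
    stop("not an invrisk maxent model file: ", path)
  spec <- feature_spec(obj$classes, obj$n_hinge_knots, obj$n_threshold_knots)
  map <- structure(list(spec = spec, covariates = obj$covariate_names,
                        range = lapply(obj$range, as.numeric),
                        knots = lapply(obj$knots, as.numeric)),
                   class = "feature_map")
  coef <- unlist(obj$coefficients)
  meta <- data.frame(name = names(coef), stringsAsFactors = FALSE)
  structure(list(
    feature_spec = spec, rm = obj$rm, coefficients = coef, map = map,
    meta = meta, alpha = obj$alpha, entropy = obj$entropy, link = obj$link,
    covariate_names = obj$covariate_names, bg_means = unlist(obj$bg_means),
    n_presence = obj$n_presence, n_background = obj$n_background),
    class = "maxent_model")
}
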