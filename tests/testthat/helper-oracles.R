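# Independent oracle for the maximum-entropy fit: maximize entropy over
# the probability simplex subject to matching target feature means, by
# direct optimization over softmax parameters with an augmented
# Lagrangian (analytic gradient) — no Gibbs machinery shared with the
# implementation under test.
brute_force_simplex_entropy <- function(F_cells, target_means) {
  lam <- numeric(length(target_means))
  mu <- 1e2
  softmax <- function(theta) {
    p <- exp(theta - max(theta))
    p / sum(p)
  }
  obj <- function(theta) {
    p <- softmax(theta)
    gap <- drop(crossprod(F_cells, p)) - target_means
    sum(ifelse(p > 0, p * log(p), 0)) + sum(lam * gap) + mu * sum(gap^2)
  }
  grad <- function(theta) {
    p <- softmax(theta)
    gap <- drop(crossprod(F_cells, p)) - target_means
    s <- log(pmax(p, .Machine$double.xmin)) + 1 +
      drop(F_cells %*% (lam + 2 * mu * gap))
    p * (s - sum(p * s))
  }
  theta <- numeric(nrow(F_cells))
  # keep theta bounded so softmax never collapses to a zero-gradient
  # vertex; ramp the penalty gently for the same reason
  for (outer in 1:12) {
    theta <- stats::optim(theta, obj, grad, method = "L-BFGS-B",
                          lower = -15, upper = 15,
                          control = list(maxit = 5000, factr = 1))$par
    p <- softmax(theta)
    gap <- drop(crossprod(F_cells, p)) - target_means
    lam <- lam + 2 * mu * gap
    if (max(abs(gap)) < 1e-11) break
    mu <- mu * 3
  }
  softmax(theta)
}
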