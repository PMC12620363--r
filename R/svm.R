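# Deterministic linear max-margin classifier.
#
# No SVM solver ships with the supported environment, so the soft-margin
# linear SVM used for projections and pairwise separability is implemented
# here as the smooth L2-regularized squared-hinge primal
#
#   min_{w,b}  1/2 ||w||^2 + C * sum_k max(0, 1 - y_k (w.x_k + b))^2
#
# solved with BFGS from a zero start.  The objective is convex and C^1, the
# optimizer is deterministic, and for large C on separable data the solution
# approaches the hard-margin geometry (gap-midpoint boundary in 1-D,
# maximal-margin normal in general).  y is coded -1/+1.

fit_linear_maxmargin <- function(X, y, cost = 1e6, maxit = 5000L) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(-1, 1)))
  obj <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1L]
    m <- 1 - y * as.vector(X %*% w + b)
    0.5 * sum(w^2) + cost * sum(pmax(m, 0)^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1L]
    m <- 1 - y * as.vector(X %*% w + b)
    a <- pmax(m, 0)
    c(w - 2 * cost * as.vector(crossprod(X, a * y)),
      -2 * cost * sum(a * y))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-15))
  w <- fit$par[seq_len(p)]
  b <- fit$par[p + 1L]
  pred <- ifelse(as.vector(X %*% w + b) >= 0, 1, -1)
  list(w = w, b = b,
       norm = sqrt(sum(w^2)),
       training_error = mean(pred != y),
       converged = fit$convergence == 0L)
}
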