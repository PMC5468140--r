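# Independent oracles used by the unit tests; written against the math,
# not the package code paths.

# Newton-Raphson logistic regression (dense, no random effects).
oracle_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    step <- solve(crossprod(X, w * X), crossprod(X, y - mu))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = beta,
       vcov = solve(crossprod(X, (1 / (1 + exp(-as.numeric(X %*% beta)))) *
                                 (1 - 1 / (1 + exp(-as.numeric(X %*% beta)))) * X)))
}

# Brute-force VIF: explicit least-squares R^2 per column.
oracle_vif <- function(X) {
  sapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
}

# Independently coded PQL fitter for an iid (exchangeable) unit-level
# random intercept: dense working-LMM alternation, no CAR structure.
oracle_iid_pql <- function(X, y, max_iter = 200, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  beta <- rep(0, p); u <- rep(0, n); tau <- 0.1
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta) + u
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    V <- diag(1 / w) + tau * diag(n)
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi %*% X)
    beta_new <- solve(XtViX, crossprod(X, Vi %*% z))
    r <- z - as.numeric(X %*% beta_new)
    u_new <- tau * as.numeric(Vi %*% r)
    # REML update of tau on the working model
    nr <- function(lt) {
      Vt <- diag(1 / w) + exp(lt) * diag(n)
      Vti <- solve(Vt)
      XtV <- crossprod(X, Vti %*% X)
      b <- solve(XtV, crossprod(X, Vti %*% z))
      rr <- z - as.numeric(X %*% b)
      as.numeric(determinant(Vt)$modulus) +
        as.numeric(determinant(XtV)$modulus) + sum(rr * (Vti %*% rr))
    }
    tau_new <- exp(optimize(nr, c(log(1e-8), log(100)))$minimum)
    delta <- max(abs(c(beta_new - beta, tau_new - tau)))
    beta <- as.numeric(beta_new); u <- u_new; tau <- tau_new
    if (delta < tol) break
  }
  list(beta = beta, tau = tau, u = u)
}

# Brute-force lattice enumeration for the local grid layout.
oracle_grid_count <- function(half_extent, transect_spacing, plot_spacing) {
  xs <- seq(-half_extent, half_extent, by = transect_spacing)
  ys <- seq(-half_extent, half_extent, by = plot_spacing)
  length(xs) * length(ys)
}
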