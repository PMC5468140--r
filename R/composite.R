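# Composite-likelihood estimation of the CAR dispersion parameters.
#
# Penalized quasi-likelihood and Laplace marginal likelihood are known to
# collapse the random-effect variance toward zero when each random effect
# carries a single binary observation; with tau underestimated, beta is
# attenuated. The composite path estimates (tau, rho) consistently from the
# exact marginal singleton and neighbour-pair likelihoods (Gauss-Hermite
# quadrature over the implied uni-/bivariate normal effects), and then
# maximizes the Laplace likelihood over beta with the dispersion fixed --
# a step that is empirically near-unbiased once (tau, rho) are right.

# Probabilist Gauss-Hermite rule: nodes z and weights w with sum(w) = 1,
# E[f(Z)] ~ sum w_k f(z_k) for Z ~ N(0,1). Golub-Welsch on the Jacobi matrix.
gauss_hermite_normal <- function(n) {
  if (n == 1) return(list(z = 0, w = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(z = sqrt(2) * e$values, w = e$vectors[1, ]^2)
}

# Entries of (I - rho D)^{-1} needed by the composite likelihood -- the
# diagonal and the pair entries -- as smooth functions of rho. Every entry
# is exactly sum_m V_im V_jm / (1 - rho lambda_m) over the eigenpairs of D,
# i.e. a combination of simple rational terms; exact dense block inversions
# on a Chebyshev rho-grid (identical year blocks inverted once) are
# therefore fitted in the rational basis 1/(1 - rho s_k) with nodes s_k
# spanning the spectrum, which reproduces the pole behaviour that defeats
# polynomial interpolation. Cached on the adjacency object.
cl_entry_grid <- function(D, n_grid = 15, margin_frac = 0.03) {
  if (inherits(D, "adjacency") && !is.null(D$cache$cl_grid))
    return(D$cache$cl_grid)
  M <- adjacency_matrix(D)
  n <- nrow(M)
  rng <- rho_valid_range(D)
  if (!is.finite(rng[1]))
    stop("composite method needs a design with at least one neighbour pair",
         call. = FALSE)
  # shrink each end in proportion to its distance from zero (the poles of
  # (I - rho D)^{-1} sit at the range ends; a width-based margin could cut
  # off admissible rho values when the spectrum is asymmetric)
  lo <- rng[1] * (1 - margin_frac)
  hi <- rng[2] * (1 - margin_frac)
  cheb <- cos(pi * (2 * seq_len(n_grid) - 1) / (2 * n_grid))  # (-1, 1)
  rho_grid <- sort((lo + hi) / 2 + (hi - lo) / 2 * cheb)

  # pairs at graph distance 1 and 2: first-order pairs identify the
  # variance-covariance scale, second-order pairs the decay with distance,
  # separating tau from rho
  Mt <- methods::as(Matrix::triu(M), "TsparseMatrix")
  e1 <- cbind(i = Mt@i + 1L, j = Mt@j + 1L)
  M2t <- methods::as(methods::as(Matrix::triu(M %*% M), "generalMatrix"),
                     "TsparseMatrix")
  e2 <- cbind(i = M2t@i + 1L, j = M2t@j + 1L)
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]
  e2 <- e2[!(paste(e2[, 1], e2[, 2]) %in% paste(e1[, 1], e1[, 2])), ,
           drop = FALSE]
  edges <- rbind(e1, e2)
  blocks <- if (inherits(D, "adjacency") && !anyNA(D$block_by_year) &&
                isTRUE(D$block_by_year))
    split(seq_len(n), D$units$year) else list(seq_len(n))

  gmat <- matrix(NA_real_, n_grid, n)
  hmat <- matrix(NA_real_, n_grid, nrow(edges))
  for (b in blocks) {
    Mb <- as.matrix(M[b, b, drop = FALSE])
    eb <- which(edges[, 1] %in% b)
    pos <- cbind(match(edges[eb, 1], b), match(edges[eb, 2], b))
    # reuse inversions of identical blocks
    done <- FALSE
    if (exists(".cl_seen", inherits = FALSE)) {
      for (s in .cl_seen) if (identical(s$Mb, Mb)) {
        gmat[, b] <- s$g; hmat[, eb] <- s$h[, match_edges(s$pos, pos)]
        done <- TRUE; break
      }
    } else .cl_seen <- list()
    if (done) next
    g <- matrix(NA_real_, n_grid, length(b))
    h <- matrix(NA_real_, n_grid, length(eb))
    I_b <- diag(length(b))
    for (k in seq_len(n_grid)) {
      K <- solve(I_b - rho_grid[k] * Mb)
      g[k, ] <- diag(K)
      h[k, ] <- K[pos]
    }
    gmat[, b] <- g; hmat[, eb] <- h
    .cl_seen[[length(.cl_seen) + 1L]] <- list(Mb = Mb, g = g, h = h, pos = pos)
  }
  # rational basis nodes: eigenvalue quantiles, extremes included
  lam <- adjacency_eigenvalues(D)
  s_nodes <- unique(round(as.numeric(
    stats::quantile(lam, probs = seq(0, 1, length.out = n_grid - 3))), 6))
  B <- 1 / (1 - outer(rho_grid, s_nodes))
  # rank-tolerant least squares: repeated eigenvalues make columns collinear
  sv <- svd(B)
  keep <- sv$d > max(sv$d) * 1e-10
  fit_coef <- function(Y) {
    sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep])
  }
  out <- list(rho_grid_range = c(lo, hi), s_nodes = s_nodes,
              coef_g = fit_coef(gmat), coef_h = fit_coef(hmat),
              edges = edges)
  if (inherits(D, "adjacency")) D$cache$cl_grid <- out
  out
}

# identical blocks produce identical local edge layouts; map stored edge
# positions onto the requested ones
match_edges <- function(stored_pos, want_pos) {
  key <- function(p) paste(p[, 1], p[, 2])
  idx <- match(key(want_pos), key(stored_pos))
  if (anyNA(idx)) stop("internal error: edge mismatch between identical blocks")
  idx
}

cl_entries <- function(grid, rho) {
  v <- 1 / (1 - rho * grid$s_nodes)
  list(g = as.numeric(v %*% grid$coef_g),
       h = as.numeric(v %*% grid$coef_h))
}

# Singleton marginal probabilities and the Newton profile of beta given the
# per-unit marginal random-effect standard deviations sd_i:
# P(y_i = 1) = E[plogis(x_i beta + sd_i Z)], Z ~ N(0,1).
cl_singleton_probs <- function(eta, sd_i, gh1) {
  Eta <- eta + outer(sd_i, gh1$z)
  P <- stats::plogis(Eta)
  p1 <- pmin(pmax(as.numeric(P %*% gh1$w), 1e-12), 1 - 1e-12)
  q0 <- as.numeric((P * (1 - P)) %*% gh1$w)   # d p1 / d eta
  list(p1 = p1, q0 = q0)
}

cl_profile_beta <- function(X, y, sd_i, gh1, beta0, max_iter = 50, tol = 1e-9) {
  beta <- beta0
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    s <- cl_singleton_probs(eta, sd_i, gh1)
    r <- (y - s$p1) / (s$p1 * (1 - s$p1))
    score <- crossprod(X, r * s$q0)
    W <- s$q0^2 / (s$p1 * (1 - s$p1))
    H <- crossprod(X, W * X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    ms <- max(abs(step))
    if (ms > 2) step <- step * (2 / ms)
    beta <- beta + as.numeric(step)
    if (ms < tol) break
  }
  eta <- as.numeric(X %*% beta)
  s <- cl_singleton_probs(eta, sd_i, gh1)
  ll <- sum(y * log(s$p1) + (1 - y) * log(1 - s$p1))
  list(beta = beta, eta = eta, p1 = s$p1, ll = ll)
}

# Neighbour-pair composite log-likelihood given eta and singleton p1.
cl_pair_loglik <- function(eta, p1, a, cij, y, edges, gh2) {
  ii <- edges[, 1]; jj <- edges[, 2]
  aii <- a[ii]; ajj <- a[jj]
  s2 <- ajj - cij^2 / aii
  if (any(s2 <= 0) || any(aii <= 0)) return(-1e10)
  sa <- sqrt(aii); sb <- sqrt(s2); slope <- cij / sa
  e_i <- eta[ii]; e_j <- eta[jj]
  p11 <- numeric(length(ii))
  for (k in seq_along(gh2$z)) {
    pi_k <- stats::plogis(e_i + sa * gh2$z[k])
    mu_j <- e_j + slope * gh2$z[k]
    pj_k <- numeric(length(ii))
    for (l in seq_along(gh2$z))
      pj_k <- pj_k + gh2$w[l] * stats::plogis(mu_j + sb * gh2$z[l])
    p11 <- p11 + gh2$w[k] * pi_k * pj_k
  }
  pi1 <- p1[ii]; pj1 <- p1[jj]
  p11 <- pmin(pmax(p11, 1e-12), pmin(pi1, pj1) - 1e-12)
  p10 <- pmax(pi1 - p11, 1e-12)
  p01 <- pmax(pj1 - p11, 1e-12)
  p00 <- pmax(1 - pi1 - pj1 + p11, 1e-12)
  yi <- y[ii]; yj <- y[jj]
  sum(log(ifelse(yi == 1 & yj == 1, p11,
                 ifelse(yi == 1 & yj == 0, p10,
                        ifelse(yi == 0 & yj == 1, p01, p00)))))
}

# Composite fit: an outer search over (tau, rho) maximizes the sum of the
# singleton and neighbour-pair composite log-likelihoods, with beta profiled
# out of the singleton part by Newton iteration at every evaluation (warm
# started). Profiling inside the outer objective resolves the attenuation
# ridge (beta_marginal, tau = 0) that defeats stagewise alternation: moving
# along the ridge changes the pair likelihood, so the outer search picks the
# (tau, rho) the neighbour concordance supports. beta is then re-estimated
# by fixed-dispersion Laplace at the selected (tau, rho). Returns the same
# contract as laplace_refit.
composite_fit <- function(y, X, M, D, lam, edgeless, beta0, opt, cache,
                          gh_singles = 20, gh_pairs = 6) {
  grid <- cl_entry_grid(D)
  gh1 <- gauss_hermite_normal(gh_singles)
  gh2 <- gauss_hermite_normal(gh_pairs)
  rng <- grid$rho_grid_range
  tau <- opt$fix_tau %||% 0.3
  rho <- opt$fix_rho %||% min(max(opt$rho_init, rng[1]), rng[2])
  free_tau <- is.null(opt$fix_tau); free_rho <- is.null(opt$fix_rho)
  env <- new.env(parent = emptyenv())
  env$beta <- beta0

  outer_obj <- function(par) {
    lt <- if (free_tau) par[["ltau"]] else log(tau)
    rh <- if (free_rho) par[["rho"]] else rho
    tau_ <- exp(lt)
    ent <- cl_entries(grid, rh)
    a <- tau_ * ent$g
    if (any(a <= 0)) return(1e10)
    prof <- cl_profile_beta(X, y, sqrt(a), gh1, env$beta)
    env$beta <- prof$beta
    llp <- cl_pair_loglik(prof$eta, prof$p1, a, tau_ * ent$h, y, grid$edges, gh2)
    val <- -(prof$ll + llp)
    if (!is.finite(val)) 1e10 else val
  }

  conv <- TRUE
  Vth <- NULL
  db <- NULL
  if (free_tau || free_rho) {
    par <- c(if (free_tau) c(ltau = log(tau)), if (free_rho) c(rho = rho))
    res <- stats::optim(par, outer_obj, method = "L-BFGS-B",
                        lower = c(if (free_tau) log(1e-4), if (free_rho) rng[1]),
                        upper = c(if (free_tau) log(50), if (free_rho) rng[2]),
                        control = list(maxit = 200))
    if (free_tau) tau <- exp(res$par[["ltau"]])
    if (free_rho) rho <- res$par[["rho"]]
    conv <- res$convergence == 0
    outer_obj(res$par)  # leave env$beta at the optimum
    # curvature of the outer composite objective, for the two-stage
    # variance propagation below
    H <- tryCatch(stats::optimHess(res$par, outer_obj),
                  error = function(e) NULL)
    if (!is.null(H)) {
      # the objective can be numerically flat along the attenuation ridge;
      # clip the curvature spectrum away from zero before inverting
      eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
      vals <- pmax(eh$values, max(abs(eh$values)) * 1e-6, 1e-8)
      Vth <- eh$vectors %*% (t(eh$vectors) / vals)
    }
    # sensitivity of the profiled beta to the dispersion parameters
    if (!is.null(Vth)) {
      steps <- c(ltau = 0.15, rho = 0.05 * (rng[2] - rng[1]))[names(res$par)]
      db <- vapply(seq_along(res$par), function(j) {
        pj <- res$par
        hi_j <- c(log(50), rng[2])[match(names(res$par)[j], c("ltau", "rho"))]
        # step into the interior when the estimate sits at the upper bound
        pj[j] <- if (pj[j] + steps[j] <= hi_j) pj[j] + steps[j] else
          pj[j] - steps[j]
        h <- pj[j] - res$par[j]
        tau_j <- if (free_tau) exp(pj[["ltau"]]) else tau
        rho_j <- if (free_rho) pj[["rho"]] else rho
        aj <- tau_j * cl_entries(grid, rho_j)$g
        (cl_profile_beta(X, y, sqrt(aj), gh1, env$beta)$beta - env$beta) / h
      }, numeric(ncol(X)))
      if (is.null(dim(db))) db <- matrix(db, ncol = length(res$par))
    }
  }
  beta <- env$beta
  ent <- cl_entries(grid, rho)
  a <- tau * ent$g
  sfin <- cl_singleton_probs(as.numeric(X %*% beta), sqrt(a), gh1)
  info_b <- crossprod(X, (sfin$q0^2 / (sfin$p1 * (1 - sfin$p1))) * X)
  vcov_b <- solve(info_b)
  if (!is.null(Vth) && !is.null(db))
    vcov_b <- vcov_b + db %*% Vth %*% t(db)
  dimnames(vcov_b) <- list(colnames(X), colnames(X))
  # random-effect predictions at the composite estimates: penalized Newton
  # for u given beta and the selected dispersion
  Q <- car_precision(D, tau, rho)
  u <- numeric(length(y))
  for (it in 1:100) {
    eta <- as.numeric(X %*% beta) + u
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    A <- car_system(M, w, tau, rho)
    ch <- chol_solve_logdet(A, cache, key = "ch_cl")
    step <- as.numeric(Matrix::solve(ch, (y - mu) - as.numeric(Q %*% u),
                                     system = "A"))
    ms <- max(abs(step))
    if (ms > 5) step <- step * (5 / ms)
    u <- u + step
    if (ms < 1e-9) break
  }
  list(beta = stats::setNames(beta, colnames(X)), tau = tau, rho = rho,
       sy2 = NULL, v = u, converged = conv, vcov_override = vcov_b)
}
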