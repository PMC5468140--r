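#' Build the spatial neighbourhood matrix over plot-year units
#'
#' Two units are neighbours when their plot centres lie within `threshold`
#' metres of each other (inclusive). The diagonal is zero. Under the default
#' blocking rule, units observed in different years are never neighbours, so
#' the matrix is block-diagonal by year; a pooled cross-year option is
#' available behind `block_by_year = FALSE`.
#'
#' @param units Data frame with columns `plot_id`, `x`, `y` and (unless a
#'   single-year design) `year`. Each (plot_id, year) pair must be unique.
#' @param threshold Neighbourhood radius in metres (inclusive).
#' @param block_by_year Logical; forbid cross-year neighbour pairs.
#' @return An object of class `adjacency`: list with the sparse symmetric
#'   pattern matrix `M`, the `units` table, `threshold`, and a cache
#'   environment for spectral quantities.
#' @export
build_adjacency <- function(units, threshold = 350, block_by_year = TRUE) {
  stopifnot(is.data.frame(units), all(c("plot_id", "x", "y") %in% names(units)))
  if (!"year" %in% names(units)) units$year <- 0L
  if (any(!is.finite(units$x)) || any(!is.finite(units$y)))
    stop("coordinates must be finite", call. = FALSE)
  key <- paste(units$plot_id, units$year, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (plot, year) unit(s)", call. = FALSE)
  n <- nrow(units)
  ii <- integer(0); jj <- integer(0)
  blocks <- if (block_by_year) split(seq_len(n), units$year) else list(seq_len(n))
  for (idx in blocks) {
    if (length(idx) < 2L) next
    d2 <- distance2_within(units$x[idx], units$y[idx])
    hit <- which(d2 <= threshold^2, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    ii <- c(ii, idx[hit[, 1]])
    jj <- c(jj, idx[hit[, 2]])
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n), symmetric = TRUE)
  M <- methods::as(M, "CsparseMatrix")
  structure(list(M = M, units = units[, intersect(c("plot_id", "year", "x", "y"),
                                                  names(units))],
                 threshold = threshold, block_by_year = block_by_year,
                 cache = new.env(parent = emptyenv())),
            class = "adjacency")
}

distance2_within <- function(x, y) {
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  dx * dx + dy * dy
}

#' @export
print.adjacency <- function(x, ...) {
  cat("<adjacency> ", nrow(x$M), " units, ",
      Matrix::nnzero(x$M) / 2, " neighbour pairs, threshold ", x$threshold,
      " m", if (x$block_by_year) ", blocked by year", "\n", sep = "")
  invisible(x)
}

#' @export
dim.adjacency <- function(x) dim(x$M)

#' Restrict an adjacency to a subset of its units
#'
#' @param adj An `adjacency` object.
#' @param keep Logical or integer index into the unit rows.
#' @return A new `adjacency` over the retained units.
#' @export
subset_adjacency <- function(adj, keep) {
  stopifnot(inherits(adj, "adjacency"))
  structure(list(M = adj$M[keep, keep, drop = FALSE], units = adj$units[keep, , drop = FALSE],
                 threshold = adj$threshold, block_by_year = adj$block_by_year,
                 cache = new.env(parent = emptyenv())),
            class = "adjacency")
}

adjacency_matrix <- function(D) {
  if (inherits(D, "adjacency")) D$M else methods::as(D, "CsparseMatrix")
}

# Eigenvalues of the neighbourhood matrix, cached. Computed per year block;
# identical blocks (the usual case: the same plots revisited every year) are
# decomposed once.
adjacency_eigenvalues <- function(D) {
  if (inherits(D, "adjacency") && !is.null(D$cache$eigenvalues))
    return(D$cache$eigenvalues)
  M <- adjacency_matrix(D)
  n <- nrow(M)
  ev <- if (inherits(D, "adjacency") && D$block_by_year && n > 500L) {
    blocks <- split(seq_len(n), D$units$year)
    seen <- list()
    unlist(lapply(blocks, function(idx) {
      B <- M[idx, idx, drop = FALSE]
      for (s in seen) if (identical(dim(s$B), dim(B)) && identical(s$B, B))
        return(s$ev)
      e <- eigen(as.matrix(B), symmetric = TRUE, only.values = TRUE)$values
      seen[[length(seen) + 1L]] <<- list(B = B, ev = e)
      e
    }), use.names = FALSE)
  } else {
    eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  }
  if (inherits(D, "adjacency")) D$cache$eigenvalues <- ev
  ev
}

#' Valid range of the CAR dependence parameter
#'
#' The CAR covariance \eqn{\tau (I - \rho D)^{-1}} is positive definite iff
#' \eqn{\rho} lies strictly between the reciprocals of the extreme
#' eigenvalues of D. An edgeless D leaves \eqn{\rho} unconstrained (and
#' without effect): the full real line is returned.
#'
#' @param D An `adjacency` object or symmetric zero-diagonal binary matrix.
#' @return Numeric length-2 vector, the open interval for rho.
#' @export
rho_valid_range <- function(D) {
  M <- adjacency_matrix(D)
  if (!Matrix::isSymmetric(M)) stop("D must be symmetric", call. = FALSE)
  if (any(Matrix::diag(M) != 0)) stop("D must have a zero diagonal", call. = FALSE)
  if (Matrix::nnzero(M) == 0L) return(c(-Inf, Inf))
  ev <- adjacency_eigenvalues(D)
  c(1 / min(ev), 1 / max(ev))
}

car_precision <- function(D, tau, rho) {
  M <- adjacency_matrix(D)
  (Matrix::Diagonal(nrow(M)) - rho * M) / tau
}

check_car_params <- function(D, tau, rho) {
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive", call. = FALSE)
  r <- rho_valid_range(D)
  if (!is.finite(rho) || rho <= r[1] || rho >= r[2])
    stop(sprintf("`rho` = %g outside the positive-definite range (%g, %g)",
                 rho, r[1], r[2]), call. = FALSE)
  invisible(r)
}

#' CAR covariance matrix
#'
#' Dense inverse \eqn{\tau (I - \rho D)^{-1}} of the sparse precision;
#' intended for small problems and testing. The fitting and simulation code
#' works with the sparse precision throughout.
#'
#' @param tau Positive variance parameter.
#' @param rho Spatial dependence parameter, inside [rho_valid_range()].
#' @param D An `adjacency` object or neighbourhood matrix.
#' @return Dense symmetric positive-definite covariance matrix.
#' @export
car_covariance <- function(tau, rho, D) {
  check_car_params(D, tau, rho)
  S <- as.matrix(Matrix::solve(car_precision(D, tau, rho)))
  (S + t(S)) / 2
}

#' Draw spatially correlated CAR random effects
#'
#' One draw of \eqn{u \sim N(0, \tau (I - \rho D)^{-1})}, generated through a
#' Cholesky factorization of the sparse precision matrix.
#'
#' @inheritParams car_covariance
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return Numeric vector of length `nrow(D)`.
#' @export
sample_car_effects <- function(tau, rho, D, seed = NULL) {
  check_car_params(D, tau, rho)
  Q <- methods::as(Matrix::forceSymmetric(car_precision(D, tau, rho)), "CsparseMatrix")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  z <- stats::rnorm(nrow(Q))
  # Q = P' L L' P  =>  u = P' solve(L', z) has covariance Q^{-1}
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  L <- Matrix::expand(ch)$L
  P <- Matrix::expand(ch)$P
  as.numeric(Matrix::crossprod(P, Matrix::solve(Matrix::t(L), z)))
}

#' Export an adjacency as Matrix Market (coordinate pattern symmetric)
#'
#' @param adj An `adjacency` object.
#' @param path Output path (conventionally `.mtx`).
#' @return The path, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  P <- methods::as(methods::as(adj$M, "nMatrix"), "symmetricMatrix")
  Matrix::writeMM(P, path)
  invisible(path)
}

#' Read an adjacency pattern back from Matrix Market
#'
#' @param path Path written by [write_adjacency()].
#' @param units Optional unit table to reattach.
#' @param threshold Threshold metadata to record.
#' @return An `adjacency` object.
#' @export
read_adjacency <- function(path, units = NULL, threshold = NA_real_) {
  M <- Matrix::readMM(path)
  M <- methods::as(Matrix::forceSymmetric(methods::as(M, "dMatrix")), "CsparseMatrix")
  if (is.null(units))
    units <- data.frame(plot_id = sprintf("u%05d", seq_len(nrow(M))),
                        year = 0L, x = NA_real_, y = NA_real_)
  structure(list(M = M, units = units, threshold = threshold,
                 block_by_year = NA, cache = new.env(parent = emptyenv())),
            class = "adjacency")
}
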