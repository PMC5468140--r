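#' Generate a local point-transect grid
#'
#' Plots are laid on parallel transects covering the square
#' \code{[center - half_extent, center + half_extent]} in both coordinates.
#' Transects run along the y-axis (lines of constant x) starting at the west
#' edge; plots are placed along each transect starting at the south edge.
#' With the defaults (300 m between transects, 100 m between plots) this is
#' the layout used on the wind-farm mountains.
#'
#' @param center_x,center_y Grid centre, planar metres.
#' @param half_extent Half side-length of the covered square, metres.
#' @param transect_spacing Distance between transects, metres.
#' @param plot_spacing Distance between plots along a transect, metres.
#' @param site Site label stored with the plots.
#' @param prefix Prefix for plot ids.
#' @return Data frame of plots: `plot_id`, `x`, `y`, `scale`, `site`.
#' @export
generate_local_grid <- function(center_x = 0, center_y = 0, half_extent = 1400,
                                transect_spacing = 300, plot_spacing = 100,
                                site = "local", prefix = site) {
  if (!is.finite(half_extent) || half_extent < 0)
    stop("`half_extent` must be non-negative and finite", call. = FALSE)
  if (transect_spacing <= 0 || plot_spacing <= 0)
    stop("spacings must be positive", call. = FALSE)
  xs <- center_x - half_extent + transect_spacing * seq(0, floor(2 * half_extent / transect_spacing))
  ys <- center_y - half_extent + plot_spacing * seq(0, floor(2 * half_extent / plot_spacing))
  g <- expand.grid(y = ys, x = xs)  # y fastest: plots ordered along each transect
  data.frame(plot_id = sprintf("%s_%04d", prefix, seq_len(nrow(g))),
             x = g$x, y = g$y, scale = "local", site = site,
             stringsAsFactors = FALSE)
}

# Plot coordinates along the perimeter of an axis-aligned square,
# anti-clockwise from the south-west corner; corners counted once.
square_perimeter_plots <- function(cx, cy, side, spacing) {
  k <- side / spacing
  t <- spacing * seq(0, 4 * k - 1)
  x <- numeric(length(t)); y <- numeric(length(t))
  seg <- pmin(floor(t / side), 3)
  s <- t - seg * side
  x[seg == 0] <- s[seg == 0];        y[seg == 0] <- 0
  x[seg == 1] <- side;               y[seg == 1] <- s[seg == 1]
  x[seg == 2] <- side - s[seg == 2]; y[seg == 2] <- side
  x[seg == 3] <- 0;                  y[seg == 3] <- side - s[seg == 3]
  cbind(x = cx - side / 2 + x, y = cy - side / 2 + y)
}

#' Generate regional survey squares with perimeter plots
#'
#' Square centres are placed by rejection sampling, uniformly within a disc,
#' subject to the nearest plots of any two squares being at least
#' `min_separation` apart. Each 1 x 1 km square carries 20 plots every 200 m
#' along its perimeter under the defaults.
#'
#' @param n_squares Number of squares.
#' @param side Square side, metres; must be divisible by `perimeter_spacing`.
#' @param perimeter_spacing Plot spacing along the perimeter, metres.
#' @param min_separation Minimum distance between plots of different squares.
#' @param region_radius Radius of the disc holding the square centres.
#' @param center_x,center_y Disc centre.
#' @param seed Integer seed; placement is reproducible.
#' @param max_attempts Rejection-sampling attempts allowed per square before
#'   a placement-failure error.
#' @return Data frame of plots: `plot_id`, `x`, `y`, `scale`, `site`, `square`.
#' @export
generate_regional_squares <- function(n_squares = 29, side = 1000,
                                      perimeter_spacing = 200,
                                      min_separation = 1400,
                                      region_radius = 15000,
                                      center_x = 0, center_y = 0,
                                      seed = 1, max_attempts = 10000) {
  if (side <= 0 || perimeter_spacing <= 0 || side %% perimeter_spacing != 0)
    stop("`side` must be a positive multiple of `perimeter_spacing`", call. = FALSE)
  if (min_separation < 0) stop("`min_separation` must be >= 0", call. = FALSE)
  per_square <- as.integer(4 * side / perimeter_spacing)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  placed <- vector("list", n_squares)
  all_xy <- NULL
  for (s in seq_len(n_squares)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      r <- region_radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      xy <- square_perimeter_plots(center_x + r * cos(th), center_y + r * sin(th),
                                   side, perimeter_spacing)
      if (is.null(all_xy) || min_plot_distance(xy, all_xy) >= min_separation) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("placement failure: could not place square ", s, " of ", n_squares,
           " within ", max_attempts, " attempts", call. = FALSE)
    placed[[s]] <- xy
    all_xy <- rbind(all_xy, xy)
  }
  out <- do.call(rbind, lapply(seq_len(n_squares), function(s) {
    data.frame(plot_id = sprintf("region_%02d_%02d", s, seq_len(per_square)),
               x = placed[[s]][, 1], y = placed[[s]][, 2],
               scale = "regional", site = "region", square = s,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

min_plot_distance <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(min(dx * dx + dy * dy))
}

#' Square-root distance covariate
#'
#' Distances enter the habitat model as the square root of the distance
#' measured in units of 100 m, damping the influence of far-away features.
#'
#' @param distance Distance in metres, non-negative.
#' @return `sqrt(distance / 100)`, dimensionless.
#' @export
sqrt_distance_covariate <- function(distance) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("`distance` must be non-negative and finite", call. = FALSE)
  sqrt(distance / 100)
}

#' Variance inflation factors with a removal threshold
#'
#' VIF of column j is \eqn{1/(1-R^2_j)} from the least-squares regression of
#' that column on all the others; exactly collinear columns are reported as
#' infinite. Columns at or above the threshold are flagged for removal.
#'
#' @param X Numeric matrix (or data frame) of covariate columns; at least two
#'   columns and more rows than columns.
#' @param threshold Removal threshold (default 3.0).
#' @return Data frame with `column`, `vif`, `remove`.
#' @export
compute_vif <- function(X, threshold = 3.0) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least two columns", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("need more rows than columns", call. = FALSE)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(X)))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) return(Inf)  # constant column: perfectly predicted by intercept
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(column = nm, vif = vif, remove = vif >= threshold,
             stringsAsFactors = FALSE)
}

#' Map raw landcover classes to the five analysis vegetation classes
#'
#' @param raw_class Character vector of raw landcover class labels.
#' @param mapping Named character vector or two-column data frame
#'   (`raw`, `merged`) mapping every raw class to one of
#'   forest, clear_cut, young_forest, mire, other.
#' @return Character vector of merged classes.
#' @export
apply_class_merge <- function(raw_class, mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("raw", "merged") %in% names(mapping)))
    mapping <- stats::setNames(as.character(mapping$merged), as.character(mapping$raw))
  }
  allowed <- vegetation_classes()
  bad <- setdiff(unique(unname(mapping)), allowed)
  if (length(bad))
    stop("configuration error: mapping targets outside the five classes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  miss <- setdiff(unique(as.character(raw_class)), names(mapping))
  if (length(miss))
    stop("unmapped raw class(es): ", paste(miss, collapse = ", "), call. = FALSE)
  unname(mapping[as.character(raw_class)])
}

#' The five merged vegetation classes
#' @return Character vector, reference class (mire) not first.
#' @export
vegetation_classes <- function() c("mire", "forest", "clear_cut", "young_forest", "other")

#' Read / write plot tables
#'
#' Plots travel as CSV with header `plot_id,x,y,scale,site` (plus any extra
#' columns such as `square`).
#'
#' @param plots Data frame of plots.
#' @param path File path.
#' @return `read_plots` returns the data frame; `write_plots` its path,
#'   invisibly.
#' @export
write_plots <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plots
#' @export
read_plots <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "x", "y", "scale", "site")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("plot file missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  p
}
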