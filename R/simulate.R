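#' Published final-model estimates from the Malaa wind-farm pellet study
#'
#' Coefficients, standard errors and dispersion components of the fitted
#' final presence/absence models for the four analysis data sets (combined,
#' region, Storliden, Jokkmokksliden). The combined column doubles as the
#' default generating truth of the survey simulator. Distance is the square
#' root of distance in 100 m; precipitation is in 1e-1 m; mire and
#' preconstruction are the reference categories.
#'
#' @param dataset One of `"combined"`, `"region"`, `"storliden"`,
#'   `"jokkmokksliden"`.
#' @return List with `beta` (named vector), `se` (named vector), `phi`,
#'   `tau`, `rho`, `n_obs`.
#' @export
mala_estimates <- function(dataset = c("combined", "region", "storliden",
                                       "jokkmokksliden")) {
  dataset <- match.arg(dataset)
  nm <- c("(Intercept)", "sqrt_dist",
          "phaseconstruction", "phaseoperation",
          "vegetationclear_cut", "vegetationforest", "vegetationyoung_forest",
          "precip",
          "sqrt_dist:phaseconstruction", "sqrt_dist:phaseoperation")
  tab <- list(
    combined = list(
      beta = c(-1.01, 0.05, -0.16, -2.23, 1.65, 0.38, 0.18, -3.45, -0.05, 0.09),
      se   = c(0.29, 0.02, 0.14, 0.16, 0.16, 0.13, 0.13, 0.31, 0.03, 0.03),
      phi = 0.33, tau = 1.96, rho = 0.05, n_obs = 7175),
    region = list(
      beta = c(-1.15, 0.01, -1.12, -2.68, 1.58, 0.49, 0.29, -4.82, -0.05, 0.11),
      se   = c(0.67, 0.07, 0.33, 0.36, 0.46, 0.31, 0.36, 0.45, 0.05, 0.05),
      phi = 0.28, tau = 5.83, rho = 0.22, n_obs = 2991),
    storliden = list(
      beta = c(-3.01, 0.48, -0.28, -0.74, 0.85, 0.08, -0.22, -1.43, -0.27, -0.60),
      se   = c(0.67, 0.27, 0.47, 0.53, 0.62, 0.56, 0.55, 0.56, 0.16, 0.19),
      phi = 0.33, tau = 2.77, rho = 0.08, n_obs = 1948),
    jokkmokksliden = list(
      beta = c(-0.51, 0.00, 1.25, -2.21, 0.09, -1.34, -1.35, -5.69, -0.26, 0.14),
      se   = c(1.48, 0.43, 0.51, 0.62, 1.10, 0.79, 0.77, 0.56, 0.21, 0.25),
      phi = 0.16, tau = 5.78, rho = 0.08, n_obs = 2190)
  )[[dataset]]
  list(beta = stats::setNames(tab$beta, nm), se = stats::setNames(tab$se, nm),
       phi = tab$phi, tau = tab$tau, rho = tab$rho, n_obs = tab$n_obs)
}

#' Parameters of the survey simulator
#'
#' Defaults reproduce the statistical structure of the Malaa study: the
#' combined-data final-model coefficients as generating truth (`tau` 1.96,
#' `rho` 0.05), landcover proportions of the study area (forest 34.7%,
#' clear cuts 9.9%, young forest 20.3%, mires 27.1%, other 7.9%), yearly
#' May--October precipitation drawn uniformly from the observed 47--93 mm
#' range, survey years 2009--2015 with the 2009 plot-establishment year
#' flagged excluded, and a 2% chance that an occupied plot holds two pellet
#' groups (counts above one were at most ~2% of plots in the study).
#'
#' @param beta Named coefficient vector on design-matrix columns; names must
#'   match columns built by [build_model_frame()]. Columns without a named
#'   coefficient get 0 (the `other` vegetation class has no published
#'   estimate and sits at the reference level's 0 by default).
#' @param tau,rho CAR dispersion parameters of the generating model.
#' @param vegetation_proportions Named proportions over the five classes,
#'   summing to 1 (the published study-area percentages total 99.9 from
#'   rounding, so the defaults are rescaled by 1/0.999).
#' @param precipitation_range Yearly precipitation range in mm.
#' @param years Survey years to simulate.
#' @param phase_map Year-to-phase mapping.
#' @param p_multi_group Probability an occupied plot holds two groups.
#' @param seed Integer seed.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(beta = mala_estimates("combined")$beta,
                             tau = mala_estimates("combined")$tau,
                             rho = mala_estimates("combined")$rho,
                             vegetation_proportions = c(
                               mire = 0.271, forest = 0.347, clear_cut = 0.099,
                               young_forest = 0.203, other = 0.079) / 0.999,
                             precipitation_range = c(47, 93),
                             years = 2009:2015,
                             phase_map = default_phase_map(),
                             p_multi_group = 0.02,
                             seed = 1L) {
  if (abs(sum(vegetation_proportions) - 1) > 1e-9)
    stop("vegetation proportions must sum to 1", call. = FALSE)
  if (!setequal(names(vegetation_proportions), vegetation_classes()))
    stop("vegetation proportions must cover exactly the five classes", call. = FALSE)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (p_multi_group < 0 || p_multi_group > 1)
    stop("`p_multi_group` must be a probability", call. = FALSE)
  structure(list(beta = beta, tau = tau, rho = rho,
                 vegetation_proportions = vegetation_proportions,
                 precipitation_range = precipitation_range,
                 years = years, phase_map = phase_map,
                 p_multi_group = p_multi_group, seed = as.integer(seed)),
            class = "generator_params")
}

#' Default turbine layout for the emulated study
#'
#' Two clusters: ten turbines on the Jokkmokksliden grid centre and eight on
#' the Storliden grid centre, in rows at 400 m spacing.
#'
#' @param centers Two-row matrix or data frame of cluster centres (x, y).
#' @param n_turbines Turbines per cluster.
#' @param spacing Along-row turbine spacing, metres.
#' @return Data frame with `x`, `y`, `cluster`.
#' @export
default_turbines <- function(centers = rbind(storliden = c(-2000, 0),
                                             jokkmokksliden = c(2000, 0)),
                             n_turbines = c(8, 10), spacing = 400) {
  out <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    n <- n_turbines[k]
    off <- spacing * (seq_len(n) - (n + 1) / 2)
    data.frame(x = as.numeric(centers[k, 1]) + off,
               y = rep(as.numeric(centers[k, 2]), n),
               cluster = rep(rownames(centers)[k] %||% as.character(k), n))
  }))
  rownames(out) <- NULL
  out
}

#' The emulated Malaa survey design
#'
#' Two local point-transect grids (300 m between transects, 100 m between
#' plots, covering ~2.8 km squares on the two wind-farm mountains) and 29
#' regional 1 x 1 km squares with 20 perimeter plots each, placed in a
#' 15 km disc with nearest plots of different squares at least 1.4 km
#' apart; about 1,160 plots per survey year.
#'
#' @param seed Seed for the random square placement.
#' @param n_squares Number of regional squares.
#' @param half_extent Half-extent of each local grid, metres.
#' @param turbines Turbine coordinates; see [default_turbines()].
#' @return List of class `survey_design`: `plots`, `turbines`.
#' @export
mala_design <- function(seed = 1L, n_squares = 29, half_extent = 1400,
                        turbines = default_turbines()) {
  sto <- generate_local_grid(-2000, 0, half_extent, site = "Storliden",
                             prefix = "sto")
  jok <- generate_local_grid(2000, 0, half_extent, site = "Jokkmokksliden",
                             prefix = "jok")
  reg <- generate_regional_squares(n_squares = n_squares, seed = seed)
  plots <- rbind(sto, jok, reg[, names(sto)])
  structure(list(plots = plots, turbines = turbines), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design> ", nrow(x$plots), " plots (",
      sum(x$plots$scale == "local"), " local, ",
      sum(x$plots$scale == "regional"), " regional), ",
      nrow(x$turbines), " turbines\n", sep = "")
  invisible(x)
}

min_distance_to <- function(x, y, pts) {
  d2 <- outer(x, pts[, 1], "-")^2 + outer(y, pts[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Simulate a pellet-group survey from the presence/absence model
#'
#' For every plot-year unit the linear predictor combines the named
#' generating coefficients with the plot's covariates (vegetation fixed per
#' plot, distance to the nearest turbine, yearly precipitation shared by all
#' plots) plus one CAR random-effect draw per year block; presence is
#' Bernoulli on the logit scale, and occupied plots carry one pellet group,
#' or two with probability `p_multi_group`. Everything is reproducible from
#' `params$seed`.
#'
#' @param design A `survey_design` (plots + turbines); see [mala_design()].
#' @param params A `generator_params` object.
#' @param adjacency Optional precomputed adjacency over the design's
#'   plot-year units (passed to avoid rebuilding it across replicates).
#' @return List of class `survey_sim`: `records` (plot_id, year, groups,
#'   presence), `covariates`, `adjacency`, `u`, `params`.
#' @export
simulate_survey <- function(design, params = generator_params(),
                            adjacency = NULL) {
  stopifnot(inherits(design, "survey_design"))
  plots <- design$plots
  if (!nrow(plots)) stop("design has no plots", call. = FALSE)
  years <- params$years
  old <- local_seed(params$seed)
  on.exit(restore_seed(old), add = TRUE)

  veg <- sample(names(params$vegetation_proportions), nrow(plots),
                replace = TRUE, prob = params$vegetation_proportions)
  precip_mm <- stats::runif(length(years), params$precipitation_range[1],
                            params$precipitation_range[2])
  dist_turbine <- min_distance_to(plots$x, plots$y, as.matrix(design$turbines[, c("x", "y")]))

  units <- do.call(rbind, lapply(seq_along(years), function(k) {
    data.frame(plot_id = plots$plot_id, year = years[k], x = plots$x, y = plots$y,
               stringsAsFactors = FALSE)
  }))
  covariates <- do.call(rbind, lapply(seq_along(years), function(k) {
    data.frame(plot_id = plots$plot_id, year = years[k],
               vegetation = veg, dist_turbine = dist_turbine,
               precipitation_mm = precip_mm[k],
               scale = plots$scale, site = plots$site,
               stringsAsFactors = FALSE)
  }))

  if (is.null(adjacency)) adjacency <- build_adjacency(units)
  u_seed <- sample.int(.Machine$integer.max, 1)
  u <- sample_car_effects(params$tau, params$rho, adjacency, seed = u_seed)

  # Design matrix via the same frame builder used for fitting, so coefficient
  # names always line up; phases are attached over all years including any
  # excluded ones (presence is generated there too, the analysis drops them).
  pm <- params$phase_map
  gen_pm <- pm
  gen_pm[gen_pm == "excluded"] <- "preconstruction"
  shell <- data.frame(plot_id = units$plot_id, year = units$year,
                      groups = 0L, stringsAsFactors = FALSE)
  fr <- suppressMessages(build_model_frame(shell, covariates,
                                           phase_map = gen_pm))
  bad <- setdiff(names(params$beta), colnames(fr$X))
  if (length(bad))
    stop("configuration error: coefficient(s) without a design column: ",
         paste(bad, collapse = ", "), call. = FALSE)
  b <- stats::setNames(numeric(ncol(fr$X)), colnames(fr$X))
  b[names(params$beta)] <- params$beta
  eta <- as.numeric(fr$X %*% b) + u
  presence <- stats::rbinom(length(eta), 1, stats::plogis(eta))
  groups <- presence * (1L + stats::rbinom(length(eta), 1, params$p_multi_group))

  records <- data.frame(plot_id = units$plot_id, year = units$year,
                        groups = groups, presence = presence,
                        stringsAsFactors = FALSE)
  structure(list(records = records, covariates = covariates,
                 adjacency = adjacency, u = u, params = params,
                 eta = eta),
            class = "survey_sim")
}

#' @export
print.survey_sim <- function(x, ...) {
  cat("<survey_sim> ", nrow(x$records), " plot-year records over ",
      length(unique(x$records$year)), " years; presence fraction ",
      round(mean(x$records$presence), 3), "\n", sep = "")
  invisible(x)
}
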