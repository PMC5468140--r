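#' Assemble the model frame for the presence/absence habitat model
#'
#' Joins survey records to plot-year covariates, assigns development phases,
#' drops excluded years and rows with missing covariates (with a message),
#' derives the transformed covariates (square-root distance in 100 m units,
#' precipitation in 1e-1 m), and builds the fixed-effect design matrix with
#' mire and preconstruction as reference categories.
#'
#' @param records Data frame: `plot_id`, `year`, `groups` (and/or `presence`).
#' @param covariates Data frame keyed by `plot_id` (+ `year` if time-varying)
#'   with `vegetation`, `dist_turbine` (metres), `precipitation_mm`, and any
#'   further numeric covariates named in `terms`.
#' @param terms Character vector of model terms; interactions as `"a:b"`.
#' @param phase_map Year-to-phase mapping; see [default_phase_map()].
#' @param phase_coding `"phase"` for the three development phases;
#'   `"yearwise"` replaces the phase factor by {2010, 2011, 2012, operation}
#'   for the sensitivity refit.
#' @return A `model_frame` list: `y`, `X`, `data`, `units`, `terms`,
#'   `assign`, `n_dropped`.
#' @export
build_model_frame <- function(records, covariates,
                              terms = default_model_terms(),
                              phase_map = default_phase_map(),
                              phase_coding = c("phase", "yearwise")) {
  phase_coding <- match.arg(phase_coding)
  stopifnot(is.data.frame(records), is.data.frame(covariates))
  by <- intersect(c("plot_id", "year"), names(covariates))
  records$.row_order <- seq_len(nrow(records))
  d <- merge(records, covariates, by = by, sort = FALSE)
  d <- d[order(d$.row_order), , drop = FALSE]  # merge() does not keep order
  d$.row_order <- NULL
  if (nrow(d) != nrow(records))
    stop("records and covariates do not match one-to-one on ",
         paste(by, collapse = " + "), call. = FALSE)
  d$phase <- phase_of_year(d$year, phase_map)
  n_excluded <- sum(d$phase == "excluded")
  if (n_excluded > 0) {
    message("dropping ", n_excluded, " record(s) from excluded year(s)")
    d <- d[d$phase != "excluded", , drop = FALSE]
  }
  if (!nrow(d)) stop("no records left after excluding years", call. = FALSE)
  if (!"presence" %in% names(d)) d$presence <- presence_indicator(d$groups)
  if ("dist_turbine" %in% names(d)) d$sqrt_dist <- sqrt_distance_covariate(d$dist_turbine)
  if ("precipitation_mm" %in% names(d)) d$precip <- d$precipitation_mm / 100
  if ("vegetation" %in% names(d))
    d$vegetation <- factor(d$vegetation, levels = vegetation_classes())
  if (phase_coding == "yearwise") {
    d$phase <- ifelse(d$phase == "operation", "operation", as.character(d$year))
    d$phase <- factor(d$phase, levels = c("2010", "2011", "2012", "operation"))
  } else {
    d$phase <- factor(d$phase, levels = c("preconstruction", "construction", "operation"))
  }
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(d))
  if (length(miss))
    stop("term variable(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(d[, vars, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " record(s) with missing covariates")
    d <- d[keep, , drop = FALSE]
  }
  X <- stats::model.matrix(stats::reformulate(terms), data = d)
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(stats::reformulate(terms)), "term.labels")
  structure(list(y = as.numeric(d$presence), X = X, data = d,
                 units = d[, c("plot_id", "year")],
                 terms = term_labels,
                 assign = assign,
                 references = c(vegetation = "mire",
                                phase = levels(d$phase)[1]),
                 n_dropped = n_dropped, n_excluded = n_excluded),
            class = "model_frame")
}

#' Default fixed-effect terms of the habitat-use model
#' @return Character vector of term labels.
#' @export
default_model_terms <- function() {
  c("sqrt_dist", "vegetation", "phase", "precip", "sqrt_dist:phase")
}

#' @export
print.model_frame <- function(x, ...) {
  cat("<model_frame> ", length(x$y), " units, ", ncol(x$X), " design columns; terms: ",
      paste(x$terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Align an adjacency with the rows of a model frame
#'
#' Subsets a master adjacency so its units match the frame rows one-to-one,
#' in frame order (needed after rows were dropped for missing data or
#' excluded years).
#'
#' @param adj An `adjacency` built over at least the frame's units.
#' @param frame A `model_frame`.
#' @return An `adjacency` whose i-th unit is the frame's i-th row.
#' @export
align_adjacency <- function(adj, frame) {
  stopifnot(inherits(adj, "adjacency"), inherits(frame, "model_frame"))
  akey <- paste(adj$units$plot_id, adj$units$year, sep = "\r")
  fkey <- paste(frame$units$plot_id, frame$units$year, sep = "\r")
  idx <- match(fkey, akey)
  if (anyNA(idx))
    stop("adjacency is missing ", sum(is.na(idx)), " frame unit(s)", call. = FALSE)
  subset_adjacency(adj, idx)
}
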