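#' Convert a raw pellet count to a pellet-group count
#'
#' Field rule for evenly scattered pellets: a cluster of fewer than 20 pellets
#' is no group; 20--146 pellets count as one group, 147--273 as two, and so on,
#' the bin width being the 127-pellet mean size of a reindeer pellet group.
#'
#' @param n_pellets Non-negative integer vector of raw pellet counts.
#' @return Integer vector of pellet-group counts.
#' @examples
#' pellets_to_groups(c(0, 19, 20, 146, 147, 274))
#' @export
pellets_to_groups <- function(n_pellets) {
  if (any(!is.finite(n_pellets)) || any(n_pellets < 0))
    stop("`n_pellets` must be non-negative and finite", call. = FALSE)
  n <- as.integer(round(n_pellets))
  ifelse(n < 20L, 0L, 1L + (n - 20L) %/% 127L)
}

#' Presence indicator from a group count
#'
#' @param groups Non-negative integer vector of pellet-group counts.
#' @return Binary vector: 1 where at least one group was counted.
#' @export
presence_indicator <- function(groups) {
  if (any(!is.finite(groups)) || any(groups < 0))
    stop("`groups` must be non-negative and finite", call. = FALSE)
  as.integer(groups >= 1)
}

#' Default year-to-phase mapping for the Malaa surveys
#'
#' The 2009 plot-establishment inventory is excluded from analysis; 2010 is
#' treated as preconstruction, 2011 and 2012 as construction (the 2012 count
#' overlaps the first month of operation), and 2013--2015 as operation.
#'
#' @return Named character vector mapping year to phase, of class
#'   \code{phase_map}.
#' @export
default_phase_map <- function() {
  pm <- c("2009" = "excluded",
          "2010" = "preconstruction",
          "2011" = "construction",
          "2012" = "construction",
          "2013" = "operation",
          "2014" = "operation",
          "2015" = "operation")
  class(pm) <- c("phase_map", "character")
  pm
}

#' Look up the development phase of a survey year
#'
#' @param year Integer vector of calendar years.
#' @param phase_map Named vector year -> phase; see [default_phase_map()].
#' @return Character vector of phases (one of excluded, preconstruction,
#'   construction, operation).
#' @export
phase_of_year <- function(year, phase_map = default_phase_map()) {
  key <- as.character(year)
  miss <- setdiff(unique(key), names(phase_map))
  if (length(miss))
    stop("year(s) not in phase map: ", paste(miss, collapse = ", "), call. = FALSE)
  ph <- unname(phase_map[key])
  bad <- setdiff(unique(ph), c("excluded", "preconstruction", "construction", "operation"))
  if (length(bad))
    stop("invalid phase label(s) in map: ", paste(bad, collapse = ", "), call. = FALSE)
  ph
}

#' Phase-to-phase difference in mean pellet groups per plot
#'
#' Plot-level group counts are pooled within each phase; the difference in
#' means (phase a minus phase b) is returned with the independent two-sample
#' standard error \eqn{\sqrt{s_a^2/n_a + s_b^2/n_b}}. Records from excluded
#' years are dropped.
#'
#' @param records Data frame with columns `year` and `groups`.
#' @param phase_map Named vector year -> phase.
#' @param phase_a,phase_b Phase labels to compare.
#' @return List with `difference`, `se`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
phase_mean_difference <- function(records, phase_map = default_phase_map(),
                                  phase_a = "preconstruction",
                                  phase_b = "construction") {
  stopifnot(is.data.frame(records), all(c("year", "groups") %in% names(records)))
  ph <- phase_of_year(records$year, phase_map)
  ga <- records$groups[ph == phase_a]
  gb <- records$groups[ph == phase_b]
  if (length(ga) < 2L || length(gb) < 2L)
    stop("insufficient data: each phase needs at least 2 plot observations",
         call. = FALSE)
  list(difference = mean(ga) - mean(gb),
       se = sqrt(stats::var(ga) / length(ga) + stats::var(gb) / length(gb)),
       mean_a = mean(ga), mean_b = mean(gb),
       n_a = length(ga), n_b = length(gb))
}

#' Percent reduction in mean pellet groups per plot
#'
#' @param mean_pre Mean groups per plot in the earlier phase (must be > 0).
#' @param mean_post Mean groups per plot in the later phase.
#' @param digits Rounding for reporting; 0 gives the nearest integer percent.
#' @return Percent reduction, `100 * (1 - mean_post / mean_pre)`.
#' @export
percent_reduction <- function(mean_pre, mean_post, digits = 0) {
  if (!is.finite(mean_pre) || mean_pre <= 0)
    stop("undefined reduction: `mean_pre` must be positive", call. = FALSE)
  round(100 * (1 - mean_post / mean_pre), digits)
}

#' Validate survey records against the counting rules
#'
#' Checks that `groups` is a non-negative integer, that `presence` (if
#' present) equals `groups >= 1`, and that `groups` is consistent with
#' [pellets_to_groups()] wherever a raw `pellets` count was recorded.
#'
#' @param records Data frame with columns `plot_id`, `year`, `groups` and
#'   optionally `pellets` and `presence`.
#' @return Invisibly, a data frame of rule violations (zero rows when clean).
#' @export
validate_survey <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("plot_id", "year", "groups")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  probs <- list()
  bad <- which(!is.finite(records$groups) | records$groups < 0 |
                 records$groups != round(records$groups))
  if (length(bad))
    probs$groups <- data.frame(row = bad, rule = "groups must be a non-negative integer")
  if ("presence" %in% names(records)) {
    bad <- which(records$presence != as.integer(records$groups >= 1))
    if (length(bad))
      probs$presence <- data.frame(row = bad, rule = "presence must equal (groups >= 1)")
  }
  if ("pellets" %in% names(records)) {
    have <- which(!is.na(records$pellets))
    bad <- have[pellets_to_groups(records$pellets[have]) != records$groups[have]]
    if (length(bad))
      probs$pellets <- data.frame(row = bad, rule = "groups inconsistent with pellet binning rule")
  }
  out <- if (length(probs)) do.call(rbind, unname(probs)) else
    data.frame(row = integer(), rule = character())
  rownames(out) <- NULL
  if (nrow(out)) message(nrow(out), " survey rule violation(s) found")
  invisible(out)
}
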