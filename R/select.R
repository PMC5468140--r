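#' Construct a model specification for backward elimination
#'
#' @param terms Ordered character vector of term labels; interactions as
#'   `"a:b"` with both parents listed.
#' @param forced Terms that are never dropped (the intercept is always
#'   forced implicitly).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(terms = default_model_terms(), forced = character()) {
  if (anyDuplicated(terms)) stop("duplicate terms", call. = FALSE)
  ints <- terms[grepl(":", terms, fixed = TRUE)]
  for (tm in ints) {
    parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parents, terms)
    if (length(miss))
      stop("interaction ", tm, " lacks parent main effect(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(setdiff(forced, terms)))
    stop("forced terms must be among the terms", call. = FALSE)
  structure(list(terms = terms, forced = forced), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", paste(x$terms, collapse = " + "),
      if (length(x$forced)) paste0("  [forced: ", paste(x$forced, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

term_is_interaction <- function(term) grepl(":", term, fixed = TRUE)

term_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# Columns of the design matrix belonging to each term label.
term_columns <- function(fit) {
  labs <- fit$terms
  asg <- fit$assign
  cols <- names(fit$beta)
  out <- lapply(seq_along(labs), function(k) cols[asg == k])
  names(out) <- labs
  out
}

# Term-level p-value: max single-coefficient Wald p over the term's columns
# (default), or a joint Wald chi-square.
term_p_value <- function(fit, term, test = c("max_coef", "joint")) {
  test <- match.arg(test)
  cols <- term_columns(fit)[[term]]
  if (is.null(cols) || !length(cols))
    stop("term not in fit: ", term, call. = FALSE)
  if (test == "joint" && length(cols) > 1L) {
    wald_joint_test(fit, cols)$p
  } else {
    max(vapply(cols, function(cc) wald_test(fit, cc)$p, numeric(1)))
  }
}

#' Backward elimination respecting model hierarchy
#'
#' Iteratively refits the model, dropping the single least-significant
#' droppable term whose p-value exceeds `alpha`. A main effect is droppable
#' only once no retained interaction involves it. Ties on p are broken
#' deterministically: interactions are dropped before main effects, and on
#' equal p the later-listed term goes first. For a multi-level factor the
#' term p-value is the maximum Wald p across its non-reference levels (or a
#' joint chi-square with `test = "joint"`).
#'
#' @param spec A `model_spec` with the initial terms.
#' @param frame_builder Function taking a character vector of terms and
#'   returning a `model_frame`.
#' @param D Adjacency over the frame rows (constant across refits).
#' @param alpha Retention level; terms with p > alpha are candidates.
#' @param test Term-level test, `"max_coef"` or `"joint"`.
#' @param options Fitter options.
#' @param random_year Passed to the fitter.
#' @return List: final `spec`, `fit` (final model), and `trail`, a data
#'   frame of (step, term, p, action).
#' @export
backward_eliminate <- function(spec, frame_builder, D, alpha = 0.10,
                               test = c("max_coef", "joint"),
                               options = hglm_options(),
                               random_year = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  test <- match.arg(test)
  terms <- spec$terms
  trail <- data.frame(step = integer(), term = character(), p = numeric(),
                      action = character(), stringsAsFactors = FALSE)
  step <- 0L
  fit <- NULL
  repeat {
    step <- step + 1L
    frame <- frame_builder(terms)
    Da <- if (inherits(D, "adjacency") && nrow(D$M) != length(frame$y))
      align_adjacency(D, frame) else D
    fit <- tryCatch(fit_spatial_binomial_hglm(frame, Da, options = options,
                                              random_year = random_year),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fit failed at step ", step, ": ", conditionMessage(fit),
              "; returning trail so far", call. = FALSE)
      return(list(spec = model_spec(terms, spec$forced), fit = NULL,
                  trail = trail, aborted = TRUE))
    }
    retained_ints <- terms[term_is_interaction(terms)]
    droppable <- vapply(terms, function(tm) {
      if (tm %in% spec$forced) return(FALSE)
      if (!term_is_interaction(tm) &&
          any(vapply(retained_ints, function(ii) tm %in% term_parents(ii),
                     logical(1)))) return(FALSE)
      TRUE
    }, logical(1))
    if (!any(droppable)) break
    cand <- terms[droppable]
    p <- vapply(cand, function(tm) term_p_value(fit, tm, test), numeric(1))
    over <- p > alpha
    if (!any(over)) break
    # deterministic choice: highest p; ties -> interactions first, then the
    # later-listed term
    cand <- cand[over]; p <- p[over]
    key <- order(-p, !term_is_interaction(cand), -match(cand, terms))
    drop_term <- cand[key[1]]
    trail <- rbind(trail, data.frame(step = step, term = drop_term,
                                     p = unname(p[cand == drop_term][1]),
                                     action = "drop", stringsAsFactors = FALSE))
    terms <- setdiff(terms, drop_term)
    if (!length(terms)) break
  }
  list(spec = model_spec(terms, spec$forced), fit = fit, trail = trail,
       aborted = FALSE)
}

#' Sensitivity refits of the final model
#'
#' Variant `"yearwise_phases"` replaces the three-phase factor by
#' {2010, 2011, 2012, operation}, testing the stability of the phase
#' contrasts against the overlapping phase definitions; `"random_year"`
#' adds an exchangeable year-level random intercept (with a warning that a
#' handful of year levels gives an unstable variance component).
#'
#' @param final_spec `model_spec` from [backward_eliminate()].
#' @param frame_builder Function(terms, phase_coding) returning a
#'   `model_frame`.
#' @param D Adjacency over the frame rows.
#' @param variant `"yearwise_phases"` or `"random_year"`.
#' @param options Fitter options.
#' @return A `car_hglm` fit.
#' @export
sensitivity_refit <- function(final_spec, frame_builder, D,
                              variant = c("yearwise_phases", "random_year"),
                              options = hglm_options()) {
  stopifnot(inherits(final_spec, "model_spec"))
  variant <- match.arg(variant)
  if (variant == "yearwise_phases") {
    frame <- frame_builder(final_spec$terms, phase_coding = "yearwise")
    Da <- if (inherits(D, "adjacency") && nrow(D$M) != length(frame$y))
      align_adjacency(D, frame) else D
    fit_spatial_binomial_hglm(frame, Da, options = options)
  } else {
    frame <- frame_builder(final_spec$terms, phase_coding = "phase")
    Da <- if (inherits(D, "adjacency") && nrow(D$M) != length(frame$y))
      align_adjacency(D, frame) else D
    fit_spatial_binomial_hglm(frame, Da, options = options, random_year = TRUE)
  }
}
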