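#' Aligned coefficient table across fitted models
#'
#' Builds a publication-style table with one row per coefficient and one
#' estimate/SE/significance column block per fit, aligned so that every
#' term retained in at least one model appears in all columns (blank where
#' a model does not carry the term). Reference categories are rendered as
#' an estimate of 0.00 with no standard error. Estimates are rounded
#' half-away-from-zero to two decimals for printing; the underlying values
#' are kept at full precision.
#'
#' @param fits Named list of `car_hglm` fits.
#' @return Object of class `coefficient_table`: `rows` (data frame) and
#'   `footer` (dispersion components and observation counts per fit).
#' @export
make_coefficient_table <- function(fits) {
  if (!length(fits)) stop("empty fit set", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("fit", seq_along(fits))
  stopifnot(all(vapply(fits, inherits, logical(1), "car_hglm")))

  rows <- character()
  refs <- character()
  for (f in fits) {
    nm <- names(f$beta)
    # insert factor reference rows next to their dummy blocks
    for (fac in names(f$references)) {
      ref_row <- paste0(fac, f$references[[fac]])
      block <- grep(paste0("^", fac), nm, value = TRUE)
      block <- block[!grepl(":", block, fixed = TRUE)]
      if (length(block)) {
        nm <- append(nm, ref_row, after = match(block[1], nm) - 1L)
        refs <- union(refs, ref_row)
      }
    }
    rows <- union(rows, nm)
  }

  out <- data.frame(term = rows, stringsAsFactors = FALSE)
  for (k in names(fits)) {
    f <- fits[[k]]
    est <- se <- rep(NA_real_, length(rows))
    sig <- rep(NA, length(rows))
    hit <- match(names(f$beta), rows)
    est[hit] <- f$beta
    se[hit] <- f$se_beta
    sig[hit] <- 2 * stats::pnorm(-abs(f$beta / f$se_beta)) < 0.05
    own_refs <- paste0(names(f$references), f$references)
    est[rows %in% intersect(refs, own_refs)] <- 0
    out[[paste0("estimate.", k)]] <- est
    out[[paste0("se.", k)]] <- se
    out[[paste0("sig.", k)]] <- sig
  }
  footer <- data.frame(fit = names(fits),
                       phi = vapply(fits, `[[`, numeric(1), "phi"),
                       tau = vapply(fits, `[[`, numeric(1), "tau"),
                       rho = vapply(fits, `[[`, numeric(1), "rho"),
                       n_obs = vapply(fits, `[[`, numeric(1), "n_obs"),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(rows = out, footer = footer), class = "coefficient_table")
}

format_ct_cell <- function(est, se, sig) {
  if (is.na(est)) return("")
  if (is.na(se)) return("0.00 (-)")
  sprintf("%.2f%s (%.2f)", round_half_away(est, 2), if (isTRUE(sig)) "*" else "",
          round_half_away(se, 2))
}

#' @export
print.coefficient_table <- function(x, ...) {
  fits <- x$footer$fit
  disp <- data.frame(term = x$rows$term, stringsAsFactors = FALSE)
  for (k in fits) {
    disp[[k]] <- mapply(format_ct_cell,
                        x$rows[[paste0("estimate.", k)]],
                        x$rows[[paste0("se.", k)]],
                        x$rows[[paste0("sig.", k)]])
  }
  print(disp, right = FALSE, row.names = FALSE)
  cat("---\n")
  print(x$footer, row.names = FALSE)
  cat("* significant at the 5% level; 0.00 (-) marks a reference category\n")
  invisible(x)
}

pipeline_config_schema <- function() {
  list(
    seed = NULL, out_dir = NULL,
    design = c("n_squares", "half_extent", "seed"),
    generator = c("tau", "rho", "p_multi_group", "years"),
    model = c("terms", "alpha", "test", "vif_threshold"),
    fit = c("method", "tol", "max_iter"),
    subsets = NULL,
    power = c("enabled", "n_sim", "terms", "alpha", "seed")
  )
}

validate_pipeline_config <- function(config) {
  schema <- pipeline_config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad))
    stop("config validation error: unknown key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (k in names(config)) {
    if (is.null(schema[[k]]) || !is.list(config[[k]])) next
    bad <- setdiff(names(config[[k]]), schema[[k]])
    if (length(bad))
      stop("config validation error: unknown key(s) under `", k, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

subset_index <- function(covariates, subset) {
  switch(subset,
         combined = rep(TRUE, nrow(covariates)),
         region = covariates$scale == "regional",
         storliden = covariates$site == "Storliden",
         jokkmokksliden = covariates$site == "Jokkmokksliden",
         stop("unknown subset: ", subset, call. = FALSE))
}

#' Run the full survey-to-report pipeline
#'
#' Simulates (or loads) a survey, validates it, builds per-subset model
#' frames (combined, region, and the two wind-farm mountains), screens the
#' continuous covariates for collinearity, runs hierarchy-respecting
#' backward elimination, fits the final models, assembles the aligned
#' coefficient table, and (optionally) runs the Monte Carlo power study.
#' All artefacts (CSV/JSON/MTX and a run log) are written under `out_dir`;
#' rerunning with the same config reproduces them byte-for-byte.
#'
#' @param config Nested list; see the package vignette. Top-level keys:
#'   `seed`, `out_dir`, `design`, `generator`, `model`, `fit`, `subsets`,
#'   `power`. Unknown keys raise a config-validation error. A path to a
#'   YAML file is also accepted.
#' @return Invisibly, a list with the simulation, per-subset selection
#'   results, fits, the coefficient table and any power results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  dcfg <- config$design %||% list()
  design <- mala_design(seed = dcfg$seed %||% seed,
                        n_squares = dcfg$n_squares %||% 29,
                        half_extent = dcfg$half_extent %||% 1400)
  gcfg <- config$generator %||% list()
  params <- do.call(generator_params,
                    c(list(seed = seed), gcfg))
  say("seed: %d", seed)
  say("design: %d plots, %d turbines", nrow(design$plots), nrow(design$turbines))

  sim <- simulate_survey(design, params)
  viol <- validate_survey(sim$records)
  say("survey records: %d, rule violations: %d", nrow(sim$records), nrow(viol))
  write_plots(design$plots, file.path(out_dir, "plots.csv"))
  utils::write.csv(sim$records, file.path(out_dir, "records.csv"), row.names = FALSE)
  utils::write.csv(sim$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  write_adjacency(sim$adjacency, file.path(out_dir, "adjacency.mtx"))
  jsonlite::write_json(
    list(seed = seed, tau = params$tau, rho = params$rho,
         p_multi_group = params$p_multi_group, years = params$years,
         beta = as.list(params$beta)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  mcfg <- config$model %||% list()
  terms0 <- mcfg$terms %||% default_model_terms()
  alpha <- mcfg$alpha %||% 0.10
  test <- mcfg$test %||% "max_coef"
  vif_threshold <- mcfg$vif_threshold %||% 3.0
  fcfg <- config$fit %||% list()
  options <- hglm_options(method = fcfg$method %||% "eql",
                          tol = fcfg$tol %||% 1e-6,
                          max_iter = fcfg$max_iter %||% 200)
  say("model terms: %s; alpha: %g; fit tol: %g", paste(terms0, collapse = " + "),
      alpha, options$tol)

  subsets <- config$subsets %||% c("combined", "region", "storliden",
                                   "jokkmokksliden")
  selections <- list()
  fits <- list()
  for (ss in subsets) {
    keep <- subset_index(sim$covariates, ss)
    recs <- sim$records[keep, , drop = FALSE]
    covs <- sim$covariates[keep, , drop = FALSE]
    fb <- function(terms, phase_coding = "phase") {
      suppressMessages(build_model_frame(recs, covs, terms = terms,
                                         phase_map = params$phase_map,
                                         phase_coding = phase_coding))
    }
    # collinearity screen on the continuous covariates of the initial frame
    terms_ss <- terms0
    fr0 <- fb(terms_ss)
    contin <- setdiff(colnames(fr0$X), "(Intercept)")
    contin <- contin[!grepl("vegetation|phase|:", contin)]
    if (length(contin) >= 2L) {
      vif <- compute_vif(fr0$X[, contin, drop = FALSE], threshold = vif_threshold)
      utils::write.csv(vif, file.path(out_dir, paste0("vif_", ss, ".csv")),
                       row.names = FALSE)
      for (rmv in vif$column[vif$remove]) {
        terms_ss <- terms_ss[!vapply(strsplit(terms_ss, ":", fixed = TRUE),
                                     function(v) rmv %in% v, logical(1))]
        say("subset %s: removed %s (VIF >= %g)", ss, rmv, vif_threshold)
      }
    }
    sel <- backward_eliminate(model_spec(terms_ss), fb, sim$adjacency,
                              alpha = alpha, test = test, options = options)
    utils::write.csv(sel$trail, file.path(out_dir, paste0("trail_", ss, ".csv")),
                     row.names = FALSE)
    say("subset %s: n = %d, final terms: %s, dropped rows: %d", ss,
        sel$fit$n_obs %||% 0L, paste(sel$spec$terms, collapse = " + "),
        attr(sel, "n_dropped") %||% 0L)
    selections[[ss]] <- sel
    fits[[ss]] <- sel$fit
    jsonlite::write_json(
      list(subset = ss, coefficients = as.list(sel$fit$beta),
           se = as.list(sel$fit$se_beta), tau = sel$fit$tau, rho = sel$fit$rho,
           phi = sel$fit$phi, converged = sel$fit$converged,
           n_obs = sel$fit$n_obs),
      file.path(out_dir, paste0("fit_", ss, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  ct <- make_coefficient_table(fits)
  utils::write.csv(ct$rows, file.path(out_dir, "coefficient_table.csv"),
                   row.names = FALSE)
  utils::write.csv(ct$footer, file.path(out_dir, "coefficient_table_footer.csv"),
                   row.names = FALSE)

  power <- NULL
  pcfg <- config$power %||% list(enabled = FALSE)
  if (isTRUE(pcfg$enabled)) {
    power <- estimate_power(params, design,
                            terms = pcfg$terms %||%
                              c("sqrt_dist:phaseconstruction",
                                "sqrt_dist:phaseoperation"),
                            n_sim = pcfg$n_sim %||% 200,
                            alpha = pcfg$alpha %||% 0.05,
                            seed = pcfg$seed %||% seed,
                            options = options)
    utils::write.csv(power, file.path(out_dir, "power.csv"), row.names = FALSE)
    jsonlite::write_json(power, file.path(out_dir, "power.json"),
                         dataframe = "rows", digits = NA)
    say("power: %s", paste(sprintf("%s=%.3f", power$term, power$power),
                           collapse = ", "))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(design = design, sim = sim, selections = selections,
                 fits = fits, coefficient_table = ct, power = power,
                 log = log_lines))
}
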