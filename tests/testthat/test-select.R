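# A fast frame factory over simulated covariates for selection tests:
# builds X from a term subset of independent covariates a, b, c and their
# interactions, fitted on an edgeless design (plain logistic refits).
make_toy_builder <- function(n, beta_true, seed) {
  set.seed(seed)
  dat <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  eta <- with(dat, beta_true["a"] * a + beta_true["b"] * b +
                beta_true["c"] * c + beta_true["ab"] * a * b)
  dat$y <- rbinom(n, 1, plogis(beta_true["int"] + eta))
  units <- scatter_units(n)
  builder <- function(terms, phase_coding = "phase") {
    X <- model.matrix(reformulate(terms), dat)
    structure(list(y = dat$y, X = X, units = units, terms = terms,
                   assign = attr(X, "assign"), references = character()),
              class = "model_frame")
  }
  list(builder = builder, D = build_adjacency(units), data = dat)
}

fast_opts <- hglm_options(fix_tau = 1e-8)

test_that("model_spec enforces hierarchy and duplicates at construction", {
  expect_error(model_spec(c("a", "a")), "duplicate")
  expect_error(model_spec(c("a", "a:b")), "parent")
  s <- model_spec(c("a", "b", "a:b"), forced = "a")
  expect_s3_class(s, "model_spec")
  expect_error(model_spec(c("a"), forced = "b"), "among the terms")
})

test_that("terms below the retention level survive; pure noise is dropped first", {
  tb <- make_toy_builder(500, c(int = -0.3, a = 1.2, b = 0.9, c = 0, ab = 0),
                         seed = 51)
  res <- backward_eliminate(model_spec(c("a", "b", "c")), tb$builder, tb$D,
                            alpha = 0.10, options = fast_opts)
  expect_true(all(c("a", "b") %in% res$spec$terms))
  # the noise covariate is the first (and typically only) drop
  if (nrow(res$trail) > 0) expect_identical(res$trail$term[1], "c")
  # strong terms only: nothing dropped
  tb2 <- make_toy_builder(500, c(int = 0, a = 1.5, b = 1.5, c = 1.5, ab = 0),
                          seed = 52)
  res2 <- backward_eliminate(model_spec(c("a", "b", "c")), tb2$builder, tb2$D,
                             alpha = 0.10, options = fast_opts)
  expect_identical(res2$spec$terms, c("a", "b", "c"))
  expect_identical(nrow(res2$trail), 0L)
})

test_that("pure-noise covariate is eliminated first in most seeds", {
  hits <- 0L
  for (s in 1:20) {
    tb <- make_toy_builder(500, c(int = -0.2, a = 1.2, b = 1.0, c = 0, ab = 0),
                           seed = 600 + s)
    res <- backward_eliminate(model_spec(c("a", "b", "c")), tb$builder, tb$D,
                              alpha = 0.10, options = fast_opts)
    if (nrow(res$trail) >= 1 && res$trail$term[1] == "c") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("a main effect is never dropped while its interaction is retained", {
  # b is pure noise as a main effect but a:b matters
  tb <- make_toy_builder(800, c(int = -0.2, a = 0.8, b = 0, c = 0, ab = 1.2),
                         seed = 53)
  res <- backward_eliminate(model_spec(c("a", "b", "c", "a:b")), tb$builder,
                            tb$D, alpha = 0.10, options = fast_opts)
  expect_true("a:b" %in% res$spec$terms)
  expect_true(all(c("a", "b") %in% res$spec$terms))
  expect_false("c" %in% res$spec$terms)
})

test_that("alpha endpoints: 1 keeps everything, 0 reduces to forced terms", {
  tb <- make_toy_builder(300, c(int = 0, a = 1, b = 0.5, c = 0, ab = 0),
                         seed = 54)
  res1 <- backward_eliminate(model_spec(c("a", "b", "c")), tb$builder, tb$D,
                             alpha = 1.0, options = fast_opts)
  expect_identical(res1$spec$terms, c("a", "b", "c"))
  res0 <- backward_eliminate(model_spec(c("a", "b", "c"), forced = "a"),
                             tb$builder, tb$D, alpha = 0, options = fast_opts)
  expect_identical(res0$spec$terms, "a")
})

test_that("elimination trails always respect hierarchy on randomized problems", {
  set.seed(55)
  n_trails <- 120
  ok <- TRUE
  deterministic <- TRUE
  for (k in seq_len(n_trails)) {
    bt <- c(int = runif(1, -1, 0.5), a = rnorm(1, 0, 0.7),
            b = rnorm(1, 0, 0.7), c = rnorm(1, 0, 0.7),
            ab = rnorm(1, 0, 0.5))
    terms <- if (k %% 2) c("a", "b", "c", "a:b") else c("a", "b", "a:b")
    tb <- make_toy_builder(120, bt, seed = 7000 + k)
    res <- backward_eliminate(model_spec(terms), tb$builder, tb$D,
                              alpha = runif(1, 0.05, 0.5),
                              options = fast_opts)
    fin <- res$spec$terms
    for (tm in fin[grepl(":", fin)]) {
      if (!all(strsplit(tm, ":")[[1]] %in% fin)) ok <- FALSE
    }
    # interactions are dropped before their parents along the trail
    if (nrow(res$trail) > 1) {
      seen_main <- character()
      for (i in seq_len(nrow(res$trail))) {
        tm <- res$trail$term[i]
        if (grepl(":", tm) &&
            any(strsplit(tm, ":")[[1]] %in% seen_main)) deterministic <- FALSE
        if (!grepl(":", tm)) seen_main <- c(seen_main, tm)
      }
    }
  }
  expect_true(ok)
  expect_true(deterministic)
})

test_that("elimination is deterministic given data and options", {
  tb <- make_toy_builder(300, c(int = 0, a = 0.4, b = 0.2, c = 0.1, ab = 0),
                         seed = 56)
  r1 <- backward_eliminate(model_spec(c("a", "b", "c")), tb$builder, tb$D,
                           alpha = 0.3, options = fast_opts)
  r2 <- backward_eliminate(model_spec(c("a", "b", "c")), tb$builder, tb$D,
                           alpha = 0.3, options = fast_opts)
  expect_identical(r1$trail, r2$trail)
  expect_identical(r1$spec$terms, r2$spec$terms)
})

test_that("sensitivity refits rewire phases or add a year random effect", {
  d <- mala_design(seed = 8, n_squares = 4, half_extent = 400)
  p <- generator_params(seed = 21, tau = 0.3, rho = 0.01)
  s <- simulate_survey(d, p)
  builder <- function(terms, phase_coding = "phase") {
    suppressMessages(build_model_frame(s$records, s$covariates, terms = terms,
                                       phase_coding = phase_coding))
  }
  spec <- model_spec(default_model_terms())
  fy <- suppressWarnings(sensitivity_refit(spec, builder, s$adjacency,
                                           "yearwise_phases",
                                           options = hglm_options(tol = 1e-4)))
  expect_true(any(grepl("phase2011", names(fy$beta))))
  expect_true(any(grepl("phase2012", names(fy$beta))))
  fr <- suppressWarnings(sensitivity_refit(spec, builder, s$adjacency,
                                           "random_year",
                                           options = hglm_options(tol = 1e-4)))
  expect_length(fr$year_effects, 6)  # 2010-2015 analysis years
  expect_true(fr$sigma2_year >= 0)
  expect_error(sensitivity_refit(spec, builder, s$adjacency, "bootstrap"))
})

test_that("a year-homogeneous world gives a near-zero year variance and
           matching construction-year coefficients", {
  d <- mala_design(seed = 9, n_squares = 5, half_extent = 500)
  p <- generator_params(seed = 31, tau = 0.2, rho = 0.005,
                        precipitation_range = c(70, 70))
  s <- simulate_survey(d, p)
  builder <- function(terms, phase_coding = "phase") {
    suppressMessages(build_model_frame(s$records, s$covariates, terms = terms,
                                       phase_coding = phase_coding))
  }
  spec <- model_spec(c("sqrt_dist", "vegetation", "phase", "sqrt_dist:phase"))
  fr <- suppressWarnings(sensitivity_refit(spec, builder, s$adjacency,
                                           "random_year",
                                           options = hglm_options(tol = 1e-4)))
  expect_lt(fr$sigma2_year, 0.05)
  fy <- suppressWarnings(sensitivity_refit(spec, builder, s$adjacency,
                                           "yearwise_phases",
                                           options = hglm_options(tol = 1e-4)))
  # 2011 and 2012 share one construction effect in truth
  d11 <- fy$beta["phase2011"]; d12 <- fy$beta["phase2012"]
  se <- sqrt(fy$se_beta["phase2011"]^2 + fy$se_beta["phase2012"]^2)
  expect_lt(abs(d11 - d12) / se, 2)
})
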