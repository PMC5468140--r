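test_that("local grid counts match the closed form and brute-force lattice", {
  g <- generate_local_grid(0, 0, half_extent = 450,
                           transect_spacing = 300, plot_spacing = 100)
  expect_identical(nrow(g), 40L)  # 4 transects x 10 plots over a 900 m square
  expect_identical(length(unique(g$x)), 4L)
  expect_identical(length(unique(g$y)), 10L)

  # degenerate extent: a single plot at the centre
  g0 <- generate_local_grid(10, -5, half_extent = 0)
  expect_identical(nrow(g0), 1L)
  expect_equal(c(g0$x, g0$y), c(10, -5))

  # spacing equal to the half-extent: positions at -he, 0, +he on both axes
  g2 <- generate_local_grid(0, 0, half_extent = 300,
                            transect_spacing = 300, plot_spacing = 300)
  expect_identical(nrow(g2), 9L)
  expect_setequal(unique(g2$x), c(-300, 0, 300))

  # property: closed-form count equals brute-force lattice enumeration
  set.seed(41)
  for (k in 1:25) {
    he <- runif(1, 50, 2000)
    ts <- runif(1, 40, 700)
    ps <- runif(1, 20, 400)
    g <- generate_local_grid(0, 0, he, ts, ps)
    expect_identical(nrow(g), oracle_grid_count(he, ts, ps))
    expect_identical(nrow(g),
                     as.integer((floor(2 * he / ts) + 1) * (floor(2 * he / ps) + 1)))
  }
  expect_error(generate_local_grid(0, 0, 100, -1, 100), "positive")
  expect_error(generate_local_grid(0, 0, -5), "non-negative")
})

test_that("regional squares have 20 perimeter plots, spacing and separation", {
  sq <- generate_regional_squares(n_squares = 5, seed = 3)
  expect_identical(nrow(sq), 100L)
  one <- sq[sq$square == 1, ]
  expect_identical(nrow(one), 20L)  # 4000 m perimeter / 200 m, corners once
  # consecutive perimeter plots are 200 m apart (closed loop)
  d <- sqrt(diff(c(one$x, one$x[1]))^2 + diff(c(one$y, one$y[1]))^2)
  expect_equal(d, rep(200, 20))
  # nearest plots of different squares >= 1400 m
  for (a in 1:4) for (b in (a + 1):5) {
    pa <- as.matrix(sq[sq$square == a, c("x", "y")])
    pb <- as.matrix(sq[sq$square == b, c("x", "y")])
    dd <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
    expect_gte(min(dd), 1400)
  }
  # reproducible from the seed
  expect_identical(generate_regional_squares(n_squares = 5, seed = 3), sq)
  # single square traces one square
  expect_identical(nrow(generate_regional_squares(n_squares = 1, seed = 1)), 20L)
  # infeasible packing errors out (area argument: 200 separated squares
  # cannot fit a 2 km disc)
  expect_error(generate_regional_squares(n_squares = 200, region_radius = 2000,
                                         seed = 1, max_attempts = 50),
               "placement failure")
  expect_error(generate_regional_squares(side = 1000, perimeter_spacing = 300),
               "multiple")
})

test_that("adjacency is symmetric, zero-diagonal, inclusive at the threshold", {
  u <- data.frame(plot_id = c("a", "b", "c", "d"), year = 2010,
                  x = c(0, 100, 350, 701), y = 0)
  A <- build_adjacency(u)
  M <- as.matrix(A$M)
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 0))
  expect_equal(M[1, 2], 1)   # 100 m apart
  expect_equal(M[1, 3], 1)   # exactly 350 m: inclusive rule
  expect_equal(M[3, 4], 0)   # 351 m apart
  u2 <- data.frame(plot_id = c("a", "b"), year = 2010, x = c(0, 351), y = 0)
  expect_equal(as.matrix(build_adjacency(u2)$M)[1, 2], 0)  # 351 m: not neighbours

  # year blocking: same plots in two years are never cross-neighbours
  uu <- rbind(transform(u, year = 2010), transform(u, year = 2011))
  Ab <- build_adjacency(uu)
  Mb <- as.matrix(Ab$M)
  expect_true(all(Mb[1:4, 5:8] == 0))
  Ap <- build_adjacency(uu, block_by_year = FALSE)
  expect_true(any(as.matrix(Ap$M)[1:4, 5:8] != 0))

  # duplicate units error
  expect_error(build_adjacency(rbind(u, u[1, ])), "duplicate")

  # property: symmetric zero-diagonal on random designs
  set.seed(99)
  for (k in 1:10) {
    ur <- data.frame(plot_id = sprintf("r%03d", 1:60),
                     year = sample(2010:2012, 60, replace = TRUE),
                     x = runif(60, 0, 3000), y = runif(60, 0, 3000))
    Mk <- as.matrix(build_adjacency(ur)$M)
    expect_true(isSymmetric(Mk))
    expect_true(all(diag(Mk) == 0))
    expect_true(all(Mk %in% c(0, 1)))
  }
})

test_that("sqrt-distance transform is exact and monotone", {
  expect_equal(sqrt_distance_covariate(100), 1)
  expect_equal(sqrt_distance_covariate(400), 2)
  expect_equal(sqrt_distance_covariate(0), 0)
  d <- sort(runif(50, 0, 20000))
  expect_true(all(diff(sqrt_distance_covariate(d)) >= 0))
  expect_error(sqrt_distance_covariate(-1), "non-negative")
})

test_that("VIF agrees with the least-squares oracle and flags collinearity", {
  # orthogonal centred columns: all VIF 1
  set.seed(6)
  X <- qr.Q(qr(scale(matrix(rnorm(100 * 4), 100), center = TRUE,
                     scale = FALSE)))
  v <- compute_vif(X)
  expect_equal(v$vif, rep(1, 4), tolerance = 1e-10)
  expect_false(any(v$remove))

  # two columns with sample correlation exactly 0.8 -> VIF 25/9, unflagged
  set.seed(7)
  a <- rnorm(200); b <- rnorm(200)
  a <- (a - mean(a)) / sd(a); b <- resid(lm(b ~ a)); b <- b / sd(b)
  x2 <- 0.8 * a + sqrt(1 - 0.64) * b
  v2 <- compute_vif(cbind(a, x2))
  expect_equal(v2$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_false(any(v2$remove))

  # duplicated column: infinite VIF, flagged, no crash
  v3 <- compute_vif(cbind(a, a, b))
  expect_true(all(is.infinite(v3$vif[1:2])))
  expect_true(all(v3$remove[1:2]))

  # property: agreement with brute-force oracle on random matrices
  set.seed(13)
  for (k in 1:8) {
    p <- sample(2:10, 1)
    Xr <- matrix(rnorm(60 * p), 60)
    Xr[, p] <- Xr[, 1] * runif(1, 0.3, 0.9) + rnorm(60, sd = 0.5)
    expect_equal(compute_vif(Xr)$vif, oracle_vif(Xr), tolerance = 1e-10)
  }
  expect_error(compute_vif(matrix(1:10, ncol = 1)), "two columns")
})

test_that("the shipped synthetic mapping example covers the five classes", {
  f <- system.file("extdata", "vegetation_mapping_synthetic.csv",
                   package = "windpellet")
  map <- read.csv(f, stringsAsFactors = FALSE)
  merged <- apply_class_merge(map$raw, map)
  expect_setequal(unique(merged), vegetation_classes())
  expect_identical(apply_class_merge("open_mire", map), "mire")
})

test_that("vegetation class merge is closed over the five classes", {
  map <- c(barrmyr = "mire", tallskog = "forest", hygge = "clear_cut")
  expect_identical(apply_class_merge(c("barrmyr", "hygge"), map),
                   c("mire", "clear_cut"))
  expect_error(apply_class_merge("okant", map), "unmapped")
  bad_map <- c(barrmyr = "mire", stad = "urban")
  expect_error(apply_class_merge("barrmyr", bad_map), "configuration error")
})

test_that("plots and adjacency round-trip through CSV and Matrix Market", {
  g <- generate_local_grid(0, 0, 300, site = "Storliden", prefix = "sto")
  f <- tempfile(fileext = ".csv")
  write_plots(g, f)
  expect_equal(read_plots(f)$x, g$x)
  u <- transform(g, year = 2010)
  A <- build_adjacency(u)
  fm <- tempfile(fileext = ".mtx")
  write_adjacency(A, fm)
  expect_match(readLines(fm, n = 1), "pattern symmetric")
  B <- read_adjacency(fm, units = A$units, threshold = 350)
  expect_equal(as.matrix(B$M), unname(as.matrix(A$M)))
})
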