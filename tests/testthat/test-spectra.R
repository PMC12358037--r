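test_that("long and wide dialects read, relabel and resample correctly", {
  grid <- wl_grid()
  # flat long file on the exact grid: identity resampling
  long <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance",
               paste(grid, 10.0, sep = ",")), long)
  ss <- read_spectra(long)
  expect_equal(length(ss), 1L)
  expect_equal(unname(ss$refl[, 1]), rep(10, 401))

  # 0.4 nm sampling: interpolation passes through shared wavelengths
  fine <- seq(300, 700, by = 0.4)
  y <- 20 + 10 * sin(fine / 40)
  f04 <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance",
               paste(fine, y, sep = ",")), f04)
  ss04 <- read_spectra(f04)
  shared <- grid[grid %in% fine]
  expect_equal(unname(ss04$refl[match(shared, grid), 1]),
               20 + 10 * sin(shared / 40), tolerance = 1e-12)

  # wide file with 3 sample columns keeps header labels
  wide <- tempfile(fileext = ".tsv")
  df <- data.frame(wavelength_nm = grid, alpha = 1:401 / 10,
                   beta = rep(5, 401), gamma = rev(1:401) / 10)
  write.table(df, wide, sep = "\t", row.names = FALSE, quote = FALSE)
  ssw <- read_spectra(wide)
  expect_equal(labels(ssw), c("alpha", "beta", "gamma"))
  expect_equal(unname(ssw$refl[, "beta"]), rep(5, 401))

  # 0-1 scale auto-detected and rescaled to percent
  frac <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance",
               paste(grid, 0.25, sep = ",")), frac)
  expect_message(ssf <- read_spectra(frac), "0-1 scale")
  expect_equal(unname(ssf$refl[, 1]), rep(25, 401))
})

test_that("reader rejects bad cells and narrow coverage with clear errors", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance", "300,1.0", "301,oops", "302,3.0"),
             bad)
  expect_error(read_spectra(bad), "non-numeric.*row 2")

  narrow <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance",
               paste(seq(350, 650, 1), 10, sep = ",")), narrow)
  expect_error(read_spectra(narrow), "coverage.*extrapolation refused")
})

test_that("round trip through write_spectra preserves values and labels", {
  ss <- make_study_set(n_per_class = c(green = 2, white = 1), seed = 7)
  path <- tempfile(fileext = ".tsv")
  write_spectra(ss, path)
  back <- read_spectra(path)
  expect_equal(labels(back), labels(ss))
  expect_equal(back$refl, ss$refl, tolerance = 1e-10)
})

test_that("local-regression smoothing preserves constants and linear trends", {
  grid <- wl_grid()
  flat <- make_flat_set(25)
  expect_equal(smooth_spectra(flat)$refl, flat$refl, tolerance = 1e-9)

  ramp <- spec_set(grid, (grid - 300) / 4)  # 0 -> 100 linear
  sm <- smooth_spectra(ramp)
  interior <- grid > 320 & grid < 680
  expect_equal(sm$refl[interior, 1], ramp$refl[interior, 1], tolerance = 1e-6)

  expect_error(smooth_spectra(flat, span = 0), "span")
  expect_error(smooth_spectra(flat, span = 1.2), "span")
})

test_that("smoothing a noisy sinusoid reduces noise at least as well as a
           moving-window least-squares oracle", {
  grid <- wl_grid()
  truth <- 30 + 10 * sin(2 * pi * grid / 150)
  noisy <- truth + withr::with_seed(42, rnorm(length(grid), sd = 2))
  ss <- spec_set(grid, noisy)
  sm <- smooth_spectra(ss, span = 0.20)
  resid_pkg <- sd(sm$refl[, 1] - truth)
  resid_ora <- sd(oracle_movwin_ls(grid, noisy, 0.20) - truth)
  expect_lt(resid_pkg, 2)             # strictly below the input noise sd
  expect_lt(resid_pkg, resid_ora * 1.5)  # same order as the oracle smoother
})

test_that("smoothing commutes with adding a constant", {
  grid <- wl_grid()
  y <- 20 + 15 * exp(-(grid - 550)^2 / (2 * 40^2))
  a <- smooth_spectra(spec_set(grid, y + 7))$refl[, 1]
  b <- smooth_spectra(spec_set(grid, y))$refl[, 1] + 7
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("negative-value correction shifts by |min|, is idempotent and
           order-preserving", {
  grid <- wl_grid()
  y <- 5 + 0.02 * (grid - 300)
  y[grid == 400] <- -2
  ss <- spec_set(grid, y)
  fixed <- fix_negative(ss)
  expect_equal(unname(fixed$refl[grid == 400, 1]), 0)
  expect_equal(fixed$refl[, 1], y + 2)
  expect_equal(order(fixed$refl[, 1]), order(y))
  expect_equal(fix_negative(fixed)$refl, fixed$refl)  # idempotent

  pos <- make_flat_set(5)
  expect_identical(fix_negative(pos)$refl, pos$refl)  # no-op
  zero <- make_flat_set(0)
  expect_identical(fix_negative(zero)$refl, zero$refl)
})

test_that("aggregation takes per-wavelength mean and sample sd", {
  grid <- wl_grid()
  two <- spec_set(grid, cbind(a1 = rep(10, 401), a2 = rep(30, 401)),
                  groups = c(a1 = "sp", a2 = "sp"))
  agg <- aggregate_spectra(two)
  expect_equal(unname(agg$refl[, "sp"]), rep(20, 401))
  expect_equal(unname(agg$sd[, "sp"]), rep(sqrt(200), 401))
  expect_equal(unname(agg$n_aggregated["sp"]), 2L)

  same <- spec_set(grid, cbind(b1 = rep(12, 401), b2 = rep(12, 401)),
                   groups = c(b1 = "sp", b2 = "sp"))
  agg2 <- aggregate_spectra(same)
  expect_equal(unname(agg2$refl[, "sp"]), rep(12, 401))
  expect_equal(unname(agg2$sd[, "sp"]), rep(0, 401))
})

test_that("aggregation matches a two-pass oracle and is idempotent", {
  grid <- wl_grid()
  refl <- withr::with_seed(11, matrix(runif(401 * 10, 0, 60), 401, 10))
  colnames(refl) <- paste0("s", 1:10)
  by <- setNames(rep(c("gA", "gB"), each = 5), colnames(refl))
  ss <- spec_set(grid, refl, groups = by)
  agg <- aggregate_spectra(ss)
  for (g in c("gA", "gB")) {
    cols <- names(by)[by == g]
    mu <- rowSums(refl[, cols]) / length(cols)
    s2 <- rowSums((refl[, cols] - mu)^2) / (length(cols) - 1)
    expect_equal(unname(agg$refl[, g]), mu, tolerance = 1e-12)
    expect_equal(unname(agg$sd[, g]), sqrt(s2), tolerance = 1e-12)
  }
  # aggregating the aggregate (one per group) is the identity on values
  agg2 <- aggregate_spectra(agg, by = setNames(c("gA", "gB"), c("gA", "gB")))
  expect_equal(agg2$refl, agg$refl)
})

test_that("resampling onto the same grid is the identity and the container
           enforces its invariants", {
  ss <- make_flat_set(10)
  expect_identical(resample_spectra(ss, wl_grid()), ss)
  expect_error(spec_set(c(300, 300, 301), 1:3), "strictly increasing")
  expect_error(spec_set(wl_grid(), rep(NA_real_, 401)), "finite")
  expect_error(spec_set(wl_grid(), 1:5), "length")
  neg <- spec_set(wl_grid(), rep(-1, 401))
  expect_error(validate_spectra(neg), "negative")
})
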