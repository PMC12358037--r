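test_that("nomogram receptors peak at lambda_max and fall off above it", {
  grid <- wl_grid()
  r <- make_receptor(544, grid = grid, name = "green")
  expect_equal(r$curve[grid == 544], 1)
  expect_equal(max(r$curve), 1)
  # strictly decreasing for at least 80 nm above the peak, for several peaks
  for (lm in c(340, 436, 460, 544)) {
    cr <- make_receptor(lm, grid = grid)$curve
    above <- grid > lm & grid <= lm + 80
    expect_true(all(diff(cr[above]) < 0), info = paste("lambda_max", lm))
    # fine-grid template agrees: the maximum of the raw formula sits at the peak
    fine <- seq(lm - 5, lm + 5, by = 0.01)
    expect_lt(abs(fine[which.max(pigment_template(fine, lm))] - lm), 3)
  }
  expect_error(make_receptor(250), "grid")
})

test_that("a tabulated curve equal to a templated one is substitutable", {
  grid <- wl_grid()
  tpl <- make_receptor(436, grid = grid, name = "blue")
  tab <- make_receptor(template = "tabulated", curve = tpl$curve,
                       grid = grid, name = "blue")
  ill <- illuminant_d65(grid)
  ss <- make_study_set(n_per_class = c(green = 3), seed = 2)
  expect_equal(quantum_catch(ss, tab, ill), quantum_catch(ss, tpl, ill))
})

test_that("quantum catch is linear, null on dark spectra and grid-checked", {
  grid <- wl_grid()
  r <- make_receptor(436, grid = grid)
  ill <- illuminant_flat(grid)
  dark <- make_flat_set(0)
  expect_equal(unname(quantum_catch(dark, r, ill)), 0)
  y <- 20 * exp(-(grid - 500)^2 / (2 * 50^2))
  one <- spec_set(grid, y); two <- spec_set(grid, 2 * y)
  expect_equal(quantum_catch(two, r, ill), 2 * quantum_catch(one, r, ill))
  short <- spec_set(wl_grid(400, 700), rep(10, 301))
  expect_error(quantum_catch(short, r, ill), "grid")
})

test_that("von Kries adaptation normalizes to the background", {
  expect_equal(adapt_von_kries(3.2, 3.2), 1)
  expect_equal(adapt_von_kries(0, 2), 0)
  expect_error(adapt_von_kries(1, 0), "background")
})

test_that("hyperbolic transduction maps background to 0.5 and is bounded", {
  expect_equal(excite_hyperbolic(1), 0.5)
  expect_equal(excite_hyperbolic(0), 0)
  expect_equal(excite_hyperbolic(3), 0.75)
  q <- seq(0, 50, by = 0.5)
  expect_true(all(diff(excite_hyperbolic(q)) > 0))
  expect_true(all(excite_hyperbolic(q) < 1))
  expect_error(excite_hyperbolic(-0.1), "non-negative")
})

test_that("hexagon geometry: centre, corners and sector labels", {
  ctr <- hexagon_locus(0.5, 0.5, 0.5)
  expect_equal(c(ctr$x, ctr$y), c(0, 0))
  expect_equal(ctr$sector, "achromatic")

  blue <- hexagon_locus(0, 1 - 1e-12, 0)
  expect_equal(c(blue$x, blue$y), c(0, 1), tolerance = 1e-9)
  expect_equal(blue$sector, "blue")
  expect_equal(chromatic_contrast(blue), 1, tolerance = 1e-9)

  green <- hexagon_locus(0, 0, 1 - 1e-12)
  expect_equal(c(green$x, green$y), c(sqrt(3) / 2, -0.5), tolerance = 1e-9)
  expect_equal(green$sector, "green")
  expect_equal(chromatic_contrast(green), 1, tolerance = 1e-9)

  uv <- hexagon_locus(1 - 1e-12, 0, 0)
  expect_equal(uv$sector, "uv")
})

test_that("fly locus: achromatic centre, direct differences, antisymmetry", {
  eq <- fly_locus(1, 1, 1, 1)
  expect_equal(c(eq$x, eq$y), c(0, 0))
  expect_equal(eq$sector, "achromatic")

  # normalized signals (0.3, 0.25, 0.1, 0.35) -> direct differences
  l <- fly_locus(0.3, 0.25, 0.1, 0.35)
  expect_equal(c(l$x, l$y), c(0.2, -0.1), tolerance = 1e-12)

  a <- fly_locus(0.3, 0.25, 0.1, 0.35)
  b <- fly_locus(0.1, 0.25, 0.3, 0.35)  # swap R7p and R8p
  expect_equal(b$x, -a$x)
  expect_equal(b$y, a$y)
})

test_that("contrast arithmetic and threshold flags follow the documented
           conventions", {
  expect_equal(chromatic_contrast(0, 0), 0)
  expect_equal(chromatic_contrast(sqrt(3) / 2, -0.5), 1)
  expect_equal(chromatic_contrast(0.06, 0.08), 0.10)

  expect_equal(achromatic_contrast(0.5), 0)
  expect_equal(achromatic_contrast(0.822), 0.322)
  expect_equal(achromatic_contrast(0.1), 0.4)

  expect_false(flag_discriminable(0.107, "hexagon"))
  expect_true(flag_discriminable(0.096, "fly"))     # boundary is inclusive
  expect_true(flag_discriminable(0.293, "hexagon"))
})

test_that("the background maps to the achromatic centre in both models", {
  for (model in c("hexagon", "fly")) {
    ctx <- viewing_context(model)
    res <- colour_loci(ctx$background, ctx)
    expect_lt(res$chromatic_EU, 1e-10)
    if (model == "hexagon") expect_lt(res$achromatic_EU, 1e-10)
  }
})

test_that("rescaling the illuminant leaves every locus unchanged", {
  ss <- make_study_set(n_per_class = c(green = 3, yellow = 2), seed = 5)
  for (model in c("hexagon", "fly")) {
    base <- viewing_context(model)
    ref <- colour_loci(ss, base)
    for (k in c(0.1, 10)) {
      ill <- base$illuminant
      ill$irradiance <- ill$irradiance * k
      scaled <- viewing_context(model, illuminant = ill)
      got <- colour_loci(ss, scaled)
      expect_lt(max(abs(got$x - ref$x), abs(got$y - ref$y)), 1e-12)
    }
  }
})

test_that("loci stay inside their colour spaces and the narrowband sweep is
           continuous", {
  grid <- wl_grid()
  cs <- seq(310, 690, by = 5)
  nb <- spec_set(grid, sapply(cs, function(c0)
    1 + 60 * exp(-(grid - c0)^2 / (2 * 12^2))),
    labels = paste0("nb", cs))
  hex <- colour_loci(nb, viewing_context("hexagon"))
  # regular hexagon with circumradius 1: |y'| <= 1 along each of the three
  # axis projections
  for (ang in c(90, 210, 330) * pi / 180) {
    proj <- hex$x * cos(ang) + hex$y * sin(ang)
    expect_true(all(abs(proj) <= 1 + 1e-9))
  }
  fly <- colour_loci(nb, viewing_context("fly"))
  expect_true(all(abs(fly$x) <= 1 & abs(fly$y) <= 1))
  # smooth hue trajectory: no jumps beyond the step-induced bound
  jumps <- sqrt(diff(hex$x)^2 + diff(hex$y)^2)
  expect_lt(max(jumps), 0.15)
})

test_that("the tidy loci table carries labels, groups and both models", {
  ss <- make_study_set(n_per_class = c(green = 2, white = 2), seed = 3)
  out <- rbind(colour_loci(ss, viewing_context("hexagon")),
               colour_loci(ss, viewing_context("fly")))
  expect_equal(nrow(out), 8L)
  expect_setequal(unique(out$model), c("hexagon", "fly"))
  expect_true(all(is.na(out$achromatic_EU[out$model == "fly"])))
  expect_true(all(out$chromatic_EU >= 0))
})
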