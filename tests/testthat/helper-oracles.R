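# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written without reusing package internals.

# moving-window least-squares smoother: at each grid point, fit an ordinary
# (unweighted) straight line to the window covering `span` of the grid and
# take its fitted value. Independent of the package's loess-based smoother.
oracle_movwin_ls <- function(wl, y, span) {
  n <- length(wl)
  half <- max(1L, floor(span * n / 2))
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    fit <- stats::lm.fit(cbind(1, wl[idx] - wl[i]), y[idx])
    fit$coefficients[1]
  }, numeric(1))
}

# step-down Holm adjustment coded as the literal sequential procedure
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (k in seq_len(n)) {
    running <- max(running, (n - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

# brute-force quantum catch: evaluate the analytic reflectance model, the
# nomogram formula and the analytic illuminant on a much finer grid and take
# the midpoint-cell sum over the same span the coarse rule covers (each
# 1 nm grid point weighs its full cell, i.e. 299.5-700.5 nm for the default
# grid)
oracle_fine_catch <- function(wl, refl_fun, lambda_max, ill_fun, step_fine) {
  step <- wl[2] - wl[1]
  fine <- seq(min(wl) - step / 2 + step_fine / 2,
              max(wl) + step / 2 - step_fine / 2, by = step_fine)
  r <- refl_fun(fine) / 100
  s <- pigment_template(fine, lambda_max)
  s <- s / max(pigment_template(wl, lambda_max))   # same normalization basis
  sum(r * s * ill_fun(fine)) * step_fine
}

# logistic reflectance transition: low -> low + amp, inflection at x0
logistic_spectrum <- function(grid, x0, amp, low = 10, scale = 8) {
  low + amp / (1 + exp(-(grid - x0) / scale))
}

# star phylogeny with unit-length edges
star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

make_flat_set <- function(value, grid = wl_grid(), label = "flat") {
  spec_set(grid, rep(value, length(grid)), labels = label)
}
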