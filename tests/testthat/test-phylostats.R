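test_that("the Brownian rate has its closed form on star trees and scales
           with tree depth", {
  tr4 <- star_tree(4)
  zero <- data.frame(label = tr4$tip.label, value = 0, group = "g")
  expect_equal(fit_bm_rate(tr4, zero)$sigma2, 0)

  tr2 <- star_tree(2)
  pm <- data.frame(label = tr2$tip.label, value = c(-1, 1), group = "g")
  expect_equal(fit_bm_rate(tr2, pm)$sigma2, 1)   # ML: sum((x - mean)^2) / n

  tr <- make_yule_tree(12, seed = 3)
  x <- setNames(withr::with_seed(8, rnorm(12)), tr$tip.label)
  s1 <- fit_bm_rate(tr, x)$sigma2
  tr2x <- tr; tr2x$edge.length <- tr$edge.length * 2
  expect_equal(fit_bm_rate(tr2x, x)$sigma2, s1 / 2, tolerance = 1e-10)
})

test_that("Brownian simulation honours the tree covariance", {
  tr <- star_tree(5)
  expect_equal(unname(simulate_bm(tr, 0, nsim = 3, root = 2)),
               matrix(2, 5, 3))
  # seeded runs are bit-reproducible
  a <- simulate_bm(tr, 1.3, nsim = 4, seed = 77)
  b <- simulate_bm(tr, 1.3, nsim = 4, seed = 77)
  expect_identical(a, b)

  # star tree: unit variance, no cross-tip covariance
  X <- simulate_bm(tr, 1, nsim = 10000, seed = 5)
  v <- apply(X, 1, var)
  expect_true(all(abs(v - 1) < 0.05))
  cc <- cor(t(X))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)

  # sister tips with a long shared stem: correlation ~ shared/total depth
  tx <- ape::read.tree(text = "((a:0.2,b:0.2):0.8,c:1.0);")
  Xs <- simulate_bm(tx, 1, nsim = 20000, seed = 9)
  expect_equal(cor(Xs["a", ], Xs["b", ]), 0.8, tolerance = 0.03)
})

test_that("the F statistic matches its textbook identities", {
  expect_equal(anova_f(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))$f, 0)
  expect_true(is.infinite(anova_f(c(0, 0, 1, 1), c("A", "A", "B", "B"))$f))

  x <- withr::with_seed(21, rnorm(20))
  g <- rep(c("A", "B"), each = 10)
  f <- anova_f(x, g)$f
  t2 <- unname(t.test(x ~ g, var.equal = TRUE)$statistic^2)
  expect_equal(f, t2, tolerance = 1e-10)
})

test_that("Holm adjustment matches hand-computed cases and p.adjust", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.6, 0.7, 0.8)), c(1, 1, 1))
  for (i in 1:200) {
    p <- withr::with_seed(3000 + i, runif(sample(1:8, 1)))
    expect_equal(holm_adjust(p), p.adjust(p, "holm"))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("phylANOVA saturates under extreme effects and reports the add-one
           minimum", {
  tr <- star_tree(20)
  traits <- data.frame(label = tr$tip.label,
                       value = rep(c(0, 100), each = 10) +
                         withr::with_seed(2, rnorm(20, sd = 1)),
                       group = rep(c("A", "B"), each = 10))
  res <- phyl_anova(tr, traits, n_sim = 300, seed = 1)
  expect_equal(res$p_phylo, 1 / 301)
  expect_equal(res$posthoc$p_raw, 1 / 301)
})

test_that("phylANOVA is invariant to shifting and rescaling the trait", {
  tr <- make_yule_tree(15, seed = 6)
  traits <- data.frame(label = tr$tip.label,
                       value = withr::with_seed(31, rnorm(15)),
                       group = rep(c("A", "B", "C"), each = 5))
  base <- phyl_anova(tr, traits, n_sim = 200, seed = 42)
  shifted <- traits; shifted$value <- shifted$value + 100
  scaled <- traits; scaled$value <- scaled$value * 7
  expect_equal(phyl_anova(tr, shifted, n_sim = 200, seed = 42)$p_phylo,
               base$p_phylo)
  expect_equal(phyl_anova(tr, scaled, n_sim = 200, seed = 42)$p_phylo,
               base$p_phylo)
  # seeded runs are bit-reproducible
  expect_identical(phyl_anova(tr, traits, n_sim = 200, seed = 42)$p_phylo,
                   base$p_phylo)
})

test_that("phylANOVA rejects unmatched labels, naming the offenders", {
  tr <- star_tree(4)
  traits <- data.frame(label = c("t1", "t2", "t3", "zz"),
                       value = 1:4, group = c("A", "A", "B", "B"))
  expect_error(phyl_anova(tr, traits, n_sim = 10), "zz")
  expect_error(phyl_anova(tr, traits, n_sim = 10), "t4")
})

test_that("the simulation ANOVA agrees with an independent reference
           implementation", {
  tr <- make_yule_tree(24, seed = 12)
  grp <- setNames(rep(c("A", "B", "C"), each = 8), tr$tip.label)
  traits <- make_trait_dataset(tr, grp, sigma2 = 1,
                               shifts = c(B = 1.2), seed = 13)
  mine <- phyl_anova(tr, traits, n_sim = 4000, seed = 3)
  x <- setNames(traits$value, traits$label)
  ref <- withr::with_seed(4, phytools::phylANOVA(tr, setNames(factor(traits$group),
                                                              traits$label),
                                                 x, nsim = 4000,
                                                 posthoc = FALSE, p.adj = "holm"))
  expect_equal(mine$f_observed, ref$F, tolerance = 1e-8)
  se <- sqrt(mine$p_phylo * (1 - mine$p_phylo) / 4000)
  expect_lt(abs(mine$p_phylo - ref$Pf), 3 * se + 2 / 4000 + 0.005)
})
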