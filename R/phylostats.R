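# Simulation-based phylogenetic ANOVA and the Brownian-motion machinery
# behind it.

check_trait_table <- function(traits) {
  stopifnot(is.data.frame(traits),
            all(c("label", "value", "group") %in% names(traits)))
  if (anyDuplicated(traits$label)) stop("trait labels must be unique", call. = FALSE)
  invisible(traits)
}

match_tree_traits <- function(tree, traits) {
  check_trait_table(traits)
  missing_tip <- setdiff(traits$label, tree$tip.label)
  missing_row <- setdiff(tree$tip.label, traits$label)
  if (length(missing_tip) || length(missing_row)) {
    stop("tree/trait label mismatch; traits without tips: [",
         paste(missing_tip, collapse = ", "), "]; tips without traits: [",
         paste(missing_row, collapse = ", "), "]", call. = FALSE)
  }
  traits[match(tree$tip.label, traits$label), , drop = FALSE]
}

#' Maximum-likelihood Brownian rate
#'
#' Estimates the Brownian-motion rate (sigma^2, trait units squared per unit
#' branch length) of a continuous trait on a rooted tree, by maximum
#' likelihood under the multivariate-normal model implied by the tree's
#' shared path-length covariance: the GLS root state is profiled out and
#' `sigma^2 = r' C^-1 r / n` for centred residuals `r`.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param traits data.frame `label, value, group` (group unused here), or a
#'   named numeric vector of tip values.
#' @return list with `sigma2` and the estimated root state `root`.
#' @export
fit_bm_rate <- function(tree, traits) {
  if (is.numeric(traits)) {
    traits <- data.frame(label = names(traits), value = unname(traits),
                         group = NA_character_)
  }
  traits <- match_tree_traits(tree, traits)
  C <- ape::vcv(tree)
  if (max(diag(C)) <= 0) stop("degenerate tree: zero depth", call. = FALSE)
  x <- traits$value
  one <- rep(1, length(x))
  Cinv_x <- solve(C, x)
  Cinv_1 <- solve(C, one)
  mu <- sum(Cinv_x) / sum(Cinv_1)
  r <- x - mu
  sigma2 <- drop(crossprod(r, solve(C, r))) / length(x)
  list(sigma2 = sigma2, root = mu)
}

#' Simulate Brownian trait evolution on a tree
#'
#' Draws tip trait vectors from the multivariate normal distribution with
#' mean `root` and covariance `sigma2` times the shared path-length matrix
#' of the tree. Reproducible under `seed` (the caller's RNG state is left
#' untouched).
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param sigma2 Brownian rate, `>= 0`.
#' @param nsim number of replicate tip vectors.
#' @param seed optional integer seed.
#' @param root root (ancestral) state.
#' @return numeric matrix, tips in rows (named), replicates in columns.
#' @export
simulate_bm <- function(tree, sigma2, nsim = 1, seed = NULL, root = 0) {
  stopifnot(sigma2 >= 0, nsim >= 1)
  n <- length(tree$tip.label)
  draw <- function() matrix(stats::rnorm(n * nsim), n, nsim)
  Z <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (sigma2 == 0) {
    X <- matrix(root, n, nsim)
  } else {
    C <- ape::vcv(tree)
    R <- chol(C)          # C = R'R
    X <- root + sqrt(sigma2) * crossprod(R, Z)
  }
  rownames(X) <- tree$tip.label
  X
}

#' One-way ANOVA F statistic
#'
#' The classical between/within mean-square ratio. Zero within-group
#' variance with unequal group means returns `Inf` (documented sentinel);
#' identical group means return 0.
#'
#' @param values numeric trait values.
#' @param groups group labels, at least two groups and residual df >= 1.
#' @return list with `f`, `df1`, `df2`.
#' @export
anova_f <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (n - k < 1) stop("residual degrees of freedom must be >= 1", call. = FALSE)
  gm <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  grand <- mean(values)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  f <- if (ssw == 0) { if (ssb == 0) 0 else Inf } else (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, df1 = k - 1L, df2 = n - k)
}

# Vectorized F and pairwise t statistics over the columns of X.
f_stats_matrix <- function(X, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- nrow(X)
  G <- stats::model.matrix(~ groups - 1)          # n x k indicator
  ng <- colSums(G)
  M <- crossprod(G, X) / ng                       # k x nsim group means
  grand <- colMeans(X)
  ssb <- colSums(ng * sweep(M, 2, grand, `-`)^2)
  sst <- colSums(sweep(X, 2, grand, `-`)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf), (ssb / (k - 1)) / (ssw / (n - k)))
  list(f = f, means = M, ssw = ssw, ng = ng, df2 = n - k)
}

t_stats_matrix <- function(fs, pairs, welch = FALSE, X = NULL, groups = NULL) {
  s2 <- fs$ssw / fs$df2                            # pooled residual MS
  out <- matrix(NA_real_, nrow(pairs), length(s2))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (welch) {
      gi <- levels(factor(groups))[i]; gj <- levels(factor(groups))[j]
      Xi <- X[groups == gi, , drop = FALSE]; Xj <- X[groups == gj, , drop = FALSE]
      vi <- apply(Xi, 2, stats::var); vj <- apply(Xj, 2, stats::var)
      out[r, ] <- (colMeans(Xi) - colMeans(Xj)) /
        sqrt(vi / nrow(Xi) + vj / nrow(Xj))
    } else {
      out[r, ] <- (fs$means[i, ] - fs$means[j, ]) /
        sqrt(s2 * (1 / fs$ng[i] + 1 / fs$ng[j]))
    }
  }
  out
}

#' Holm step-down adjustment of P-values
#'
#' Step-down multiplicative adjustment with monotonicity enforcement,
#' capped at 1: the i-th smallest raw P is multiplied by (n - i + 1), then
#' running maxima are taken in ascending order.
#'
#' @param p numeric vector of raw P-values in `[0, 1]`.
#' @return adjusted P-values in the original order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  adj[order(o)]
}

#' Simulation-based phylogenetic ANOVA
#'
#' Tests for group differences in a continuous trait while controlling for
#' phylogenetic relatedness: the observed one-way F statistic is referred to
#' a null distribution of F statistics obtained by simulating the trait
#' under Brownian motion on the tree (rate estimated once from the observed
#' data by [fit_bm_rate()]), with the group labels held fixed on the tips.
#' The P-value uses the add-one estimator
#' `(1 + #\{F_sim >= F_obs\}) / (n_sim + 1)`, so it can never be exactly
#' zero. Post hoc pairwise t statistics (pooled residual variance by
#' default, Welch by flag) are referred to the same simulated draws and
#' Holm-adjusted across pairs.
#'
#' @param tree an `ape::phylo` tree; tip labels must match `traits$label`.
#' @param traits data.frame `label, value, group`; at least two groups.
#' @param n_sim number of Brownian simulations (default 10000).
#' @param seed optional integer seed; recorded in the result.
#' @param posthoc compute the pairwise table.
#' @param welch use Welch (unpooled) pairwise t statistics.
#' @return object of class `phyl_anova`: list with `f_observed`, `df1`,
#'   `df2`, `p_phylo`, `n_sim`, `seed`, `sigma2` and `posthoc` (data.frame
#'   `group1, group2, t, p_raw, p_holm`).
#' @export
phyl_anova <- function(tree, traits, n_sim = 10000, seed = NULL,
                       posthoc = TRUE, welch = FALSE) {
  stopifnot(n_sim >= 1)
  traits <- match_tree_traits(tree, traits)
  groups <- factor(traits$group)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  obs <- f_stats_matrix(matrix(traits$value, ncol = 1), groups)
  fit <- fit_bm_rate(tree, traits)
  X <- simulate_bm(tree, fit$sigma2, nsim = n_sim, seed = seed)
  sim <- f_stats_matrix(X, groups)
  p_phylo <- (1 + sum(sim$f >= obs$f[1])) / (n_sim + 1)
  ph <- NULL
  if (posthoc) {
    lev <- levels(groups)
    pairs <- t(utils::combn(seq_along(lev), 2))
    t_obs <- t_stats_matrix(obs, pairs, welch,
                            X = matrix(traits$value, ncol = 1), groups = groups)
    t_sim <- t_stats_matrix(sim, pairs, welch, X = X, groups = groups)
    p_raw <- vapply(seq_len(nrow(pairs)), function(r) {
      (1 + sum(abs(t_sim[r, ]) >= abs(t_obs[r, 1]))) / (n_sim + 1)
    }, numeric(1))
    ph <- data.frame(group1 = lev[pairs[, 1]], group2 = lev[pairs[, 2]],
                     t = t_obs[, 1], p_raw = p_raw,
                     p_holm = holm_adjust(p_raw))
  }
  structure(list(f_observed = obs$f[1], df1 = nlevels(groups) - 1L,
                 df2 = nrow(traits) - nlevels(groups), p_phylo = p_phylo,
                 n_sim = n_sim, seed = seed, sigma2 = fit$sigma2,
                 posthoc = ph),
            class = "phyl_anova")
}

#' @export
print.phyl_anova <- function(x, ...) {
  cat(sprintf("phylANOVA: F_%d,%d = %.3g, p (phylogenetic, %d sims) = %.4g\n",
              x$df1, x$df2, x$f_observed, x$n_sim, x$p_phylo))
  if (!is.null(x$posthoc)) {
    cat("post hoc (Holm-adjusted):\n")
    print(x$posthoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Read a trait/group table from delimited text
#'
#' Columns `label, value, group`; separator auto-detected.
#'
#' @param path file path.
#' @return data.frame `label, value, group`.
#' @export
read_traits <- function(path) {
  sep <- detect_sep(readLines(path, n = 5))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  check_trait_table(df[, c("label", "value", "group")])
}
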