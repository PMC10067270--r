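# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: the Walsh oracle is the direct signed sum
# over genotypes, and the OLS oracle is stats::lm.

toy_landscape <- function() {
  as_landscape(data.frame(m1 = c(0, 1, 0, 1), m2 = c(0, 0, 1, 1),
                          fitness = c(1.0, 1.2, 1.1, 1.4)))
}

# direct-sum Walsh transform: coefficient of subset S is the mean over all
# genotypes of F(g) * prod_{i in S} (2 g_i - 1)
walsh_direct_oracle <- function(landscape) {
  G <- 2 * as.matrix(landscape[locus_names(landscape)]) - 1
  f <- landscape$fitness
  n <- ncol(G)
  subsets <- unlist(lapply(0:n, function(k) utils::combn(n, k, simplify = FALSE)),
                    recursive = FALSE)
  coef <- vapply(subsets, function(s) {
    chi <- if (length(s) == 0) rep(1, nrow(G)) else {
      apply(G[, s, drop = FALSE], 1, prod)
    }
    mean(f * chi)
  }, numeric(1))
  labels <- vapply(subsets, function(s) {
    paste(locus_names(landscape)[s], collapse = ",")
  }, character(1))
  stats::setNames(coef, labels)
}

ols_oracle <- function(points) {
  fit <- stats::lm(dF ~ F_B, data = points)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

random_landscape <- function(n, seed) {
  withr::with_seed(seed, {
    simulate_hoc(n, mean = stats::runif(1, -1, 2), sd = stats::runif(1, 0.1, 1))
  })
}

# complete pairwise-interaction landscape with random effects and a random
# subset of interacting pairs
random_pairwise_landscape <- function(n, seed, eps_scale = 0.2) {
  withr::with_seed(seed, {
    effects <- stats::setNames(stats::runif(n, -0.5, 0.5), paste0("m", 1:n))
    pairs <- utils::combn(n, 2)
    keep <- sample(ncol(pairs), max(1, rbinom(1, ncol(pairs), 0.5)))
    interactions <- data.frame(
      i = paste0("m", pairs[1, keep]),
      j = paste0("m", pairs[2, keep]),
      epsilon = stats::runif(length(keep), -eps_scale, eps_scale))
    simulate_pairwise(effects, interactions, baseline = stats::runif(1, 0, 2))
  })
}
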