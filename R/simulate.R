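#' Simulate an additive fitness landscape
#'
#' The maximally smooth regime: every mutation contributes a fixed additive
#' effect on the presence/absence (0/1) scale, so
#' `F(g) = baseline + sum_i delta_i * presence_i(g)`. Every mutation's
#' fitness effect is the same on every background and all global epistasis
#' scatters are flat.
#'
#' @param effects Named numeric vector of per-locus additive effects
#'   `delta_i`; names become the locus names (default `m1..mN`).
#' @param baseline Fitness of the all-absent genotype.
#' @return A complete [landscape][as_landscape] over `2^N` genotypes, in
#'   standard binary order (locus 1 varying fastest).
#' @examples
#' simulate_additive(c(m1 = 0.5), baseline = 1)  # fitness 1.0, 1.5
#' @export
simulate_additive <- function(effects, baseline = 0) {
  simulate_pairwise(effects, interactions = NULL, baseline = baseline)
}

#' Simulate a landscape with sparse pairwise interactions
#'
#' Additive effects on the 0/1 scale plus interaction terms added when
#' both members of a pair are present:
#' `F(g) = baseline + sum_i delta_i p_i + sum_(i<j) eps_ij p_i p_j`.
#' With a single interaction `eps_12` this is the sparse-epistasis
#' regime in which the global epistasis scatter of mutation 1 splits into
#' two clusters (backgrounds with and without mutation 2) offset
#' vertically by `eps_12` and horizontally by `delta_2`, giving a slope
#' proportional to `eps_12 / delta_2`.
#'
#' @inheritParams simulate_additive
#' @param interactions A data frame with columns `i`, `j` (locus names)
#'   and `epsilon`, or `NULL` for none. Pairs are unordered and must be
#'   unique.
#' @return A complete [landscape][as_landscape].
#' @examples
#' simulate_pairwise(c(m1 = 0.5, m2 = 0.3, m3 = 0.2),
#'                   interactions = data.frame(i = "m1", j = "m2",
#'                                             epsilon = 0.12),
#'                   baseline = 1)
#' @export
simulate_pairwise <- function(effects, interactions = NULL, baseline = 0) {
  effects <- validate_effects(effects)
  loci <- names(effects)
  n <- length(loci)
  G <- complete_genotypes(n, loci)
  f <- baseline + as.vector(G %*% effects)
  if (!is.null(interactions) && nrow(as.data.frame(interactions)) > 0L) {
    interactions <- as.data.frame(interactions)
    if (!all(c("i", "j", "epsilon") %in% names(interactions))) {
      abort_usage("`interactions` needs columns i, j, epsilon.")
    }
    ii <- match(as.character(interactions$i), loci)
    jj <- match(as.character(interactions$j), loci)
    if (anyNA(ii) || anyNA(jj)) {
      abort_usage("Interaction names unknown loci.")
    }
    if (any(ii == jj)) abort_usage("Self-interactions are not allowed.")
    key <- paste(pmin(ii, jj), pmax(ii, jj))
    if (anyDuplicated(key)) abort_usage("Duplicate interaction pair.")
    for (r in seq_along(ii)) {
      f <- f + interactions$epsilon[r] * G[, ii[r]] * G[, jj[r]]
    }
  }
  as_landscape(cbind(tibble::as_tibble(as.data.frame(G)), fitness = f))
}

#' Simulate a house-of-cards (maximally rugged) landscape
#'
#' Every genotype's fitness is drawn independently from
#' `Normal(mean, sd)`: the fitnesses of neighbouring genotypes are
#' uncorrelated, the idiosyncratic limit. Regression to the mean then
#' makes every mutation's fitness effect anticorrelate with background
#' fitness: across replicate landscapes the per-mutation OLS slopes
#' concentrate near -1, the coefficients of determination near 0.5 and
#' the intercepts near the distribution mean.
#'
#' @param n_loci Number of loci.
#' @param mean,sd Parameters of the normal fitness distribution.
#' @param seed Optional integer seed; when given the draw is made in an
#'   isolated RNG scope ([withr::with_seed()]) so the identical seed
#'   always yields the identical landscape and the caller's RNG stream is
#'   untouched. `NULL` draws from the current stream.
#' @param locus_names Locus names (default `m1..mN`).
#' @return A complete [landscape][as_landscape].
#' @examples
#' L <- simulate_hoc(6, mean = 1, sd = 0.2, seed = 42)
#' ge_fit(L)$slope  # all near -1
#' @export
simulate_hoc <- function(n_loci, mean = 1, sd = 0.2, seed = NULL,
                         locus_names = NULL) {
  if (!is.numeric(sd) || sd <= 0) abort_usage("`sd` must be > 0.")
  if (is.null(locus_names)) locus_names <- paste0("m", seq_len(n_loci))
  check_locus_names(locus_names)
  G <- complete_genotypes(n_loci, locus_names)
  draw <- function() stats::rnorm(2^n_loci, mean = mean, sd = sd)
  f <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  as_landscape(cbind(tibble::as_tibble(as.data.frame(G)), fitness = f))
}

#' Simulate a nonlinear transform of a latent additive trait
#'
#' Mutations contribute additively to a latent variable (fitness
#' potential) `lambda(g) = baseline + sum_i delta_i p_i`, and fitness is a
#' fixed nonlinear function of it: `F = exp(lambda)` (`convex_exp`) or
#' `F = 1 - exp(-lambda)` (`concave_saturating`). There is no microscopic
#' epistasis on the latent scale, yet both transforms generate exactly
#' linear global epistasis scatters (R^2 = 1) whose slope and intercept
#' are given in closed form by [latent_closed_form_slope()]: the concave
#' transform yields diminishing returns / decreasing costs, the convex one
#' increasing returns / increasing costs.
#'
#' @param effects Named numeric vector of latent-scale effects
#'   `delta_lambda_i`.
#' @param transform `"convex_exp"` or `"concave_saturating"`.
#' @param baseline Latent value of the all-absent genotype.
#' @return A complete [landscape][as_landscape].
#' @examples
#' L <- simulate_latent(c(m1 = 0.3, m2 = -0.2), transform = "convex_exp")
#' ge_fit(L)$r_squared  # exactly 1
#' @export
simulate_latent <- function(effects,
                            transform = c("convex_exp", "concave_saturating"),
                            baseline = 0) {
  transform <- match.arg(transform)
  effects <- validate_effects(effects)
  loci <- names(effects)
  G <- complete_genotypes(length(loci), loci)
  lambda <- baseline + as.vector(G %*% effects)
  f <- switch(transform,
              convex_exp = exp(lambda),
              concave_saturating = 1 - exp(-lambda))
  as_landscape(cbind(tibble::as_tibble(as.data.frame(G)), fitness = f))
}

#' Closed-form global epistasis line of the latent exponential transforms
#'
#' For `F = exp(lambda)` a mutation of latent effect `d` satisfies
#' `dF = (e^d - 1) F_B` exactly: slope `e^d - 1`, intercept 0. For
#' `F = 1 - exp(-lambda)`, `dF = (1 - e^(-d)) (1 - F_B)`: slope
#' `-(1 - e^(-d))`, intercept `1 - e^(-d)`. Simulated scatters from
#' [simulate_latent()] match these lines to machine precision.
#'
#' @param transform `"convex_exp"` or `"concave_saturating"`.
#' @param delta_lambda Latent-scale effect of the mutation.
#' @return A one-row tibble with columns `transform`, `delta_lambda`,
#'   `slope`, `intercept`.
#' @examples
#' latent_closed_form_slope("convex_exp", 0.3)  # slope exp(0.3) - 1
#' @export
latent_closed_form_slope <- function(transform = c("convex_exp",
                                                   "concave_saturating"),
                                     delta_lambda) {
  transform <- match.arg(transform)
  d <- delta_lambda
  if (transform == "convex_exp") {
    slope <- exp(d) - 1
    intercept <- rep(0, length(d))
  } else {
    slope <- -(1 - exp(-d))
    intercept <- 1 - exp(-d)
  }
  tibble::tibble(transform = transform, delta_lambda = d,
                 slope = slope, intercept = intercept)
}

# ---- helpers ---------------------------------------------------------------

validate_effects <- function(effects) {
  if (!is.numeric(effects) || length(effects) < 1L) {
    abort_usage("`effects` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(effects))) abort_usage("Effects must be finite.")
  if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
    names(effects) <- paste0("m", seq_along(effects))
  }
  check_locus_names(names(effects))
  effects
}

# all 2^n genotypes, locus 1 varying fastest (= least-significant bit)
complete_genotypes <- function(n, loci) {
  G <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  storage.mode(G) <- "integer"
  colnames(G) <- loci
  G
}
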