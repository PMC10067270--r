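test_that("ge_scatter enumerates one point per usable background", {
  toy <- toy_landscape()
  sc <- ge_scatter(toy, "m1")
  expect_equal(sc[order(sc$F_B), c("F_B", "dF")],
               tibble::tibble(F_B = c(1.0, 1.1), dF = c(0.2, 0.3)),
               ignore_attr = TRUE)

  L <- simulate_hoc(6, seed = 4)
  expect_equal(nrow(ge_scatter(L, "m3")), 32)

  # additive landscape: all dF identical (up to summation roundoff)
  La <- simulate_additive(c(a = 0.3, b = 0.2, c = -0.1), baseline = 1)
  expect_equal(ge_scatter(La, "a")$dF, rep(0.3, 4), tolerance = 1e-12)
})

test_that("ols_fit matches the lm oracle and handles degenerate scatters", {
  for (seed in 1:5) {
    L <- random_landscape(5, seed = seed + 30)
    pts <- ge_scatter(L, "m2")
    fit <- ols_fit(pts, "m2")
    oracle <- ols_oracle(pts)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-12)
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  }

  # exact line dF = 0.35 F_B
  pts <- tibble::tibble(F_B = c(1, 2, 3, 4), dF = 0.35 * c(1, 2, 3, 4))
  fit <- ols_fit(pts)
  expect_equal(fit$slope, 0.35)
  expect_equal(fit$r_squared, 1)

  # constant dF: slope 0, r_squared defined as 0
  pts <- tibble::tibble(F_B = c(1, 2, 3), dF = c(0.2, 0.2, 0.2))
  fit <- ols_fit(pts)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_false(fit$degenerate)

  # zero variance in F_B: flagged degenerate, not an error
  pts <- tibble::tibble(F_B = c(1, 1, 1), dF = c(0.1, 0.2, 0.3))
  expect_true(ols_fit(pts)$degenerate)

  expect_error(ols_fit(tibble::tibble(F_B = 1:2, dF = 1:2)), "3 points",
               class = "globalepi_data_error")
})

test_that("background-averaged effect and epistasis match their identities", {
  # additive mutation: effect constant regardless of focal
  La <- simulate_additive(c(a = 0.1, b = 0.3, c = -0.2), baseline = 1)
  expect_equal(avg_background_effect(La, "b", "a")$value, 0.3)
  expect_equal(avg_background_effect(La, "b", "c")$value, 0.3)
  expect_equal(avg_pairwise_epistasis(La, "a", "b")$value, 0)

  # toy landscape: single quartet
  eps <- avg_pairwise_epistasis(toy_landscape(), "m1", "m2")
  expect_equal(eps$value, 0.1)
  expect_equal(eps$n_used, 1L)

  # single-interaction regime: <dF_2>_B(1) is exactly delta_2
  Lp <- simulate_pairwise(c(m1 = 0.5, m2 = 0.3, m3 = 0.2),
                          data.frame(i = "m1", j = "m2", epsilon = 0.12),
                          baseline = 1)
  expect_equal(avg_background_effect(Lp, "m2", "m1")$value, 0.3)
  expect_equal(avg_pairwise_epistasis(Lp, "m1", "m2")$value, 0.12)

  # Walsh identities on random pairwise landscapes:
  # <eps_ij> = 4 f_ij and <dF_j>_B(i) = 2 (f_j - f_ij)
  for (seed in 1:6) {
    L <- random_pairwise_landscape(sample(4:6, 1), seed = seed * 13)
    w <- to_walsh(L, max_order = 2)
    loci <- locus_names(L)
    pick <- withr::with_seed(seed, sample(length(loci), 2))
    i <- loci[pick[1]]; j <- loci[pick[2]]
    f_j <- w$coefficient[w$subset == j]
    pair <- paste(loci[sort(match(c(i, j), loci))], collapse = ",")
    f_ij <- w$coefficient[w$subset == pair]
    expect_equal(avg_pairwise_epistasis(L, i, j)$value, 4 * f_ij,
                 tolerance = 1e-10)
    expect_equal(avg_background_effect(L, j, i)$value, 2 * (f_j - f_ij),
                 tolerance = 1e-10)
  }

  # incomplete landscapes report the usable count
  Li <- as_landscape(tibble::as_tibble(Lp)[-1, ])  # drop genotype 000
  eff <- avg_background_effect(Li, "m2", "m1")
  expect_equal(eff$n_used, 1L)  # only background 001 remains usable
  expect_equal(eff$value, 0.3)
})

test_that("predicted slope equals OLS exactly for focal-only interactions", {
  # worked example: delta = 0.5/0.3/0.2, single eps_12 = 0.12;
  # expected slope eps12*d2/(d2^2+d3^2) = 0.036/0.13
  L <- simulate_pairwise(c(m1 = 0.5, m2 = 0.3, m3 = 0.2),
                         data.frame(i = "m1", j = "m2", epsilon = 0.12),
                         baseline = 1)
  dec <- decompose_slope(L, "m1")
  fit <- ols_fit(ge_scatter(L, "m1"), "m1")
  expect_equal(dec$predicted_slope, 0.036 / 0.13, tolerance = 1e-12)
  expect_equal(fit$slope, ols_oracle(ge_scatter(L, "m1"))$slope,
               tolerance = 1e-12)
  expect_equal(dec$predicted_slope, fit$slope, tolerance = 1e-13)
  expect_equal(dec$predicted_intercept, fit$intercept, tolerance = 1e-13)

  # random landscapes whose interactions all involve the focal locus
  for (seed in 1:5) {
    n <- 5
    eff <- withr::with_seed(seed, stats::setNames(stats::runif(n, -0.5, 0.5),
                                                  paste0("m", 1:n)))
    ints <- withr::with_seed(seed + 100, data.frame(
      i = "m1", j = paste0("m", 2:n),
      epsilon = stats::runif(n - 1, -0.3, 0.3)))
    L <- simulate_pairwise(eff, ints, baseline = 1)
    dec <- decompose_slope(L, "m1")
    fit <- ols_fit(ge_scatter(L, "m1"), "m1")
    expect_equal(dec$predicted_slope, fit$slope, tolerance = 1e-12)
  }
})

test_that("averages and walsh modes agree; omega sums to one", {
  for (seed in 1:6) {
    L <- random_pairwise_landscape(sample(4:6, 1), seed = seed * 17)
    for (lc in locus_names(L)[1:2]) {
      da <- decompose_slope(L, lc, mode = "averages")
      dw <- decompose_slope(L, lc, mode = "walsh")
      expect_equal(da$predicted_slope, dw$predicted_slope, tolerance = 1e-10)
      expect_equal(da$partners$avg_epistasis, dw$partners$avg_epistasis,
                   tolerance = 1e-10)
      expect_equal(sum(da$partners$omega), 1, tolerance = 1e-12)
    }
  }
})

test_that("prediction converges to OLS as interactions shrink", {
  err_at <- function(scale) {
    errs <- vapply(1:5, function(seed) {
      L <- random_pairwise_landscape(5, seed = 1000 + seed,
                                     eps_scale = scale)
      dec <- decompose_slope(L, "m1")
      fit <- ols_fit(ge_scatter(L, "m1"), "m1")
      abs(dec$predicted_slope - fit$slope)
    }, numeric(1))
    mean(errs)
  }
  errors <- vapply(c(0.2, 0.02, 0.002), err_at, numeric(1))
  expect_true(all(diff(errors) < 0))
  expect_lt(errors[3], 1e-4)
})

test_that("sign rule: aligned products give positive slopes, dominant negative flips", {
  # all products positive -> positive predicted slope
  L <- simulate_pairwise(
    c(m1 = 0.2, m2 = 0.3, m3 = 0.25, m4 = 0.4),
    data.frame(i = "m1", j = c("m2", "m3", "m4"),
               epsilon = c(0.05, 0.04, 0.06)), baseline = 1)
  dec <- decompose_slope(L, "m1")
  expect_true(all(dec$partners$product > 0))
  expect_gt(dec$predicted_slope, 0)

  # one strongly negative product outweighing three positive ones
  L2 <- simulate_pairwise(
    c(m1 = 0.2, m2 = 0.3, m3 = 0.1, m4 = 0.1, m5 = 0.1),
    data.frame(i = "m1", j = c("m2", "m3", "m4", "m5"),
               epsilon = c(-0.3, 0.02, 0.02, 0.02)), baseline = 1)
  dec2 <- decompose_slope(L2, "m1")
  expect_equal(sum(dec2$partners$product > 0), 3)
  expect_lt(dec2$predicted_slope, 0)

  # additive landscape: every decomposition is all-zero products, slope 0
  La <- simulate_additive(c(a = 0.3, b = 0.2, c = -0.1), baseline = 1)
  for (lc in locus_names(La)) {
    d <- decompose_slope(La, lc)
    expect_equal(d$partners$product, rep(0, 2))
    expect_equal(d$predicted_slope, 0)
  }
})

test_that("partner with zero average effect keeps its product, loses beta", {
  # m2 has delta_2 = 0 but interacts with m1
  L <- simulate_pairwise(c(m1 = 0.3, m2 = 0, m3 = 0.2),
                         data.frame(i = "m1", j = "m2", epsilon = 0.1),
                         baseline = 1)
  dec <- decompose_slope(L, "m1")
  row <- dec$partners[dec$partners$partner == "m2", ]
  expect_true(is.na(row$beta))
  expect_equal(row$product, 0)          # eps * 0
  expect_equal(row$avg_epistasis, 0.1)  # still reported
  expect_false(dec$degenerate)

  # all partner effects zero -> degenerate, no defined slope
  L0 <- simulate_pairwise(c(m1 = 0.3, m2 = 0, m3 = 0),
                          data.frame(i = "m1", j = "m2", epsilon = 0.1),
                          baseline = 1)
  d0 <- decompose_slope(L0, "m1")
  expect_true(d0$degenerate)
  expect_true(is.na(d0$predicted_slope))
})

test_that("decompose_report joins prediction and least squares per focal", {
  L <- random_pairwise_landscape(5, seed = 202)
  rep_all <- decompose_report(L)
  expect_equal(nrow(rep_all), 5 * 4)
  expect_named(rep_all, c("focal", "partner", "avg_epistasis",
                          "n_epistasis_terms", "avg_effect",
                          "n_effect_terms", "omega", "beta", "product",
                          "predicted_slope", "predicted_intercept",
                          "ols_slope", "ols_intercept"))
  # per-focal omega sums to 1 and both slope estimates are close
  sums <- tapply(rep_all$omega, rep_all$focal, sum)
  expect_equal(as.vector(sums), rep(1, 5), tolerance = 1e-12)
  expect_lt(max(abs(rep_all$predicted_slope - rep_all$ols_slope)), 0.5)
})

test_that("classification follows effect sign and slope significance", {
  # additive -> flat everywhere
  La <- simulate_additive(c(a = 0.3, b = -0.2, c = 0.1), baseline = 1)
  fits <- ge_fit(La)
  expect_true(all(fits$classification == "flat"))
  expect_true(all(abs(fits$slope) < 1e-12))

  # concave latent, lambda-beneficial -> diminishing returns;
  # lambda-deleterious -> decreasing costs
  Lc <- simulate_latent(c(m1 = 0.4, m2 = -0.3, m3 = 0.2),
                        transform = "concave_saturating", baseline = 0.5)
  fc <- ge_fit(Lc)
  expect_equal(fc$classification[fc$focal == "m1"], "diminishing returns")
  expect_equal(fc$classification[fc$focal == "m2"], "decreasing costs")

  # convex latent -> increasing returns / increasing costs
  Lv <- simulate_latent(c(m1 = 0.4, m2 = -0.3, m3 = 0.2),
                        transform = "convex_exp", baseline = 0.5)
  fv <- ge_fit(Lv)
  expect_equal(fv$classification[fv$focal == "m1"], "increasing returns")
  expect_equal(fv$classification[fv$focal == "m2"], "increasing costs")

  # mixed-sign effects on a rugged landscape
  Lh <- simulate_hoc(5, seed = 9)
  fh <- ge_fit(Lh)
  expect_true(all(fh$classification %in%
                    c("mixed-sign", "flat", "diminishing returns",
                      "increasing returns", "increasing costs",
                      "decreasing costs")))
  expect_true(any(fh$classification == "mixed-sign"))

  # degenerate fit -> flat
  pts <- tibble::tibble(F_B = c(1, 1, 1), dF = c(0.1, 0.2, 0.3))
  expect_equal(classify_pattern(ols_fit(pts)), "flat")

  # loci with < 3 usable backgrounds are flagged, not dropped
  inc <- as_landscape(data.frame(m1 = c(0, 1, 0), m2 = c(0, 0, 1),
                                 fitness = c(1.0, 1.2, 1.1)))
  fi <- ge_fit(inc)
  expect_true(all(fi$degenerate))
  expect_true(all(is.na(fi$slope)))
})

test_that("tidy, glance and autoplot methods work on fitted objects", {
  L <- simulate_hoc(4, seed = 21)
  fit <- ols_fit(ge_scatter(L, "m1"), "m1")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "F_B"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$r_squared, fit$r_squared)
  expect_s3_class(autoplot(fit), "ggplot")

  dec <- decompose_slope(L, "m1")
  expect_equal(nrow(tidy(dec)), 3)
  expect_equal(glance(dec)$predicted_slope, dec$predicted_slope)
  expect_s3_class(autoplot(dec), "ggplot")
  expect_s3_class(autoplot(to_walsh(L)), "ggplot")
  expect_s3_class(plot_global_epistasis(L), "ggplot")
})
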