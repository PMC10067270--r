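#' Global epistasis scatter of a focal mutation
#'
#' One point per background in the focal mutation's background set: the
#' background fitness `F_B` against the fitness effect
#' `dF = F(B+i) - F(B)`. A systematic dependence of `dF` on `F_B` is the
#' signature of global epistasis; an additive landscape gives a flat
#' scatter.
#'
#' @param landscape A [landscape][as_landscape].
#' @param focal Locus name (or index) of the focal mutation.
#' @return A tibble with columns `background` (bit-string key), `F_B` and
#'   `dF`.
#' @examples
#' toy <- as_landscape(data.frame(m1 = c(0, 1, 0, 1), m2 = c(0, 0, 1, 1),
#'                                fitness = c(1.0, 1.2, 1.1, 1.4)))
#' ge_scatter(toy, "m1")
#' @export
ge_scatter <- function(landscape, focal) {
  i <- locus_index(landscape, focal)
  G <- genotype_matrix(landscape)
  id <- genotype_id(G)
  k <- which(G[, i] == 0L)
  partner <- match(id[k] + 2^(i - 1L), id)
  ok <- !is.na(partner)
  if (!any(ok)) {
    abort_data(sprintf("No usable background for focal locus '%s'.",
                       locus_names(landscape)[i]))
  }
  k <- k[ok]
  f <- landscape$fitness
  tibble::tibble(
    background = genotype_key_matrix(G[k, , drop = FALSE]),
    F_B = f[k],
    dF = f[partner[ok]] - f[k]
  )
}

#' Least-squares fit of a global epistasis scatter
#'
#' Ordinary least squares of `dF` on `F_B`. `r_squared` is the squared
#' Pearson correlation of the points (identical to the OLS coefficient of
#' determination for simple regression); a scatter with constant `dF`
#' reports `r_squared = 0`. A scatter with zero variance in `F_B` has no
#' defined slope and is returned flagged `degenerate` rather than failing.
#'
#' @param points A data frame with columns `F_B` and `dF` (as returned by
#'   [ge_scatter()]).
#' @param focal Optional focal-locus label carried into the result.
#' @return A `ge_ols` object: a list with elements `focal`, `points`,
#'   `n_points`, `slope`, `intercept`, `r_squared`, `slope_se`, `p_value`,
#'   `mean_dF`, `mean_F_B` and `degenerate`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' L <- simulate_hoc(4, mean = 1, sd = 0.2, seed = 1)
#' fit <- ols_fit(ge_scatter(L, "m1"), focal = "m1")
#' glance(fit)
#' @export
ols_fit <- function(points, focal = NA_character_) {
  x <- points$F_B
  y <- points$dF
  n <- length(x)
  if (n < 3L) abort_data("At least 3 points are required for a fit.")
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (sxx == 0) {
    res <- list(focal = focal, points = tibble::as_tibble(points),
                n_points = n, slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, slope_se = NA_real_,
                p_value = NA_real_, mean_dF = my, mean_F_B = mx,
                degenerate = TRUE)
    class(res) <- "ge_ols"
    return(res)
  }
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r2 <- if (syy == 0) 0 else (sxy * sxy) / (sxx * syy)
  sse <- max(syy - slope * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  p <- if (se == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  res <- list(focal = focal, points = tibble::as_tibble(points),
              n_points = n, slope = slope, intercept = intercept,
              r_squared = r2, slope_se = se, p_value = p,
              mean_dF = my, mean_F_B = mx, degenerate = FALSE)
  class(res) <- "ge_ols"
  res
}

#' @export
print.ge_ols <- function(x, ...) {
  cat(sprintf(
    "# Global epistasis fit%s: n = %d\n",
    if (is.na(x$focal)) "" else paste0(" (focal ", x$focal, ")"), x$n_points))
  if (x$degenerate) {
    cat("  degenerate scatter: no variance in F_B, slope undefined\n")
  } else {
    cat(sprintf("  dF = %.6g %+.6g * F_B   (R^2 = %.4g)\n",
                x$intercept, x$slope, x$r_squared))
  }
  invisible(x)
}

#' Classify the global epistasis pattern of a fitted mutation
#'
#' The mutation is called beneficial or deleterious from the sign of its
#' fitness effects when all `dF` share a sign (zeros are compatible with
#' either call), and `mixed-sign` otherwise. The slope is called nonzero
#' when the two-sided t-test on the OLS slope rejects zero at level
#' `alpha`; a non-rejected (or degenerate) slope gives `flat`. The four
#' sign combinations map to the canonical pattern names: a beneficial
#' mutation whose effect shrinks in fitter backgrounds shows
#' `diminishing returns`, and so on.
#'
#' @param fit A `ge_ols` object from [ols_fit()].
#' @param alpha Significance level for the slope test (default 0.05).
#' @return One of `"diminishing returns"`, `"increasing returns"`,
#'   `"increasing costs"`, `"decreasing costs"`, `"flat"`, `"mixed-sign"`.
#' @export
classify_pattern <- function(fit, alpha = 0.05) {
  y <- fit$points$dF
  all_nonneg <- all(y >= 0)
  all_nonpos <- all(y <= 0)
  if (!all_nonneg && !all_nonpos) return("mixed-sign")
  if (fit$degenerate || is.na(fit$p_value) || fit$p_value > alpha ||
      fit$slope == 0) {
    return("flat")
  }
  beneficial <- all_nonneg && any(y > 0)
  deleterious <- all_nonpos && any(y < 0)
  if (!beneficial && !deleterious) return("flat")  # all effects exactly 0
  if (beneficial) {
    if (fit$slope < 0) "diminishing returns" else "increasing returns"
  } else {
    if (fit$slope < 0) "increasing costs" else "decreasing costs"
  }
}

#' Global epistasis fits for every mutation in a landscape
#'
#' Builds the `(F_B, dF)` scatter of each locus, fits it by ordinary least
#' squares and classifies its pattern. Loci with fewer than three usable
#' backgrounds are reported with `NA` estimates and flagged rather than
#' dropped.
#'
#' @param landscape A [landscape][as_landscape].
#' @param alpha Significance level for the slope test used in
#'   classification.
#' @param bonferroni Apply a Bonferroni correction across loci to the
#'   classification test (off by default; the per-mutation tests are
#'   reported uncorrected).
#' @return A tibble with one row per locus: `focal`, `n_points`, `slope`,
#'   `intercept`, `r_squared`, `slope_se`, `p_value`, `mean_dF`,
#'   `classification`, `degenerate`.
#' @examples
#' L <- simulate_hoc(5, mean = 1, sd = 0.2, seed = 7)
#' ge_fit(L)
#' @export
ge_fit <- function(landscape, alpha = 0.05, bonferroni = FALSE) {
  loci <- locus_names(landscape)
  eff_alpha <- if (bonferroni) alpha / length(loci) else alpha
  rows <- purrr::map(loci, function(lc) {
    pts <- tryCatch(ge_scatter(landscape, lc), error = function(e) NULL)
    if (is.null(pts) || nrow(pts) < 3L) {
      return(tibble::tibble(
        focal = lc, n_points = if (is.null(pts)) 0L else nrow(pts),
        slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
        slope_se = NA_real_, p_value = NA_real_,
        mean_dF = if (is.null(pts)) NA_real_ else mean(pts$dF),
        classification = NA_character_, degenerate = TRUE))
    }
    fit <- ols_fit(pts, focal = lc)
    tibble::tibble(
      focal = lc, n_points = fit$n_points, slope = fit$slope,
      intercept = fit$intercept, r_squared = fit$r_squared,
      slope_se = fit$slope_se, p_value = fit$p_value, mean_dF = fit$mean_dF,
      classification = classify_pattern(fit, eff_alpha),
      degenerate = fit$degenerate)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  out
}

# ---- background-averaged quantities ---------------------------------------

#' Background-averaged fitness effect of a partner mutation
#'
#' The mean fitness effect of mutation `j` over the background set of a
#' focal mutation `i`: the average of `F(B+j) - F(B)` across every
#' measured background lacking both `i` and `j`. This is the average
#' horizontal shift that carrying `j` induces in the background fitness of
#' `i`'s scatter. On a complete landscape it equals `2 (f_j - f_ij)` in
#' Walsh coefficients.
#'
#' @param landscape A [landscape][as_landscape].
#' @param j Partner locus.
#' @param focal Focal locus (distinct from `j`).
#' @return A one-row tibble with columns `value` and `n_used` (number of
#'   measurable background pairs averaged).
#' @export
avg_background_effect <- function(landscape, j, focal) {
  jj <- locus_index(landscape, j)
  ii <- locus_index(landscape, focal)
  if (ii == jj) abort_data("Partner and focal locus must differ.")
  v <- avg_effect_impl(landscape, jj, ii)
  if (v[["n"]] == 0L) {
    abort_data(sprintf(
      "No measurable background for effect of '%s' on B(%s).",
      locus_names(landscape)[jj], locus_names(landscape)[ii]))
  }
  tibble::tibble(value = v[["value"]], n_used = as.integer(v[["n"]]))
}

avg_effect_impl <- function(landscape, jj, ii) {
  G <- genotype_matrix(landscape)
  id <- genotype_id(G)
  k <- which(G[, ii] == 0L & G[, jj] == 0L)
  pos <- match(id[k] + 2^(jj - 1L), id)
  ok <- !is.na(pos)
  n <- sum(ok)
  value <- if (n == 0L) NA_real_ else {
    mean(landscape$fitness[pos[ok]] - landscape$fitness[k[ok]])
  }
  c(value = value, n = n)
}

#' Background-averaged pairwise epistasis
#'
#' The mean four-corner epistasis between mutations `i` and `j` over every
#' measured background lacking both: the average of
#' `F(B+i+j) - F(B+i) - F(B+j) + F(B)`. This is the average vertical shift
#' that carrying `j` induces in `i`'s fitness effect. On a complete
#' landscape it equals `4 f_ij` in Walsh coefficients.
#'
#' @param landscape A [landscape][as_landscape].
#' @param i,j Distinct loci.
#' @return A one-row tibble with columns `value` and `n_used` (number of
#'   complete four-corner quartets averaged).
#' @export
avg_pairwise_epistasis <- function(landscape, i, j) {
  ii <- locus_index(landscape, i)
  jj <- locus_index(landscape, j)
  if (ii == jj) abort_data("Loci i and j must be distinct.")
  v <- avg_epistasis_impl(landscape, ii, jj)
  if (v[["n"]] == 0L) {
    abort_data(sprintf("No complete four-corner quartet for loci '%s','%s'.",
                       locus_names(landscape)[ii], locus_names(landscape)[jj]))
  }
  tibble::tibble(value = v[["value"]], n_used = as.integer(v[["n"]]))
}

avg_epistasis_impl <- function(landscape, ii, jj) {
  G <- genotype_matrix(landscape)
  id <- genotype_id(G)
  wi <- 2^(ii - 1L)
  wj <- 2^(jj - 1L)
  k <- which(G[, ii] == 0L & G[, jj] == 0L)
  p_i <- match(id[k] + wi, id)
  p_j <- match(id[k] + wj, id)
  p_ij <- match(id[k] + wi + wj, id)
  ok <- !is.na(p_i) & !is.na(p_j) & !is.na(p_ij)
  n <- sum(ok)
  value <- if (n == 0L) NA_real_ else {
    f <- landscape$fitness
    mean(f[p_ij[ok]] - f[p_i[ok]] - f[p_j[ok]] + f[k[ok]])
  }
  c(value = value, n = n)
}

# ---- slope decomposition ---------------------------------------------------

#' Decompose a global epistasis slope into per-partner contributions
#'
#' Predicts the slope of the `dF`-vs-`F_B` regression of a focal mutation
#' `i` from microscopic quantities, and attributes it to the other loci.
#' For each partner `j`, the background-averaged pairwise epistasis
#' `<eps_ij>` ([avg_pairwise_epistasis()]) is the average vertical shift
#' carrying `j` induces in `dF_i`, and the background-averaged effect
#' `<dF_j>` ([avg_background_effect()]) is the average horizontal shift it
#' induces in `F_B`. The predicted slope is
#' \deqn{b_i = \frac{\sum_{j \ne i} \langle\varepsilon_{ij}\rangle
#'   \langle\delta F_j\rangle}{\sum_{j \ne i} \langle\delta F_j\rangle^2},}
#' equivalently `sum_j omega_ij * beta_ij` with weight
#' `omega_ij = <dF_j>^2 / sum <dF_j>^2` and per-partner slope contribution
#' `beta_ij = <eps_ij> / <dF_j>`. The predicted intercept is
#' `a_i = mean(dF) - b_i * mean(F_B)` over the focal scatter. In `walsh`
#' mode the same slope is computed from order-<=2 Walsh coefficients as
#' `b_i = 2 sum f_ij (f_j - f_ij) / sum (f_j - f_ij)^2`; on complete
#' landscapes the two modes agree exactly.
#'
#' A partner with zero average effect but nonzero average epistasis has an
#' undefined `beta` (reported `NA`); its product term still enters the
#' authoritative sum form. If every partner's average effect is zero the
#' slope is undefined and the result is flagged degenerate.
#'
#' @param landscape A [landscape][as_landscape].
#' @param focal Focal locus.
#' @param mode `"averages"` (background-averaged quantities, works on
#'   incomplete landscapes) or `"walsh"` (order-2 Walsh coefficients,
#'   requires a complete landscape).
#' @return A `slope_decomposition` object: a list with `focal`, `mode`,
#'   `partners` (a tibble with one row per partner: `avg_epistasis`,
#'   `n_epistasis_terms`, `avg_effect`, `n_effect_terms`, `omega`, `beta`,
#'   `product`), `predicted_slope`, `predicted_intercept`, `degenerate`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' L <- simulate_pairwise(c(m1 = 0.5, m2 = 0.3, m3 = 0.2),
#'                        interactions = data.frame(i = "m1", j = "m2",
#'                                                  epsilon = 0.12),
#'                        baseline = 1)
#' dec <- decompose_slope(L, "m1")
#' dec$predicted_slope  # 0.036 / 0.13
#' @export
decompose_slope <- function(landscape, focal,
                            mode = c("averages", "walsh")) {
  mode <- match.arg(mode)
  ii <- locus_index(landscape, focal)
  loci <- locus_names(landscape)
  partners_idx <- setdiff(seq_along(loci), ii)
  if (mode == "walsh") {
    if (!is_complete(landscape)) {
      abort_data("walsh-mode decomposition requires a complete landscape.")
    }
    w <- to_walsh(landscape, max_order = min(2L, n_loci(landscape)))
    n_bg <- 2^(n_loci(landscape) - 2L)
    rows <- purrr::map(partners_idx, function(jj) {
      f_j <- w$coefficient[w$subset == loci[jj]]
      pair <- paste(loci[sort(c(ii, jj))], collapse = ",")
      f_ij <- w$coefficient[w$subset == pair]
      tibble::tibble(partner = loci[jj],
                     avg_epistasis = 4 * f_ij,
                     n_epistasis_terms = as.integer(n_bg),
                     avg_effect = 2 * (f_j - f_ij),
                     n_effect_terms = as.integer(n_bg))
    })
  } else {
    rows <- purrr::map(partners_idx, function(jj) {
      e <- avg_epistasis_impl(landscape, ii, jj)
      d <- avg_effect_impl(landscape, jj, ii)
      tibble::tibble(partner = loci[jj],
                     avg_epistasis = e[["value"]],
                     n_epistasis_terms = as.integer(e[["n"]]),
                     avg_effect = d[["value"]],
                     n_effect_terms = as.integer(d[["n"]]))
    })
  }
  partners <- dplyr::bind_rows(rows)
  usable <- !is.na(partners$avg_epistasis) & !is.na(partners$avg_effect)
  if (!any(usable)) {
    abort_data(sprintf("No partner of '%s' has computable terms.", loci[ii]))
  }
  d2 <- partners$avg_effect^2
  denom <- sum(d2[usable])
  partners$product <- partners$avg_epistasis * partners$avg_effect
  degenerate <- denom == 0
  partners$omega <- if (degenerate) NA_real_ else {
    ifelse(usable, d2 / denom, NA_real_)
  }
  partners$beta <- ifelse(usable & partners$avg_effect != 0,
                          partners$avg_epistasis / partners$avg_effect,
                          NA_real_)
  predicted_slope <- if (degenerate) NA_real_ else {
    sum(partners$product[usable]) / denom
  }
  sc <- ge_scatter(landscape, loci[ii])
  predicted_intercept <- if (degenerate) NA_real_ else {
    mean(sc$dF) - predicted_slope * mean(sc$F_B)
  }
  partners <- partners[c("partner", "avg_epistasis", "n_epistasis_terms",
                         "avg_effect", "n_effect_terms", "omega", "beta",
                         "product")]
  res <- list(focal = loci[ii], mode = mode, partners = partners,
              predicted_slope = predicted_slope,
              predicted_intercept = predicted_intercept,
              degenerate = degenerate)
  class(res) <- "slope_decomposition"
  res
}

#' @export
print.slope_decomposition <- function(x, ...) {
  cat(sprintf("# Slope decomposition for focal '%s' (%s mode)\n",
              x$focal, x$mode))
  if (x$degenerate) {
    cat("  degenerate: all partner average effects are zero\n")
  } else {
    cat(sprintf("  predicted slope %.6g, intercept %.6g\n",
                x$predicted_slope, x$predicted_intercept))
  }
  print(x$partners)
  invisible(x)
}

#' Joint decomposition and least-squares report
#'
#' For each focal mutation, compares the microscopic slope prediction of
#' [decompose_slope()] with the direct least-squares fit of the scatter:
#' one row per (focal, partner) pair carrying the partner-level averages
#' alongside both slope/intercept estimates.
#'
#' @param landscape A [landscape][as_landscape].
#' @param focal A locus name, or `NULL` (default) for every locus.
#' @param mode Passed to [decompose_slope()].
#' @return A tibble with columns `focal`, `partner`, `avg_epistasis`,
#'   `n_epistasis_terms`, `avg_effect`, `n_effect_terms`, `omega`, `beta`,
#'   `product`, `predicted_slope`, `predicted_intercept`, `ols_slope`,
#'   `ols_intercept`.
#' @export
decompose_report <- function(landscape, focal = NULL,
                             mode = c("averages", "walsh")) {
  mode <- match.arg(mode)
  foci <- if (is.null(focal)) locus_names(landscape) else focal
  out <- purrr::map_dfr(foci, function(lc) {
    dec <- decompose_slope(landscape, lc, mode = mode)
    pts <- ge_scatter(landscape, lc)
    fit <- if (nrow(pts) >= 3L) ols_fit(pts, focal = lc) else NULL
    dplyr::mutate(dec$partners,
                  focal = dec$focal,
                  predicted_slope = dec$predicted_slope,
                  predicted_intercept = dec$predicted_intercept,
                  ols_slope = if (is.null(fit)) NA_real_ else fit$slope,
                  ols_intercept = if (is.null(fit)) NA_real_ else fit$intercept)
  })
  dplyr::select(out, "focal", "partner", "avg_epistasis", "n_epistasis_terms",
                "avg_effect", "n_effect_terms", "omega", "beta", "product",
                "predicted_slope", "predicted_intercept", "ols_slope",
                "ols_intercept")
}
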