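#' Walsh (Fourier) expansion of a fitness landscape
#'
#' Any complete landscape over N binary loci can be written exactly as
#' \deqn{F = \bar{F} + \sum_i f_i x_i + \sum_{j>i} f_{ij} x_i x_j + \dots}
#' with the +/-1 genotype encoding `x_i = 2 * presence_i - 1`. The
#' coefficient of a locus subset S is the mean over all genotypes of
#' `F(g) * prod_{i in S} x_i(g)` (the uniform-measure orthonormal basis on
#' `{-1,+1}^N`), computed here with the fast Walsh-Hadamard butterfly.
#' Under this normalization the background-averaged identities
#' `f_ij = <eps_ij>/4` and `f_j - f_ij = <dF_j>/2` used by
#' [decompose_slope()] hold exactly on complete landscapes.
#'
#' For an incomplete landscape the exact transform is undefined;
#' `estimate = TRUE` instead fits coefficients up to `max_order` by least
#' squares over the measured genotypes, and the result is labelled an
#' estimate in `attr(, "method")`.
#'
#' @param landscape A [landscape][as_landscape].
#' @param max_order Largest subset size to retain (default `N`).
#' @param estimate Fit by least squares when the landscape is incomplete.
#' @return A `walsh_expansion`: a tibble with columns `subset` (comma-joined
#'   locus names, `""` for the mean term), `order` and `coefficient`,
#'   carrying the locus names and transform method as attributes. The mean
#'   term is the `order == 0` row.
#' @examples
#' toy <- as_landscape(data.frame(m1 = c(0, 1, 0, 1), m2 = c(0, 0, 1, 1),
#'                                fitness = c(1.0, 1.2, 1.1, 1.4)))
#' to_walsh(toy)  # mean 1.175, f1 0.125, f2 0.075, f12 0.025
#' @export
to_walsh <- function(landscape, max_order = NULL, estimate = FALSE) {
  loci <- locus_names(landscape)
  n <- length(loci)
  if (is.null(max_order)) max_order <- n
  if (max_order < 1L || max_order > n) {
    abort_usage(sprintf("max_order must be in 1..%d.", n))
  }
  if (!is_complete(landscape)) {
    if (!estimate) {
      abort_data(paste0("Landscape is incomplete (", nrow(landscape), "/",
                        2^n, " genotypes); the exact transform requires all ",
                        "genotypes. Use estimate = TRUE for a least-squares fit."))
    }
    return(walsh_ls_estimate(landscape, max_order))
  }
  G <- genotype_matrix(landscape)
  f <- landscape$fitness[order(genotype_id(G))]
  coef <- fwht_forward(f, n)
  subsets <- subset_index(n)
  keep <- subsets$order <= max_order
  tbl <- tibble::tibble(
    subset = subset_labels(subsets$members[keep], loci),
    order = subsets$order[keep],
    coefficient = coef[keep]
  )
  tbl <- tbl[order(tbl$order), ]
  new_walsh(tbl, loci, max_order, method = "exact")
}

new_walsh <- function(tbl, locus_names, max_order, method) {
  structure(tibble::as_tibble(tbl),
            locus_names = locus_names,
            max_order = max_order,
            method = method,
            class = c("walsh_expansion", class(tibble::tibble())))
}

#' @export
print.walsh_expansion <- function(x, ...) {
  cat(sprintf("# Walsh expansion: %d loci, max order %d (%s)\n",
              length(attr(x, "locus_names")), attr(x, "max_order"),
              attr(x, "method")))
  NextMethod()
}

# in-place butterfly; index k of the result encodes subset membership in
# its bits (locus 1 = least-significant bit); forward divides by 2 per
# stage so each coefficient is the mean of F times the subset character
fwht_forward <- function(f, n) {
  for (b in seq_len(n)) {
    step <- 2^(b - 1L)
    block <- 2^b
    idx0 <- which(bitwAnd(seq_along(f) - 1L, step) == 0L)
    i0 <- idx0
    i1 <- idx0 + step
    a <- f[i0]
    d <- f[i1]
    f[i0] <- (a + d) / 2
    f[i1] <- (d - a) / 2
  }
  f
}

fwht_inverse <- function(coef, n) {
  for (b in seq_len(n)) {
    step <- 2^(b - 1L)
    idx0 <- which(bitwAnd(seq_along(coef) - 1L, step) == 0L)
    i0 <- idx0
    i1 <- idx0 + step
    m <- coef[i0]
    d <- coef[i1]
    coef[i0] <- m - d
    coef[i1] <- m + d
  }
  coef
}

subset_index <- function(n) {
  ids <- 0:(2^n - 1)
  members <- lapply(ids, function(k) which(bitwAnd(k, 2^(0:(n - 1))) > 0))
  list(members = members, order = lengths(members))
}

subset_labels <- function(members, loci) {
  vapply(members, function(m) paste(loci[m], collapse = ","), character(1))
}

parse_subset_label <- function(label, loci) {
  if (!nzchar(label)) return(integer(0))
  m <- match(strsplit(label, ",")[[1L]], loci)
  if (anyNA(m)) abort_data(sprintf("Subset '%s' names unknown loci.", label))
  sort(m)
}

walsh_ls_estimate <- function(landscape, max_order) {
  loci <- locus_names(landscape)
  n <- length(loci)
  X2 <- 2 * genotype_matrix(landscape) - 1
  members <- list(integer(0))
  for (k in seq_len(max_order)) {
    members <- c(members, utils::combn(n, k, simplify = FALSE))
  }
  X <- vapply(members, function(m) {
    if (length(m) == 0L) rep(1, nrow(X2)) else apply(X2[, m, drop = FALSE], 1, prod)
  }, numeric(nrow(X2)))
  if (nrow(X) < ncol(X)) {
    abort_data(sprintf(
      "Too few genotypes (%d) to estimate %d coefficients; lower max_order.",
      nrow(X), ncol(X)))
  }
  fit <- stats::lm.fit(X, landscape$fitness)
  tbl <- tibble::tibble(
    subset = subset_labels(members, loci),
    order = lengths(members),
    coefficient = unname(fit$coefficients)
  )
  new_walsh(tbl, loci, max_order, method = "least-squares")
}

#' Reconstruct a landscape from a Walsh expansion
#'
#' Evaluates the expansion forward over all `2^N` genotypes. For a
#' full-order expansion obtained from [to_walsh()] on a complete landscape
#' this is the exact inverse; for a truncated expansion it is the
#' corresponding low-order approximation of the landscape.
#'
#' @param expansion A `walsh_expansion`.
#' @return A complete [landscape][as_landscape].
#' @export
from_walsh <- function(expansion) {
  loci <- attr(expansion, "locus_names")
  n <- length(loci)
  coef <- numeric(2^n)
  for (r in seq_len(nrow(expansion))) {
    m <- parse_subset_label(expansion$subset[r], loci)
    coef[1L + sum(2^(m - 1L))] <- expansion$coefficient[r]
  }
  f <- fwht_inverse(coef, n)
  G <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(G) <- loci
  as_landscape(cbind(tibble::as_tibble(as.data.frame(G)), fitness = f))
}

#' Truncate a Walsh expansion to a maximum interaction order
#'
#' Drops every coefficient whose subset is larger than `order`; the mean
#' term is always kept. Truncation is lossy whenever the landscape has
#' interactions above the retained order.
#'
#' @param expansion A `walsh_expansion`.
#' @param order Largest subset size to keep (`>= 1`).
#' @return A `walsh_expansion`.
#' @export
truncate_walsh <- function(expansion, order) {
  if (order < 1L) abort_usage("Truncation order must be >= 1.")
  keep <- expansion$order <= order
  new_walsh(expansion[keep, ],
            locus_names = attr(expansion, "locus_names"),
            max_order = min(order, attr(expansion, "max_order")),
            method = attr(expansion, "method"))
}

#' @export
autoplot.walsh_expansion <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat <- dat[dat$order > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$subset,
                                                       .data$order),
                                    y = .data$coefficient,
                                    fill = factor(.data$order))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "locus subset", y = "Walsh coefficient",
                  fill = "order") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
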