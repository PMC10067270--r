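#' Combinatorial fitness landscapes over binary loci
#'
#' A `landscape` is a tibble with one row per genotype: one integer 0/1
#' column per locus (presence/absence of the mutation) and a numeric
#' `fitness` column, in caller-defined units. The locus columns define the
#' bit order used throughout the package. A landscape is *complete* when
#' all `2^N` genotypes over its `N` loci are present; incomplete landscapes
#' are first-class, and every averaging operation reports how many terms it
#' could actually use.
#'
#' @param x A data frame with 0/1 locus columns and a fitness column.
#' @param fitness Name of the fitness column. Default `"fitness"`.
#'
#' @return A validated `landscape` tibble (locus columns first, then
#'   `fitness`), with the locus names stored in `attr(, "locus_names")`.
#'
#' @examples
#' toy <- as_landscape(data.frame(m1 = c(0, 1, 0, 1), m2 = c(0, 0, 1, 1),
#'                                fitness = c(1.0, 1.2, 1.1, 1.4)))
#' n_loci(toy)
#' is_complete(toy)
#' @export
as_landscape <- function(x, fitness = "fitness") {
  if (!is.data.frame(x)) {
    abort_data("`x` must be a data frame.")
  }
  if (!fitness %in% names(x)) {
    abort_data(sprintf("Fitness column '%s' not found.", fitness))
  }
  loci <- setdiff(names(x), fitness)
  if (length(loci) < 1L) {
    abort_data("At least one locus column is required.")
  }
  check_locus_names(loci)
  tbl <- tibble::as_tibble(x)
  for (lc in loci) {
    v <- tbl[[lc]]
    if (!is.numeric(v) && !is.logical(v)) {
      abort_data(sprintf("Locus column '%s' is not numeric 0/1.", lc))
    }
    v <- as.numeric(v)
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad) > 0L) {
      abort_data(sprintf("Locus column '%s' has non-binary value in row %d.",
                         lc, bad[1L]))
    }
    tbl[[lc]] <- as.integer(v)
  }
  fv <- tbl[[fitness]]
  if (!is.numeric(fv)) abort_data("Fitness values must be numeric.")
  bad <- which(!is.finite(fv))
  if (length(bad) > 0L) {
    abort_data(sprintf("Non-finite or missing fitness in row %d.", bad[1L]))
  }
  key <- genotype_key_matrix(as.matrix(tbl[loci]))
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    abort_data(sprintf("Duplicate genotype '%s' in row %d.",
                       key[dup[1L]], dup[1L]))
  }
  out <- tbl[c(loci, fitness)]
  names(out)[length(out)] <- "fitness"
  new_landscape(out, loci)
}

new_landscape <- function(tbl, locus_names) {
  structure(tbl,
            locus_names = locus_names,
            class = c("landscape", class(tibble::tibble())))
}

#' @rdname as_landscape
#' @param landscape A `landscape` object.
#' @export
locus_names <- function(landscape) {
  ln <- attr(landscape, "locus_names")
  if (is.null(ln)) setdiff(names(landscape), "fitness") else ln
}

#' @rdname as_landscape
#' @export
n_loci <- function(landscape) length(locus_names(landscape))

#' @rdname as_landscape
#' @export
is_complete <- function(landscape) {
  nrow(landscape) == 2^n_loci(landscape)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("# Fitness landscape: %d loci, %d/%d genotypes%s\n",
              n_loci(x), nrow(x), 2^n_loci(x),
              if (is_complete(x)) " (complete)" else " (incomplete)"))
  NextMethod()
}

# ---- internal genotype indexing -------------------------------------------

# canonical key: bits pasted left-to-right in locus order, e.g. "010"
genotype_key_matrix <- function(G) {
  apply(G, 1L, paste0, collapse = "")
}

# integer id with locus 1 as the least-significant bit; doubles are exact
# up to 2^53 so any practical N is safe
genotype_id <- function(G) {
  w <- 2^(seq_len(ncol(G)) - 1L)
  as.vector(G %*% w)
}

genotype_matrix <- function(landscape) {
  G <- as.matrix(landscape[locus_names(landscape)])
  storage.mode(G) <- "integer"
  G
}

# accepts "010", c(0,1,0) or a named 0/1 vector; returns integer vector
parse_genotype <- function(g, loci) {
  n <- length(loci)
  if (is.character(g) && length(g) == 1L) {
    bits <- strsplit(g, "")[[1L]]
    if (length(bits) != n || !all(bits %in% c("0", "1"))) {
      abort_data(sprintf("Genotype string '%s' is not a length-%d 0/1 string.",
                         g, n))
    }
    return(as.integer(bits))
  }
  if (!is.null(names(g)) && all(loci %in% names(g))) g <- g[loci]
  g <- as.numeric(g)
  if (length(g) != n || !all(g %in% c(0, 1))) {
    abort_data("Genotype must be a length-N vector over {0,1}.")
  }
  as.integer(g)
}

locus_index <- function(landscape, locus) {
  loci <- locus_names(landscape)
  if (is.numeric(locus)) {
    if (locus < 1 || locus > length(loci)) {
      abort_data(sprintf("Locus index %s out of range.", locus))
    }
    return(as.integer(locus))
  }
  i <- match(locus, loci)
  if (is.na(i)) abort_data(sprintf("Unknown locus '%s'.", locus))
  i
}

check_locus_names <- function(loci) {
  if (anyDuplicated(loci)) abort_data("Duplicate locus names.")
  if (any(!nzchar(loci))) abort_data("Empty locus name.")
  if (any(grepl("[\t,[:space:]]", loci))) {
    abort_data("Locus names must not contain whitespace, tabs or commas.")
  }
  if (any(loci %in% c("fitness", "genotype"))) {
    abort_data("Locus names 'fitness' and 'genotype' are reserved.")
  }
  invisible(loci)
}

abort_data <- function(msg) {
  rlang::abort(msg, class = "globalepi_data_error")
}

abort_usage <- function(msg) {
  rlang::abort(msg, class = "globalepi_usage_error")
}

# ---- background sets and elementary effects -------------------------------

#' Backgrounds on which a focal mutation can be added
#'
#' The background set B(i) of a focal mutation i: every measured genotype
#' that lacks i and whose partner genotype B+i is also measured. For a
#' complete landscape over N loci this is all `2^(N-1)` genotypes lacking i.
#'
#' @param landscape A `landscape`.
#' @param focal Locus name (or index) of the focal mutation.
#' @return A tibble of background genotypes (one 0/1 column per locus) with
#'   a `background` key column, the focal locus recorded in
#'   `attr(, "focal")`.
#' @examples
#' L <- simulate_additive(c(m1 = 0.5, m2 = 0.3), baseline = 1)
#' backgrounds_of(L, "m1")
#' @export
backgrounds_of <- function(landscape, focal) {
  i <- locus_index(landscape, focal)
  loci <- locus_names(landscape)
  G <- genotype_matrix(landscape)
  id <- genotype_id(G)
  k <- which(G[, i] == 0L)
  has_partner <- !is.na(match(id[k] + 2^(i - 1L), id))
  k <- k[has_partner]
  out <- tibble::as_tibble(as.data.frame(G[k, , drop = FALSE]))
  names(out) <- loci
  out <- tibble::add_column(out,
                            background = genotype_key_matrix(G[k, , drop = FALSE]),
                            .before = 1L)
  attr(out, "focal") <- loci[i]
  out
}

#' Fitness effect of a mutation on a given background
#'
#' The fitness effect of the focal mutation i on background B is
#' `F(B+i) - F(B)`: the change in fitness when the mutation is added.
#'
#' @inheritParams backgrounds_of
#' @param background Genotype lacking the focal mutation, as a 0/1 vector or
#'   a bit string such as `"010"` (left-to-right in locus order).
#' @return A single numeric value.
#' @examples
#' toy <- as_landscape(data.frame(m1 = c(0, 1, 0, 1), m2 = c(0, 0, 1, 1),
#'                                fitness = c(1.0, 1.2, 1.1, 1.4)))
#' fitness_effect(toy, "m1", "00")  # 0.2
#' @export
fitness_effect <- function(landscape, focal, background) {
  i <- locus_index(landscape, focal)
  loci <- locus_names(landscape)
  b <- parse_genotype(background, loci)
  if (b[i] != 0L) {
    abort_data(sprintf("Background already contains focal locus '%s'.",
                       loci[i]))
  }
  G <- genotype_matrix(landscape)
  id <- genotype_id(G)
  id_b <- sum(b * 2^(seq_along(b) - 1L))
  kb <- match(id_b, id)
  ki <- match(id_b + 2^(i - 1L), id)
  if (is.na(kb)) {
    abort_data(sprintf("Background genotype '%s' is not measured.",
                       paste0(b, collapse = "")))
  }
  if (is.na(ki)) {
    bi <- b
    bi[i] <- 1L
    abort_data(sprintf("Genotype '%s' (background + focal) is not measured.",
                       paste0(bi, collapse = "")))
  }
  landscape$fitness[ki] - landscape$fitness[kb]
}

#' Pairwise epistasis between two mutations on a given background
#'
#' The four-corner epistasis of mutations i and j on background B:
#' `F(B+i+j) - F(B+i) - F(B+j) + F(B)`. Zero everywhere on an additive
#' landscape; symmetric in i and j.
#'
#' @inheritParams backgrounds_of
#' @param i,j Distinct locus names (or indices).
#' @param background Genotype lacking both i and j, as a 0/1 vector or bit
#'   string.
#' @return A single numeric value.
#' @examples
#' toy <- as_landscape(data.frame(m1 = c(0, 1, 0, 1), m2 = c(0, 0, 1, 1),
#'                                fitness = c(1.0, 1.2, 1.1, 1.4)))
#' pairwise_epistasis(toy, "m1", "m2", "00")  # 0.1
#' @export
pairwise_epistasis <- function(landscape, i, j, background) {
  ii <- locus_index(landscape, i)
  jj <- locus_index(landscape, j)
  if (ii == jj) abort_data("Loci i and j must be distinct.")
  loci <- locus_names(landscape)
  b <- parse_genotype(background, loci)
  if (b[ii] != 0L || b[jj] != 0L) {
    abort_data("Background must lack both loci i and j.")
  }
  G <- genotype_matrix(landscape)
  id <- genotype_id(G)
  id_b <- sum(b * 2^(seq_along(b) - 1L))
  wi <- 2^(ii - 1L)
  wj <- 2^(jj - 1L)
  corners <- c(id_b, id_b + wi, id_b + wj, id_b + wi + wj)
  pos <- match(corners, id)
  if (anyNA(pos)) {
    missing_bits <- b
    which_missing <- which(is.na(pos))[1L]
    add <- list(integer(0), ii, jj, c(ii, jj))[[which_missing]]
    missing_bits[add] <- 1L
    abort_data(sprintf("Corner genotype '%s' is not measured.",
                       paste0(missing_bits, collapse = "")))
  }
  f <- landscape$fitness[pos]
  f[4L] - f[2L] - f[3L] + f[1L]
}
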