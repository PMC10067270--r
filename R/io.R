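#' Read and write fitness landscape tables
#'
#' Two tab-separated dialects are supported. The *wide* dialect has one 0/1
#' column per locus (header gives the locus names) plus a literal `fitness`
#' column. The *genotype-string* dialect has two columns, `genotype` (a bit
#' string over `{0,1}`, read left-to-right as locus 1..N) and `fitness`.
#' Lines starting with `#` are metadata comments and are ignored on read.
#'
#' `write_landscape()` and `read_landscape()` round-trip exactly: fitness
#' values are written at full double precision.
#'
#' @param path File path.
#' @param dialect `"wide"` or `"genotype-string"`.
#' @param locus_names Locus names to use for the genotype-string dialect
#'   (default `m1..mN`); ignored for the wide dialect.
#' @return `read_landscape()` returns a validated [landscape][as_landscape];
#'   `write_landscape()` returns `path` invisibly.
#' @examples
#' L <- simulate_additive(c(m1 = 0.5, m2 = 0.3), baseline = 1)
#' tf <- tempfile(fileext = ".tsv")
#' write_landscape(L, tf)
#' identical(read_landscape(tf)$fitness, L$fitness)
#' @export
read_landscape <- function(path, dialect = c("wide", "genotype-string"),
                           locus_names = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_data(sprintf("File '%s' does not exist.", path))
  # base strtod parsing: doubles written at full precision round-trip exactly
  classes <- if (dialect == "genotype-string") {
    c(genotype = "character")  # keep leading zeros
  } else {
    NA
  }
  tbl <- tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                             check.names = FALSE,
                                             colClasses = classes,
                                             stringsAsFactors = FALSE))
  if (dialect == "wide") {
    if (!"fitness" %in% names(tbl)) {
      abort_data("Wide landscape file must have a 'fitness' column.")
    }
    return(as_landscape(tbl))
  }
  if (!all(c("genotype", "fitness") %in% names(tbl))) {
    abort_data("Genotype-string file must have 'genotype' and 'fitness' columns.")
  }
  gs <- as.character(tbl$genotype)
  n <- nchar(gs[1L])
  if (any(nchar(gs) != n) || any(!grepl("^[01]+$", gs))) {
    abort_data("All genotype strings must be equal-length strings over {0,1}.")
  }
  if (is.null(locus_names)) locus_names <- paste0("m", seq_len(n))
  G <- do.call(rbind, lapply(strsplit(gs, ""), as.integer))
  colnames(G) <- locus_names
  as_landscape(cbind(tibble::as_tibble(as.data.frame(G)),
                     fitness = tbl$fitness))
}

#' @rdname read_landscape
#' @param landscape A [landscape][as_landscape].
#' @param metadata Optional character vector of metadata lines to write as
#'   leading `#` comments.
#' @export
write_landscape <- function(landscape, path,
                            dialect = c("wide", "genotype-string"),
                            metadata = NULL) {
  dialect <- match.arg(dialect)
  loci <- locus_names(landscape)
  check_locus_names(loci)
  if (dialect == "wide") {
    out <- tibble::as_tibble(landscape)[c(loci, "fitness")]
  } else {
    out <- tibble::tibble(
      genotype = genotype_key_matrix(genotype_matrix(landscape)),
      fitness = landscape$fitness
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(paste0("# ", metadata), con)
  }
  writeLines(paste(names(out), collapse = "\t"), con)
  cells <- lapply(out, function(col) {
    if (is.double(col)) format_full(col) else as.character(col)
  })
  writeLines(do.call(paste, c(cells, sep = "\t")), con)
  invisible(path)
}

# shortest representation that round-trips a double exactly
format_full <- function(x) {
  vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
}

#' Read and write Walsh coefficient tables
#'
#' Tab-separated with columns `subset` (comma-joined locus names; empty
#' string for the landscape mean), `order` (subset size) and `coefficient`.
#' `#`-prefixed metadata lines are ignored on read.
#'
#' @param expansion A [walsh_expansion][to_walsh].
#' @param path File path.
#' @param locus_names Locus names of the underlying landscape (needed on
#'   read to reconstruct the expansion; defaults to the loci mentioned in
#'   the file, in order of first appearance).
#' @param metadata Optional `#` metadata lines.
#' @return `read_walsh()` returns a `walsh_expansion`; `write_walsh()`
#'   returns `path` invisibly.
#' @export
write_walsh <- function(expansion, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) writeLines(paste0("# ", metadata), con)
  writeLines("subset\torder\tcoefficient", con)
  writeLines(paste(expansion$subset, expansion$order,
                   format_full(expansion$coefficient), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_walsh
#' @export
read_walsh <- function(path, locus_names = NULL) {
  tbl <- tibble::as_tibble(utils::read.delim(
    path, comment.char = "#", check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = c(subset = "character", order = "integer",
                   coefficient = "numeric")))
  tbl$subset[is.na(tbl$subset)] <- ""
  if (is.null(locus_names)) {
    mentioned <- unlist(strsplit(tbl$subset[nzchar(tbl$subset)], ","))
    locus_names <- unique(mentioned)
  }
  new_walsh(tbl, locus_names = locus_names,
            max_order = max(tbl$order), method = "file")
}
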