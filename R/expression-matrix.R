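#' Read an expression matrix from a tab-separated file
#'
#' Reads a genes x samples expression table: first row is the sample header,
#' first column holds gene identifiers, remaining cells are nonnegative
#' expression values (counts or intensities). Missing cells may be written as
#' `NA` or left empty; the decimal separator is `.`.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names, preserving file order. Missing cells are
#'   `NA`.
#' @details Duplicate gene or sample identifiers and ragged rows are hard
#'   errors (the offending identifier / row number is named), since all
#'   downstream ranking assumes a unique gene and sample universe.
#' @seealso [write_expression_matrix()], [filter_na()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading corner label for the gene column
  body <- fields[-1L]
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  width <- lengths(body)
  n_col <- width[1L]
  samples <- if (length(header) == n_col) header[-1L] else header
  if (length(samples) != n_col - 1L) {
    stop("header has ", length(header), " fields but data rows have ",
         n_col, call. = FALSE)
  }
  bad <- which(width != n_col)
  if (length(bad) > 0L) {
    stop("ragged row at line ", bad[1L] + 1L, ": expected ", n_col,
         " fields, found ", width[bad[1L]], call. = FALSE)
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g) > 0L) {
    stop("duplicated gene identifier: ", dup_g[1L], call. = FALSE)
  }
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0L) {
    stop("duplicated sample identifier: ", dup_s[1L], call. = FALSE)
  }
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  cells[cells == ""] <- NA_character_
  values <- suppressWarnings(as.numeric(cells))
  bad_cell <- !is.na(cells) & cells != "NA" & is.na(values)
  if (any(bad_cell)) {
    stop("non-numeric cell value: ", cells[bad_cell][1L], call. = FALSE)
  }
  matrix(values, nrow = length(genes), ncol = length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

#' Write an expression or call matrix to a tab-separated file
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces finite doubles bit-identically.
#'
#' @param x Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- as_expression_matrix(x, allow_na = TRUE)
  body <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  body[is.na(x)] <- "NA"
  lines <- c(
    paste(c("gene_id", colnames(x)), collapse = "\t"),
    paste(rownames(x), apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Coerce/validate the genes x samples container used throughout the package.
as_expression_matrix <- function(x, allow_na = FALSE,
                                 arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric genes x samples matrix", call. = FALSE)
  }
  if ((nrow(x) > 0L && is.null(rownames(x))) ||
      (ncol(x) > 0L && is.null(colnames(x)))) {
    stop(arg, " must carry gene row names and sample column names",
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- character(0)
  if (is.null(colnames(x))) colnames(x) <- character(0)
  if (anyDuplicated(rownames(x))) {
    stop("duplicated gene identifier: ",
         rownames(x)[duplicated(rownames(x))][1L], call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicated sample identifier: ",
         colnames(x)[duplicated(colnames(x))][1L], call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(arg, " contains NA values; run filter_na() first", call. = FALSE)
  }
  finite <- x[!is.na(x)]
  if (any(!is.finite(finite))) stop(arg, " contains non-finite values",
                                    call. = FALSE)
  if (any(finite < 0)) stop(arg, " contains negative values", call. = FALSE)
  x
}

#' Remove genes and samples containing missing values
#'
#' Entirely missing samples are dropped first (they carry no information and
#' would otherwise disqualify every gene), then every gene still containing
#' an `NA` is dropped. A sample with scattered missing cells is therefore
#' retained at the cost of its incomplete genes — downstream ranking is per
#' gene, so an incomplete gene is unusable while such a sample can still
#' anchor the remaining genes.
#'
#' @param x Expression matrix (genes x samples), possibly with `NA` cells.
#' @return The filtered matrix, with a `"removal"` attribute: a list with
#'   `genes` and `samples` (the removed identifiers).
#' @export
filter_na <- function(x) {
  x <- as_expression_matrix(x, allow_na = TRUE)
  bad_sample <- colSums(is.na(x)) == nrow(x)
  removed_samples <- colnames(x)[bad_sample]
  x2 <- x[, !bad_sample, drop = FALSE]
  bad_gene <- rowSums(is.na(x2)) > 0L
  if (ncol(x2) == 0L || all(bad_gene)) {
    stop("all genes contain NA values", call. = FALSE)
  }
  out <- x2[!bad_gene, , drop = FALSE]
  attr(out, "removal") <- list(genes = rownames(x2)[bad_gene],
                               samples = removed_samples)
  out
}

#' Remove lowly expressed genes
#'
#' Drops every gene whose expression is strictly below `val_min` in at least
#' a fraction `frac` of the samples of `x`. With the defaults
#' (`val_min = 10`, `frac = 0.99`) a gene survives only if it reaches at
#' least `val_min` in more than 1% of samples.
#'
#' @param x NA-free expression matrix.
#' @param val_min Nonnegative expression threshold; values strictly below it
#'   count as "low".
#' @param frac Fraction of samples in (0, 1] that must be low for removal.
#' @return Filtered matrix with a `"removal"` attribute listing removed gene
#'   identifiers.
#' @examples
#' m <- matrix(c(0, 0, 50, 60), 2, 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' filter_low_expression(m, val_min = 10, frac = 0.99)
#' @export
filter_low_expression <- function(x, val_min = 10, frac = 0.99) {
  x <- as_expression_matrix(x)
  if (!is.numeric(val_min) || length(val_min) != 1L || val_min < 0) {
    stop("val_min must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1) {
    stop("frac must lie in (0, 1]", call. = FALSE)
  }
  low_frac <- rowMeans(x < val_min)
  drop <- low_frac >= frac
  out <- x[!drop, , drop = FALSE]
  attr(out, "removal") <- list(genes = rownames(x)[drop],
                               samples = character(0))
  out
}

#' Median-of-ratios size-factor normalization
#'
#' Scales each sample by a single positive factor computed as the median,
#' over genes with a positive geometric mean across samples, of the ratio
#' between the sample's value and that geometric mean. This makes library
#' sizes comparable across samples while leaving within-sample ordering
#' untouched; the rank-based detector does not require it, so it is offered
#' as an optional preprocessing utility.
#'
#' @param x NA-free expression matrix with at least two samples.
#' @return Normalized matrix of the same shape, with a `"size_factors"`
#'   attribute (named per sample).
#' @export
size_factor_normalize <- function(x) {
  x <- as_expression_matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  all_pos <- rowSums(x > 0) == ncol(x)
  if (!any(all_pos)) {
    stop("no gene is positive in all samples; size factors are undefined",
         call. = FALSE)
  }
  log_geo <- rowMeans(log(x[all_pos, , drop = FALSE]))
  log_ratios <- log(x[all_pos, , drop = FALSE]) - log_geo
  factors <- exp(apply(log_ratios, 2L, stats::median))
  out <- sweep(x, 2L, factors, "/")
  attr(out, "size_factors") <- factors
  out
}

#' Summarise a removal report
#'
#' @param x A matrix returned by [filter_na()] or [filter_low_expression()].
#' @return A tibble with one row per removed identifier (`kind`, `id`).
#' @export
removal_report <- function(x) {
  rem <- attr(x, "removal")
  if (is.null(rem)) rem <- list(genes = character(0), samples = character(0))
  tibble::tibble(
    kind = c(rep("gene", length(rem$genes)),
             rep("sample", length(rem$samples))),
    id = c(rem$genes, rem$samples)
  )
}
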