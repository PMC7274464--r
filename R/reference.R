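#' Build the per-gene ordering reference from a control cohort
#'
#' For every gene `g`, finds the genes whose expression is strictly lower
#' (`L(g)`) or strictly higher (`H(g)`) than that of `g` in at least a
#' fraction `threshold_LH` of the control samples, then keeps for each list
#' only the `l` candidates whose control median is closest to `g`'s median.
#' These lists encode the stable relative expression ordering that the
#' detector later tests for perturbation in individual case samples.
#'
#' @param controls NA-free expression matrix of the reference cohort
#'   (genes x samples).
#' @param threshold_LH Fraction in (0.5, 1]: the minimal proportion of
#'   control samples in which the ordering must hold. The comparison is done
#'   on fractions (`qualifying / n >= threshold_LH`), so with 14 controls and
#'   the default 0.99 all 14 samples must agree.
#' @param l Maximal size of each of `L(g)` and `H(g)` (applied per list).
#' @return An object of class `reo_reference`: a list with `gene_ids`,
#'   `sample_ids`, `medians` (named numeric), `L` and `H` (named lists of
#'   gene-id vectors, ordered by increasing median distance), and `params`.
#' @details Ties (`E(g') == E(g)` in a sample) count as a failure of both
#'   "lower" and "higher" for that sample, so two genes with identical
#'   control profiles never enter each other's lists. Median-distance ties
#'   during truncation are broken by input gene order. Lists are stored in
#'   median-distance order, so [shrink_reference()] can derive the reference
#'   for any smaller `l` without recomputation.
#' @examples
#' ctl <- matrix(c(1, 2, 3, 10, 11, 12, 100, 90, 110), 3, 3, byrow = TRUE,
#'               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
#' ref <- build_reference(ctl, threshold_LH = 0.99, l = 30)
#' ref$L$g2  # "g1"
#' @export
build_reference <- function(controls, threshold_LH = 0.99, l = 30) {
  controls <- as_expression_matrix(controls)
  if (nrow(controls) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(controls) < 1L) stop("need at least 1 control sample",
                                call. = FALSE)
  if (!is.numeric(threshold_LH) || length(threshold_LH) != 1L ||
      threshold_LH <= 0.5 || threshold_LH > 1) {
    stop("threshold_LH must lie in (0.5, 1]", call. = FALSE)
  }
  if (!is.numeric(l) || length(l) != 1L || l < 1) {
    stop("l must be a positive integer", call. = FALSE)
  }
  l <- as.integer(l)
  genes <- rownames(controls)
  n_genes <- length(genes)
  med <- apply(controls, 1L, stats::median)
  tm <- t(controls)                         # samples x genes, for fast blocks
  block <- max(64L, 4L * l)
  L <- vector("list", n_genes)
  H <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    # candidates in increasing median distance; ties by input gene order
    ord <- order(abs(med - med[i]), seq_len(n_genes))
    ord <- ord[ord != i]
    li <- integer(0)
    hi <- integer(0)
    pos <- 1L
    while ((length(li) < l || length(hi) < l) && pos <= length(ord)) {
      idx <- ord[pos:min(pos + block - 1L, length(ord))]
      pos <- pos + length(idx)
      blk <- tm[, idx, drop = FALSE]
      n_s <- nrow(tm)
      cmp_lo <- .colMeans(blk < tm[, i], n_s, length(idx))
      cmp_hi <- .colMeans(blk > tm[, i], n_s, length(idx))
      new_lo <- idx[cmp_lo >= threshold_LH]
      new_hi <- idx[cmp_hi >= threshold_LH]
      if (length(li) < l && length(new_lo) > 0L) {
        li <- c(li, new_lo[seq_len(min(length(new_lo), l - length(li)))])
      }
      if (length(hi) < l && length(new_hi) > 0L) {
        hi <- c(hi, new_hi[seq_len(min(length(new_hi), l - length(hi)))])
      }
    }
    L[[i]] <- genes[li]
    H[[i]] <- genes[hi]
  }
  names(L) <- genes
  names(H) <- genes
  structure(
    list(gene_ids = genes, sample_ids = colnames(controls),
         medians = stats::setNames(med, genes), L = L, H = H,
         params = list(threshold_LH = threshold_LH, l = l)),
    class = "reo_reference"
  )
}

#' Restrict an ordering reference to smaller lists
#'
#' Because lists are stored in median-distance order, truncating them to the
#' first `l` entries reproduces exactly what [build_reference()] would have
#' returned for that `l`. Useful when sweeping list sizes.
#'
#' @param reference A `reo_reference`.
#' @param l New maximal list size, at most the reference's current `l`.
#' @return A `reo_reference` with truncated lists.
#' @export
shrink_reference <- function(reference, l) {
  stopifnot(inherits(reference, "reo_reference"))
  if (l > reference$params$l) {
    stop("cannot grow lists: rebuild with build_reference()", call. = FALSE)
  }
  l <- as.integer(l)
  reference$L <- lapply(reference$L, utils::head, l)
  reference$H <- lapply(reference$H, utils::head, l)
  reference$params$l <- l
  reference
}

#' @export
print.reo_reference <- function(x, ...) {
  cat("<reo_reference> ", length(x$gene_ids), " genes, ",
      length(x$sample_ids), " controls\n", sep = "")
  cat("  threshold_LH = ", x$params$threshold_LH,
      ", l = ", x$params$l, "\n", sep = "")
  cat("  mean |L| = ", round(mean(lengths(x$L)), 2),
      ", mean |H| = ", round(mean(lengths(x$H)), 2), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reference into a per-gene tibble
#'
#' @param x A `reo_reference`.
#' @param ... Unused.
#' @return Tibble with `gene`, `median`, `n_lower`, `n_higher`.
#' @export
tidy.reo_reference <- function(x, ...) {
  tibble::tibble(
    gene = x$gene_ids,
    median = unname(x$medians),
    n_lower = unname(lengths(x$L)),
    n_higher = unname(lengths(x$H))
  )
}

#' Serialize an ordering reference to JSON
#'
#' @param reference A `reo_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "reo_reference"))
  obj <- list(
    params = c(reference$params,
               list(sample_ids = as.list(reference$sample_ids))),
    genes = lapply(reference$gene_ids, function(g) {
      list(id = g, median = reference$medians[[g]],
           L = as.list(reference$L[[g]]), H = as.list(reference$H[[g]]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ordering reference from JSON
#'
#' @param path Path written by [write_reference()].
#' @return A `reo_reference`.
#' @export
read_reference <- function(path) {
  obj <- jsonlite::read_json(path)
  genes <- vapply(obj$genes, `[[`, character(1), "id")
  as_chr <- function(x) vapply(x, as.character, character(1))
  structure(
    list(
      gene_ids = genes,
      sample_ids = as_chr(obj$params$sample_ids),
      medians = stats::setNames(
        vapply(obj$genes, function(g) as.numeric(g$median), numeric(1)),
        genes),
      L = stats::setNames(lapply(obj$genes, function(g) as_chr(g$L)), genes),
      H = stats::setNames(lapply(obj$genes, function(g) as_chr(g$H)), genes),
      params = list(threshold_LH = as.numeric(obj$params$threshold_LH),
                    l = as.integer(obj$params$l))
    ),
    class = "reo_reference"
  )
}
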