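#' Score deregulation calls against ground truth
#'
#' A (gene, sample) cell is a positive when its truth label is nonzero; a
#' call is a true positive when both call and truth are nonzero, regardless
#' of direction (direction correctness among true positives is reported
#' separately as `direction_accuracy`).
#'
#' @param calls A `dereg_calls` object or calls matrix in `{-1, 0, 1}`.
#' @param truth Integer matrix of the same shape in `{-1, 0, 1}`.
#' @return A one-row tibble with counts (`tp`, `fp`, `tn`, `fn`), rates
#'   (`tpr`, `fpr`, `fdr`), `informedness` (TPR - FPR) and
#'   `direction_accuracy`.
#' @export
score_calls <- function(calls, truth) {
  m <- calls_matrix(calls)
  if (!is.matrix(truth) || !identical(dim(m), dim(truth))) {
    stop("calls and truth shapes do not match", call. = FALSE)
  }
  if (!is.null(rownames(truth)) && !is.null(rownames(m))) {
    if (!identical(rownames(m), rownames(truth)) ||
        !identical(colnames(m), colnames(truth))) {
      truth <- truth[rownames(m), colnames(m), drop = FALSE]
    }
  }
  pos <- truth != 0L
  called <- m != 0L
  tp <- sum(called & pos)
  fp <- sum(called & !pos)
  fn <- sum(!called & pos)
  tn <- sum(!called & !pos)
  tpr <- if (tp + fn > 0L) tp / (tp + fn) else 0
  fpr <- if (fp + tn > 0L) fp / (fp + tn) else 0
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = tpr, fpr = fpr,
    fdr = if (tp + fp > 0L) fp / (tp + fp) else NA_real_,
    informedness = tpr - fpr,
    direction_accuracy = if (tp > 0L) {
      mean(m[called & pos] == truth[called & pos])
    } else NA_real_
  )
}

#' Sweep the decision threshold into an ROC curve on simulated tumors
#'
#' For every value of `h` in the grid, re-runs the full iterative detector
#' on each simulated tumor and pools the resulting cells over tumors into
#' one confusion summary. Each tumor is scored against a reference built
#' with its own source control left out (the reference a tumor was derived
#' from must never vouch for it); references are cached across tumors
#' sharing a source.
#'
#' @param sims A `sim_dataset` from [simulate_tumors()].
#' @param controls The full control expression matrix.
#' @param h_grid Ordered vector of thresholds in `[0, 1]` (at `h = 0` any
#'   flipped neighbour triggers the rule; genes with no flips still abstain
#'   through the direction tie).
#' @param params A [detection_params()] object (`h` is overridden by the
#'   grid).
#' @param threshold_LH,l Reference-building parameters.
#' @param refs Optional pre-built leave-one-out references: a named list
#'   keyed by the excluded control sample id. Each is checked against the
#'   leave-one-out contract and its lists are shrunk to `l` if larger.
#' @return A tibble of class `roc_sweep`: one row per `h` with the pooled
#'   confusion summary columns of [score_calls()].
#' @export
roc_sweep <- function(sims, controls, h_grid = seq(0, 1, length.out = 21),
                      params = detection_params(), threshold_LH = 0.99,
                      l = 30, refs = NULL) {
  stopifnot(inherits(sims, "sim_dataset"))
  controls <- as_expression_matrix(controls)
  if (any(h_grid < 0 | h_grid > 1)) {
    stop("h_grid values must lie in [0, 1]", call. = FALSE)
  }
  sources <- sims$source_sample
  uniq <- unique(sources)
  loo <- list()
  for (s in uniq) {
    ref <- if (!is.null(refs) && !is.null(refs[[s]])) refs[[s]] else {
      build_reference(controls[, setdiff(colnames(controls), s),
                               drop = FALSE],
                      threshold_LH = threshold_LH, l = l)
    }
    assert_leave_one_out(ref, s)
    if (ref$params$l > l) ref <- shrink_reference(ref, l)
    loo[[s]] <- list(
      ref = ref,
      flat = flatten_reference(ref),
      bounds = if (params$fallback == "percentile") {
        fallback_bounds(
          controls[ref$gene_ids, setdiff(colnames(controls), s),
                   drop = FALSE],
          params$x, params$f)
      }
    )
  }
  gene_order <- loo[[1L]]$ref$gene_ids
  truth <- sims$truth[gene_order, , drop = FALSE]
  rows <- vector("list", length(h_grid))
  n_capped <- 0L
  for (i in seq_along(h_grid)) {
    p <- params
    p$h <- h_grid[i]
    calls <- matrix(0L, length(gene_order), ncol(sims$cases),
                    dimnames = list(gene_order, colnames(sims$cases)))
    for (j in seq_len(ncol(sims$cases))) {
      env <- loo[[sources[j]]]
      # the per-run iteration-cap warning is aggregated below
      res <- withCallingHandlers(
        detect_sample_core(sims$cases[gene_order, j], env$flat,
                           env$bounds, p),
        warning = function(w) {
          if (grepl("iteration limit", conditionMessage(w))) {
            n_capped <<- n_capped + 1L
            invokeRestart("muffleWarning")
          }
        })
      calls[, j] <- res$call
    }
    rows[[i]] <- dplyr::bind_cols(tibble::tibble(h = h_grid[i]),
                                  score_calls(calls, truth))
  }
  if (n_capped > 0L) {
    warning(n_capped, " of ", length(h_grid) * ncol(sims$cases),
            " detection runs hit the iteration cap and returned the union ",
            "of their last two deregulated sets (expected at extreme h)",
            call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("roc_sweep", class(out))
  out
}

# Leave-one-out contract: refuse a reference whose control cohort contains
# the sample a tumor was simulated from.
assert_leave_one_out <- function(reference, source_sample) {
  if (source_sample %in% reference$sample_ids) {
    stop("reference was built with control '", source_sample,
         "', the source of a tumor it would score; rebuild without it",
         call. = FALSE)
  }
  invisible(reference)
}

#' Maximal informedness of an ROC sweep
#'
#' @param roc A `roc_sweep` tibble.
#' @return The maximal Youden's J (TPR - FPR) over the grid.
#' @export
max_informedness <- function(roc) {
  stopifnot(inherits(roc, "roc_sweep") || "informedness" %in% names(roc))
  max(roc$informedness)
}

#' Operating point of an ROC sweep under a specificity constraint
#'
#' @param roc A `roc_sweep` tibble.
#' @param fpr_max Maximal acceptable pooled false positive rate.
#' @return The grid row with the highest TPR among rows with
#'   `fpr <= fpr_max` (ties broken by lower FPR); errors if no row
#'   satisfies the constraint.
#' @export
operating_point <- function(roc, fpr_max = 0.05) {
  ok <- roc[roc$fpr <= fpr_max, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no grid point with FPR <= ", fpr_max,
                           call. = FALSE)
  ok <- ok[order(-ok$tpr, ok$fpr), , drop = FALSE]
  ok[1L, , drop = FALSE]
}

#' Summary row of an ROC sweep
#'
#' @param x A `roc_sweep` tibble.
#' @param ... Unused.
#' @return One-row tibble: `h_best`, `max_informedness`, and the TPR/FPR at
#'   the best grid point.
#' @export
glance.roc_sweep <- function(x, ...) {
  best <- x[which.max(x$informedness), ]
  tibble::tibble(
    h_best = best$h,
    max_informedness = best$informedness,
    tpr_best = best$tpr,
    fpr_best = best$fpr
  )
}

#' False discovery rate from sensitivity and specificity
#'
#' Closed form for a screen of `T` genes of which `P` are truly deregulated,
#' detected with sensitivity `SE` and specificity `SP`:
#' `FDR = (T - P)(1 - SP) / [(T - P)(1 - SP) + P * SE]`.
#'
#' @param T Total number of genes.
#' @param P Number of truly deregulated genes, with `0 < P < T`.
#' @param SE Sensitivity in `[0, 1]`.
#' @param SP Specificity in `[0, 1]`.
#' @return The false discovery rate as a fraction.
#' @examples
#' fdr_from_se_sp(15000, 3000, SE = 0.8, SP = 0.9)  # 1/3
#' @export
fdr_from_se_sp <- function(T, P, SE, SP) {
  if (!(P > 0 && P < T)) stop("require 0 < P < T", call. = FALSE)
  if (SE < 0 || SE > 1 || SP < 0 || SP > 1) {
    stop("SE and SP must lie in [0, 1]", call. = FALSE)
  }
  denom <- (T - P) * (1 - SP) + P * SE
  if (denom == 0) {
    stop("FDR undefined: no gene is called at SE = 0, SP = 1",
         call. = FALSE)
  }
  (T - P) * (1 - SP) / denom
}

#' Apply per-sample scaling perturbation
#'
#' Multiplies every value of each sample by one random factor drawn
#' uniformly in `[lo, hi]` (the same factor for all genes of a sample),
#' emulating library-size / normalization artefacts. The rank detector's
#' calls are invariant to this perturbation as long as the percentile
#' fallback is disabled.
#'
#' @param x Expression matrix.
#' @param lo,hi Factor range, `0 <= lo <= hi`.
#' @param seed Integer seed.
#' @return The scaled matrix, with a `"scaling_factors"` attribute.
#' @export
scaling_perturbation <- function(x, lo = 1, hi = 5, seed = 1) {
  x <- as_expression_matrix(x)
  if (lo < 0 || hi < lo) stop("require 0 <= lo <= hi", call. = FALSE)
  factors <- withr::with_seed(seed, stats::runif(ncol(x), lo, hi))
  out <- sweep(x, 2L, factors, "*")
  attr(out, "scaling_factors") <- stats::setNames(factors, colnames(x))
  out
}
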