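#' Detection parameters
#'
#' Bundles the tunable parameters of the rank-perturbation detector.
#'
#' @param h Decision threshold in (0, 1]: minimal fraction of a gene's L (or
#'   H) list that must have switched sides for the gene to be called.
#' @param x Percentile in (0, 50), in percent, used by the fallback outlier
#'   test (`x = 2` means the 2nd and 98th percentiles of the control
#'   distribution).
#' @param f Window expansion factor (>= 1) of the fallback test: a case value
#'   must fall below `p_l / f` or above `p_u * f` to be called.
#' @param max_iter Maximal number of exclusion iterations.
#' @param fallback `"percentile"` (default) to resolve genes with no usable
#'   ordering information by the percentile test, `"none"` to abstain on
#'   them (keeps the detector fully scale-invariant).
#' @return A list of class `detection_params`.
#' @details The defaults (`h = 0.3`, `x = 2`, `f = 1.2`) are the tuned
#'   operating point for RNA-seq count data; array intensities typically
#'   want a milder window (e.g. `x = 5`, `f = 1.05`) and a stricter `h`.
#' @export
detection_params <- function(h = 0.3, x = 2, f = 1.2, max_iter = 20,
                             fallback = c("percentile", "none")) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h > 1) {
    stop("h must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 50) {
    stop("x must lie in (0, 50) percent", call. = FALSE)
  }
  if (!is.numeric(f) || length(f) != 1L || f < 1) {
    stop("f must be >= 1", call. = FALSE)
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1) {
    stop("max_iter must be a positive integer", call. = FALSE)
  }
  structure(list(h = h, x = x, f = f, max_iter = as.integer(max_iter),
                 fallback = match.arg(fallback)),
            class = "detection_params")
}

# Flatten L/H lists into index vectors for vectorized per-iteration counting.
flatten_reference <- function(reference) {
  genes <- reference$gene_ids
  idx <- stats::setNames(seq_along(genes), genes)
  L_len <- lengths(reference$L)
  H_len <- lengths(reference$H)
  list(
    n = length(genes),
    L_member = unname(idx[unlist(reference$L, use.names = FALSE)]),
    L_owner = rep.int(seq_along(genes), L_len),
    H_member = unname(idx[unlist(reference$H, use.names = FALSE)]),
    H_owner = rep.int(seq_along(genes), H_len)
  )
}

# One sweep of the decision rule over all genes, given the active-gene mask.
# Returns integer calls in {-1,0,1} and a logical vector marking genes whose
# both lists are effectively empty (fallback required).
classify_all_once <- function(case, flat, active, h) {
  G <- flat$n
  vL <- case[flat$L_member]
  gL <- case[flat$L_owner]
  okL <- active[flat$L_member]
  lu <- tabulate(flat$L_owner[okL & vL > gL], G)
  ld <- tabulate(flat$L_owner[okL & vL < gL], G)
  vH <- case[flat$H_member]
  gH <- case[flat$H_owner]
  okH <- active[flat$H_member]
  hd <- tabulate(flat$H_owner[okH & vH < gH], G)
  hu <- tabulate(flat$H_owner[okH & vH > gH], G)
  L_eff <- lu + ld            # ties are excluded from the denominators
  H_eff <- hd + hu
  p_down <- ifelse(L_eff > 0L, lu / L_eff, -Inf)   # L-genes now above g
  p_up <- ifelse(H_eff > 0L, hd / H_eff, -Inf)     # H-genes now below g
  dereg <- p_down >= h | p_up >= h
  down_ok <- (ld + hd) < L_eff
  up_ok <- (lu + hu) < H_eff
  call <- integer(G)
  only_down <- dereg & down_ok & !up_ok
  only_up <- dereg & up_ok & !down_ok
  both <- dereg & down_ok & up_ok
  call[only_down] <- -1L
  call[only_up] <- 1L
  call[both & (p_down > p_up)] <- -1L
  call[both & (p_up > p_down)] <- 1L
  list(call = call, needs_fallback = L_eff == 0L & H_eff == 0L)
}

#' Classify a single gene in one case sample (one pass, no iteration)
#'
#' Applies the rank-perturbation decision rule once: the gene's L and H
#' lists are intersected with `active`, partitioned by the case values into
#' members now below / above the gene (ties belong to neither side and are
#' excluded from the list sizes), and the gene is called deregulated when
#' the fraction of L-members now above it, or of H-members now below it,
#' reaches `h`. Direction is down when `|Ld|+|Hd| < |L|` and up when
#' `|Lu|+|Hu| < |H|`; if both hold the side with the larger perturbed
#' fraction wins and an exact tie abstains.
#'
#' @param g Gene identifier.
#' @param sample_values Named per-gene expression vector of one case sample.
#' @param reference A `reo_reference`.
#' @param active Character vector of gene ids currently usable as list
#'   members (default: all genes).
#' @param params A [detection_params()] object (only `h` is used).
#' @return `-1`, `0` or `+1`; `NA` when both effective lists are empty,
#'   signalling that the percentile fallback is required.
#' @export
classify_gene_once <- function(g, sample_values, reference,
                               active = reference$gene_ids,
                               params = detection_params()) {
  stopifnot(inherits(reference, "reo_reference"))
  if (!g %in% reference$gene_ids) stop("unknown gene: ", g, call. = FALSE)
  vg <- sample_values[[g]]
  if (!is.finite(vg)) stop("case value for ", g, " is not finite",
                           call. = FALSE)
  Lg <- intersect(reference$L[[g]], active)
  Hg <- intersect(reference$H[[g]], active)
  lu <- sum(sample_values[Lg] > vg)
  ld <- sum(sample_values[Lg] < vg)
  hd <- sum(sample_values[Hg] < vg)
  hu <- sum(sample_values[Hg] > vg)
  L_eff <- lu + ld
  H_eff <- hd + hu
  if (L_eff == 0L && H_eff == 0L) return(NA_integer_)
  p_down <- if (L_eff > 0L) lu / L_eff else -Inf
  p_up <- if (H_eff > 0L) hd / H_eff else -Inf
  if (!(p_down >= params$h || p_up >= params$h)) return(0L)
  down_ok <- (ld + hd) < L_eff
  up_ok <- (lu + hu) < H_eff
  if (down_ok && !up_ok) return(-1L)
  if (up_ok && !down_ok) return(1L)
  if (down_ok && up_ok) {
    if (p_down > p_up) return(-1L)
    if (p_up > p_down) return(1L)
  }
  0L
}

#' Percentile outlier call for one gene
#'
#' Fallback test used when a gene carries no usable ordering information:
#' the case value is compared against the `x`-th and `(100-x)`-th
#' percentiles (`p_l`, `p_u`, linear-interpolation quantiles) of the gene's
#' control distribution, with the window widened by the factor `f`. The call
#' is `-1` when `case_value < p_l / f`, `+1` when `case_value > p_u * f`,
#' and `0` otherwise.
#'
#' @param g Gene identifier (must be a row of `controls`).
#' @param case_value Expression of `g` in the case sample.
#' @param controls Control expression matrix.
#' @param x Percentile in (0, 50), in percent.
#' @param f Window expansion factor >= 1.
#' @return `-1`, `0` or `+1`.
#' @export
percentile_call <- function(g, case_value, controls, x = 2, f = 1.2) {
  controls <- as_expression_matrix(controls)
  if (!g %in% rownames(controls)) stop("unknown gene: ", g, call. = FALSE)
  if (f < 1) stop("f must be >= 1", call. = FALSE)
  vals <- controls[g, ]
  p_l <- unname(stats::quantile(vals, x / 100, type = 7))
  p_u <- unname(stats::quantile(vals, 1 - x / 100, type = 7))
  if (case_value < p_l / f) return(-1L)
  if (case_value > p_u * f) return(1L)
  0L
}

# Per-gene fallback bounds: p_l / f and p_u * f from the control matrix.
fallback_bounds <- function(controls, x, f) {
  probs <- c(x / 100, 1 - x / 100)
  q <- apply(controls, 1L, stats::quantile, probs = probs, type = 7,
             names = FALSE)
  list(lower = q[1L, ] / f, upper = q[2L, ] * f)
}

# Core single-sample iteration. `case` is the per-gene value vector aligned
# to the reference gene order; `bounds` may be NULL when fallback is "none".
detect_sample_core <- function(case, flat, bounds, params) {
  G <- flat$n
  active <- rep(TRUE, G)
  history <- list(integer(G))   # iteration 0: empty deregulated set
  sizes <- integer(0)
  status <- "max_iter"
  final <- NULL
  for (it in seq_len(params$max_iter)) {
    res <- classify_all_once(case, flat, active, params$h)
    call <- res$call
    if (!is.null(bounds) && any(res$needs_fallback)) {
      fb <- which(res$needs_fallback)
      call[fb] <- (case[fb] > bounds$upper[fb]) - (case[fb] < bounds$lower[fb])
    }
    sizes <- c(sizes, sum(call != 0L))
    prev <- history[[length(history)]]
    if (identical(call, prev)) {
      status <- "converged"
      final <- call
      break
    }
    if (length(history) >= 2L &&
        identical(call, history[[length(history) - 1L]])) {
      status <- "oscillating"
      final <- union_calls(call, prev)
      break
    }
    history[[length(history) + 1L]] <- call
    active <- call == 0L
  }
  if (is.null(final)) {  # max_iter hit: union of the last two sets
    n <- length(history)
    final <- union_calls(history[[n]], history[[n - 1L]])
    warning("iteration limit reached; returning the union of the last two ",
            "deregulated sets", call. = FALSE)
  }
  list(call = final, sizes = sizes, status = status)
}

# Union of two signed call vectors; the later iteration's direction wins.
union_calls <- function(last, prev) {
  out <- prev
  out[last != 0L] <- last[last != 0L]
  out
}

#' Call deregulation for one case sample
#'
#' Runs the iterated rank-perturbation test: every gene is classified with
#' [classify_gene_once()]'s rule, the set of deregulated genes is excluded
#' from all L/H lists, and the sweep is repeated until the set stabilises.
#' When the final iterations oscillate between two sets, the union of both
#' is returned (each gene keeping the direction of its latest nonzero
#' call). Genes with no usable ordering information are resolved by the
#' percentile fallback and, once called, participate in the exclusion like
#' any other deregulated gene.
#'
#' @param case Named per-gene expression vector (or single-column matrix)
#'   covering exactly the reference's gene universe.
#' @param reference A `reo_reference` built from the control cohort.
#' @param controls Control expression matrix used by the percentile
#'   fallback; must cover the reference's gene universe.
#' @param params A [detection_params()] object.
#' @return A list with `call` (named integer vector in `{-1, 0, 1}`),
#'   `sizes` (deregulated-set size at each iteration) and `status`
#'   (`"converged"`, `"oscillating"` or `"max_iter"`).
#' @export
detect_sample <- function(case, reference, controls,
                          params = detection_params()) {
  stopifnot(inherits(reference, "reo_reference"))
  if (is.matrix(case)) {
    stopifnot(ncol(case) == 1L)
    case <- stats::setNames(case[, 1L], rownames(case))
  }
  if (is.null(names(case)) || !setequal(names(case), reference$gene_ids)) {
    stop("case gene universe does not match the reference", call. = FALSE)
  }
  case <- case[reference$gene_ids]
  flat <- flatten_reference(reference)
  bounds <- NULL
  if (params$fallback == "percentile") {
    controls <- as_expression_matrix(controls)
    if (!all(reference$gene_ids %in% rownames(controls))) {
      stop("controls do not cover the reference gene universe",
           call. = FALSE)
    }
    bounds <- fallback_bounds(controls[reference$gene_ids, , drop = FALSE],
                              params$x, params$f)
  }
  res <- detect_sample_core(unname(case), flat, bounds, params)
  res$call <- stats::setNames(res$call, reference$gene_ids)
  res
}

#' Call deregulation for a cohort of case samples
#'
#' Applies [detect_sample()] to every column of `cases`. Samples are fully
#' independent: the calls for one sample never depend on which other samples
#' are present.
#'
#' @param cases Case expression matrix (genes x samples) sharing the
#'   reference's gene universe.
#' @param reference A `reo_reference`.
#' @param controls Control expression matrix (percentile fallback).
#' @param params A [detection_params()] object.
#' @return An object of class `dereg_calls`: a list with `calls` (integer
#'   genes x samples matrix in `{-1, 0, 1}`), `iteration_log` (tibble with
#'   `sample`, `iteration`, `n_dereg`, `status`) and `params`.
#' @export
detect_cohort <- function(cases, reference, controls,
                          params = detection_params()) {
  stopifnot(inherits(reference, "reo_reference"))
  cases <- as_expression_matrix(cases)
  if (!setequal(rownames(cases), reference$gene_ids)) {
    stop("case gene universe does not match the reference", call. = FALSE)
  }
  cases <- cases[reference$gene_ids, , drop = FALSE]
  flat <- flatten_reference(reference)
  bounds <- NULL
  if (params$fallback == "percentile") {
    controls <- as_expression_matrix(controls)
    if (!all(reference$gene_ids %in% rownames(controls))) {
      stop("controls do not cover the reference gene universe",
           call. = FALSE)
    }
    bounds <- fallback_bounds(controls[reference$gene_ids, , drop = FALSE],
                              params$x, params$f)
  }
  calls <- matrix(0L, nrow = nrow(cases), ncol = ncol(cases),
                  dimnames = dimnames(cases))
  logs <- vector("list", ncol(cases))
  for (j in seq_len(ncol(cases))) {
    res <- detect_sample_core(cases[, j], flat, bounds, params)
    calls[, j] <- res$call
    logs[[j]] <- tibble::tibble(
      sample = colnames(cases)[j],
      iteration = seq_along(res$sizes),
      n_dereg = res$sizes,
      status = res$status
    )
  }
  new_dereg_calls(calls, dplyr::bind_rows(logs), params)
}

new_dereg_calls <- function(calls, iteration_log, params) {
  structure(list(calls = calls, iteration_log = iteration_log,
                 params = params),
            class = "dereg_calls")
}

#' @export
print.dereg_calls <- function(x, ...) {
  cat("<dereg_calls> ", nrow(x$calls), " genes x ", ncol(x$calls),
      " samples\n", sep = "")
  cat("  up: ", sum(x$calls == 1L), " cells, down: ", sum(x$calls == -1L),
      " cells (", round(100 * mean(x$calls != 0L), 2),
      "% of cells deregulated)\n", sep = "")
  if (nrow(x$iteration_log) > 0L) {
    st <- table(dplyr::distinct(x$iteration_log,
                                .data$sample, .data$status)$status)
    cat("  convergence: ", paste(names(st), st, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Binary views of a deregulation matrix
#'
#' `dereg_up()`, `dereg_down()` and `dereg_total()` return the binary
#' genes x samples indicator matrices of up-, down- and total deregulation
#' (total = up + down, still binary since a cell cannot be both).
#'
#' @param x A `dereg_calls` object or a calls matrix in `{-1, 0, 1}`.
#' @return An integer 0/1 matrix.
#' @export
dereg_up <- function(x) (calls_matrix(x) == 1L) + 0L

#' @rdname dereg_up
#' @export
dereg_down <- function(x) (calls_matrix(x) == -1L) + 0L

#' @rdname dereg_up
#' @export
dereg_total <- function(x) (calls_matrix(x) != 0L) + 0L

calls_matrix <- function(x) {
  m <- if (inherits(x, "dereg_calls")) x$calls else x
  if (!is.matrix(m)) stop("expected a dereg_calls object or a calls matrix",
                          call. = FALSE)
  if (!all(m %in% c(-1L, 0L, 1L))) {
    stop("calls must lie in {-1, 0, 1}", call. = FALSE)
  }
  m
}

#' Tidy deregulation calls into long format
#'
#' @param x A `dereg_calls` object.
#' @param ... Unused.
#' @return Tibble with `gene`, `sample`, `call`.
#' @export
tidy.dereg_calls <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$calls), times = ncol(x$calls)),
    sample = rep(colnames(x$calls), each = nrow(x$calls)),
    call = as.integer(x$calls)
  )
}

#' One-row summary of a deregulation matrix
#'
#' @param x A `dereg_calls` object.
#' @param ... Unused.
#' @return Tibble with dimensions, call fractions and convergence counts.
#' @export
glance.dereg_calls <- function(x, ...) {
  st <- dplyr::distinct(x$iteration_log, .data$sample, .data$status)$status
  tibble::tibble(
    n_genes = nrow(x$calls),
    n_samples = ncol(x$calls),
    frac_up = mean(x$calls == 1L),
    frac_down = mean(x$calls == -1L),
    frac_total = mean(x$calls != 0L),
    n_converged = sum(st == "converged"),
    n_oscillating = sum(st == "oscillating"),
    n_max_iter = sum(st == "max_iter")
  )
}

#' Write / read a deregulation call matrix as TSV
#'
#' @param x A `dereg_calls` object or calls matrix.
#' @param path File path.
#' @return `write_calls()` returns `path` invisibly; `read_calls()` returns
#'   an integer matrix in `{-1, 0, 1}`.
#' @export
write_calls <- function(x, path) {
  m <- calls_matrix(x)
  lines <- c(
    paste(c("gene_id", colnames(m)), collapse = "\t"),
    paste(rownames(m), apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  m <- read_expression_matrix_signed(path)
  if (!all(m %in% c(-1, 0, 1))) {
    stop("call file contains values outside {-1, 0, 1}", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

# Like read_expression_matrix() but allows negative entries (call matrices).
read_expression_matrix_signed <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  genes <- vapply(body, `[[`, character(1), 1L)
  samples <- header[-1L]
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE)))
  matrix(vals, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}
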