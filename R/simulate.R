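#' Fit a rank-packet perturbation model from control and tumor cohorts
#'
#' All control expression values (every gene in every control sample) are
#' ranked in ascending order and chunked into consecutive packets of
#' `packet_size` values of similar magnitude (the last packet may be
#' smaller). For each packet the model records the distribution of
#' within-control differences `dn` (each packet value against the same gene
#' in every other control), the tumor-minus-control differences `dc` (each
#' packet value against the same gene in every tumor), the `lo`/`hi`
#' percentile band of `dn`, the outlier subset `dc_prime` of `dc` lying
#' outside that band (the pool of "abnormal" perturbations), and the
#' deregulation probability `r = |dc_prime| / |dc|`.
#'
#' @param controls Control expression matrix (genes x samples).
#' @param tumors Tumor expression matrix sharing the gene universe. Use
#'   [surrogate_packet_model()] when no tumor cohort is available.
#' @param packet_size Number of (gene, sample) values per packet (>= 2).
#' @param lo,hi Percentile bounds (in percent) of the normal-difference band.
#' @return An object of class `packet_model`; see Details.
#' @details The returned object holds `cell_packet`, the genes x samples
#'   integer matrix assigning every control cell to its packet, so that
#'   [simulate_tumors()] can look up the packet of each gene of a chosen
#'   source control in O(1). Packets with an empty `dc` get `r = 0`.
#' @export
fit_packet_model <- function(controls, tumors, packet_size = 100,
                             lo = 5, hi = 95) {
  controls <- as_expression_matrix(controls)
  if (missing(tumors) || is.null(tumors)) {
    stop("no tumor cohort supplied; use surrogate_packet_model() for ",
         "fully synthetic perturbation pools", call. = FALSE)
  }
  tumors <- as_expression_matrix(tumors)
  if (!setequal(rownames(tumors), rownames(controls))) {
    stop("controls and tumors must share the gene universe", call. = FALSE)
  }
  tumors <- tumors[rownames(controls), , drop = FALSE]
  pk <- packetize(controls, packet_size)
  n_pk <- pk$n_packets
  pools <- vector("list", n_pk)
  r <- numeric(n_pk)
  p_lo <- numeric(n_pk)
  p_hi <- numeric(n_pk)
  for (k in seq_len(n_pk)) {
    dn <- packet_normal_diffs(controls, pk, k)
    band <- stats::quantile(dn, c(lo, hi) / 100, type = 7, names = FALSE)
    p_lo[k] <- band[1L]
    p_hi[k] <- band[2L]
    gi <- pk$gene_idx[pk$packet == k]
    si <- pk$sample_idx[pk$packet == k]
    dc <- as.numeric(tumors[gi, , drop = FALSE] - controls[cbind(gi, si)])
    keep <- dc < band[1L] | dc > band[2L]
    pools[[k]] <- dc[keep]
    r[k] <- if (length(dc) > 0L) mean(keep) else 0
  }
  new_packet_model(controls, pk, pools, r, p_lo, p_hi, packet_size, lo, hi,
                   surrogate = FALSE)
}

#' Build a packet model with surrogate perturbation pools
#'
#' When no real tumor cohort exists (fully synthetic benchmarking), the
#' abnormal-difference pools cannot be estimated from data. This constructor
#' computes the packets and their normal-difference bands exactly as
#' [fit_packet_model()] does, then fills each pool with synthetic
#' perturbations: `delta = s * (m_k * (2^u - 1) + band_k)` upward or
#' `delta = -(m_k * (1 - 2^-u) + band_k)` downward, with random sign `s`,
#' `u ~ Unif(1, 3)` (2- to 8-fold changes), `m_k` the packet's median
#' expression and `band_k = max(|p_lo|, |p_hi|)`. Every element therefore
#' lies strictly outside the normal band and has the magnitude of a
#' multi-fold expression change. The deregulation probabilities `r` are left
#' `NA`: a surrogate model can only be used in fixed-proportion mode.
#'
#' This is fixture machinery for benchmarking without case data, not an
#' estimate of real tumor differences.
#'
#' @inheritParams fit_packet_model
#' @param n_per_packet Number of synthetic perturbations per packet pool.
#' @param seed Integer seed making the pools reproducible.
#' @return A `packet_model` with `surrogate = TRUE`.
#' @export
surrogate_packet_model <- function(controls, packet_size = 100,
                                   lo = 5, hi = 95, n_per_packet = 200,
                                   seed = 1) {
  controls <- as_expression_matrix(controls)
  pk <- packetize(controls, packet_size)
  n_pk <- pk$n_packets
  pools <- vector("list", n_pk)
  p_lo <- numeric(n_pk)
  p_hi <- numeric(n_pk)
  withr::with_seed(seed, {
    for (k in seq_len(n_pk)) {
      dn <- packet_normal_diffs(controls, pk, k)
      band <- stats::quantile(dn, c(lo, hi) / 100, type = 7, names = FALSE)
      p_lo[k] <- band[1L]
      p_hi[k] <- band[2L]
      m_k <- stats::median(pk$values[pk$packet == k])
      band_k <- max(abs(band))
      s <- sample(c(-1, 1), n_per_packet, replace = TRUE)
      u <- stats::runif(n_per_packet, 1, 3)
      mag <- ifelse(s > 0, m_k * (2^u - 1), m_k * (1 - 2^-u)) + band_k
      pools[[k]] <- s * mag
    }
  })
  new_packet_model(controls, pk, pools, rep(NA_real_, n_pk), p_lo, p_hi,
                   packet_size, lo, hi, surrogate = TRUE)
}

# Rank all control cells ascending and cut into consecutive packets.
packetize <- function(controls, packet_size) {
  if (!is.numeric(packet_size) || length(packet_size) != 1L ||
      packet_size < 2) {
    stop("packet_size must be >= 2", call. = FALSE)
  }
  packet_size <- as.integer(packet_size)
  n_cells <- length(controls)
  ord <- order(controls)            # column-major cell order as tiebreak
  packet_of_rank <- rep(seq_len(ceiling(n_cells / packet_size)),
                        each = packet_size, length.out = n_cells)
  gene_idx <- ((ord - 1L) %% nrow(controls)) + 1L
  sample_idx <- ((ord - 1L) %/% nrow(controls)) + 1L
  cell_packet <- matrix(0L, nrow(controls), ncol(controls),
                        dimnames = dimnames(controls))
  cell_packet[ord] <- packet_of_rank
  list(values = controls[ord], gene_idx = gene_idx, sample_idx = sample_idx,
       packet = packet_of_rank, cell_packet = cell_packet,
       n_packets = max(packet_of_rank))
}

# Within-control differences for packet k: each packet cell's gene compared
# against the same gene in every other control sample.
packet_normal_diffs <- function(controls, pk, k) {
  sel <- pk$packet == k
  gi <- pk$gene_idx[sel]
  si <- pk$sample_idx[sel]
  vals <- pk$values[sel]
  d <- controls[gi, , drop = FALSE] - vals
  own <- cbind(seq_along(gi), si)
  d[own] <- NA
  d <- as.numeric(d)
  d[!is.na(d)]
}

new_packet_model <- function(controls, pk, pools, r, p_lo, p_hi,
                             packet_size, lo, hi, surrogate) {
  structure(
    list(gene_ids = rownames(controls), sample_ids = colnames(controls),
         cell_packet = pk$cell_packet, pools = pools, r = r,
         p_lo = p_lo, p_hi = p_hi, n_packets = pk$n_packets,
         packet_size = packet_size, lo = lo, hi = hi,
         surrogate = surrogate),
    class = "packet_model"
  )
}

#' @export
print.packet_model <- function(x, ...) {
  cat("<packet_model> ", x$n_packets, " packets of size ", x$packet_size,
      if (x$surrogate) " (surrogate pools)", "\n", sep = "")
  cat("  band: ", x$lo, "% / ", x$hi, "% percentiles of normal differences\n",
      sep = "")
  if (!anyNA(x$r)) {
    cat("  deregulation probability r: ",
        paste(round(stats::quantile(x$r, c(0, .5, 1)), 3),
              collapse = " / "), " (min/median/max)\n", sep = "")
  }
  invisible(x)
}

#' Simulate tumors from a control cohort with known ground truth
#'
#' Each simulated tumor starts as a copy of one uniformly chosen control
#' sample. Every gene is then perturbed independently — with probability
#' `r(k)` of its packet, or with the fixed `proportion` if given — by adding
#' one uniformly chosen element of the packet's abnormal-difference pool.
#' Perturbed values falling below zero are clipped to zero (and flagged);
#' the ground-truth label records the sign of the added perturbation.
#'
#' @param model A `packet_model` fitted on `controls`.
#' @param controls The same control matrix the model was fitted on.
#' @param n_tumors Number of tumors to simulate.
#' @param proportion Optional fixed deregulation probability in (0, 1) (or
#'   exactly 0 for a pure negative control), overriding the per-packet `r`.
#'   Required for surrogate models.
#' @param seed Integer seed. Per-tumor substreams are derived
#'   deterministically from it, so growing `n_tumors` leaves earlier tumors
#'   unchanged.
#' @return An object of class `sim_dataset`: list with `cases` (matrix),
#'   `truth` (integer matrix in `{-1, 0, 1}`), `source_sample` (named
#'   character, per tumor), `clipped` (logical matrix), `seed`.
#' @export
simulate_tumors <- function(model, controls, n_tumors, proportion = NULL,
                            seed = 1) {
  stopifnot(inherits(model, "packet_model"))
  controls <- as_expression_matrix(controls)
  if (!identical(rownames(controls), model$gene_ids) ||
      !identical(colnames(controls), model$sample_ids)) {
    stop("controls do not match the matrix the packet model was fitted on",
         call. = FALSE)
  }
  if (!is.null(proportion)) {
    if (!is.numeric(proportion) || length(proportion) != 1L ||
        proportion < 0 || proportion >= 1) {
      stop("proportion must lie in [0, 1)", call. = FALSE)
    }
  } else if (anyNA(model$r)) {
    stop("surrogate packet models carry no r(k); supply a fixed proportion",
         call. = FALSE)
  }
  n_tumors <- as.integer(n_tumors)
  stopifnot(n_tumors >= 1L)
  G <- nrow(controls)
  pool_len <- lengths(model$pools)
  cases <- matrix(0, G, n_tumors,
                  dimnames = list(rownames(controls),
                                  sprintf("sim%02d", seq_len(n_tumors))))
  truth <- matrix(0L, G, n_tumors, dimnames = dimnames(cases))
  clipped <- matrix(FALSE, G, n_tumors, dimnames = dimnames(cases))
  sources <- character(n_tumors)
  for (j in seq_len(n_tumors)) {
    tumor_seed <- (seed + j * 7919) %% 2147483629
    withr::with_seed(tumor_seed, {
      src <- sample.int(ncol(controls), 1L)
      sources[j] <- colnames(controls)[src]
      vals <- controls[, src]
      k <- model$cell_packet[, src]
      p <- if (is.null(proportion)) model$r[k] else rep(proportion, G)
      hit <- stats::runif(G) < p
      if (any(hit & pool_len[k] == 0L)) {
        stop("packet with empty perturbation pool but positive ",
             "deregulation probability", call. = FALSE)
      }
      idx <- which(hit)
      if (length(idx) > 0L) {
        delta <- vapply(idx, function(i) {
          pool <- model$pools[[k[i]]]
          pool[sample.int(length(pool), 1L)]
        }, numeric(1))
        vals[idx] <- vals[idx] + delta
        truth[idx, j] <- as.integer(sign(delta))
        neg <- idx[vals[idx] < 0]
        vals[neg] <- 0
        clipped[neg, j] <- TRUE
      }
      cases[, j] <- vals
    })
  }
  structure(
    list(cases = cases, truth = truth,
         source_sample = stats::setNames(sources, colnames(cases)),
         clipped = clipped, seed = seed),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$cases), " genes x ", ncol(x$cases),
      " simulated tumors (seed ", x$seed, ")\n", sep = "")
  cat("  mean deregulated fraction: ",
      round(mean(colMeans(x$truth != 0L)), 3), "\n", sep = "")
  cat("  source controls: ",
      paste(unique(x$source_sample), collapse = ", "), "\n", sep = "")
  invisible(x)
}
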