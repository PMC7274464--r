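#' Generate a synthetic control cohort
#'
#' Builds a fully synthetic genes x samples expression matrix with the two
#' features the rank detector relies on: per-gene base levels spanning
#' several orders of magnitude (heavy-tailed, log-normal across genes) and
#' stable within-gene ordering across samples (multiplicative log-normal
#' noise around each base level). It emulates the rank structure of a
#' normalized bulk expression cohort, not count-level sampling noise or
#' gene-gene correlation.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_controls Number of control samples (>= 1).
#' @param meanlog,sdlog Log-scale location and spread of the per-gene base
#'   levels; the default spread makes per-gene medians span more than three
#'   orders of magnitude.
#' @param noise_sdlog Log-scale standard deviation of the per-sample
#'   multiplicative noise around each gene's base level.
#' @param seed Integer seed; the matrix is fully reproducible from it.
#' @return An expression matrix with gene ids `g0001, ...` and sample ids
#'   `ctrl01, ...`.
#' @examples
#' ctl <- generate_controls(n_genes = 100, n_controls = 10, seed = 7)
#' range(apply(ctl, 1, median))
#' @export
generate_controls <- function(n_genes = 5000, n_controls = 97,
                              meanlog = 4, sdlog = 1.5, noise_sdlog = 0.2,
                              seed = 1) {
  stopifnot(n_genes >= 2, n_controls >= 1, sdlog > 0, noise_sdlog >= 0)
  withr::with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
    noise <- matrix(stats::rnorm(n_genes * n_controls, 0, noise_sdlog),
                    n_genes, n_controls)
    m <- base * exp(noise)
  })
  dimnames(m) <- list(
    sprintf("g%0*d", max(4L, nchar(n_genes)), seq_len(n_genes)),
    sprintf("ctrl%0*d", max(2L, nchar(n_controls)), seq_len(n_controls))
  )
  m
}
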