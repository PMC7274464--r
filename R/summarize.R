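#' Per-sample deregulation burden
#'
#' @param calls A `dereg_calls` object or calls matrix in `{-1, 0, 1}`.
#' @return A tibble with one row per sample: counts and percentages of up-
#'   and down-regulated genes over the gene universe, and the down/up ratio
#'   (`NA` when no gene is up).
#' @export
sample_burden <- function(calls) {
  m <- calls_matrix(calls)
  n_up <- colSums(m == 1L)
  n_down <- colSums(m == -1L)
  tibble::tibble(
    sample = colnames(m),
    n_up = unname(n_up),
    n_down = unname(n_down),
    pct_up = unname(100 * n_up / nrow(m)),
    pct_down = unname(100 * n_down / nrow(m)),
    pct_total = unname(100 * (n_up + n_down) / nrow(m)),
    down_up_ratio = unname(ifelse(n_up > 0L, n_down / n_up, NA_real_))
  )
}

#' Per-gene deregulation profile and super-pattern classification
#'
#' Summarises each gene across a cohort of calls: the fraction of samples
#' where it is up, down, or deregulated at all, and its commitment
#' (up / (up + down) among deregulated samples). Genes are then tested for
#' the three "super" patterns against the cohort-wide mean deregulation
#' frequency `mu` (the grand mean of the relevant 0/1 indicator matrix):
#'
#' * super-up: deregulated-up count above the cohort's median total
#'   deregulation count, expressed in controls, and significantly more often
#'   up than `mu` of the up-indicator matrix;
#' * super-down: symmetric, on the down indicators;
#' * super-conserved: total deregulation count below the median, expressed
#'   in controls, and significantly less often deregulated than `mu` of the
#'   total indicator matrix.
#'
#' Significance is a per-gene one-sample t-test of the indicator vector
#' against `mu`, Benjamini-Hochberg adjusted across genes. A constant
#' indicator vector has no t-statistic; such genes carry an infinite
#' sentinel and count as significant exactly when the constant differs from
#' `mu` (flagged in the `zero_variance` column).
#'
#' @param calls A `dereg_calls` object or calls matrix.
#' @param controls Control expression matrix (for the expression condition).
#' @param count_min Expression value that must be exceeded in controls.
#' @param count_frac Fraction of control samples that must exceed it.
#' @param alpha Adjusted-significance threshold.
#' @return A tibble with one row per gene: deregulation fractions,
#'   `commitment`, the t-statistic / p / q of the test backing the assigned
#'   label (the total-deregulation test for unlabeled genes),
#'   `zero_variance`, and `super_label` in
#'   `{"none", "super_up", "super_down", "super_conserved"}`.
#' @details A gene qualifying for both super-up and super-down (possible
#'   when both counts exceed the median) is assigned the side with the
#'   larger count; an exact tie leaves it unlabeled.
#' @export
super_pattern_classify <- function(calls, controls, count_min = 10,
                                   count_frac = 0.8, alpha = 0.05) {
  m <- calls_matrix(calls)
  controls <- as_expression_matrix(controls)
  if (!all(rownames(m) %in% rownames(controls))) {
    stop("calls and controls must share the gene universe", call. = FALSE)
  }
  controls <- controls[rownames(m), , drop = FALSE]
  S <- ncol(m)
  if (S < 2L) stop("need at least 2 samples for the super test",
                   call. = FALSE)
  U <- dereg_up(m)
  D <- dereg_down(m)
  Tot <- dereg_total(m)
  med_tot <- stats::median(rowSums(Tot))
  expressed <- rowMeans(controls > count_min) >= count_frac

  test_mat <- function(X) {
    mu <- mean(X)
    xbar <- rowMeans(X)
    s <- apply(X, 1L, stats::sd)
    t_stat <- ifelse(s > 0, (xbar - mu) / (s / sqrt(S)),
                     ifelse(xbar == mu, 0, Inf * sign(xbar - mu)))
    p <- ifelse(s > 0, 2 * stats::pt(-abs(t_stat), df = S - 1L), NA_real_)
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    sig <- ifelse(s > 0, q < alpha, xbar != mu)
    list(mu = mu, t = t_stat, p = p, q = q, sig = sig, zero_var = s == 0)
  }
  t_up <- test_mat(U)
  t_down <- test_mat(D)
  t_tot <- test_mat(Tot)

  su <- rowSums(U) > med_tot & expressed & t_up$sig
  sd_ <- rowSums(D) > med_tot & expressed & t_down$sig
  sc <- rowSums(Tot) < med_tot & expressed & t_tot$sig
  label <- rep("none", nrow(m))
  label[sc] <- "super_conserved"
  both <- su & sd_
  label[su & !both] <- "super_up"
  label[sd_ & !both] <- "super_down"
  label[both & rowSums(U) > rowSums(D)] <- "super_up"
  label[both & rowSums(D) > rowSums(U)] <- "super_down"

  pick <- function(field) {
    out <- t_tot[[field]]
    out[label == "super_up"] <- t_up[[field]][label == "super_up"]
    out[label == "super_down"] <- t_down[[field]][label == "super_down"]
    out
  }
  n_dereg <- rowSums(Tot)
  tibble::tibble(
    gene = rownames(m),
    frac_up = unname(rowMeans(U)),
    frac_down = unname(rowMeans(D)),
    frac_total = unname(rowMeans(Tot)),
    commitment = unname(ifelse(n_dereg > 0, rowSums(U) / n_dereg,
                               NA_real_)),
    expressed_in_controls = unname(expressed),
    t_statistic = unname(pick("t")),
    p_value = unname(pick("p")),
    q_value = unname(pick("q")),
    zero_variance = unname(pick("zero_var")),
    super_label = label
  )
}

#' Compare deregulation proportions between two cohorts
#'
#' Thin convenience wrapper around [stats::prop.test()] (two-sided
#' two-proportion z-test with continuity correction disabled), applied per
#' gene with multiple-testing adjustment. Non-novel utility for contrasting
#' how often a gene is deregulated in two cohorts.
#'
#' @param count1,count2 Per-gene deregulated-sample counts (named vectors).
#' @param n1,n2 Cohort sizes.
#' @param adjust Method passed to [stats::p.adjust()].
#' @return Tibble with `gene`, the two proportions, `p_value`, `q_value`.
#' @export
compare_deregulation_proportions <- function(count1, n1, count2, n2,
                                             adjust = "bonferroni") {
  stopifnot(length(count1) == length(count2))
  p <- vapply(seq_along(count1), function(i) {
    suppressWarnings(
      stats::prop.test(c(count1[i], count2[i]), c(n1, n2),
                       correct = FALSE)$p.value)
  }, numeric(1))
  tibble::tibble(
    gene = if (!is.null(names(count1))) names(count1)
           else as.character(seq_along(count1)),
    prop1 = unname(count1 / n1),
    prop2 = unname(count2 / n2),
    p_value = p,
    q_value = stats::p.adjust(p, method = adjust)
  )
}
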