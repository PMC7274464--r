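# Shared fixtures and independent oracles used across the suite.

# Small labelled matrix builder.
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# The 3-gene control cohort used in several hand traces.
toy_controls <- function() {
  toy_matrix(c(1, 2, 3, 10, 11, 12, 100, 90, 110),
             c("g1", "g2", "g3"), c("s1", "s2", "s3"))
}

# Random control cohort with log-normal levels and multiplicative noise;
# kept independent of generate_controls() so the two can cross-check.
random_cohort <- function(n_genes, n_samples, seed, noise = 0.3) {
  set.seed(seed)
  base <- exp(stats::runif(n_genes, 0, 8))
  m <- base * exp(matrix(stats::rnorm(n_genes * n_samples, 0, noise),
                         n_genes, n_samples))
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n_samples)))
  m
}

# Exhaustive O(G^2 * S) comparator for the ordering reference: for every
# gene pair, counts samples with a strict ordering, forms the unrestricted
# candidate sets, then truncates each to the l genes with the closest
# control median (ties by input gene order).
brute_force_reference <- function(controls, threshold_LH, l) {
  genes <- rownames(controls)
  G <- length(genes)
  med <- apply(controls, 1, stats::median)
  L <- vector("list", G)
  H <- vector("list", G)
  for (i in seq_len(G)) {
    lower <- logical(G)
    higher <- logical(G)
    for (j in seq_len(G)) {
      if (i == j) next
      lower[j] <- mean(controls[j, ] < controls[i, ]) >= threshold_LH
      higher[j] <- mean(controls[j, ] > controls[i, ]) >= threshold_LH
    }
    pick <- function(cand) {
      idx <- which(cand)
      idx <- idx[order(abs(med[idx] - med[i]), idx)]
      genes[utils::head(idx, l)]
    }
    L[[i]] <- pick(lower)
    H[[i]] <- pick(higher)
  }
  names(L) <- genes
  names(H) <- genes
  list(L = L, H = H, medians = med)
}

# Oscillating four-gene fixture: in the case sample gene "b" has risen above
# gene "a" although b < a in every control. Evaluated jointly the pair
# implicates each other; excluding either removes the other's evidence, so
# the deregulated set alternates between {a, b} and {} until the union rule
# resolves it.
oscillation_fixture <- function() {
  ctl <- toy_matrix(c(10, 10, 10, 8, 8, 8, 20, 20, 20, 2, 2, 2),
                    c("a", "b", "u1", "v1"), c("s1", "s2", "s3"))
  case <- c(a = 10, b = 12, u1 = 20, v1 = 2)
  list(controls = ctl, case = case)
}
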