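test_that("packetization sorts all control cells into equal chunks", {
  m <- random_cohort(30, 5, seed = 8)
  model <- surrogate_packet_model(m, packet_size = 20, seed = 1)
  expect_identical(model$n_packets, as.integer(ceiling(150 / 20)))
  # cell -> packet assignment respects the global value ordering
  k <- model$cell_packet
  expect_identical(dim(k), dim(m))
  ord <- order(m)
  expect_true(all(diff(k[ord]) >= 0))
  sizes <- tabulate(k)
  expect_true(all(sizes[-length(sizes)] == 20L))
  expect_identical(sum(sizes), length(m))
})

test_that("single-packet fit matches exhaustive enumeration", {
  ctl <- toy_matrix(c(1, 2, 3,
                      10, 12, 11,
                      100, 90, 95,
                      1000, 1100, 900),
                    paste0("g", 1:4), paste0("s", 1:3))
  tum <- toy_matrix(c(5, 0,
                      50, 12,
                      100, 400,
                      100, 1000),
                    paste0("g", 1:4), c("t1", "t2"))
  model <- fit_packet_model(ctl, tum, packet_size = 12, lo = 5, hi = 95)
  expect_identical(model$n_packets, 1L)

  # oracle: plain loops over every cell
  dn <- c()
  dc <- c()
  for (g in 1:4) {
    for (s in 1:3) {
      dn <- c(dn, unname(ctl[g, -s] - ctl[g, s]))
      dc <- c(dc, unname(tum[g, ] - ctl[g, s]))
    }
  }
  band <- unname(quantile(dn, c(0.05, 0.95), type = 7))
  pool <- dc[dc < band[1] | dc > band[2]]
  expect_equal(model$p_lo, band[1])
  expect_equal(model$p_hi, band[2])
  expect_equal(sort(model$pools[[1]]), sort(pool))
  expect_equal(model$r, length(pool) / length(dc))
})

test_that("constant controls give a degenerate normal band", {
  ctl <- toy_matrix(rep(c(5, 70), each = 4), c("gA", "gB"),
                    paste0("s", 1:4))
  tum <- toy_matrix(c(5, 6, 70, 68), c("gA", "gB"), c("t1", "t2"))
  model <- fit_packet_model(ctl, tum, packet_size = 4)
  expect_identical(model$p_lo, c(0, 0))
  expect_identical(model$p_hi, c(0, 0))
  # every nonzero tumor difference is an outlier; zero differences are not
  expect_setequal(model$pools[[1]], 1)       # gA: diffs 0 and +1
  expect_setequal(model$pools[[2]], -2)      # gB: diffs 0 and -2
})

test_that("surrogate pools lie strictly outside the normal band", {
  m <- random_cohort(40, 6, seed = 17)
  model <- surrogate_packet_model(m, packet_size = 30, n_per_packet = 50,
                                  seed = 3)
  expect_true(all(is.na(model$r)))
  for (k in seq_len(model$n_packets)) {
    pool <- model$pools[[k]]
    expect_true(all(pool < model$p_lo[k] | pool > model$p_hi[k]))
  }
  # reproducible
  again <- surrogate_packet_model(m, packet_size = 30, n_per_packet = 50,
                                  seed = 3)
  expect_identical(model$pools, again$pools)
})

test_that("zero proportion reproduces the chosen control exactly", {
  m <- random_cohort(50, 6, seed = 23)
  model <- surrogate_packet_model(m, packet_size = 50, seed = 2)
  sims <- simulate_tumors(model, m, n_tumors = 3, proportion = 0, seed = 5)
  expect_true(all(sims$truth == 0L))
  for (j in 1:3) {
    expect_identical(unname(sims$cases[, j]),
                     unname(m[, sims$source_sample[j]]))
  }
})

test_that("fixed proportions are realized within binomial bounds", {
  m <- random_cohort(2000, 10, seed = 29)
  model <- surrogate_packet_model(m, packet_size = 100, seed = 4)
  for (p in c(0.05, 0.3, 0.9)) {
    sims <- simulate_tumors(model, m, n_tumors = 5, proportion = p,
                            seed = 11)
    counts <- colSums(sims$truth != 0L)
    sigma <- sqrt(2000 * p * (1 - p))
    expect_true(all(abs(counts - 2000 * p) <= 3 * sigma),
                label = sprintf("p = %.2f realized in 3 sigma", p))
  }
})

test_that("simulations are seed-reproducible and prefix-stable", {
  m <- random_cohort(80, 5, seed = 37)
  model <- surrogate_packet_model(m, packet_size = 40, seed = 6)
  a <- simulate_tumors(model, m, 4, proportion = 0.3, seed = 9)
  b <- simulate_tumors(model, m, 4, proportion = 0.3, seed = 9)
  expect_identical(a, b)
  # growing n_tumors leaves earlier tumors unchanged
  bigger <- simulate_tumors(model, m, 6, proportion = 0.3, seed = 9)
  expect_identical(bigger$cases[, 1:4], a$cases)
  expect_identical(bigger$truth[, 1:4], a$truth)
  # a different seed changes the draw
  c_ <- simulate_tumors(model, m, 4, proportion = 0.3, seed = 10)
  expect_false(identical(a$cases, c_$cases))
})

test_that("truth labels track perturbations exactly", {
  m <- random_cohort(300, 8, seed = 43)
  model <- surrogate_packet_model(m, packet_size = 100, seed = 7)
  sims <- simulate_tumors(model, m, 5, proportion = 0.4, seed = 13)
  for (j in 1:5) {
    src <- m[, sims$source_sample[j]]
    un <- sims$truth[, j] == 0L
    # unperturbed genes carry the source control's values bit-identically
    expect_identical(unname(sims$cases[un, j]), unname(src[un]))
    # perturbed genes moved in the labelled direction (modulo clipping)
    moved <- !un & !sims$clipped[, j]
    expect_true(all(sign(sims$cases[moved, j] - src[moved]) ==
                      sims$truth[moved, j]))
    expect_true(all(sims$cases[sims$clipped[, j], j] == 0))
  }
})

test_that("invalid simulation inputs are rejected", {
  m <- random_cohort(20, 4, seed = 47)
  model <- surrogate_packet_model(m, packet_size = 20, seed = 1)
  expect_error(simulate_tumors(model, m, 2, seed = 1), "proportion")
  expect_error(simulate_tumors(model, m, 2, proportion = 1.5, seed = 1),
               "proportion")
  expect_error(simulate_tumors(model, m[, c(2, 1, 3, 4)], 2,
                               proportion = 0.2, seed = 1), "match")
  expect_error(fit_packet_model(m, NULL), "tumor")
  expect_error(fit_packet_model(m, m, packet_size = 1), "packet_size")
})
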