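# A 3-variable DBN with a strong within-slice chain and self-edges, used
# throughout: small enough for the exhaustive oracle, strong enough that
# the posterior is informative.
chain_fixture <- function(rows = 500, seed = 7) {
  tr <- generate_true_dbn(3, within_density = 0.5, between_density = 0.1,
                          self_edge_prob = 1, seed = seed)
  pan <- simulate_cohort(tr, rows, 2, seed = seed + 1)
  tt <- build_transition_table(pan)
  list(truth = tr, tt = tt,
       st = build_score_table(tt, ess = 1, max_parents = 2))
}

test_that("identical seeds give byte-identical samples", {
  fx <- chain_fixture(rows = 100)
  a <- sample_dags(fx$st, n_samples = 50, chain_length = 2000,
                   burn_in = 500, seed = 99)
  b <- sample_dags(fx$st, n_samples = 50, chain_length = 2000,
                   burn_in = 500, seed = 99)
  expect_identical(a, b)
  expect_false(identical(
    a$w_mask,
    sample_dags(fx$st, n_samples = 50, chain_length = 2000,
                burn_in = 500, seed = 100)$w_mask))
})

test_that("every draw respects acyclicity, the blacklist and the cap", {
  fx <- chain_fixture(rows = 150)
  for (m in c("partition", "structure")) {
    smp <- sample_dags(fx$st, n_samples = 200, chain_length = 5000,
                       burn_in = 1000, seed = 3, method = m)
    for (d in seq_len(200)) {
      W <- matrix(0L, 3, 3); B <- matrix(0L, 3, 3)
      for (j in 1:3) {
        W[dbncausal:::bits_of(smp$w_mask[d, j], 3), j] <- 1L
        B[dbncausal:::bits_of(smp$b_mask[d, j], 3), j] <- 1L
      }
      expect_silent(dbn_structure(W, B))   # validates W acyclic + unrolled
      expect_true(all(colSums(W) + colSums(B) <= 2))
    }
    expect_gt(smp$meta$acceptance_rate, 0)
    expect_lt(smp$meta$acceptance_rate, 1)
    expect_true(all(is.finite(smp$meta$score_trace)))
  }
})

test_that("with a flat likelihood the sampler reproduces the prior exactly", {
  # no data, between-slice parents disabled: the 3 two-node within-slice
  # graphs (empty, 1->2, 2->1) are equiprobable
  tt0 <- empty_tt(2)
  st0 <- build_score_table(tt0, ess = 1, max_parents = 1,
                           between_slice = FALSE)
  smp <- sample_dags(st0, n_samples = 20000, chain_length = 6e4,
                     burn_in = 5000, seed = 8)
  key <- paste(smp$w_mask[, 1], smp$w_mask[, 2])
  freq <- table(key) / length(key)
  expect_equal(length(freq), 3L)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("edge posteriors summarise draw frequencies", {
  fx <- chain_fixture(rows = 100)
  smp <- sample_dags(fx$st, n_samples = 2, chain_length = 1000,
                     burn_in = 100, seed = 5)
  smp$w_mask <- rbind(c(0L, 1L, 0L), c(0L, 0L, 0L))  # edge 1->2 in one draw
  smp$b_mask <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L))
  ep <- edge_posteriors(smp)
  expect_equal(ep$W[1, 2], 0.5)
  expect_equal(ep$B[1, 1], 1)
  expect_true(all(ep$W %in% c(0, 0.5, 1) & ep$B %in% c(0, 0.5, 1)))
})

test_that("exhaustive enumeration matches a hand enumeration on n = 2", {
  tt <- coin_tt(2, 30, seed = 9)
  st <- build_score_table(tt, ess = 1, max_parents = 2)
  ex <- exhaustive_posterior(st)
  # hand enumeration: 3 W graphs x independent B sets per child via
  # score_structure on every concrete (W, B)
  Ws <- list(matrix(0L, 2, 2), matrix(c(0L, 1L, 0L, 0L), 2),
             matrix(c(0L, 0L, 1L, 0L), 2))
  bsets <- list(integer(0), 1L, 2L, c(1L, 2L))
  tot <- -Inf; e12 <- -Inf; b11 <- -Inf
  for (W in Ws) for (b1 in seq_along(bsets)) for (b2 in seq_along(bsets)) {
    B <- matrix(0L, 2, 2)
    B[bsets[[b1]], 1] <- 1L; B[bsets[[b2]], 2] <- 1L
    if (any(colSums(W) + colSums(B) > 2)) next
    sc <- score_structure(dbn_structure(W, B), tt, ess = 1)
    tot <- dbncausal:::logsumexp(c(tot, sc))
    if (W[2, 1] == 1) e12 <- dbncausal:::logsumexp(c(e12, sc))
    if (B[1, 1] == 1) b11 <- dbncausal:::logsumexp(c(b11, sc))
  }
  expect_equal(ex$log_Z, tot, tolerance = 1e-10)
  expect_equal(ex$W[2, 1], exp(e12 - tot), tolerance = 1e-10)
  expect_equal(ex$B[1, 1], exp(b11 - tot), tolerance = 1e-10)
  # orientation posteriors of a pair are disjoint events
  expect_lte(ex$W[1, 2] + ex$W[2, 1], 1 + 1e-12)
  expect_error(exhaustive_posterior(st, budget = 2), "budget")
})

test_that("partition MCMC matches the enumeration oracle on planted chains", {
  fx <- chain_fixture(rows = 500)
  ex <- exhaustive_posterior(fx$st)
  smp <- sample_dags(fx$st, n_samples = 2000, chain_length = 4e4,
                     burn_in = 8000, seed = 21)
  ep <- edge_posteriors(smp)
  expect_lt(max(abs(ep$W - ex$W)), 0.03)
  expect_lt(max(abs(ep$B - ex$B)), 0.03)
  # the true skeleton is confidently recovered
  wi <- which(fx$truth$structure$W == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(wi))) {
    i <- wi[r, 1]; j <- wi[r, 2]
    expect_gte(ex$W[i, j] + ex$W[j, i], 0.9)
  }
})

test_that("partition and structure methods agree on edge posteriors", {
  fx <- chain_fixture(rows = 300, seed = 31)
  p <- edge_posteriors(sample_dags(fx$st, n_samples = 4000,
                                   chain_length = 1e5, burn_in = 2e4,
                                   seed = 1, method = "partition"))
  s <- edge_posteriors(sample_dags(fx$st, n_samples = 4000,
                                   chain_length = 1e5, burn_in = 2e4,
                                   seed = 2, method = "structure"))
  expect_lt(max(abs(p$W - s$W)), 0.03)
  expect_lt(max(abs(p$B - s$B)), 0.03)
})

test_that("sampler input validation", {
  fx <- chain_fixture(rows = 50)
  expect_error(sample_dags(fx$st, n_samples = 10, chain_length = 100,
                           burn_in = 100, seed = 1), "burn_in")
  expect_error(sample_dags(fx$st, n_samples = 1000, chain_length = 100,
                           burn_in = 10, seed = 1), "n_samples")
  expect_error(sample_dags(fx$st, n_samples = 10, chain_length = 100,
                           burn_in = 10), "seed")
})

test_that("DAG samples serialise and round-trip as bitstring records", {
  fx <- chain_fixture(rows = 80)
  smp <- sample_dags(fx$st, n_samples = 25, chain_length = 2000,
                     burn_in = 400, seed = 6)
  f <- tempfile()
  write_dag_sample(smp, f)
  back <- read_dag_sample(f)
  expect_identical(back$w_mask, smp$w_mask)
  expect_identical(back$b_mask, smp$b_mask)
  expect_equal(back$meta$seed, smp$meta$seed)
})
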