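test_that("parameter draws follow the conjugate Beta posterior", {
  # node with no data and ess = 2: Beta(1, 1), i.e. uniform
  tt <- empty_tt(2)
  z <- dbn_structure(matrix(0L, 2, 2), matrix(0L, 2, 2))
  set.seed(1)
  ms <- replicate(2000, draw_parameters(z, tt, ess = 2)$cpt[[1]]$p1)
  expect_equal(mean(ms), 0.5, tolerance = 0.02)
  expect_gt(stats::var(ms), 1 / 12 * 0.8)   # uniform variance, not point mass

  # counts 8 ones / 2 zeros at alpha = 0.5 (ess = 1): posterior mean 8.5/11
  x <- make_tt(cbind(0, 0, rep(c(1, 0), c(8, 2)), 0))
  s2 <- dbn_structure(matrix(0L, 2, 2), matrix(0L, 2, 2))
  set.seed(2)
  ms2 <- replicate(5000, draw_parameters(s2, x, ess = 1)$cpt[[3]]$p1)
  expect_equal(mean(ms2), 8.5 / 11, tolerance = 0.01)
  expect_equal(draw_parameters(s2, x, ess = 1, point = "mean")$cpt[[3]]$p1,
               8.5 / 11)
  # seeded determinism
  expect_identical(draw_parameters(s2, x, seed = 5),
                   draw_parameters(s2, x, seed = 5))
})

test_that("a lone transition edge gives the direct conditional contrast", {
  n <- 2
  B <- matrix(0L, n, n); B[1, 2] <- 1L
  s <- dbn_structure(matrix(0L, n, n), B)
  pd <- draw_parameters(s, empty_tt(n), seed = 1)
  pd$cpt[[4]]$p1 <- c(0.2, 0.8)     # target | source = 0 / 1
  expect_equal(do_effect(s, pd, 1, 2), 0.6, tolerance = 1e-12)
  # a non-descendant target has exactly zero effect
  expect_identical(do_effect(s, pd, 2, 1), 0)
})

test_that("confounding by an unclamped slice-1 variable is marginalised", {
  # Z -> source (within slice 1), Z -> target (between slices),
  # source -> target (between slices): effect must average over P(z)
  n <- 3
  W <- matrix(0L, n, n); W[3, 1] <- 1L
  B <- matrix(0L, n, n); B[3, 2] <- 1L; B[1, 2] <- 1L
  s <- dbn_structure(W, B)
  pd <- draw_parameters(s, empty_tt(n), seed = 3)
  ef <- do_effect(s, pd, 1, 2)
  expect_equal(ef, brute_do_effect(pd, 1, n + 2), tolerance = 1e-10)
  # closed form: sum_z P(z) [P(t|s=1,z) - P(t|s=0,z)]
  pz <- pd$cpt[[3]]$p1
  ptab <- pd$cpt[[5]]$p1   # parents sorted: (1, 3) -> bits (source, z)
  closed <- (1 - pz) * (ptab[2] - ptab[1]) + pz * (ptab[4] - ptab[3])
  expect_equal(ef, closed, tolerance = 1e-12)
})

test_that("do_effect equals full-joint enumeration on random networks", {
  set.seed(14)
  worst <- 0
  for (rep in 1:60) {
    n <- sample(2:5, 1)
    tr <- generate_true_dbn(n, within_density = 0.5, between_density = 0.3,
                            self_edge_prob = 0.6, seed = 5000 + rep)
    pan <- simulate_cohort(tr, 30, 2, seed = rep)
    tt <- build_transition_table(pan)
    pd <- draw_parameters(tr$structure, tt, ess = 1, seed = rep)
    src <- sample(n, 1); tgt <- sample(n, 1)
    worst <- max(worst, abs(do_effect(tr$structure, pd, src, tgt) -
                              brute_do_effect(pd, src, n + tgt)))
  }
  expect_lt(worst, 1e-10)
})

test_that("effects are bounded and zero off the descendant set per draw", {
  fxt <- generate_true_dbn(4, within_density = 0.3, between_density = 0.2,
                           seed = 77)
  pan <- simulate_cohort(fxt, 150, 2, seed = 78)
  tt <- build_transition_table(pan)
  st <- build_score_table(tt, max_parents = 2)
  smp <- sample_dags(st, n_samples = 60, chain_length = 4000, burn_in = 800,
                     seed = 79)
  eff <- effect_distribution(smp, tt, seed = 80)
  expect_true(all(eff$draws >= -1 & eff$draws <= 1))
  expect_true(all(eff$mean >= apply(eff$draws, c(1, 2), min) - 1e-12))
  expect_true(all(eff$mean <= apply(eff$draws, c(1, 2), max) + 1e-12))
  expect_identical(eff$significant, eff$lower > 0 | eff$upper < 0)
  # spot-check the zero-effect shortcut against draw 1's structure
  W <- matrix(0L, 4, 4); B <- matrix(0L, 4, 4)
  for (j in 1:4) {
    W[dbncausal:::bits_of(smp$w_mask[1, j], 4), j] <- 1L
    B[dbncausal:::bits_of(smp$b_mask[1, j], 4), j] <- 1L
  }
  A <- unroll_dbn(dbn_structure(W, B))
  reach <- function(a, b) {
    seen <- integer(0); fr <- which(A[a, ] != 0)
    while (length(fr)) {
      seen <- union(seen, fr)
      fr <- setdiff(which(colSums(A[fr, , drop = FALSE]) > 0), seen)
    }
    b %in% seen
  }
  for (s_ in 1:4) for (t_ in 1:4)
    if (!reach(s_, 4 + t_)) expect_identical(eff$draws[s_, t_, 1], 0)
})

test_that("degenerate parameter draws give a point-mass interval", {
  smp <- structure(list(w_mask = matrix(0L, 40, 2),
                        b_mask = matrix(c(1L, 0L), 40, 2, byrow = TRUE),
                        n = 2, items = c("A", "B"),
                        meta = list(method = "manual")),
                   class = "dag_sample")
  # overwhelming counts make the Beta posterior essentially a point mass
  x <- make_tt(matrix(rep(c(1, 0, 1, 0,
                            0, 0, 0, 0), 2000), ncol = 4, byrow = TRUE))
  eff <- effect_distribution(smp, x, seed = 9)
  expect_lt(eff$upper[1, 1] - eff$lower[1, 1], 0.1)
  # all draws >= 0.2 forces significance at the 95% interval rule
  expect_true(all(eff$draws[1, 1, ] > 0.2))
  expect_true(eff$significant[1, 1])
})

test_that("structure mixtures produce bimodal effects at the exact modes", {
  n <- 3
  W1 <- matrix(0L, n, n); W1[1, 2] <- 1L          # slice-2 mediator 1 -> 2
  Bm <- matrix(0L, n, n); Bm[1, 1] <- 1L          # strong momentum on 1
  sA <- dbn_structure(W1, Bm)
  sB <- dbn_structure(matrix(0L, n, n), Bm)
  p1 <- list(0.5, c(0.2, 0.8), 0.5,
             c(0.1, 0.9), c(0.2, 0.8), 0.5)
  pan <- simulate_cohort(dbn_ground_truth(sA, p1), 800, 2, seed = 3)
  tt <- build_transition_table(pan)
  half <- 250
  smp <- structure(list(
    w_mask = rbind(matrix(rep(c(0L, 1L, 0L), each = half), half),
                   matrix(0L, half, n)),
    b_mask = matrix(rep(c(1L, 0L, 0L), each = 2 * half), 2 * half),
    n = n, items = paste0("V", 1:n),
    meta = list(method = "manual")), class = "dag_sample")
  eff <- effect_distribution(smp, tt, seed = 4)
  d <- eff$draws[1, 2, ]
  exactA <- do_effect(sA, draw_parameters(sA, tt, point = "mean"), 1, 2)
  exactB <- do_effect(sB, draw_parameters(sB, tt, point = "mean"), 1, 2)
  expect_equal(mean(d[seq_len(half)]), exactA, tolerance = 0.05)
  expect_equal(mean(d[half + seq_len(half)]), exactB, tolerance = 0.05)
  expect_gt(exactA, 0.3)                      # the two modes are separated
  expect_equal(exactB, 0)
})

test_that("effect summaries export tidily and round-trip", {
  smp <- structure(list(w_mask = matrix(0L, 5, 2),
                        b_mask = matrix(3L, 5, 2),
                        n = 2, items = c("A", "B"),
                        meta = list(method = "manual")),
                   class = "dag_sample")
  eff <- effect_distribution(smp, coin_tt(2, 50, seed = 1), seed = 2)
  df <- as.data.frame(eff)
  expect_equal(names(df), c("source", "target", "mean", "lower", "upper",
                            "significant", "n_draws"))
  expect_equal(df$mean[df$source == "A" & df$target == "B"], eff$mean[1, 2])
  f <- tempfile(fileext = ".csv"); fd <- tempfile(fileext = ".csv")
  write_effects_csv(eff, f, fd)
  back <- utils::read.csv(f)
  expect_equal(back$mean, df$mean, tolerance = 1e-12)
  rawd <- utils::read.csv(fd)
  expect_equal(nrow(rawd), 5L)
  expect_equal(rawd$A.B[1], eff$draws[1, 2, 1], tolerance = 1e-12)
})
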