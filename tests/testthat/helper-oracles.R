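# Fixtures are built in code; oracles here are deliberately brute-force and
# independent of the implementation paths they check.

# transition_table built directly from a complete binary matrix
make_tt <- function(x, items = paste0("V", seq_len(ncol(x) / 2))) {
  n <- length(items)
  x <- matrix(as.integer(x), nrow = nrow(x), ncol = 2 * n)
  colnames(x) <- c(paste0(items, "_t0"), paste0(items, "_t1"))
  structure(list(x = x, participant = sprintf("P%03d", seq_len(nrow(x))),
                 pair = rep(1L, nrow(x)), items = items, n = n),
            class = "transition_table")
}

# zero-row table (flat likelihood: every family scores 0)
empty_tt <- function(n) make_tt(matrix(integer(0), 0, 2 * n))

# independent-coin data
coin_tt <- function(n, rows, seed) {
  set.seed(seed)
  make_tt(matrix(rbinom(rows * 2 * n, 1, 0.5), rows))
}

# all-ones ground truth helper: empty structure, constant marginals
flat_truth <- function(n, p = 0.5) {
  z <- matrix(0L, n, n)
  dbn_ground_truth(dbn_structure(z, z), rep(list(p), 2 * n))
}

# Beta-binomial closed form for a parentless node (independent of lbeta
# bookkeeping in the implementation): integral of theta^k (1-theta)^m
# under Beta(alpha, alpha), via the sequential predictive product.
bde_parentless_oracle <- function(k, m, ess) {
  alpha <- ess / 2
  logp <- 0
  ones <- 0; zeros <- 0
  for (step in seq_len(k + m)) {
    draw1 <- ones < k
    p1 <- (alpha + ones) / (2 * alpha + ones + zeros)
    logp <- logp + log(if (draw1) p1 else 1 - p1)
    if (draw1) ones <- ones + 1 else zeros <- zeros + 1
  }
  logp
}

# full-joint enumeration of a do-effect on the unrolled 2n network
# (vectorised over all 2^(2n) joint states)
brute_do_effect <- function(params, src, tgt) {
  N <- 2L * params$n
  pa <- lapply(params$cpt, `[[`, "parents")
  pa[[src]] <- integer(0)
  cfg <- 0:(2^N - 1)
  bits <- vapply(seq_len(N), function(p)
    bitwAnd(bitwShiftR(cfg, p - 1L), 1L), integer(length(cfg)))
  marg <- function(v) {
    bs <- bits[bits[, src] == v, , drop = FALSE]
    p <- rep(1, nrow(bs))
    for (nd in setdiff(seq_len(N), src)) {
      pcfg <- if (length(pa[[nd]]))
        as.vector(bs[, pa[[nd]], drop = FALSE] %*%
                    2^(seq_along(pa[[nd]]) - 1)) else rep(0, nrow(bs))
      p1 <- params$cpt[[nd]]$p1[pcfg + 1]
      p <- p * ifelse(bs[, nd] == 1L, p1, 1 - p1)
    }
    sum(p[bs[, tgt] == 1L]) / sum(p)
  }
  marg(1L) - marg(0L)
}

# random DBN with fully random CPTs (no data involved)
random_params <- function(n, seed) {
  set.seed(seed)
  ordn <- sample(n)
  W <- matrix(0L, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (runif(1) < 0.5) W[ordn[a], ordn[b]] <- 1L
  B <- matrix(as.integer(runif(n * n) < 0.35), n, n)
  s <- dbncausal::dbn_structure(W, B)
  pa <- lapply(seq_len(2 * n), function(v) NULL)
  cpt <- lapply(dbncausal:::unrolled_parents(s), function(p)
    list(parents = p, p1 = runif(2^length(p), 0.02, 0.98)))
  structure(list(cpt = cpt, n = n, structure = s, ess = 1),
            class = "parameter_draw")
}

# all DAG adjacency matrices on n nodes (brute force over parent-set combos)
all_dags <- function(n) {
  sets <- lapply(seq_len(n), function(j) {
    u <- setdiff(seq_len(n), j)
    masks <- 0L
    for (k in seq_along(u))
      masks <- c(masks, utils::combn(u, k, function(s)
        sum(bitwShiftL(1L, s - 1L)), simplify = TRUE))
    masks
  })
  combos <- expand.grid(lapply(sets, seq_along))
  out <- list()
  for (r in seq_len(nrow(combos))) {
    W <- matrix(0L, n, n)
    for (j in seq_len(n)) {
      m <- sets[[j]][combos[r, j]]
      W[which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L), j] <- 1L
    }
    ok <- tryCatch({ dbncausal::dbn_structure(W, matrix(0L, n, n)); TRUE },
                   error = function(e) FALSE)
    if (ok) out[[length(out) + 1L]] <- W
  }
  out
}

# rank-based AUROC (Mann-Whitney), no package dependency
auroc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Markov-equivalence class key: skeleton + v-structures
mec_key <- function(W) {
  n <- nrow(W)
  skel <- (W + t(W)) > 0
  vs <- character(0)
  for (j in seq_len(n)) {
    pa <- which(W[, j] == 1)
    if (length(pa) >= 2) {
      prs <- utils::combn(pa, 2)
      for (c_ in seq_len(ncol(prs))) {
        a <- prs[1, c_]; b <- prs[2, c_]
        if (!skel[a, b]) vs <- c(vs, paste(sort(c(a, b)), j, sep = "-"))
      }
    }
  }
  paste(paste(as.integer(skel[upper.tri(skel)]), collapse = ""),
        paste(sort(vs), collapse = "|"))
}
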