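# Partition MCMC over within-slice node layerings.
#
# A within-slice DAG maps to a unique ordered partition (layering): layer 1
# holds the parentless nodes, and a node sits in layer m >= 2 iff all its
# parents lie in earlier layers with at least one in layer m-1.  The chain
# walks over these partitions; the score of a partition is the sum over all
# (W, B) consistent with it, which factorises per child node because the
# BDeu score is decomposable and between-slice parents (always admissible,
# slice 1 -> slice 2) are marginalised inside each node's layer-consistent
# sum.  A concrete DAG is then sampled conditional on the partition in
# proportion to its score.

.masks_from_parts <- function(parts, n) {
  A <- integer(n); R <- integer(n)
  acc <- 0L; prevmask <- 0L
  for (m in seq_along(parts)) {
    pm <- mask_of(parts[[m]])
    A[parts[[m]]] <- acc
    R[parts[[m]]] <- prevmask
    acc <- bitwOr(acc, pm)
    prevmask <- pm
  }
  list(A = A, R = R)
}

.node_sum <- function(nd, A, R) {
  if (A == 0L) return(nd$f[1])  # first entry is the empty parent set
  sel <- bitwAnd(nd$w_mask, A) == nd$w_mask & bitwAnd(nd$w_mask, R) != 0L
  logsumexp(nd$f[sel])
}

.pick1 <- function(x) x[sample.int(length(x), 1L)]

.descendants_of <- function(W, j) {
  seen <- integer(0)
  frontier <- which(W[j, ] != 0L)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(which(colSums(W[frontier, , drop = FALSE]) > 0), seen)
  }
  seen
}

.sample_dag_given_partition <- function(st, A, R) {
  n <- st$n
  wm <- integer(n); bm <- integer(n)
  for (j in seq_len(n)) {
    nd <- st$nodes[[j]]
    if (A[j] == 0L) {
      a <- 1L
    } else {
      sel <- which(bitwAnd(nd$w_mask, A[j]) == nd$w_mask &
                     bitwAnd(nd$w_mask, R[j]) != 0L)
      lw <- nd$f[sel]
      p <- exp(lw - max(lw))
      a <- sel[.pick1_weighted(p)]
    }
    g <- nd$groups[[a]]
    ls <- nd$s2[g]
    ci <- g[.pick1_weighted(exp(ls - max(ls)))]
    wm[j] <- nd$w_mask[a]
    bm[j] <- nd$c_b[ci]
  }
  list(wm = wm, bm = bm)
}

# categorical draw by unnormalised weights using the seeded RNG stream
.pick1_weighted <- function(w) {
  if (length(w) == 1L) return(1L)
  cw <- cumsum(w)
  findInterval(stats::runif(1) * cw[length(cw)], cw) + 1L
}

#' Sample DBN structures from their posterior
#'
#' Draws structures in proportion to `exp(score)` so that better-fitting
#' graphs appear more often.  The default partition method runs
#' Metropolis-Hastings over ordered partitions of the within-slice nodes
#' (moves: relocate a node, split a layer, merge adjacent layers, swap
#' nodes between adjacent layers, with proposal mix 0.5/0.2/0.2/0.1),
#' scoring each state by its layer-consistent parent-set sums, and samples
#' a concrete (W, B) conditional on the partition at each thinning point.
#' A structure MCMC (single-edge toggle/reversal Metropolis moves plus an
#' occasional Gibbs resampling of one child's whole parent set from its
#' exact full conditional, which lets the chain cross the score barriers
#' the parent-set cap creates) is retained as a cross-validation baseline.
#'
#' @param scores a [build_score_table()] result.
#' @param n_samples number of posterior draws to return.
#' @param chain_length number of MCMC proposals.
#' @param burn_in proposals to discard (must be < `chain_length`).
#' @param seed integer seed (mandatory; identical seed gives an identical
#'   sample).
#' @param method `"partition"` (default) or `"structure"`.
#' @return A `dag_sample`: `w_mask` and `b_mask` (`n_samples` x n integer
#'   mask matrices, column j holding node j's parent sets), `n`, `items`,
#'   and `meta` (chain settings, acceptance rates, score trace).
#' @export
sample_dags <- function(scores, n_samples = 10000L, chain_length = 1e6,
                        burn_in = floor(0.2 * chain_length), seed,
                        method = c("partition", "structure")) {
  stopifnot(inherits(scores, "dbn_score_table"))
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop_config("a seed is mandatory")
  if (burn_in >= chain_length) stop_config("burn_in must be < chain_length")
  if (n_samples > chain_length - burn_in)
    stop_config("n_samples exceeds the post-burn-in chain length")
  set.seed(as.integer(seed))
  thin_at <- unique(round(seq(burn_in + 1, chain_length,
                              length.out = n_samples)))
  if (method == "partition")
    out <- .run_partition_chain(scores, chain_length, thin_at)
  else
    out <- .run_structure_chain(scores, chain_length, thin_at)
  # thinning points may collide after rounding; recycle deterministically
  idx <- rep_len(seq_len(nrow(out$wm)), n_samples)
  structure(list(w_mask = out$wm[idx, , drop = FALSE],
                 b_mask = out$bm[idx, , drop = FALSE],
                 n = scores$n, items = scores$items,
                 meta = c(out$meta,
                          list(method = method, chain_length = chain_length,
                               burn_in = burn_in, n_samples = n_samples,
                               seed = as.integer(seed)))),
            class = "dag_sample")
}

#' @export
print.dag_sample <- function(x, ...) {
  cat(sprintf("<dag_sample> %d draws of a %d-variable DBN (%s MCMC, acceptance %.2f)\n",
              nrow(x$w_mask), x$n, x$meta$method, x$meta$acceptance_rate))
  invisible(x)
}

.run_partition_chain <- function(st, chain_length, thin_at) {
  n <- st$n
  move_p <- c(relocate = 0.5, split = 0.2, merge = 0.2, swap = 0.1)
  parts <- list(seq_len(n))
  mk <- .masks_from_parts(parts, n)
  sums <- vapply(seq_len(n), function(j) .node_sum(st$nodes[[j]], mk$A[j], mk$R[j]),
                 numeric(1))
  if (!all(is.finite(sums)))
    stop_config("non-finite initial score; node(s): ",
                paste(which(!is.finite(sums)), collapse = ", "))
  n_acc <- 0L; n_prop <- 0L
  wm_out <- matrix(0L, length(thin_at), n)
  bm_out <- matrix(0L, length(thin_at), n)
  t_next <- 1L
  trace_every <- max(1L, floor(chain_length / 200))
  trace <- numeric(0)
  splittable <- function(p) which(lengths(p) >= 2L)
  for (it in seq_len(chain_length)) {
    k <- length(parts)
    mv <- .pick1_weighted(move_p)
    prop <- NULL; log_q <- 0
    if (mv == 1L) {                      # relocate one node
      v <- .pick1(seq_len(n))
      pi <- which(vapply(parts, function(p) v %in% p, logical(1)))
      p2 <- parts
      p2[[pi]] <- setdiff(p2[[pi]], v)
      if (!length(p2[[pi]])) p2[[pi]] <- NULL
      k2 <- length(p2)
      t <- sample.int(2L * k2 + 1L, 1L)
      if (t <= k2) p2[[t]] <- c(p2[[t]], v)
      else p2 <- append(p2, list(v), after = t - k2 - 1L)
      prop <- p2
    } else if (mv == 2L) {               # split a layer
      sp <- splittable(parts)
      if (length(sp)) {
        jj <- .pick1(sp)
        mem <- parts[[jj]]
        s <- length(mem)
        val <- sample.int(2L^s - 2L, 1L)
        S <- mem[bits_of(val, s)]
        p2 <- append(parts[-jj], list(S, setdiff(mem, S)), after = jj - 1L)
        prop <- p2
        log_q <- log(move_p[["merge"]] / k) -
          log(move_p[["split"]] / length(sp) / (2L^s - 2L))
      }
    } else if (mv == 3L) {               # merge adjacent layers
      if (k >= 2L) {
        m <- sample.int(k - 1L, 1L)
        merged <- c(parts[[m]], parts[[m + 1L]])
        p2 <- append(parts[-c(m, m + 1L)], list(merged), after = m - 1L)
        s <- length(merged)
        sp_new <- splittable(p2)
        prop <- p2
        log_q <- log(move_p[["split"]] / length(sp_new) / (2L^s - 2L)) -
          log(move_p[["merge"]] / (k - 1L))
      }
    } else {                             # swap nodes across adjacent layers
      if (k >= 2L) {
        m <- sample.int(k - 1L, 1L)
        a <- .pick1(parts[[m]]); b <- .pick1(parts[[m + 1L]])
        p2 <- parts
        p2[[m]] <- c(setdiff(p2[[m]], a), b)
        p2[[m + 1L]] <- c(setdiff(p2[[m + 1L]], b), a)
        prop <- p2
      }
    }
    if (!is.null(prop)) {
      n_prop <- n_prop + 1L
      mk2 <- .masks_from_parts(prop, n)
      changed <- which(mk2$A != mk$A | mk2$R != mk$R)
      new_sums <- sums
      for (j in changed)
        new_sums[j] <- .node_sum(st$nodes[[j]], mk2$A[j], mk2$R[j])
      delta <- sum(new_sums[changed]) - sum(sums[changed])
      if (is.nan(delta)) delta <- -Inf
      if (log(stats::runif(1)) < delta + log_q) {
        parts <- prop; mk <- mk2; sums <- new_sums
        n_acc <- n_acc + 1L
      }
    }
    if (it %% trace_every == 0L) trace <- c(trace, sum(sums))
    if (t_next <= length(thin_at) && it == thin_at[t_next]) {
      d <- .sample_dag_given_partition(st, mk$A, mk$R)
      wm_out[t_next, ] <- d$wm
      bm_out[t_next, ] <- d$bm
      t_next <- t_next + 1L
    }
  }
  list(wm = wm_out, bm = bm_out,
       meta = list(acceptance_rate = n_acc / max(1L, n_prop),
                   score_trace = trace))
}

.gibbs_classify <- function(c_w, back_mask, cross_mask) {
  ok <- bitwAnd(c_w, back_mask) == 0L
  crossing <- bitwAnd(c_w, cross_mask) != 0L
  list(A = which(ok & !crossing), B = which(ok & crossing))
}

.run_structure_chain <- function(st, chain_length, thin_at) {
  n <- st$n
  wm <- integer(n); bm <- integer(n)
  W <- matrix(0L, n, n)
  ls_all <- lapply(st$nodes, function(nd) nd$s1[nd$w_index] + nd$s2)
  loc <- vapply(seq_len(n), function(j) .family_score(st, j, 0L, 0L), numeric(1))
  n_acc <- 0L; n_prop <- 0L
  wm_out <- matrix(0L, length(thin_at), n)
  bm_out <- matrix(0L, length(thin_at), n)
  t_next <- 1L
  trace <- numeric(0)
  trace_every <- max(1L, floor(chain_length / 200))
  for (it in seq_len(chain_length)) {
    u <- stats::runif(1)
    accept <- FALSE
    if (u < 0.15 && n >= 2L) {            # Gibbs: resample two children's
      ij <- sort(sample.int(n, 2L))       # families from their exact joint
      i <- ij[1]; j <- ij[2]              # full conditional
      n_prop <- n_prop + 1L
      W2 <- W; W2[, i] <- 0L; W2[, j] <- 0L
      Di <- .descendants_of(W2, i); Dj <- .descendants_of(W2, j)
      # a cycle must re-enter i or j: back-edge from a descendant, or a
      # crossing pair (i ~> parent-of-j and j ~> parent-of-i)
      cls_i <- .gibbs_classify(st$nodes[[i]]$c_w, mask_of(Di),
                               mask_of(c(j, Dj)))
      cls_j <- .gibbs_classify(st$nodes[[j]]$c_w, mask_of(Dj),
                               mask_of(c(i, Di)))
      li <- ls_all[[i]]; lj <- ls_all[[j]]
      SA_i <- logsumexp(li[cls_i$A]); SB_i <- logsumexp(li[cls_i$B])
      SA_j <- logsumexp(lj[cls_j$A]); SB_j <- logsumexp(lj[cls_j$B])
      blk <- .pick1_weighted(exp(c(SA_i + SA_j, SA_i + SB_j, SB_i + SA_j) -
                                   max(SA_i + SA_j, SA_i + SB_j, SB_i + SA_j)))
      set_i <- if (blk == 3L) cls_i$B else cls_i$A
      set_j <- if (blk == 2L) cls_j$B else cls_j$A
      ci <- set_i[.pick1_weighted(exp(li[set_i] - max(li[set_i])))]
      cj <- set_j[.pick1_weighted(exp(lj[set_j] - max(lj[set_j])))]
      for (nodefam in list(list(i, ci), list(j, cj))) {
        v <- nodefam[[1]]; cc <- nodefam[[2]]
        nd <- st$nodes[[v]]
        wm[v] <- nd$c_w[cc]; bm[v] <- nd$c_b[cc]
        loc[v] <- ls_all[[v]][cc]
        W[, v] <- 0L
        W[bits_of(wm[v], n), v] <- 1L
      }
      accept <- TRUE
    } else if (u < 0.45) {                # toggle a between-slice edge
      i <- .pick1(seq_len(n)); j <- .pick1(seq_len(n))
      n_prop <- n_prop + 1L
      bm_new <- bitwXor(bm[j], bitwShiftL(1L, i - 1L))
      s_new <- .family_score(st, j, wm[j], bm_new)
      if (log(stats::runif(1)) < s_new - loc[j]) {
        bm[j] <- bm_new; loc[j] <- s_new; accept <- TRUE
      }
    } else if (u < 0.75) {                # toggle a within-slice edge
      ij <- .pick1(which(diag(n) == 0))
      i <- (ij - 1L) %% n + 1L; j <- (ij - 1L) %/% n + 1L
      n_prop <- n_prop + 1L
      adding <- W[i, j] == 0L
      ok <- TRUE
      if (adding) {
        W[i, j] <- 1L
        ok <- !is.null(topological_order(W))
        W[i, j] <- 0L
      }
      if (ok) {
        wm_new <- bitwXor(wm[j], bitwShiftL(1L, i - 1L))
        s_new <- .family_score(st, j, wm_new, bm[j])
        if (log(stats::runif(1)) < s_new - loc[j]) {
          wm[j] <- wm_new; loc[j] <- s_new
          W[i, j] <- as.integer(adding)
          accept <- TRUE
        }
      }
    } else {                              # reverse an existing within edge
      E <- which(W == 1L)
      if (length(E)) {
        n_prop <- n_prop + 1L
        e <- .pick1(E)
        i <- (e - 1L) %% n + 1L; j <- (e - 1L) %/% n + 1L
        W[i, j] <- 0L; W[j, i] <- 1L
        if (!is.null(topological_order(W))) {
          wj_new <- bitwXor(wm[j], bitwShiftL(1L, i - 1L))
          wi_new <- bitwXor(wm[i], bitwShiftL(1L, j - 1L))
          sj <- .family_score(st, j, wj_new, bm[j])
          si <- .family_score(st, i, wi_new, bm[i])
          if (log(stats::runif(1)) < sj + si - loc[j] - loc[i]) {
            wm[j] <- wj_new; wm[i] <- wi_new
            loc[j] <- sj; loc[i] <- si
            accept <- TRUE
          }
        }
        if (!accept) { W[j, i] <- 0L; W[i, j] <- 1L }
      }
    }
    if (accept) n_acc <- n_acc + 1L
    if (it %% trace_every == 0L) trace <- c(trace, sum(loc))
    if (t_next <= length(thin_at) && it == thin_at[t_next]) {
      wm_out[t_next, ] <- wm
      bm_out[t_next, ] <- bm
      t_next <- t_next + 1L
    }
  }
  list(wm = wm_out, bm = bm_out,
       meta = list(acceptance_rate = n_acc / max(1L, n_prop),
                   score_trace = trace))
}

#' Posterior edge frequencies of a DAG sample
#'
#' @param sample a [sample_dags()] result.
#' @return List with `W` and `B`: n x n matrices of the frequency of each
#'   directed edge across draws (in `[0, 1]`).
#' @export
edge_posteriors <- function(sample) {
  stopifnot(inherits(sample, "dag_sample"), nrow(sample$w_mask) > 0L)
  n <- sample$n
  W <- matrix(0, n, n); B <- matrix(0, n, n)
  S <- nrow(sample$w_mask)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    W[i, ] <- colMeans(matrix(bitwAnd(sample$w_mask, bit) != 0L, nrow = S))
    B[i, ] <- colMeans(matrix(bitwAnd(sample$b_mask, bit) != 0L, nrow = S))
  }
  dimnames(W) <- dimnames(B) <- list(sample$items, sample$items)
  list(W = W, B = B, items = sample$items)
}

#' Exact posterior by exhaustive enumeration (small problems)
#'
#' Enumerates every admissible within-slice DAG assembled from the score
#' table's parent sets, marginalising between-slice parents analytically,
#' and returns the exact marginal posterior probability of every directed
#' edge.  Feasible for roughly n <= 4 variables per slice; refuses beyond
#' the budget.  Serves as the independent reference for [sample_dags()].
#'
#' @param scores a [build_score_table()] result.
#' @param budget maximum number of within-parent-set combinations to visit.
#' @return List with exact `W` and `B` edge-posterior matrices, `log_Z`
#'   (log normalising constant) and `n_structures` (number of admissible
#'   (W, B) structures enumerated).
#' @export
exhaustive_posterior <- function(scores, budget = 2e5) {
  stopifnot(inherits(scores, "dbn_score_table"))
  n <- scores$n
  nw <- vapply(scores$nodes, function(nd) length(nd$w_mask), integer(1))
  n_combo <- prod(as.numeric(nw))
  if (n_combo > budget)
    stop_config(sprintf(
      "%.0f parent-set combinations exceed the enumeration budget (%.0f)",
      n_combo, budget))
  combos <- as.matrix(expand.grid(lapply(nw, seq_len)))
  keep <- logical(nrow(combos))
  lw <- numeric(nrow(combos))
  lcount <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    W <- matrix(0L, n, n)
    for (j in seq_len(n))
      W[bits_of(scores$nodes[[j]]$w_mask[combos[r, j]], n), j] <- 1L
    if (is.null(topological_order(W))) next
    keep[r] <- TRUE
    lw[r] <- sum(vapply(seq_len(n), function(j)
      scores$nodes[[j]]$f[combos[r, j]], numeric(1)))
    lcount[r] <- sum(vapply(seq_len(n), function(j)
      log(length(scores$nodes[[j]]$groups[[combos[r, j]]])), numeric(1)))
  }
  combos <- combos[keep, , drop = FALSE]
  lw <- lw[keep]; lcount <- lcount[keep]
  log_Z <- logsumexp(lw)
  P <- exp(lw - log_Z)
  Wpost <- matrix(0, n, n); Bpost <- matrix(0, n, n)
  for (j in seq_len(n)) {
    nd <- scores$nodes[[j]]
    margA <- vapply(seq_along(nd$w_mask), function(a)
      sum(P[combos[, j] == a]), numeric(1))
    # within-slice edge posteriors
    for (a in seq_along(nd$w_mask))
      Wpost[bits_of(nd$w_mask[a], n), j] <-
        Wpost[bits_of(nd$w_mask[a], n), j] + margA[a]
    # between-slice: P(b in paB | wmask) weighted by wmask posterior
    for (a in seq_along(nd$w_mask)) {
      if (margA[a] == 0) next
      g <- nd$groups[[a]]
      pb <- exp(nd$s2[g] - nd$bsum[a])
      for (i in seq_len(n)) {
        bit <- bitwShiftL(1L, i - 1L)
        Bpost[i, j] <- Bpost[i, j] +
          margA[a] * sum(pb[bitwAnd(nd$c_b[g], bit) != 0L])
      }
    }
  }
  dimnames(Wpost) <- dimnames(Bpost) <- list(scores$items, scores$items)
  list(W = Wpost, B = Bpost, log_Z = log_Z,
       n_structures = sum(exp(lcount)), items = scores$items)
}

#' Serialize a DAG sample as newline-delimited bitstring records
#'
#' One line per draw: draw index, flattened W bits (column-major, parent i
#' of child j at position (j-1)*n+i) and flattened B bits; metadata in a
#' JSON sidecar `<path>.meta.json`.
#'
#' @param sample a [sample_dags()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dag_sample <- function(sample, path) {
  n <- sample$n
  lines <- vapply(seq_len(nrow(sample$w_mask)), function(r) {
    wb <- unlist(lapply(seq_len(n), function(j)
      as.integer(bitwAnd(sample$w_mask[r, j], bitwShiftL(1L, seq_len(n) - 1L)) != 0L)))
    bb <- unlist(lapply(seq_len(n), function(j)
      as.integer(bitwAnd(sample$b_mask[r, j], bitwShiftL(1L, seq_len(n) - 1L)) != 0L)))
    paste(r, paste(wb, collapse = ""), paste(bb, collapse = ""))
  }, character(1))
  writeLines(lines, path)
  jsonlite::write_json(c(sample$meta, list(n = n, items = sample$items)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a DAG sample written by [write_dag_sample()]
#' @param path file written by [write_dag_sample()].
#' @return A `dag_sample`.
#' @export
read_dag_sample <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  n <- meta$n
  lines <- readLines(path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  conv <- function(s) {
    bits <- as.integer(strsplit(s, "")[[1]])
    vapply(seq_len(n), function(j)
      mask_of(which(bits[(j - 1L) * n + seq_len(n)] == 1L)), integer(1))
  }
  wm <- t(vapply(parts, function(p) conv(p[2]), integer(n)))
  bm <- t(vapply(parts, function(p) conv(p[3]), integer(n)))
  structure(list(w_mask = wm, b_mask = bm, n = n, items = meta$items,
                 meta = meta[setdiff(names(meta), c("n", "items"))]),
            class = "dag_sample")
}
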