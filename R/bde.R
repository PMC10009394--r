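#' Local BDeu marginal likelihood of a binary node given binary parents
#'
#' The log Bayesian-Dirichlet marginal likelihood with a uniform-equivalent
#' (BDeu) prior: over the `q = 2^k` parent configurations, with per-cell
#' prior weight `alpha = ess / (2 q)` and configuration counts `k_j` ones
#' and `m_j` zeros, the score is
#' `sum_j [log B(alpha + k_j, alpha + m_j) - log B(alpha, alpha)]`.
#' Empty data score 0 (the vacuous product).  Computed entirely in the log
#' domain through `lbeta`.
#'
#' @param child_values binary vector (the node's observed values).
#' @param parent_values binary matrix with one column per parent and rows
#'   aligned with `child_values`; `NULL` or zero columns for a parentless
#'   node.
#' @param ess equivalent sample size (total Dirichlet prior weight), > 0.
#' @return The log marginal likelihood (a finite scalar).
#' @export
local_bde_score <- function(child_values, parent_values = NULL, ess = 1) {
  if (!is.numeric(ess) || length(ess) != 1L || ess <= 0)
    stop_config("ess must be a positive scalar")
  ch <- as.integer(child_values)
  if (anyNA(ch)) stop_config("missing values are not allowed in scoring")
  k <- if (is.null(parent_values)) 0L else ncol(as.matrix(parent_values))
  q <- 2L^k
  alpha <- ess / (2 * q)
  if (!length(ch)) return(0)
  if (k == 0L) {
    cfg <- rep(1L, length(ch))
  } else {
    pm <- as.matrix(parent_values)
    if (nrow(pm) != length(ch)) stop_config("child and parent rows must align")
    if (anyNA(pm)) stop_config("missing values are not allowed in scoring")
    cfg <- as.integer(pm %*% 2^(seq_len(k) - 1)) + 1L
  }
  n1 <- tabulate(cfg[ch == 1L], nbins = q)
  n0 <- tabulate(cfg[ch == 0L], nbins = q)
  sum(lbeta(alpha + n1, alpha + n0) - lbeta(alpha, alpha))
}

# counts per parent configuration (used by scoring and parameter draws)
.family_counts <- function(child, pmat) {
  k <- if (is.null(pmat)) 0L else ncol(pmat)
  q <- 2L^k
  cfg <- if (k == 0L) rep(1L, length(child))
         else as.integer(pmat %*% 2^(seq_len(k) - 1)) + 1L
  list(n1 = tabulate(cfg[child == 1L], nbins = q),
       n0 = tabulate(cfg[child == 0L], nbins = q), q = q)
}

#' Log posterior score of a full DBN structure
#'
#' Decomposable sum over child nodes of local BDeu terms: each slice-2 node
#' scored on the transition rows given its within-slice parents (slice-2
#' columns) and between-slice parents (slice-1 columns); each slice-1 node
#' scored on the slice-1 columns given its within-slice parents (the prior
#' time-point's data contributing to the within-slice structure); plus the
#' log structure prior.  Toggling one between-slice edge changes exactly one
#' slice-2 local term; toggling a within-slice edge changes the two role
#' terms of the one affected child node.
#'
#' @param structure a [dbn_structure()].
#' @param table a [build_transition_table()] result with matching `n`.
#' @param ess equivalent sample size, > 0.
#' @param edge_penalty per-edge log prior penalty `gamma`; the structure
#'   prior is `exp(-gamma (|W| + |B|))`, uniform when 0 (the default).
#' @param score_first_slice if `FALSE`, only the slice-2 conditionals are
#'   scored (sensitivity analysis).
#' @return The log posterior score (up to the normalising constant).
#' @export
score_structure <- function(structure, table, ess = 1, edge_penalty = 0,
                            score_first_slice = TRUE) {
  stopifnot(inherits(structure, "dbn_structure"),
            inherits(table, "transition_table"))
  if (structure$n != table$n)
    stop_config("structure and table dimensions differ")
  n <- structure$n
  X <- table$x
  total <- -edge_penalty * (sum(structure$W) + sum(structure$B))
  for (j in seq_len(n)) {
    wpar <- which(structure$W[, j] != 0)
    bpar <- which(structure$B[, j] != 0)
    if (score_first_slice) {
      pm <- if (length(wpar)) X[, wpar, drop = FALSE] else NULL
      total <- total + local_bde_score(X[, j], pm, ess)
    }
    cols2 <- c(bpar, n + wpar)
    pm2 <- if (length(cols2)) X[, cols2, drop = FALSE] else NULL
    total <- total + local_bde_score(X[, n + j], pm2, ess)
  }
  total
}

#' Precompute parent-set score tables for the sampler
#'
#' Exhaustively scores, for every node, (i) each admissible within-slice
#' parent set up to `max_parents` in the slice-1 role and (ii) each
#' admissible combined (within-slice union between-slice) parent set up to
#' `max_parents` in the slice-2 role, respecting the time-ordering
#' blacklist.  Also caches, per within-parent set, the log-sum over all
#' between-slice completions, which is what the partition sampler and the
#' enumeration oracle consume.
#'
#' @inheritParams score_structure
#' @param max_parents cap on the size of any parent set (>= 0).
#' @param budget maximum total number of parent sets to score before
#'   refusing (guards against combinatorial blow-up; lower `max_parents`
#'   if exceeded).
#' @param between_slice if `FALSE`, between-slice parent sets are
#'   restricted to empty (within-slice-only analysis).
#' @return A `dbn_score_table` object.
#' @export
build_score_table <- function(table, ess = 1, max_parents = 4L,
                              edge_penalty = 0, score_first_slice = TRUE,
                              budget = 1e6, between_slice = TRUE) {
  stopifnot(inherits(table, "transition_table"))
  if (max_parents < 0) stop_config("max_parents must be >= 0")
  n <- table$n
  X <- table$x
  w_universe <- lapply(seq_len(n), function(j) setdiff(seq_len(n), j))
  w_masks <- lapply(w_universe, subset_masks, cap = max_parents)
  n_b <- vapply(0:max_parents, function(kw)
    sum(choose(n, 0:(max_parents - kw))), numeric(1))
  total_sets <- sum(vapply(w_masks, function(m)
    sum(n_b[popcount(m) + 1L]), numeric(1)))
  if (total_sets > budget)
    stop_config(sprintf(
      "score table would need %.0f parent sets (budget %.0f); reduce max_parents",
      total_sets, budget))
  nodes <- vector("list", n)
  pow2 <- 2^(0:(2 * n))
  for (j in seq_len(n)) {
    wm <- w_masks[[j]]
    nw <- length(wm)
    wsize <- popcount(wm)
    # slice-1 role scores
    s1 <- numeric(nw)
    if (score_first_slice) {
      child1 <- X[, j]
      for (a in seq_len(nw)) {
        pc <- bits_of(wm[a], n)
        pm <- if (length(pc)) X[, pc, drop = FALSE] else NULL
        s1[a] <- local_bde_score(child1, pm, ess)
      }
    }
    # slice-2 role: combined sets grouped by within-parent mask
    child2 <- X[, n + j]
    c_w <- integer(0); c_b <- integer(0); s2 <- numeric(0)
    w_index <- integer(0)
    for (a in seq_len(nw)) {
      bm <- if (between_slice)
        subset_masks(seq_len(n), max_parents - wsize[a]) else 0L
      for (b in bm) {
        wpar <- bits_of(wm[a], n)
        bpar <- bits_of(b, n)
        cols <- c(bpar, n + wpar)
        pmat <- if (length(cols)) X[, cols, drop = FALSE] else NULL
        sc <- local_bde_score(child2, pmat, ess) -
          edge_penalty * (length(wpar) + length(bpar))
        c_w <- c(c_w, wm[a]); c_b <- c(c_b, b); s2 <- c(s2, sc)
        w_index <- c(w_index, a)
      }
    }
    bsum <- vapply(seq_len(nw), function(a) logsumexp(s2[w_index == a]),
                   numeric(1))
    grp <- split(seq_along(w_index), w_index)
    groups <- vector("list", nw)
    groups[as.integer(names(grp))] <- grp
    nodes[[j]] <- list(w_mask = wm, s1 = s1, c_w = c_w, c_b = c_b, s2 = s2,
                       w_index = w_index, bsum = bsum, f = s1 + bsum,
                       groups = groups)
  }
  structure(list(nodes = nodes, n = n, items = table$items, ess = ess,
                 max_parents = as.integer(max_parents),
                 edge_penalty = edge_penalty,
                 score_first_slice = score_first_slice,
                 n_rows = nrow(X)),
            class = "dbn_score_table")
}

#' @export
print.dbn_score_table <- function(x, ...) {
  cat(sprintf(
    "<dbn_score_table> %d variables, max_parents %d, ess %g, %d rows, %d parent sets\n",
    x$n, x$max_parents, x$ess, x$n_rows,
    sum(vapply(x$nodes, function(nd) length(nd$s2), numeric(1)))))
  invisible(x)
}

# log score of one (wmask, bmask) family for node j, -Inf if inadmissible
.family_score <- function(st, j, wmask, bmask) {
  nd <- st$nodes[[j]]
  a <- match(wmask, nd$w_mask)
  if (is.na(a)) return(-Inf)
  g <- nd$groups[[a]]
  hit <- g[nd$c_b[g] == bmask]
  if (!length(hit)) return(-Inf)
  nd$s1[a] + nd$s2[hit[1]]
}
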