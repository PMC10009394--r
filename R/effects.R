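# Exact inference on the unrolled two-slice network by variable
# elimination over binary factors, restricted to the ancestral set of the
# target in the mutilated graph.  Factors are (sorted variable ids, table
# over 2^k configs with the first id as least-significant bit).

.bit_at <- function(cfg, p) bitwAnd(bitwShiftR(cfg, p), 1L)

.f_from_cpt <- function(node, parents, p1) {
  v <- sort(c(parents, node))
  k <- length(v)
  cfg <- 0:(2L^k - 1L)
  ppos <- match(parents, v) - 1L
  np <- length(parents)
  pcfg <- if (np == 0L) rep(0L, length(cfg)) else {
    acc <- 0L
    for (q in seq_len(np)) acc <- acc + bitwShiftL(.bit_at(cfg, ppos[q]), q - 1L)
    acc
  }
  pr1 <- p1[pcfg + 1L]
  xbit <- .bit_at(cfg, match(node, v) - 1L)
  list(v = v, t = ifelse(xbit == 1L, pr1, 1 - pr1))
}

.f_clamp <- function(f, var, val) {
  p <- match(var, f$v)
  if (is.na(p)) return(f)
  cfg <- 0:(2L^length(f$v) - 1L)
  sel <- .bit_at(cfg, p - 1L) == val
  list(v = f$v[-p], t = f$t[sel])
}

.f_mult <- function(f1, f2) {
  u <- sort(union(f1$v, f2$v))
  m <- length(u)
  if (m > 24L) stop_config("factor over ", m, " variables; network too dense")
  cfg <- 0:(2L^m - 1L)
  idx_of <- function(f) {
    if (!length(f$v)) return(rep(0L, length(cfg)))
    pos <- match(f$v, u) - 1L
    acc <- 0L
    for (q in seq_along(f$v))
      acc <- acc + bitwShiftL(.bit_at(cfg, pos[q]), q - 1L)
    acc
  }
  list(v = u, t = f1$t[idx_of(f1) + 1L] * f2$t[idx_of(f2) + 1L])
}

.f_sumout <- function(f, var) {
  p <- match(var, f$v) - 1L
  cfg <- 0:(2L^length(f$v) - 1L)
  lo <- cfg[.bit_at(cfg, p) == 0L]
  list(v = f$v[-(p + 1L)], t = f$t[lo + 1L] + f$t[lo + 1L + 2L^p])
}

# P(target = 1) from a list of factors, eliminating everything else
.ve_marginal <- function(factors, target) {
  elim <- setdiff(unique(unlist(lapply(factors, `[[`, "v"))), target)
  while (length(elim)) {
    # min-fill-ish greedy: pick the variable whose factor union is smallest
    unions <- lapply(elim, function(v) {
      idx <- which(vapply(factors, function(f) v %in% f$v, logical(1)))
      list(idx = idx,
           size = length(unique(unlist(lapply(factors[idx], `[[`, "v")))))
    })
    pick <- which.min(vapply(unions, `[[`, numeric(1), "size"))
    v <- elim[pick]
    idx <- unions[[pick]]$idx
    f <- Reduce(.f_mult, factors[idx])
    f <- .f_sumout(f, v)
    factors <- c(factors[-idx], list(f))
    elim <- setdiff(elim, v)
  }
  f <- Reduce(.f_mult, factors)
  if (!length(f$v)) stop_config("target eliminated unexpectedly")
  tot <- sum(f$t)
  sum(f$t[.bit_at(0:(2L^length(f$v) - 1L), match(target, f$v) - 1L) == 1L]) / tot
}

.ancestors <- function(parents, node) {
  seen <- integer(0)
  frontier <- parents[[node]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), seen)
  }
  seen
}

#' Draw conditional probability tables from their conjugate posterior
#'
#' For every node of the unrolled two-slice network (slice-1 nodes given
#' their within-slice parents, slice-2 nodes given their within- plus
#' between-slice parents), draws each parent-configuration success
#' probability independently from `Beta(alpha + ones, alpha + zeros)` with
#' `alpha = ess / (2 q)`, the same prior weight used in scoring.
#'
#' @param structure a [dbn_structure()].
#' @param table a [build_transition_table()] result.
#' @param ess equivalent sample size, > 0.
#' @param seed optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @param point if `"mean"`, returns the posterior-mean CPTs instead of a
#'   random draw.
#' @return A `parameter_draw`: per unrolled node, `parents` (unrolled ids)
#'   and `p1` (success probability per parent configuration).
#' @export
draw_parameters <- function(structure, table, ess = 1, seed = NULL,
                            point = c("sample", "mean")) {
  stopifnot(inherits(structure, "dbn_structure"),
            inherits(table, "transition_table"))
  if (structure$n != table$n) stop_config("structure and table dimensions differ")
  point <- match.arg(point)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- structure$n
  X <- table$x
  pa <- unrolled_parents(structure)
  cpt <- lapply(seq_len(2L * n), function(v) {
    p <- pa[[v]]
    child <- X[, v]
    pmat <- if (length(p)) X[, p, drop = FALSE] else NULL
    cts <- .family_counts(child, pmat)
    alpha <- ess / (2 * cts$q)
    a1 <- alpha + cts$n1; a0 <- alpha + cts$n0
    p1 <- if (point == "mean") a1 / (a1 + a0) else stats::rbeta(cts$q, a1, a0)
    list(parents = p, p1 = p1)
  })
  structure(list(cpt = cpt, n = n, structure = structure, ess = ess),
            class = "parameter_draw")
}

#' Do-calculus intervention effect of a slice-1 variable on a slice-2 variable
#'
#' Computes `P(target = 1 | do(source = 1)) - P(target = 1 | do(source = 0))`
#' exactly on the unrolled 2n-node network: the source's incoming edges are
#' deleted, its value clamped, and the remaining variables marginalised by
#' summation restricted to the ancestral set of the target (variable
#' elimination; no sampling).  This is the total effect, through all causal
#' paths including mediation via slice-2 within-slice edges.  Exactly 0
#' whenever the target is not a descendant of the source in the mutilated
#' graph.
#'
#' @param structure a [dbn_structure()].
#' @param params a [draw_parameters()] result for that structure.
#' @param source slice-1 variable index (1..n).
#' @param target slice-2 variable index (1..n), i.e. the variable at the
#'   next time-point.
#' @return The effect, a value in `[-1, 1]`.
#' @export
do_effect <- function(structure, params, source, target) {
  stopifnot(inherits(params, "parameter_draw"))
  n <- params$n
  stopifnot(source >= 1, source <= n, target >= 1, target <= n)
  .do_effect_unrolled(params, as.integer(source), n + as.integer(target))
}

# effect between arbitrary unrolled nodes (used for the contemporaneous flag)
.do_effect_unrolled <- function(params, src, tgt) {
  parents <- lapply(params$cpt, `[[`, "parents")
  parents[[src]] <- integer(0)  # mutilation: delete incoming edges
  anc <- .ancestors(parents, tgt)
  if (!(src %in% anc)) return(0)
  nodes <- union(anc, tgt)
  p1 <- function(v) {
    fs <- lapply(setdiff(nodes, src), function(x)
      .f_clamp(.f_from_cpt(x, parents[[x]], params$cpt[[x]]$p1), src, v))
    .ve_marginal(fs, tgt)
  }
  p1(1L) - p1(0L)
}

#' Posterior distribution of all pairwise intervention effects
#'
#' For each structure draw in the sample, draws one set of CPT parameters
#' from their conjugate posterior and computes the exact do-calculus effect
#' of every slice-1 variable on every slice-2 variable (the full n x n
#' grid, including the diagonal: a variable's effect on itself at the next
#' slice, its "momentum").  Summarises each pair by the posterior mean and
#' an equal-tailed credible interval from the empirical quantiles; a pair
#' is flagged significant when that interval excludes zero.
#'
#' @param sample a [sample_dags()] result.
#' @param table the [build_transition_table()] the sample was fitted to.
#' @param ess equivalent sample size used in fitting.
#' @param seed integer seed for the parameter draws.
#' @param level credibility level of the interval (default 0.95).
#' @param contemporaneous if `TRUE`, effects of slice-2 variables on
#'   slice-2 variables are computed instead of the cross-slice grid.
#' @return An `effect_distribution`: `draws` (n x n x n_draws array),
#'   `mean`, `lower`, `upper` (n x n), `significant` (logical n x n),
#'   `items`, `level`.
#' @export
effect_distribution <- function(sample, table, ess = 1, seed = 1L,
                                level = 0.95, contemporaneous = FALSE) {
  stopifnot(inherits(sample, "dag_sample"),
            inherits(table, "transition_table"))
  S <- nrow(sample$w_mask)
  if (!S) stop_config("empty DAG sample")
  n <- sample$n
  set.seed(as.integer(seed))
  draws <- array(NA_real_, c(n, n, S))
  for (d in seq_len(S)) {
    W <- matrix(0L, n, n); B <- matrix(0L, n, n)
    for (j in seq_len(n)) {
      W[bits_of(sample$w_mask[d, j], n), j] <- 1L
      B[bits_of(sample$b_mask[d, j], n), j] <- 1L
    }
    str_d <- dbn_structure(W, B, items = sample$items)
    par_d <- draw_parameters(str_d, table, ess = ess, seed = NULL)
    for (s in seq_len(n)) for (t in seq_len(n)) {
      draws[s, t, d] <- if (contemporaneous)
        .do_effect_unrolled(par_d, n + s, n + t) else
        .do_effect_unrolled(par_d, s, n + t)
    }
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  mean_ <- apply(draws, c(1, 2), mean)
  lower <- apply(draws, c(1, 2), stats::quantile, probs = qs[1], names = FALSE)
  upper <- apply(draws, c(1, 2), stats::quantile, probs = qs[2], names = FALSE)
  sig <- lower > 0 | upper < 0
  dimnames(mean_) <- dimnames(lower) <- dimnames(upper) <- dimnames(sig) <-
    list(sample$items, sample$items)
  structure(list(draws = draws, mean = mean_, lower = lower, upper = upper,
                 significant = sig, items = sample$items, level = level,
                 n_draws = S, contemporaneous = contemporaneous),
            class = "effect_distribution")
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat(sprintf("<effect_distribution> %d x %d pairs, %d draws, %d significant at %.0f%%\n",
              nrow(x$mean), ncol(x$mean), x$n_draws, sum(x$significant),
              100 * x$level))
  invisible(x)
}

#' Tidy per-pair summary of an effect distribution
#'
#' @param x an [effect_distribution()] result.
#' @param ... unused.
#' @return Data frame `source, target, mean, lower, upper, significant,
#'   n_draws` in declared item order (sources vary slowest).
#' @export
as.data.frame.effect_distribution <- function(x, ...) {
  g <- expand.grid(target = x$items, source = x$items,
                   stringsAsFactors = FALSE)[, 2:1]
  i <- match(g$source, x$items); j <- match(g$target, x$items)
  data.frame(source = g$source, target = g$target,
             mean = x$mean[cbind(i, j)],
             lower = x$lower[cbind(i, j)],
             upper = x$upper[cbind(i, j)],
             significant = x$significant[cbind(i, j)],
             n_draws = x$n_draws,
             stringsAsFactors = FALSE)
}

#' Write effect summaries and raw draws
#' @param x an [effect_distribution()].
#' @param path summary CSV path.
#' @param draws_path optional CSV of the raw draws matrix (one row per
#'   draw, one `source.target` column per pair).
#' @return `path`, invisibly.
#' @export
write_effects_csv <- function(x, path, draws_path = NULL) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  if (!is.null(draws_path)) {
    m <- t(apply(x$draws, 3, identity))
    colnames(m) <- as.vector(outer(x$items, x$items,
                                   function(s, t) paste(s, t, sep = ".")))
    utils::write.csv(m, draws_path, row.names = FALSE)
  }
  invisible(path)
}
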