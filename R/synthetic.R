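#' Attrition schedule
#'
#' Per-wave retention probabilities with monotone dropout: once a
#' participant misses a wave, all later waves are missing too (emulating
#' loss to follow-up; wave-level, not item-level).
#'
#' @param retention numeric vector of per-wave retention probabilities in
#'   `[0, 1]`; `retention[w]` is the probability that a participant still
#'   present at wave w-1 is observed at wave w (the first entry is the
#'   baseline inclusion probability, normally 1).
#' @return An `attrition_schedule` object.
#' @export
attrition_schedule <- function(retention) {
  retention <- as.numeric(retention)
  if (any(retention < 0 | retention > 1))
    stop_config("retention probabilities must lie in [0, 1]")
  structure(list(retention = retention, monotone = TRUE),
            class = "attrition_schedule")
}

#' Five-wave attrition schedule shaped like the EuroSC cohort
#'
#' Retention 0.905 per follow-up wave, so a cohort of 1208 at wave 1 is
#' expected to retain about 810 participants by wave 5.
#'
#' @return An [attrition_schedule()] of length 5.
#' @export
eurosc_attrition <- function() attrition_schedule(c(1, rep(0.905, 4)))

# CPT for one node-role: signed per-parent contrasts plus a base rate, so
# that flipping any single parent moves P(child = 1) by at least
# `effect_floor` (scaled down proportionally when the in-degree makes that
# infeasible within (0.05, 0.95)).
.make_cpt <- function(n_par, effect_floor, margin = 0.05) {
  if (n_par == 0L)
    return(list(p1 = stats::runif(1, 0.2, 0.6), effects = numeric(0)))
  span <- 1 - 2 * margin
  cap <- span / n_par
  mag <- if (cap >= effect_floor)
    stats::runif(n_par, effect_floor, max(effect_floor,
                                          min(effect_floor + 0.25, cap)))
  else rep(cap, n_par)  # floor infeasible at this in-degree: spread evenly
  sgn <- sample(c(-1, 1), n_par, replace = TRUE)
  eff <- sgn * mag
  lo <- margin - sum(pmin(eff, 0))
  hi <- (1 - margin) - sum(pmax(eff, 0))
  base <- if (hi <= lo) (lo + hi) / 2 else stats::runif(1, lo, hi)
  cfg <- 0:(2^n_par - 1)
  bits <- vapply(seq_len(n_par), function(p) bitwAnd(bitwShiftR(cfg, p - 1L), 1L),
                 integer(length(cfg)))
  p1 <- base + as.vector(matrix(bits, ncol = n_par) %*% eff)
  list(p1 = p1, effects = eff)
}

#' Generate a ground-truth DBN with known conditional probability tables
#'
#' Draws an acyclic within-slice structure `W` (each ordered pair under a
#' random topological order included with probability `within_density`) and
#' a between-slice matrix `B` (diagonal "momentum" self-edges with
#' probability `self_edge_prob`, off-diagonal edges with probability
#' `between_density`), then equips every node-role with a CPT in which each
#' parent has an absolute contrast of at least `effect_floor` (proportionally
#' reduced if a node's in-degree makes the floor infeasible within (0,1)).
#'
#' @param n_vars number of variables per slice (>= 2).
#' @param within_density edge probability for within-slice ordered pairs.
#' @param between_density edge probability for off-diagonal between-slice
#'   pairs.
#' @param self_edge_prob probability of each diagonal between-slice edge.
#' @param effect_floor minimum absolute per-parent CPT contrast.
#' @param seed integer seed; the same seed reproduces the truth exactly.
#' @param items optional variable names.
#' @param max_in_degree optional cap on each node's combined (within plus
#'   between) parent count: excess edges are dropped at random, diagonal
#'   self-edges last.  `NULL` (default) leaves densities untouched.  A cap
#'   of `floor(0.9 / effect_floor)` guarantees every surviving edge keeps a
#'   contrast of at least `effect_floor`.
#' @return A `dbn_ground_truth`: list with `structure` ([dbn_structure()]),
#'   `cpt` (per unrolled node: `parents` and `p1` over parent configs) and
#'   `seed`.
#' @export
generate_true_dbn <- function(n_vars, within_density = 0.2,
                              between_density = 0.05, self_edge_prob = 0.9,
                              effect_floor = 0.3, seed = 1L, items = NULL,
                              max_in_degree = NULL) {
  if (n_vars < 2) stop_config("n_vars must be at least 2")
  probs <- c(within_density, between_density, self_edge_prob)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must lie in [0, 1]")
  if (effect_floor > 1) stop_config("effect_floor above 1 is infeasible")
  set.seed(as.integer(seed))
  n <- as.integer(n_vars)
  ord <- sample(n)  # topological order: ord[1] first
  W <- matrix(0L, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    if (stats::runif(1) < within_density) W[ord[a], ord[b]] <- 1L
  B <- matrix(as.integer(stats::runif(n * n) < between_density), n, n)
  diag(B) <- as.integer(stats::runif(n) < self_edge_prob)
  if (!is.null(max_in_degree)) {
    for (j in seq_len(n)) {
      repeat {
        wpar <- which(W[, j] == 1L); bpar <- which(B[, j] == 1L)
        if (length(wpar) + length(bpar) <= max_in_degree) break
        boff <- setdiff(bpar, j)
        pool <- rbind(if (length(wpar)) cbind(1L, wpar),
                      if (length(boff)) cbind(2L, boff))
        if (is.null(pool)) pool <- cbind(2L, j)  # self-edge dropped last
        d <- pool[sample.int(nrow(pool), 1L), ]
        if (d[1] == 1L) W[d[2], j] <- 0L else B[d[2], j] <- 0L
      }
    }
  }
  structure_ <- dbn_structure(W, B, items = items)
  pa <- unrolled_parents(structure_)
  cpt <- lapply(pa, function(p) {
    cp <- .make_cpt(length(p), effect_floor)
    list(parents = p, p1 = cp$p1)
  })
  structure(list(structure = structure_, cpt = cpt, seed = as.integer(seed)),
            class = "dbn_ground_truth")
}

#' Assemble a ground truth from explicit conditional probability tables
#'
#' Companion to [generate_true_dbn()] for designs where exact planted
#' contrasts matter (e.g. a single transition edge of known strength).
#'
#' @param structure a [dbn_structure()].
#' @param p1 list of length 2n (unrolled node order: slice-1 nodes then
#'   slice-2 nodes); element v is the vector of `P(node = 1)` over the
#'   `2^k` configurations of node v's parents (sorted unrolled ids, first
#'   parent as least-significant bit).
#' @return A `dbn_ground_truth`.
#' @export
dbn_ground_truth <- function(structure, p1) {
  stopifnot(inherits(structure, "dbn_structure"))
  pa <- unrolled_parents(structure)
  if (length(p1) != 2L * structure$n)
    stop_config("p1 must have one entry per unrolled node (2n)")
  for (v in seq_along(pa)) {
    if (length(p1[[v]]) != 2L^length(pa[[v]]))
      stop_config(sprintf("node %d: expected %d CPT rows, got %d",
                          v, 2L^length(pa[[v]]), length(p1[[v]])))
    if (any(p1[[v]] < 0 | p1[[v]] > 1))
      stop_config("CPT probabilities must lie in [0, 1]")
  }
  cpt <- lapply(seq_along(pa), function(v)
    list(parents = pa[[v]], p1 = as.numeric(p1[[v]])))
  structure(list(structure = structure, cpt = cpt, seed = NA_integer_),
            class = "dbn_ground_truth")
}

#' @export
print.dbn_ground_truth <- function(x, ...) {
  print(x$structure)
  invisible(x)
}

# sample one wave for all participants given (possibly empty) previous wave
.sample_slice <- function(truth, prev, n_id) {
  n <- truth$structure$n
  out <- matrix(NA_real_, n_id, n)
  ord <- topological_order(truth$structure$W)
  for (j in ord) {
    node <- if (is.null(prev)) j else n + j
    cp <- truth$cpt[[node]]
    if (!length(cp$parents)) {
      p <- rep(cp$p1[1], n_id)
    } else {
      pv <- vapply(cp$parents, function(q) {
        if (q <= n) {
          if (is.null(prev)) out[, q] else prev[, q]
        } else out[, q - n]
      }, numeric(n_id))
      cfg <- as.vector(matrix(pv, ncol = length(cp$parents)) %*%
                         2^(seq_along(cp$parents) - 1)) + 1
      p <- cp$p1[cfg]
    }
    out[, j] <- as.numeric(stats::runif(n_id) < p)
  }
  out
}

#' Simulate a multi-wave binary symptom cohort from a known DBN
#'
#' Wave 1 is drawn from the within-slice model (W with its own CPTs); each
#' later wave is drawn from the stationary transition CPTs given the
#' previous wave.  Monotone wave-level dropout is then applied
#' (missing-completely-at-random): a participant lost at wave w is missing
#' at all later waves.
#'
#' @param truth a [generate_true_dbn()] result.
#' @param n_participants cohort size at baseline.
#' @param n_waves number of waves (>= 2).
#' @param attrition an [attrition_schedule()] of length `n_waves`, or `NULL`
#'   for a complete panel.
#' @param seed integer seed.
#' @return A binary [symptom_panel()].
#' @export
simulate_cohort <- function(truth, n_participants = 1208L, n_waves = 5L,
                            attrition = NULL, seed = 1L) {
  stopifnot(inherits(truth, "dbn_ground_truth"))
  if (n_waves < 2) stop_config("n_waves must be at least 2")
  if (!is.null(attrition)) {
    stopifnot(inherits(attrition, "attrition_schedule"))
    if (length(attrition$retention) != n_waves)
      stop_config("attrition schedule length must equal n_waves")
  }
  set.seed(as.integer(seed))
  n <- truth$structure$n
  arr <- array(NA_real_, c(n_participants, n_waves, n))
  prev <- NULL
  for (w in seq_len(n_waves)) {
    prev <- .sample_slice(truth, prev, n_participants)
    arr[, w, ] <- prev
  }
  if (!is.null(attrition)) {
    present <- rep(TRUE, n_participants)
    for (w in seq_len(n_waves)) {
      present <- present & (stats::runif(n_participants) < attrition$retention[w])
      arr[!present, w, ] <- NA_real_
    }
  }
  items <- truth$structure$items
  sch <- symptom_schema(items, instrument = "BINARY", min = 0L, max = 1L)
  p <- symptom_panel(arr, sch,
                     participants = sprintf("S%04d", seq_len(n_participants)))
  class(p) <- c("binary_panel", class(p))
  p
}

#' Serialize a ground truth to JSON (adjacency lists plus CPT arrays)
#' @param truth a [generate_true_dbn()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  n <- truth$structure$n
  ew <- which(truth$structure$W == 1L, arr.ind = TRUE)
  eb <- which(truth$structure$B == 1L, arr.ind = TRUE)
  obj <- list(
    items = truth$structure$items,
    seed = truth$seed,
    within_edges = data.frame(from = as.integer(ew[, 1]),
                              to = as.integer(ew[, 2])),
    between_edges = data.frame(from = as.integer(eb[, 1]),
                               to = as.integer(eb[, 2])),
    cpt = lapply(truth$cpt, function(cp)
      list(parents = as.integer(cp$parents), p1 = as.numeric(cp$p1))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
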