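#' Two-slice dynamic Bayesian network structure
#'
#' A stationary first-order DBN over `n` binary variables: an acyclic
#' within-slice adjacency `W` (shared by both slices) and an unconstrained
#' between-slice adjacency `B` (slice-1 source -> slice-2 target).  The
#' unrolled 2n-node graph places W on each slice and B across; no edge from
#' slice 2 back to slice 1 can exist by construction.
#'
#' @param W n x n 0/1 matrix, `W[i, j] = 1` for a within-slice edge i -> j.
#' @param B n x n 0/1 matrix, `B[i, j] = 1` for an edge i at T -> j at T+1.
#' @param items optional variable names.
#' @return A `dbn_structure` object.
#' @export
dbn_structure <- function(W, B, items = NULL) {
  W <- as.matrix(W); B <- as.matrix(B)
  n <- nrow(W)
  stopifnot(ncol(W) == n, nrow(B) == n, ncol(B) == n,
            all(W %in% 0:1), all(B %in% 0:1))
  if (any(diag(W) != 0)) stop("W may not contain self-loops", call. = FALSE)
  if (is.null(topological_order(W)))
    stop("within-slice graph W must be acyclic", call. = FALSE)
  items <- items %||% colnames(W) %||% paste0("V", seq_len(n))
  dimnames(W) <- dimnames(B) <- list(items, items)
  storage.mode(W) <- storage.mode(B) <- "integer"
  out <- structure(list(W = W, B = B, n = n, items = items),
                   class = "dbn_structure")
  stopifnot(!is.null(topological_order(unroll_dbn(out))))  # belt and braces
  out
}

#' @export
print.dbn_structure <- function(x, ...) {
  cat(sprintf("<dbn_structure> %d variables, %d within-slice and %d between-slice edges\n",
              x$n, sum(x$W), sum(x$B)))
  invisible(x)
}

#' Unroll a two-slice DBN to its 2n-node adjacency matrix
#'
#' Nodes 1..n are the slice-1 copies, nodes n+1..2n the slice-2 copies.
#'
#' @param structure a [dbn_structure()].
#' @return A 2n x 2n 0/1 adjacency matrix.
#' @export
unroll_dbn <- function(structure) {
  n <- structure$n
  A <- matrix(0L, 2L * n, 2L * n)
  A[seq_len(n), seq_len(n)] <- structure$W
  A[n + seq_len(n), n + seq_len(n)] <- structure$W
  A[seq_len(n), n + seq_len(n)] <- structure$B
  nm <- c(paste0(structure$items, "_t0"), paste0(structure$items, "_t1"))
  dimnames(A) <- list(nm, nm)
  A
}

# Kahn's algorithm; returns a topological order or NULL on a cycle.
topological_order <- function(A) {
  n <- nrow(A)
  indeg <- colSums(A)
  avail <- which(indeg == 0)
  ord <- integer(0)
  indeg <- as.numeric(indeg)
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    ord <- c(ord, v)
    ch <- which(A[v, ] != 0)
    indeg[ch] <- indeg[ch] - 1
    avail <- c(avail, ch[indeg[ch] == 0])
  }
  if (length(ord) < n) NULL else ord
}

# Parent list of the unrolled network: for each of the 2n nodes, the sorted
# unrolled ids of its parents.
unrolled_parents <- function(structure) {
  n <- structure$n
  lapply(seq_len(2L * n), function(v) {
    if (v <= n) which(structure$W[, v] != 0)
    else sort(c(which(structure$B[, v - n] != 0),
                n + which(structure$W[, v - n] != 0)))
  })
}
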