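#' Build the transition table of adjacent-wave pairs
#'
#' Stacks one row per (participant, adjacent wave pair) for which all `2n`
#' binary values -- the n items at wave p and the n items at wave p+1 --
#' are observed.  A participant complete at all waves contributes one row
#' per pair; completeness is judged per pair, not per participant.  Rows
#' are ordered deterministically by participant then pair index, whatever
#' the input order.
#'
#' @param panel a `binary_panel` (see [dichotomize()]) with at least two
#'   waves.
#' @return A `transition_table`: list with `x` (integer matrix, columns
#'   `<item>_t0` then `<item>_t1`), `participant`, `pair`, `items`, `n`.
#' @export
build_transition_table <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  arr <- panel$ratings
  if (!all(arr %in% c(0, 1) | is.na(arr)))
    stop_config("panel must be binary (0/1/missing); see dichotomize()")
  n_w <- panel$n_waves
  if (n_w < 2L) stop_config("panel must have at least 2 waves")
  n <- nrow(panel$schema)
  items <- panel$schema$item
  ord <- order(panel$participants)
  rows <- list(); who <- character(0); pr <- integer(0)
  per_pair <- integer(n_w - 1L)
  for (i in ord) {
    obs <- rowSums(is.na(matrix(arr[i, , ], nrow = n_w))) == 0L
    for (p in seq_len(n_w - 1L)) {
      if (obs[p] && obs[p + 1L]) {
        rows[[length(rows) + 1L]] <- c(arr[i, p, ], arr[i, p + 1L, ])
        who <- c(who, panel$participants[i])
        pr <- c(pr, p)
        per_pair[p] <- per_pair[p] + 1L
      }
    }
  }
  if (!length(rows))
    stop_config("no participant has complete data on any adjacent wave pair; ",
                "complete rows per pair: ",
                paste(sprintf("%d-%d: %d", seq_len(n_w - 1L),
                              seq_len(n_w - 1L) + 1L, per_pair),
                      collapse = ", "))
  x <- matrix(as.integer(do.call(rbind, rows)), nrow = length(rows))
  colnames(x) <- c(paste0(items, "_t0"), paste0(items, "_t1"))
  structure(list(x = x, participant = who, pair = pr, items = items, n = n),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> %d rows (%d variables per slice), pairs: %s\n",
              nrow(x$x), x$n,
              paste(names(table(x$pair)), table(x$pair), sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' @export
as.data.frame.transition_table <- function(x, ...) {
  cbind(data.frame(participant = x$participant, pair = x$pair,
                   stringsAsFactors = FALSE),
        as.data.frame(x$x))
}

#' Write a transition table to CSV
#' @param tt a [build_transition_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(tt, path) {
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE)
  invisible(path)
}

#' Read a transition table written by [write_transition_table()]
#' @param path CSV file.
#' @return A `transition_table`.
#' @export
read_transition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vc <- setdiff(names(df), c("participant", "pair"))
  t0 <- grep("_t0$", vc, value = TRUE)
  items <- sub("_t0$", "", t0)
  cols <- c(paste0(items, "_t0"), paste0(items, "_t1"))
  if (!all(cols %in% vc)) stop_config("malformed transition table header")
  x <- as.matrix(df[cols])
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% 0:1))
    stop_config("transition table must be complete and binary")
  structure(list(x = x, participant = as.character(df$participant),
                 pair = as.integer(df$pair), items = items,
                 n = length(items)),
            class = "transition_table")
}
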