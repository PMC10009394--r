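#' Item schema for a symptom panel
#'
#' Declares the measurement items of a panel: their names, the instrument
#' each belongs to and the admissible rating range.  Ratings outside the
#' declared range are rejected by [read_panel()].
#'
#' @param item character vector of unique item names.
#' @param instrument character vector (recycled) tagging each item with its
#'   instrument, e.g. `"PANSS"` or `"CDSS"`.
#' @param min,max integer vectors (recycled) giving the inclusive rating
#'   range per item.
#' @param label optional human-readable item labels.
#' @return A `symptom_schema` data frame with columns `item`, `instrument`,
#'   `min`, `max`, `label`.
#' @seealso [eurosc_items()] for the default 12-item schema.
#' @export
symptom_schema <- function(item, instrument, min, max, label = item) {
  if (anyDuplicated(item)) stop_config("item names must be unique")
  out <- data.frame(item = as.character(item),
                    instrument = rep_len(as.character(instrument), length(item)),
                    min = rep_len(as.integer(min), length(item)),
                    max = rep_len(as.integer(max), length(item)),
                    label = rep_len(as.character(label), length(item)),
                    stringsAsFactors = FALSE)
  if (any(out$min > out$max)) stop_config("schema has min > max")
  class(out) <- c("symptom_schema", "data.frame")
  out
}

#' The 12-item PANSS/CDSS symptom schema
#'
#' Nine PANSS items (P1 delusions, P3 hallucinations, P4 excitement,
#' P5 grandiosity, P6 suspiciousness/persecution, P7 hostility, G2 anxiety,
#' G11 poor attention, G14 poor impulse control; scored 1-7) and three CDSS
#' items (depressed mood, hopelessness, self-depreciation; scored 0-3).
#'
#' @return A [symptom_schema()] with 12 rows.
#' @export
eurosc_items <- function() {
  symptom_schema(
    item = c("P1", "P3", "P4", "P5", "P6", "P7", "G2", "G11", "G14",
             "CDSS1", "CDSS2", "CDSS3"),
    instrument = c(rep("PANSS", 9), rep("CDSS", 3)),
    min = c(rep(1L, 9), rep(0L, 3)),
    max = c(rep(7L, 9), rep(3L, 3)),
    label = c("delusions", "hallucinations", "excitement", "grandiosity",
              "persecution", "hostility", "anxiety", "poor attention",
              "poor impulse control", "depressed mood", "hopelessness",
              "self-depreciation"))
}

#' Construct a symptom panel
#'
#' A participant x wave x item array of ordinal ratings with missingness,
#' validated against an item schema.
#'
#' @param ratings numeric 3-d array `[participant, wave, item]`; `NA` marks
#'   a missing rating.
#' @param schema a [symptom_schema()].
#' @param participants optional participant identifiers (default taken from
#'   dimnames or `1:n`).
#' @return A `symptom_panel` object.
#' @export
symptom_panel <- function(ratings, schema, participants = NULL) {
  stopifnot(is.array(ratings), length(dim(ratings)) == 3L)
  if (dim(ratings)[3] != nrow(schema))
    stop_config("third dimension of ratings must match the schema")
  participants <- participants %||% dimnames(ratings)[[1]] %||%
    as.character(seq_len(dim(ratings)[1]))
  dimnames(ratings) <- list(participants,
                            as.character(seq_len(dim(ratings)[2])),
                            schema$item)
  for (k in seq_len(nrow(schema))) {
    v <- matrix(ratings[, , k], nrow = dim(ratings)[1])
    bad <- !is.na(v) & (v < schema$min[k] | v > schema$max[k])
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)
      stop_config(sprintf(
        "rating out of range for item %s (allowed %d-%d), e.g. participant %s wave %d value %s",
        schema$item[k], schema$min[k], schema$max[k],
        participants[w[1, 1]], w[1, 2], format(v[w[1, 1], w[1, 2]])))
    }
  }
  structure(list(ratings = ratings, schema = schema,
                 participants = participants,
                 n_waves = dim(ratings)[2]),
            class = "symptom_panel")
}

#' @export
print.symptom_panel <- function(x, ...) {
  cat(sprintf("<%s> %d participants x %d waves x %d items (%.1f%% observed)\n",
              class(x)[1], length(x$participants), x$n_waves,
              nrow(x$schema), 100 * mean(!is.na(x$ratings))))
  invisible(x)
}

#' @export
dim.symptom_panel <- function(x) dim(x$ratings)

#' Read a symptom panel from CSV
#'
#' Accepts a long dialect (`participant,wave,item,rating`) or a wide dialect
#' (`participant,wave,<item1>,...,<itemK>`).  Missing ratings are empty
#' fields or `NA`.  Ratings are validated against the schema's range.
#'
#' @param path CSV file path.
#' @param schema a [symptom_schema()] declaring the expected items.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @return A [symptom_panel()].
#' @export
read_panel <- function(path, schema = eurosc_items(),
                       format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  long_cols <- c("participant", "wave", "item", "rating")
  if (format == "auto")
    format <- if (all(long_cols %in% names(df))) "long" else "wide"
  if (format == "long") {
    miss <- setdiff(long_cols, names(df))
    if (length(miss)) stop_config("long format lacks column(s): ",
                                  paste(miss, collapse = ", "))
    unknown <- setdiff(unique(df$item), schema$item)
    if (length(unknown)) stop_config("undeclared item(s) in file: ",
                                     paste(unknown, collapse = ", "))
    absent <- setdiff(schema$item, unique(df$item))
    if (length(absent)) stop_config("declared item(s) missing from file: ",
                                    paste(absent, collapse = ", "))
    key <- paste(df$participant, df$wave, df$item, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop_config(sprintf("duplicate cell: participant %s wave %s item %s",
                          d$participant, d$wave, d$item))
    }
    long <- df
  } else {
    need <- c("participant", "wave")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop_config("wide format lacks column(s): ",
                                  paste(miss, collapse = ", "))
    absent <- setdiff(schema$item, names(df))
    if (length(absent)) stop_config("declared item(s) missing from file: ",
                                    paste(absent, collapse = ", "))
    key <- paste(df$participant, df$wave, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop_config(sprintf("duplicate (participant, wave) row: %s wave %s",
                          d$participant, d$wave))
    }
    long <- do.call(rbind, lapply(schema$item, function(it)
      data.frame(participant = df$participant, wave = df$wave, item = it,
                 rating = df[[it]], stringsAsFactors = FALSE)))
  }
  long$wave <- as.integer(long$wave)
  waves <- sort(unique(long$wave))
  if (!identical(waves, seq_along(waves)))
    stop_config("wave indices must be consecutive integers starting at 1")
  parts <- sort(unique(as.character(long$participant)))
  arr <- array(NA_real_, c(length(parts), length(waves), nrow(schema)))
  i <- match(as.character(long$participant), parts)
  j <- long$wave
  k <- match(long$item, schema$item)
  r <- suppressWarnings(as.numeric(long$rating))
  bad <- !is.na(long$rating) & long$rating != "" & is.na(r)
  if (any(bad)) {
    b <- which(bad)[1]
    stop_config(sprintf("unparseable rating '%s' (participant %s wave %d item %s)",
                        long$rating[b], long$participant[b], long$wave[b],
                        long$item[b]))
  }
  arr[cbind(i, j, k)] <- r
  symptom_panel(arr, schema, participants = parts)
}

#' Dichotomize ordinal ratings
#'
#' Applies a "clearly present" cutoff per item: ratings at or above the
#' threshold become 1, below become 0, missing stays missing.  The default
#' follows the convention of treating PANSS items rated 4 (moderate) or
#' above as present; CDSS items (scored 0-3, which have no stated cutoff in
#' that convention) default to >= 2, i.e. at least moderate.
#'
#' @param panel a [symptom_panel()].
#' @param thresholds named numeric vector of cutpoints; names may be item
#'   names or instrument names (item-level entries take precedence).
#' @return A `binary_panel` (a [symptom_panel()] with values in {0,1,NA}).
#' @export
dichotomize <- function(panel, thresholds = c(PANSS = 4, CDSS = 2)) {
  stopifnot(inherits(panel, "symptom_panel"))
  sch <- panel$schema
  thr <- numeric(nrow(sch))
  lookup <- function(nm)
    if (nm %in% names(thresholds)) thresholds[[nm]] else NULL
  for (k in seq_len(nrow(sch))) {
    t_k <- lookup(sch$item[k]) %||% lookup(sch$instrument[k])
    if (is.null(t_k) || is.na(t_k))
      stop_config("no dichotomization threshold for item ", sch$item[k],
                  " (instrument ", sch$instrument[k], ")")
    thr[k] <- t_k
  }
  bin <- panel$ratings
  for (k in seq_len(nrow(sch)))
    bin[, , k] <- as.numeric(panel$ratings[, , k] >= thr[k])
  sch2 <- sch
  sch2$min <- 0L
  sch2$max <- 1L
  out <- symptom_panel(bin, sch2, participants = panel$participants)
  out$thresholds <- stats::setNames(thr, sch$item)
  class(out) <- c("binary_panel", class(out))
  out
}

#' Write a panel to CSV
#'
#' @param panel a [symptom_panel()].
#' @param path output file.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, format = c("wide", "long")) {
  format <- match.arg(format)
  arr <- panel$ratings
  if (format == "wide") {
    rows <- expand.grid(participant = panel$participants,
                        wave = seq_len(panel$n_waves),
                        stringsAsFactors = FALSE)
    m <- sapply(seq_len(nrow(panel$schema)), function(k)
      arr[cbind(match(rows$participant, panel$participants), rows$wave, k)])
    colnames(m) <- panel$schema$item
    out <- cbind(rows, m)
    # drop waves where the participant was entirely unobserved
    out <- out[rowSums(!is.na(m)) > 0L, , drop = FALSE]
  } else {
    out <- expand.grid(participant = panel$participants,
                       wave = seq_len(panel$n_waves),
                       item = panel$schema$item, stringsAsFactors = FALSE)
    out$rating <- arr[cbind(match(out$participant, panel$participants),
                            out$wave, match(out$item, panel$schema$item))]
    out <- out[!is.na(out$rating), , drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
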