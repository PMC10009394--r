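sch <- eurosc_items()

write_long_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

make_long_df <- function(participants, waves, schema = sch) {
  g <- expand.grid(participant = participants, wave = waves,
                   item = schema$item, stringsAsFactors = FALSE)
  g$rating <- schema$min[match(g$item, schema$item)] +
    (seq_len(nrow(g)) %% 3)
  g
}

test_that("long and wide CSV dialects round-trip into the same panel", {
  df <- make_long_df(c("a", "b"), 1:5)
  p_long <- read_panel(write_long_fixture(df), sch)
  expect_s3_class(p_long, "symptom_panel")
  expect_equal(dim(p_long), c(2L, 5L, 12L))
  expect_equal(sum(!is.na(p_long$ratings)), 120L)

  wide <- stats::reshape(df, idvar = c("participant", "wave"),
                         timevar = "item", direction = "wide")
  names(wide) <- sub("^rating\\.", "", names(wide))
  p_wide <- read_panel(write_long_fixture(wide), sch)
  expect_equal(p_wide$ratings, p_long$ratings)
})

test_that("schema violations are reported with their location", {
  df <- make_long_df("a", 1:2)
  # a declared item absent from the file
  expect_error(read_panel(write_long_fixture(df[df$item != "P6", ]), sch),
               "P6")
  # rating outside the declared 1-7 PANSS range
  bad <- df
  bad$rating[bad$item == "P1"][1] <- 9
  expect_error(read_panel(write_long_fixture(bad), sch), "out of range.*P1")
  # duplicated cell
  expect_error(read_panel(write_long_fixture(rbind(df, df[1, ])), sch),
               "duplicate")
})

test_that("dichotomization applies the moderate-severity cutoffs", {
  arr <- array(NA_real_, c(1, 2, 12))
  arr[1, 1, ] <- c(4, 3, 5, 1, 7, 4, 3, 6, 2, 2, 1, 0)
  pan <- symptom_panel(arr, sch)
  bin <- dichotomize(pan)
  # PANSS: >= 4 is present (a 4 itself counts), < 4 absent
  expect_equal(bin$ratings[1, 1, 1:9], c(1, 0, 1, 0, 1, 1, 0, 1, 0),
               ignore_attr = TRUE)
  # CDSS default: >= 2
  expect_equal(bin$ratings[1, 1, 10:12], c(1, 0, 0), ignore_attr = TRUE)
  # missing stays missing
  expect_true(all(is.na(bin$ratings[1, 2, ])))
  # every item needs a threshold
  expect_error(dichotomize(pan, thresholds = c(PANSS = 4)), "CDSS")
})

test_that("dichotomize is idempotent on binary panels at threshold 1", {
  tr <- flat_truth(3)
  pan <- simulate_cohort(tr, 20, 2, seed = 4)
  bin <- dichotomize(pan, thresholds = c(BINARY = 1))
  expect_equal(bin$ratings, pan$ratings)
})

test_that("transition rows require completeness on both adjacent waves", {
  n <- 3
  arr <- array(NA_real_, c(3, 5, n))
  arr[1, , ] <- 0                      # complete at all 5 waves -> 4 rows
  arr[2, c(1, 2, 4), ] <- 1            # waves {1,2,4} -> only pair 1-2
  arr[3, 3, ] <- 1                     # a single wave -> no pair
  pan <- symptom_panel(arr, symptom_schema(paste0("V", 1:n), "BINARY", 0, 1),
                       participants = c("a", "b", "c"))
  class(pan) <- c("binary_panel", class(pan))
  tt <- build_transition_table(pan)
  expect_equal(nrow(tt$x), 5L)
  expect_equal(tt$pair[tt$participant == "a"], 1:4)
  expect_equal(tt$pair[tt$participant == "b"], 1L)
  expect_false("c" %in% tt$participant)
  # item-level missingness voids the whole pair
  arr[1, 2, 1] <- NA
  pan2 <- symptom_panel(arr, pan$schema, participants = c("a", "b", "c"))
  class(pan2) <- c("binary_panel", class(pan2))
  expect_equal(sum(build_transition_table(pan2)$participant == "a"), 2L)
})

test_that("row count equals a brute-force recount and ignores input order", {
  tr <- generate_true_dbn(4, seed = 9)
  pan <- simulate_cohort(tr, 60, 4, attrition = attrition_schedule(
    c(1, 0.8, 0.8, 0.8)), seed = 10)
  tt <- build_transition_table(pan)
  # brute-force recount
  expected <- 0L
  for (i in seq_along(pan$participants)) for (p in 1:3) {
    if (!anyNA(pan$ratings[i, p, ]) && !anyNA(pan$ratings[i, p + 1, ]))
      expected <- expected + 1L
  }
  expect_equal(nrow(tt$x), expected)
  # permuting participants leaves the (sorted) table unchanged
  perm <- sample(seq_along(pan$participants))
  pan2 <- symptom_panel(pan$ratings[perm, , ], pan$schema,
                        participants = pan$participants[perm])
  class(pan2) <- c("binary_panel", class(pan2))
  tt2 <- build_transition_table(pan2)
  expect_identical(tt2$x, tt$x)
  expect_identical(tt2$participant, tt$participant)
})

test_that("a panel with no usable pair fails with a per-pair report", {
  arr <- array(NA_real_, c(2, 3, 2))
  arr[, 1, ] <- 1
  arr[, 3, ] <- 0
  pan <- symptom_panel(arr, symptom_schema(c("x", "y"), "BINARY", 0, 1))
  class(pan) <- c("binary_panel", class(pan))
  expect_error(build_transition_table(pan), "complete rows per pair")
})

test_that("panel CSV writer and transition-table CSV round-trip", {
  tr <- generate_true_dbn(3, seed = 5)
  pan <- simulate_cohort(tr, 15, 3, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(pan, f)
  pan2 <- read_panel(f, pan$schema)
  expect_equal(pan2$ratings, pan$ratings, ignore_attr = TRUE)
  tt <- build_transition_table(pan)
  f2 <- tempfile(fileext = ".csv")
  write_transition_table(tt, f2)
  tt2 <- read_transition_table(f2)
  expect_identical(tt2$x, tt$x)
})
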