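test_that("raw extraction counts events by outcome and records latency", {
  sessions <- make_session(
    "c1", "ms", 1,
    ev_tbl(c(500, 900, 1400), c("correct", "incorrect", "correct"), "drag"),
    completed = FALSE
  )
  fm <- extract_raw_features(sessions, child_ids = "c1")
  d <- fm$data
  expect_equal(d$ms_l1_correctdrags, 2)
  expect_equal(d$ms_l1_incorrectdrag, 1)
  expect_equal(d$ms_l1_totaldrags, 3)
  expect_equal(d$ms_l1_background, 0)
  expect_equal(d$ms_l1_latency, 500)
  expect_equal(d$ms_l1_firstevent, 500)
  expect_equal(d$ms_l1_lastevent, 1400)
  expect_false(any(fm$mask[, c("ms_l1_correctdrags", "ms_l1_latency")]))
})

test_that("attempted-but-empty levels have zero counts and masked timestamps", {
  sessions <- make_session("c1", "ms", 1)
  fm <- extract_raw_features(sessions, child_ids = "c1")
  expect_equal(fm$data$ms_l1_totaldrags, 0)
  expect_false(fm$mask["c1", "ms_l1_totaldrags"])
  expect_true(is.na(fm$data$ms_l1_latency))
  expect_true(fm$mask["c1", "ms_l1_latency"])
})

test_that("unattempted levels are fully masked", {
  sessions <- make_session(
    "c1", "jig", 1, ev_tbl(c(100, 600), c("correct", "correct"), "drag"),
    completed = TRUE
  )
  fm <- extract_raw_features(sessions, child_ids = "c1")
  jig2 <- grepl("^jig_l2_", colnames(fm$mask))
  expect_true(all(fm$mask[, jig2]))
  expect_true(all(is.na(as.numeric(fm$data[1, colnames(fm$mask)[jig2]]))))
})

test_that("derived ratios follow their definitions", {
  sessions <- make_session(
    "c1", "ms", 1,
    ev_tbl(
      c(0, 2000, 5000, 10000),
      c("correct", "correct", "incorrect", "correct"), "drag"
    ),
    completed = FALSE
  )
  fm <- derive_features(extract_raw_features(sessions, child_ids = "c1"))
  d <- fm$data
  expect_equal(d$ms_l1_accuracy_cbyi, 0.75)
  expect_equal(d$ms_l1_accuracy_cbyt, 0.75)
  expect_equal(d$ms_l1_playtime, 10) # seconds, last - first
  expect_equal(d$ms_l1_correctrate, 0.3) # 3 correct over 10 s
  expect_equal(d$ms_l1_activity, 0.4) # 4 events over 10 s
  # fewer than the 5-correct threshold: completion time is the 60 s timer
  expect_equal(d$ms_l1_completion_time, 60)
  expect_equal(d$sum_all_levels_played, 1)
  expect_equal(d$ms_levels_played, 1)
})

test_that("completion time is the timestamp of the threshold-th correct", {
  sessions <- make_session(
    "c1", "st", 1,
    ev_tbl(seq(1000, 12000, by = 1000), rep("correct", 12), "tap"),
    completed = TRUE
  )
  fm <- derive_features(extract_raw_features(sessions, child_ids = "c1"))
  expect_equal(fm$data$st_l1_completion_time, 5) # 5th correct at 5000 ms
})

test_that("levels played counts attempted levels across games", {
  cohort <- small_cohort()
  fm <- derive_features(extract_raw_features(
    cohort$sessions, child_ids = cohort$children$child_id
  ))
  lp <- levels_played_per_child(cohort$sessions, cohort$children$child_id)
  expect_equal(fm$data$sum_all_levels_played, as.numeric(lp$levels_played))
  expect_true(all(fm$data$sum_all_levels_played <= 40))
})

test_that("imputation fills by the registry rules and only touches masked cells", {
  sessions <- dplyr::bind_rows(
    make_session("c1", "ms", 1,
      ev_tbl(c(500, 1500), c("correct", "incorrect"), "drag")),
    # ms levels 2-3 unattempted; jig fully unattempted
    make_session("c1", "st", 1,
      ev_tbl(c(200, 700, 1300, 2000, 2600),
             rep("correct", 5), "tap"), completed = TRUE)
  )
  fm <- impute_missing(derive_features(
    extract_raw_features(sessions, child_ids = "c1")
  ))
  d <- fm$data
  expect_false(anyNA(fm_matrix(fm)))
  expect_equal(d$ms_l3_accuracy_cbyi, 0)
  expect_equal(d$ms_l3_correctrate, 0)
  expect_equal(d$ms_l3_completion_time, 60)
  expect_equal(d$ms_l3_latency, 60000)
  expect_equal(d$ms_l3_correctdrags, 0)
  expect_equal(d$jig_levels_played, 0)
  # across-game sums use the filled per-level values: 38 missed levels at
  # 60 s, ms level 1 uncompleted (60 s), st level 1 completed at 2.6 s
  expect_equal(d$sum_completion_time, 60 * 38 + 60 + 2.6)
  expect_true(fm$mask["c1", "ms_l3_accuracy_cbyi"])
  expect_false(fm$mask["c1", "ms_l1_accuracy_cbyi"])
})

test_that("imputation leaves a fully played child unchanged", {
  cfg <- sim_config(engagement = c(intercept = 50, slope = 0))
  set.seed(21)
  sessions <- generate_gameplay(3, config = cfg, child_id = "able")
  expect_equal(sum(sessions$attempted), 40) # a theta = 3 child plays it all
  before <- derive_features(extract_raw_features(sessions, child_ids = "able"))
  after <- impute_missing(before)
  expect_equal(as.numeric(before$data[1, -1]), as.numeric(after$data[1, -1]))
  expect_false(any(before$mask))
})
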