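test_that("background moments match hand arithmetic (n-1 SD)", {
  m <- tiny_manifest(1)
  pid <- "GENE1(ex1):PART1(ex2)"
  lanes <- list(make_lane(m, "A", fusion = stats::setNames(4, pid)),
                make_lane(m, "B", fusion = stats::setNames(8, pid)))
  est <- estimate_background(lanes, m)$fusion
  expect_equal(est$bg_mean, 6)
  expect_equal(est$bg_sd, sqrt(8))                     # 2.828...
  expect_equal(est$cut3, 6 + 3 * sqrt(8))              # 14.485...
  expect_equal(est$cut5, 6 + 5 * sqrt(8), tolerance = 1e-12)  # 20.142...
  expect_equal(est$n_negatives, 2)
})

test_that("zero-variance background collapses all cutoffs onto the mean", {
  m <- tiny_manifest(1)
  pid <- "GENE1(ex1):PART1(ex2)"
  lanes <- lapply(1:3, function(i)
    make_lane(m, paste0("S", i), fusion = stats::setNames(7, pid)))
  est <- estimate_background(lanes, m)$fusion
  expect_equal(c(est$bg_mean, est$cut3, est$cut5), c(7, 7, 7))
  expect_equal(est$bg_sd, 0)
})

test_that("a probe with under two usable values is flagged, never given a cutoff", {
  m <- tiny_manifest(2)
  pid <- "GENE2(ex1):PART2(ex2)"
  lanes <- list(make_lane(m, "A", fusion = stats::setNames(NA, pid)),
                make_lane(m, "B", fusion = stats::setNames(NA, pid)),
                make_lane(m, "C", fusion = stats::setNames(9, pid)))
  est <- estimate_background(lanes, m)$fusion
  row <- est[est$probe_id == pid, ]
  expect_true(row$uncalibrated)
  expect_true(is.na(row$cut5))
  expect_error(estimate_background(lanes[1], m), "at least 2",
               class = "calibration_error")
})

test_that("cutoffs are scaling-equivariant and permutation-invariant", {
  m <- tiny_manifest()
  fus <- probe_ids(m, "FUSION")
  set.seed(42)
  mk <- function(scale) lapply(1:6, function(i) {
    make_lane(m, paste0("S", i),
              fusion = stats::setNames(scale * (5 + ((i * 7 + seq_along(fus) * 3) %% 11)),
                                       fus))
  })
  base <- estimate_background(mk(1), m)$fusion
  tripled <- estimate_background(mk(3), m)$fusion
  for (col in c("bg_mean", "bg_sd", "cut3", "cut5")) {
    expect_equal(tripled[[col]], 3 * base[[col]], tolerance = 1e-12)
  }
  shuffled <- estimate_background(rev(mk(1)), m)$fusion
  expect_equal(shuffled, base)
  expect_true(all(base$cut5 >= base$cut3 & base$cut3 >= base$bg_mean))
})

test_that("background estimation recovers generator truth on synthetic negatives", {
  m <- read_manifest(table2_fixture_path("manifest"))
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    spec <- synthetic_spec(m, lanes = lane_plan(background = 48), seed = seed)
    run <- simulate_run(spec)
    est <- estimate_background(run$samples, m)$fusion
    truth <- run$calibration$fusion
    se <- truth$bg_sd / sqrt(48)
    ok <- abs(est$bg_mean - truth$bg_mean) <= 3 * se
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})

test_that("housekeeping thresholds sit at the requested lower quantile", {
  m <- tiny_manifest()
  lanes <- lapply(1:8, function(i) make_lane(m, paste0("S", i)))
  thr <- derive_housekeeping_thresholds(lanes, m)$housekeeping
  expect_equal(thr$hk_threshold,
               unname(c(30000, 10000, 800, 3000, 200)))  # constant cohort
  expect_error(derive_housekeeping_thresholds(lanes, m, quantile = 0.9),
               "quantile", class = "calibration_error")
  expect_error(derive_housekeeping_thresholds(lanes[1:3], m),
               "at least 5", class = "calibration_error")
})

test_that("derived housekeeping thresholds fall below the adequate-RNA means", {
  m <- read_manifest(table2_fixture_path("manifest"))
  spec <- synthetic_spec(m, lanes = lane_plan(background = 30), seed = 7)
  run <- simulate_run(spec)
  thr <- derive_housekeeping_thresholds(run$samples, m)$housekeeping
  expect_true(all(thr$hk_threshold < spec$hk_mean[thr$probe_id]))
})

test_that("recalibration tracks a lower-background local instrument", {
  m <- read_manifest(table2_fixture_path("manifest"))
  base_spec <- synthetic_spec(m, lanes = lane_plan(background = 48), seed = 11)
  base <- estimate_background(simulate_run(base_spec)$samples, m)
  base <- derive_housekeeping_thresholds(simulate_run(base_spec)$samples, m,
                                         calib = base)
  # local instrument with background scaled x0.5
  local_spec <- synthetic_spec(m, lanes = lane_plan(background = 48),
                               bg_mean = base_spec$bg_mean[[1]] * 0.5,
                               seed = 12)
  local <- recalibrate(base, simulate_run(local_spec)$samples, m)
  expect_true(all(local$fusion$cut5 < base$fusion$cut5))
  expect_equal(local$instrument_id, "SIM-001")
  expect_equal(local$housekeeping, base$housekeeping)
  # empty local set: base kept, with a notice
  expect_message(same <- recalibrate(base, list(), m), "keeping base")
  expect_equal(same, base)
})

test_that("locally uncalibratable probes inherit base cutoffs and are flagged", {
  m <- tiny_manifest(2)
  p1 <- "GENE1(ex1):PART1(ex2)"; p2 <- "GENE2(ex1):PART2(ex2)"
  base_lanes <- lapply(1:4, function(i)
    make_lane(m, paste0("B", i), fusion = stats::setNames(c(6 + i, 8 + i),
                                                          c(p1, p2))))
  base <- estimate_background(base_lanes, m)
  local_lanes <- lapply(1:4, function(i)
    make_lane(m, paste0("L", i), fusion = stats::setNames(c(3 + i, NA),
                                                          c(p1, p2))))
  local <- recalibrate(base, local_lanes, m)
  row2 <- local$fusion[local$fusion$probe_id == p2, ]
  expect_true(row2$inherited)
  expect_equal(row2$cut5, base$fusion$cut5[base$fusion$probe_id == p2])
  expect_false(local$fusion$inherited[local$fusion$probe_id == p1])
})
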