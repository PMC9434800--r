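make_qc_records <- function() {
  # control + three test conditions exercising each QC rule
  rbind(
    data.frame(gene = "rpoD", condition = "control", replicate = 1:3,
               cq = c(18.0, 18.1, 17.9), ntc_cq = NA_real_,
               mrt_cq = NA_real_),
    data.frame(gene = "rpoD", condition = "shifted", replicate = 1:3,
               cq = c(20.5, 20.6, 20.4), ntc_cq = NA_real_,
               mrt_cq = NA_real_),
    data.frame(gene = "rpoD", condition = "clean", replicate = 1:3,
               cq = c(18.2, 18.1, 18.0), ntc_cq = NA_real_,
               mrt_cq = NA_real_),
    data.frame(gene = "mntS", condition = "control", replicate = 1:3,
               cq = c(25, 25, 25), ntc_cq = 40, mrt_cq = NA_real_),
    data.frame(gene = "mntS", condition = "clean", replicate = 1:2,
               cq = c(18.0, 25.0), ntc_cq = c(40.0, NA),
               mrt_cq = c(NA, 30.4)),
    data.frame(gene = "mntS", condition = "orphan", replicate = 1,
               cq = 24, ntc_cq = NA_real_, mrt_cq = NA_real_)
  )
}

test_that("reference-gene shift beyond 2 cycles excludes the condition", {
  rec <- make_qc_records()
  out <- suppressWarnings(qc_filter(rec, control_condition = "control"))
  expect_false("shifted" %in% out$records$condition)
  shifted <- out$exclusions[out$exclusions$condition == "shifted", ]
  expect_identical(shifted$rule, "ref-shift")
  # a second reference gene that tracks the control rescues the condition
  rec2 <- rbind(rec,
    data.frame(gene = "gyrA", condition = c("control", "shifted"),
               replicate = 1, cq = c(19.0, 19.3), ntc_cq = NA_real_,
               mrt_cq = NA_real_))
  out2 <- suppressWarnings(
    qc_filter(rec2, control_condition = "control",
              second_reference = "gyrA"))
  expect_true("shifted" %in% out2$records$condition)
})

test_that("contamination controls fewer than 10 rounded cycles above the sample reject it", {
  out <- suppressWarnings(
    qc_filter(make_qc_records(), control_condition = "control"))
  clean <- out$records[out$records$condition == "clean" &
                         out$records$gene == "mntS", ]
  expect_equal(clean$replicate, 1)             # Cq 18 / NTC 40 retained
  mrt <- out$exclusions[out$exclusions$rule == "mrt", ]
  expect_identical(nrow(mrt), 1L)              # Cq 25 / -RT 30.4 -> 5 < 10
  expect_identical(mrt$condition, "clean")
})

test_that("conditions without reference-gene records are excluded as such", {
  out <- suppressWarnings(
    qc_filter(make_qc_records(), control_condition = "control"))
  expect_true("no-reference" %in%
                out$exclusions$rule[out$exclusions$condition == "orphan"])
  expect_false("orphan" %in% out$records$condition)
})

test_that("fold change reproduces the hand-computed 2^-ddCq fixture", {
  fc <- fold_change(hand_cq_table(), "mntS", "induced", "baseline")
  expect_equal(fc$fold_change, 2^3.1, tolerance = 1e-12)
  # per-replicate dCq 3.9, 4.1, 3.7 against baseline mean dCq 7.0
  expect_equal(sort(fc$replicates$fold_change),
               sort(2^-(c(3.9, 4.1, 3.7) - 7.0)), tolerance = 1e-12)
  # the baseline against itself is exactly 1
  expect_equal(fold_change(hand_cq_table(), "mntS", "baseline",
                           "baseline")$fold_change, 1)
  expect_error(fold_change(hand_cq_table(), "mntS", "absent", "baseline"),
               "no mntS records")
})

test_that("ddCq of -3 gives an eight-fold change", {
  tab <- data.frame(
    gene = rep(c("g", "rpoD"), each = 2),
    condition = rep(c("lo", "hi"), 2), replicate = 1,
    cq = c(25, 22, 18, 18), ntc_cq = NA_real_, mrt_cq = NA_real_)
  expect_equal(fold_change(tab, "g", "hi", "lo")$fold_change, 8)
})

test_that("fractional response anchors the dynamic range at 0.01 and 0.99", {
  expect_equal(fractional_response(1, 50, "co-repressor"), 0.99)
  expect_equal(fractional_response(50, 50, "co-repressor"), 0.01)
  expect_equal(fractional_response(1, 50, "activator"), 0.01)
  expect_equal(fractional_response(50, 50, "activator"), 0.99)
  expect_equal(fractional_response((50 + 1) / 2, 50, "de-repressor"), 0.5)
  expect_equal(fractional_response((50 + 1) / 2, 50, "activator"), 0.5)
})

test_that("repressor and activator calibrations are complementary", {
  set.seed(7)
  fc_max <- 37
  fc <- stats::runif(25, 1, fc_max)
  thd <- fractional_response(fc, fc_max, "co-repressor")
  thdm <- fractional_response(fc, fc_max, "activator")
  expect_equal(thd + thdm, rep(1, length(fc)))
  expect_true(all(thd >= 0.01 & thd <= 0.99))
})

test_that("out-of-range fold changes clamp with a warning; degenerate max errors", {
  expect_warning(th <- fractional_response(0.5, 50, "co-repressor"),
                 "clamped")
  expect_equal(th, 0.99)
  expect_warning(th2 <- fractional_response(80, 50, "activator"), "clamped")
  expect_equal(th2, 0.99)
  expect_error(fractional_response(2, 1, "activator"), "degenerate")
  expect_error(fractional_response(2, 0.5, "co-repressor"), "degenerate")
})

test_that("replicate aggregation averages on the concentration scale", {
  p <- demo_sensor("co-repressor", k_metal = 1e-12)
  truth <- 3e-12
  theta <- sensor_occupancy(p, truth)
  est <- calibrate_availability(rep(theta, 3), p, condition = "test")
  expect_equal(est$concentration, truth, tolerance = 1e-3)
  expect_equal(est$sd, 0)
  expect_equal(est$delta_g, delta_g(est$concentration))
  # mixed replicates: mean of per-replicate concentrations, not of theta
  th2 <- sensor_occupancy(p, c(2e-12, 4e-12))
  est2 <- calibrate_availability(th2, p)
  expect_equal(est2$concentration,
               mean(sapply(th2, invert_sensor_response, params = p)),
               tolerance = 1e-6)
})

test_that("boundary-condition estimates carry no standard deviation", {
  p <- demo_sensor("co-repressor", k_metal = 1e-12)
  est <- calibrate_availability(rep(0.99, 3), p)
  expect_true(is.na(est$sd))
  est2 <- calibrate_availability(rep(0.01, 3), p)
  expect_true(is.na(est2$sd))
})

test_that("unattainable replicates are dropped with a warning", {
  p <- demo_sensor("co-repressor", k_metal = 1e-12,
                   abundance_low = 100, abundance_high = 100)
  hi <- sensor_occupancy(p, 1e-1)  # supremum of the attainable range
  theta <- c(sensor_occupancy(p, 3e-12), (1 + hi) / 2)
  expect_warning(est <- calibrate_availability(theta, p), "attainable")
  expect_identical(est$n, 1L)
})

test_that("zinc midpoint is the geometric mean and reproduces printed rows", {
  mk <- function(conc, sensor = "Zur", cond = "anaerobic") {
    structure(list(metal = "Zn2+", sensor = sensor, condition = cond,
                   concentration = conc, sd = NA_real_,
                   delta_g = delta_g(conc), n = 3,
                   replicate_concentrations = numeric()),
              class = "availability_estimate")
  }
  mid <- zinc_midpoint(mk(6.7e-12), mk(2.9e-13, "ZntR"))
  expect_equal(mid$concentration, 1.39e-12, tolerance = 1e-2)
  expect_identical(mid$sensor, "Midpoint")
  expect_true(is.na(mid$sd))
  # degenerate midpoint
  expect_equal(zinc_midpoint(mk(5e-12), mk(5e-12, "ZntR"))$concentration,
               5e-12)
  # all three published sensor pairs, to one unit in the last printed digit
  expect_lt(abs(zinc_midpoint(mk(7.0e-12, cond = "aerobic"),
                              mk(4.0e-13, "ZntR", "aerobic"))$concentration -
                  2e-12), 1e-12)
  expect_lt(abs(mid$concentration - 1.4e-12), 0.1e-12)
  expect_lt(abs(zinc_midpoint(mk(3.2e-11, cond = "h2o2"),
                              mk(1.6e-13, "ZntR", "h2o2"))$concentration -
                  2.2e-12), 0.1e-12)
  expect_error(zinc_midpoint(mk(1e-12, cond = "aerobic"),
                             mk(1e-12, "ZntR", "h2o2")),
               "condition mismatch")
  co <- mk(1e-12); co$metal <- "Co2+"
  expect_error(zinc_midpoint(co, mk(1e-12, "ZntR")), "Zn2")
})
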