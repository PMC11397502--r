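# a trajectory that stops at the initial snapshot: L_max below the initial
# total length of 2.1 um
initial_only_frame <- function() {
  p <- model_params(L_max = 2.0)
  compute_observables(simulate_tissue(p, seed = 1))
}

test_that("observables of the initial state are exact", {
  ob <- initial_only_frame()
  expect_equal(nrow(ob$bins), 1L)
  expect_equal(ob$bins$boundary, 1 / 3)       # 0.7 / 2.1
  expect_equal(ob$bins$length_ratio, 1)
  expect_equal(ob$bins$ncell_ratio, 0.5)      # 7 / 14
  expect_equal(ob$resampled$boundary, rep(1 / 3, 10))
  # an even fate split gives boundary one half
  p <- model_params(L_max = 1.9)
  ob2 <- compute_observables(
    simulate_tissue(p, init = initial_state(20L, 0.1, 10L), seed = 1))
  expect_equal(ob2$bins$boundary, 0.5)
})

test_that("stored boundary always equals tl1 / (tl0 + tl1) bit-for-bit", {
  tr <- simulate_tissue(model_params(), seed = 5)
  ob <- compute_observables(tr)
  expect_identical(ob$bins$boundary, ob$bins$tl1 / (ob$bins$tl1 + ob$bins$tl0))
  expect_identical(tr$summary$boundary,
                   tr$summary$tl1 / (tr$summary$tl1 + tr$summary$tl0))
})

test_that("resampling picks the time window nearest each tenth of final length", {
  ob <- compute_observables(simulate_tissue(model_params(), seed = 3))
  expect_equal(nrow(ob$resampled), 10L)
  Lf <- ob$bins$total_length[nrow(ob$bins)]
  for (k in c(1L, 5L, 10L)) {
    d <- abs(ob$bins$total_length - k / 10 * Lf)
    expect_equal(ob$resampled$total_length[k],
                 ob$bins$total_length[which(d == min(d))[1L]])
  }
  # resampled values are monotone in total length
  expect_true(all(diff(ob$resampled$total_length) > 0))
})

test_that("ensemble averaging is idempotent and takes bin-wise means", {
  ob <- initial_only_frame()
  avg <- ensemble_average(list(ob, ob, ob))
  expect_equal(avg$bins, ob$bins)
  expect_equal(avg$n, 3)
  ob2 <- ob
  ob2$bins$boundary <- 0.4
  ob$bins$boundary <- 0.3
  expect_equal(ensemble_average(list(ob, ob2))$bins$boundary, 0.35)
  ob3 <- ob
  ob3$n_bins <- 50L
  expect_error(ensemble_average(list(ob, ob3)), "binning")
})

test_that("objective distance is zero on self and linear in uniform error", {
  ob <- compute_observables(simulate_tissue(model_params(), seed = 2))
  expect_equal(objective_distance(ob, ob)$total, 0)
  sim <- ob
  for (o in c("boundary", "length_ratio", "ncell_ratio")) {
    sim$resampled[[o]] <- 1.2 * sim$resampled[[o]]
  }
  d <- objective_distance(sim, ob)
  expect_equal(d$total, 0.2, tolerance = 1e-12)
  expect_equal(unname(d$per_observable), rep(0.2, 3), tolerance = 1e-12)
  bad <- ob
  bad$resampled$boundary[1L] <- 0
  expect_error(objective_distance(sim, bad), "reference")
})

test_that("a neutral-ratio ensemble maintains the one-third boundary", {
  ens <- simulate_ensemble(model_params(), n_reps = 12L, base_seed = 100)
  expect_lt(abs(mean(ens$finals$boundary) - 1 / 3), 0.05)
  # averaged boundary trace stays near one third throughout
  expect_true(all(abs(ens$frame$bins$boundary - 1 / 3) < 0.08))
})

test_that("ratio scans resolve maintenance at (1,1) and shift at high ratios", {
  sc <- scan_ratios(model_params(), c(1, 1.8), c(1, 1.8), n_reps = 5L,
                    base_seed = 7)
  expect_s3_class(sc, "scan_result")
  expect_equal(nrow(sc), 4L)
  dev11 <- sc$deviation[sc$rg_ratio == 1 & sc$rd_ratio == 1]
  expect_lt(abs(dev11), 0.05)
  expect_gt(max(sc$deviation), 0.2)
  kept <- maintenance_contour(sc, tol = 0.05)
  expect_true(any(kept$rg_ratio == 1 & kept$rd_ratio == 1))
  expect_equal(nrow(maintenance_contour(sc, tol = Inf)), 4L)
  expect_error(scan_ratios(model_params(), c(-1, 1), 1, n_reps = 2L),
               "positive")
})

test_that("swapping fate labels mirrors the boundary", {
  # with equal initial block sizes and a common division-decay scale, the
  # model with inverted ratios is the mirror image measured from the tip
  init <- initial_state(20L, 0.1, 10L)
  a <- 1.4; b <- 0.8
  pA <- model_params(r_g_ratio = a, r_d_ratio = b, L0_ratio = 1)
  pB <- model_params(r_g_distal = a * 0.91, r_g_ratio = 1 / a,
                     r_d_distal = b * 1.1, r_d_ratio = 1 / b, L0_ratio = 1)
  mA <- mean(simulate_ensemble(pA, init, n_reps = 8L, base_seed = 1,
                               frames = FALSE)$finals$boundary)
  mB <- mean(simulate_ensemble(pB, init, n_reps = 8L, base_seed = 201,
                               frames = FALSE)$finals$boundary)
  expect_lt(abs(mA - (1 - mB)), 0.04)
})

test_that("sensitivity is a non-negative relative-change ratio", {
  expect_error(sensitivity(model_params(), "l_max", 0, "boundary"),
               "non-zero")
  expect_error(sensitivity(model_params(), "not_a_param", 0.1, "boundary"),
               "unknown")
  s <- sensitivity(model_params(), "l_max", 0.1, "boundary", n_reps = 5L,
                   base_seed = 3)
  expect_gte(s, 0)
  expect_true(is.finite(s))
})
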