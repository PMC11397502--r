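test_that("growth increment follows the logistic rule and clips at l_max", {
  p <- model_params()
  # direct formula evaluation: r_g * l * (1 - l/l_max) * dt
  expect_equal(growth_increment(10, 0L, p, dt = 1), 0.91 * 10 * 0.5)
  # vanishes at the maximum length
  expect_equal(growth_increment(20, 0L, p, dt = 1), 0)
  expect_equal(growth_increment(20, 1L, p, dt = 1), 0)
  # small-size limit: per-length per-day increment tends to r_g(fate)
  eps <- 1e-8
  expect_equal(growth_increment(eps, 0L, p, dt = 0.01) / (eps * 0.01),
               0.91, tolerance = 1e-6)
  p2 <- model_params(r_g_ratio = 1.5)
  expect_equal(growth_increment(eps, 1L, p2, dt = 0.01) / (eps * 0.01),
               1.5 * 0.91, tolerance = 1e-6)
  # clipping: a step never overshoots l_max
  expect_lte(19.9 + growth_increment(19.9, 0L, p, dt = 1), 20)
  expect_error(growth_increment(0, 0L, p), "positive")
  expect_error(growth_increment(-1, 0L, p), "positive")
  expect_error(growth_increment(25, 0L, p), "l_max")
})

test_that("division propensity decays exponentially with tissue length", {
  p <- model_params()
  expect_equal(division_propensity(0L, 0, p), 1.1)
  expect_equal(division_propensity(0L, 30, p), 1.1 * exp(-1))
  expect_equal(division_propensity(0L, 300, p), 1.1 * exp(-10))
  # proximal fate uses the ratio-scaled rate and its own decay scale
  p2 <- model_params(r_d_ratio = 0.5)
  expect_equal(division_propensity(1L, 0, p2), 0.55)
  expect_equal(division_propensity(1L, 18, p2), 0.55 * exp(-1))
  # strictly decreasing in L, bounded by the basal rate
  L <- seq(0, 400, by = 20)
  d <- division_propensity(0L, L, p)
  expect_true(all(diff(d) < 0))
  expect_true(all(d <= 1.1))
  expect_error(division_propensity(0L, -1, p), "non-negative")
})

test_that("cell division conserves length, contiguity and assigns fresh ids", {
  tis <- new_tissue(initial_state(n_cells = 1L + 1L, cell_length = 0.2,
                                  n_proximal = 1L))
  # single proximal cell of 0.2 divides into two of 0.1
  tis2 <- divide_cell(tis, cid = 1L)
  expect_equal(length(tis2$cid), 3L)
  expect_equal(tis2$length[1:2], c(0.1, 0.1))
  expect_equal(sum(tis2$length), sum(tis$length))
  expect_equal(tis2$cid[2L], 3L)  # fresh id = previous count + 1
  expect_equal(tis2$fate[2L], tis2$fate[1L])  # daughters inherit fate

  # dividing the last proximal cell of the default tissue keeps blocks
  # contiguous and regional lengths unchanged
  tis <- new_tissue(initial_state())
  before_tl1 <- sum(tis$length[tis$fate == 1L])
  before_tl0 <- sum(tis$length[tis$fate == 0L])
  tis2 <- divide_cell(tis, cid = 7L)
  expect_equal(length(tis2$cid), 22L)
  expect_equal(sum(tis2$fate == 1L), 8L)
  expect_silent(bullseye:::validate_tissue(tis2))
  expect_equal(sum(tis2$length[tis2$fate == 1L]), before_tl1)
  expect_equal(sum(tis2$length[tis2$fate == 0L]), before_tl0)
  # neighbour pointers consistent with ordering
  expect_equal(tis2$neigh, c(tis2$cid[-1L], -1L))

  expect_error(divide_cell(tis, cid = 999L), "no cell")
})

test_that("simulation starts at 2.1 um, terminates past L_max, reproducibly", {
  p <- model_params()
  tr <- simulate_tissue(p, seed = 11)
  s <- tr$summary
  expect_equal(s$total_length[1L], 2.1)
  expect_equal(s$boundary[1L], 1 / 3)
  expect_gte(s$total_length[nrow(s)], 300)
  # total length strictly increases when growth is positive
  expect_true(all(diff(s$total_length) > 0))
  # determinism: same seed, identical trajectory
  tr2 <- simulate_tissue(p, seed = 11)
  expect_identical(tr$summary, tr2$summary)
  tr3 <- simulate_tissue(p, seed = 12)
  expect_false(identical(tr$summary, tr3$summary))
})

test_that("degenerate parameter choices are caught", {
  # no divisions: pure logistic growth still reaches a threshold below the
  # carrying capacity of the initial 21 cells
  p <- model_params(r_d_distal = 0, L_max = 100)
  tr <- simulate_tissue(p, seed = 1)
  expect_equal(tr$summary$n_cells[nrow(tr$summary)], 21)
  expect_true(all(tr$summary$total_length <= 21 * 20))
  # zero growth: total length can never reach L_max
  p0 <- model_params(r_g_distal = 0)
  expect_error(simulate_tissue(p0, seed = 1, max_steps = 500L), "no progress")
  # coarse-step warning when dt * max propensity is large
  ph <- model_params(r_d_distal = 20, dt = 0.05)
  tis <- new_tissue(initial_state())
  set.seed(1)
  expect_warning(step_tissue(tis, ph), "coarse")
  expect_error(model_params(dt = 0.2), "dt")
  expect_error(model_params(l_max = -1), "positive")
})

test_that("fate blocks stay contiguous and divisions conserve length stepwise", {
  p <- model_params(r_g_ratio = 1.6, r_d_ratio = 0.7)
  set.seed(42)
  tis <- new_tissue(initial_state())
  for (i in 1:150) {
    L_before <- sum(tis$length)
    len_before <- tis$length
    fate <- tis$fate
    grown <- pmin(len_before + bullseye:::fate_rg(p, fate) * len_before *
                    (1 - len_before / p$l_max) * p$dt, p$l_max)
    tis <- step_tissue(tis, p)
    expect_silent(bullseye:::validate_tissue(tis))
    # divisions redistribute but never create or destroy length
    expect_equal(sum(tis$length), sum(grown))
    expect_gte(sum(tis$length), L_before)
  }
})

test_that("division counts match the analytic branching law at frozen length", {
  # zero growth freezes total length, so every cell keeps a constant division
  # probability per step and the expected cell count follows 21 * (1 + p)^k
  p <- model_params(r_g_distal = 0, L0_ratio = 1, dt = 0.02)
  d <- division_propensity(0L, 2.1, p)
  p_div <- 1 - exp(-d * p$dt)
  k_steps <- 25L
  set.seed(7)
  counts <- replicate(150, {
    tis <- new_tissue(initial_state())
    for (i in seq_len(k_steps)) tis <- step_tissue(tis, p)
    length(tis$cid)
  })
  expected <- 21 * (1 + p_div)^k_steps
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 1e-9)
})

test_that("halving the time step barely moves the ensemble-mean boundary", {
  m1 <- mean(simulate_ensemble(model_params(dt = 0.01), n_reps = 12L,
                               base_seed = 500, frames = FALSE)$finals$boundary)
  m2 <- mean(simulate_ensemble(model_params(dt = 0.005), n_reps = 12L,
                               base_seed = 900, frames = FALSE)$finals$boundary)
  expect_lt(abs(m1 - m2), 0.01)
})
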