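test_that("central stripe keeps the requested lateral fraction", {
  rec <- data.frame(pos_lat = seq(0, 1, length.out = 1001), pos_pd = 0.5)
  expect_equal(nrow(central_stripe(rec, 1)), nrow(rec))
  kept <- central_stripe(rec, 0.2)
  expect_true(all(abs(kept$pos_lat - 0.5) <= 0.1))
  expect_equal(nrow(kept) / nrow(rec), 0.2, tolerance = 0.01)
  rec2 <- data.frame(pos_lat = rep(0.5, 10), pos_pd = 0.5)
  expect_equal(nrow(central_stripe(rec2, 0.01)), 10L)
  expect_warning(central_stripe(data.frame(pos_lat = 0.01, pos_pd = 0.5), 0.2),
                 "empty")
  expect_error(central_stripe(rec, 0), "width_fraction")
})

test_that("a flat area profile yields the centre of the axis", {
  b <- detect_boundary_area(flat_cell_records())
  expect_equal(b$boundary, 0.5)
  expect_equal(b$windows_used, 20L)
})

test_that("boundary detection recovers planted peaks to half a window", {
  set.seed(17)
  peaks <- stats::runif(25, 0.1, 0.5)
  errs <- vapply(seq_along(peaks), function(i) {
    est <- detect_boundary_area(gen_peak_table(peaks[i], seed = 1000L + i))
    abs(est$boundary - peaks[i])
  }, numeric(1))
  expect_lte(mean(errs), 0.025)
  expect_lt(max(errs), 0.075)  # never off by more than 1.5 windows
})

test_that("boundary detection is invariant to uniform area rescaling", {
  tab <- gen_peak_table(0.3, seed = 4)
  b1 <- detect_boundary_area(tab)
  tab$area <- tab$area * 7.3
  b2 <- detect_boundary_area(tab)
  expect_identical(b1$boundary, b2$boundary)
})

test_that("species presets produce their characteristic boundaries", {
  wt <- detect_boundary_area(central_stripe(
    gen_cell_table("trionum_wt", "S1", seed = 21)))
  expect_lt(abs(wt$boundary - 1 / 3), 0.025)
  rich <- detect_boundary_area(central_stripe(
    gen_cell_table("richardsonii", "S5", seed = 21)))
  expect_lt(abs(rich$boundary - 0.15), 0.025)
  expect_lt(rich$boundary, wt$boundary)
  # the overexpression plateau spans 0.2-0.5, centring the estimate there
  oe <- detect_boundary_area(central_stripe(
    gen_cell_table("tcp4_oe", "S2E", seed = 21)))
  expect_gt(oe$windows_used, 1L)
  expect_true(oe$boundary > 0.25 && oe$boundary < 0.45)
})

test_that("degraded profiles fall back or fail loudly", {
  rec <- flat_cell_records(50)
  expect_warning(detect_boundary_area(rec, window = 0.25), "unsmoothed")
  few <- data.frame(pos_pd = c(0.1, 0.11), area = c(1, 2))
  expect_error(detect_boundary_area(few), "3 windows")
  expect_error(detect_boundary_area(rec[0, ]), "no cells")
})

test_that("pigment boundary is the midpoint of the colour transition", {
  rec <- data.frame(pos_pd = c(0.1, 0.2, 0.32, 0.34, 0.5),
                    pigmented = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  b <- detect_boundary_pigment(rec)
  expect_equal(b$boundary, 0.33)
  expect_false(b$degenerate)
  # shuffled row order must not matter
  b2 <- detect_boundary_pigment(rec[c(4, 1, 5, 2, 3), ])
  expect_equal(b2$boundary, 0.33)
  all_pig <- data.frame(pos_pd = c(0.2, 0.4), pigmented = c(TRUE, TRUE))
  expect_equal(detect_boundary_pigment(all_pig)$boundary, 1)
  expect_true(detect_boundary_pigment(all_pig)$degenerate)
  bad <- data.frame(pos_pd = c(0.1, 0.3, 0.5),
                    pigmented = c(TRUE, FALSE, TRUE))
  expect_error(detect_boundary_pigment(bad), "basal block")
  # synthetic mature table: estimate close to the preset transition
  tab <- gen_cell_table("trionum_wt", "S4", seed = 6)
  est <- detect_boundary_pigment(tab)
  expect_lt(abs(est$boundary - 1 / 3), 0.02)
})

test_that("EdU densities integrate to one and reflect the sampling mode", {
  dist <- edu_pdf(gen_edu("distal_biased", n = 400L, seed = 12))
  g <- dist$x
  trap <- function(d) sum((d$density[-1] + d$density[-length(d$density)]) / 2) *
    (g[2] - g[1])
  expect_equal(trap(dist), 1, tolerance = 1e-6)
  upper <- function(d) {
    w <- d$x > 0.5
    mean(d$density[w]) / 2  # mass of the upper half (interval width 0.5)
  }
  expect_gt(upper(dist), 2 * (1 - upper(dist)))  # distal mass dominates
  expect_gt(stats::median(gen_edu("distal_biased", n = 2000L, seed = 3)$pos_pd),
            0.5)
  unif <- edu_pdf(gen_edu("uniform", n = 2000L, n_replicates = 2L, seed = 12))
  expect_equal(trap(unif), 1, tolerance = 1e-6)
  ratio <- upper(unif) / (1 - upper(unif))
  expect_lt(abs(ratio - 1), 0.15)
  expect_error(edu_pdf(data.frame(pos_pd = c(0.1, 0.2))), "at least 5")
})

test_that("region summaries split counts exactly and report the contrasts", {
  rec <- data.frame(pos_pd = c(seq(0.05, 0.45, 0.1), seq(0.55, 0.95, 0.1)),
                    area = rep(2, 10))
  rs <- region_summary(rec, 0.5)
  expect_equal(sum(rs$regions$n_cells), nrow(rec))
  expect_equal(rs$length_ratio, 1)
  expect_equal(rs$ncell_ratio, 1)
  # synthetic mature wild-type table: proximal cells about twice as large,
  # distal cells about five times more numerous
  tab <- gen_cell_table("trionum_wt", "S4", seed = 9)
  rs2 <- region_summary(tab, 1 / 3)
  expect_equal(sum(rs2$regions$n_cells), nrow(tab))
  expect_lt(abs(rs2$length_ratio - 2), 0.5)
  expect_lt(abs(rs2$ncell_ratio - 0.2), 0.07)
  expect_error(region_summary(rec, 0.99), "empty region")
  expect_error(region_summary(rec, 1.5), "inside")
})

test_that("bullseye proportion is a guarded percentage", {
  expect_equal(bullseye_proportion(100, 100), 100)
  expect_equal(bullseye_proportion(0, 50), 0)
  expect_equal(bullseye_proportion(14.5, 100), 14.5)
  expect_error(bullseye_proportion(2, 1), "pigmented")
  expect_error(bullseye_proportion(1, 0), "total area")
})

test_that("generated tables round-trip through the validating reader", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tab <- gen_cell_table("trionum_wt", "S2L", seed = 2)
  utils::write.csv(tab, tmp, row.names = FALSE)
  back <- read_cell_table(tmp, "cells")
  expect_equal(nrow(back), nrow(tab))
  expect_type(back$pigmented, "logical")
  edu <- gen_edu("uniform", n = 50L, seed = 2)
  utils::write.csv(edu, tmp, row.names = FALSE)
  expect_equal(nrow(read_cell_table(tmp, "edu")), nrow(edu))
  bad <- tab
  bad$pos_pd[3L] <- 1.5
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_cell_table(tmp, "cells"), "invalid rows")
  utils::write.csv(tab[, -which(names(tab) == "area")], tmp, row.names = FALSE)
  expect_error(read_cell_table(tmp, "cells"), "missing columns")
})
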