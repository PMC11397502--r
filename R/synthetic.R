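#' Species/genotype presets for synthetic petal tables
#'
#' Encodes, per developmental stage, the statistical structure of the
#' cell-area profile and EdU distribution for the three studied genotypes:
#' \describe{
#'   \item{trionum_wt}{flat area profile at S0a, then a single peak of large
#'     cells at one-third of the petal length (transiently 0.4 at S2L,
#'     back to one-third by S4-S5); EdU distally biased from S0a; mature
#'     region contrast of roughly 2x longer proximal cells and 5x more
#'     numerous distal cells; pigment transition at the boundary from S2L.}
#'   \item{richardsonii}{peak established closer to the base (0.2 at S0c,
#'     0.15 from S2E on), smaller peak amplitude (around 140 um^2 maximum
#'     at S2E versus 165 um^2 in the wild type); small mature bullseye.}
#'   \item{tcp4_oe}{wild-type-like through S1 (peak at one-third), then a
#'     plateau of large cells spanning 0.2-0.5 at S2E, boundary around 0.5
#'     at S2L settling to 0.4 at S4-S5; EdU uniform (not distally biased)
#'     at S0a; mature count ratio around 0.35.}
#' }
#' Peak positions and orderings follow the measured profiles; functional
#' forms (Gaussian bump, smoothed top-hat for the plateau) and amplitudes at
#' stages without measured values are package choices.
#'
#' @param name One of `"trionum_wt"`, `"richardsonii"`, `"tcp4_oe"`.
#' @return A `species_preset` list: per-stage `peak` (position or
#'   `c(lo, hi)` plateau), `amplitude`, `base` area (um^2), `edu_mode`,
#'   `pigment_boundary` (NA before pigmentation).
#' @export
species_preset <- function(name = c("trionum_wt", "richardsonii", "tcp4_oe")) {
  name <- match.arg(name)
  stages <- c("S0a", "S0b", "S0c", "S1", "S2E", "S2L", "S3", "S4", "S5")
  st <- function(...) stats::setNames(list(...), stages)
  preset <- switch(name,
    trionum_wt = list(
      peak = st(NA, 1 / 3, 1 / 3, 1 / 3, 1 / 3, 0.4, 1 / 3, 1 / 3, 1 / 3),
      amplitude = st(0, 30, 55, 70, 75, 60, 70, 80, 90),
      base = st(56, 57, 60, 60, 90, 120, 160, 200, 220),
      edu_mode = st("distal_biased", "distal_biased", "distal_biased",
                    "distal_biased", "uniform", "uniform", "uniform",
                    "uniform", "uniform"),
      pigment_boundary = st(NA, NA, NA, NA, NA, 0.4, 1 / 3, 1 / 3, 1 / 3),
      # mature region contrasts: proximal cells about twice the size,
      # distal cells about five times more numerous from S3 on
      prox_contrast = st(1, 1, 1, 1, 1, 1.6, 2, 2, 2),
      count_ratio = st(NA, NA, NA, NA, NA, 0.35, 0.2, 0.2, 0.2)
    ),
    richardsonii = list(
      peak = st(NA, 0.25, 0.2, 0.18, 0.15, 0.15, 0.15, 0.15, 0.15),
      amplitude = st(0, 25, 45, 55, 50, 45, 55, 60, 65),
      base = st(54, 55, 58, 58, 90, 115, 150, 185, 200),
      edu_mode = st("distal_biased", "distal_biased", "distal_biased",
                    "distal_biased", "uniform", "uniform", "uniform",
                    "uniform", "uniform"),
      pigment_boundary = st(NA, NA, NA, NA, NA, 0.15, 0.15, 0.15, 0.15),
      prox_contrast = st(1, 1, 1, 1, 1, 1.6, 2, 2, 2),
      count_ratio = st(NA, NA, NA, NA, NA, 0.15, 0.1, 0.1, 0.1)
    ),
    tcp4_oe = list(
      peak = st(NA, 1 / 3, 1 / 3, 1 / 3, c(0.2, 0.5), c(0.25, 0.55),
                c(0.2, 0.45), 0.4, 0.4),
      amplitude = st(0, 30, 55, 70, 75, 60, 70, 80, 90),
      base = st(56, 57, 60, 60, 90, 120, 160, 200, 220),
      edu_mode = st("uniform", "distal_biased", "distal_biased",
                    "distal_biased", "uniform", "uniform", "uniform",
                    "uniform", "uniform"),
      pigment_boundary = st(NA, NA, NA, NA, NA, 0.5, 0.45, 0.4, 0.4),
      prox_contrast = st(1, 1, 1, 1, 1, 1.6, 2, 2, 2),
      count_ratio = st(NA, NA, NA, NA, NA, 0.5, 0.4, 0.35, 0.35)
    )
  )
  preset$name <- name
  preset$stages <- stages
  class(preset) <- "species_preset"
  preset
}

# area profile value at positions x for one preset/stage (no noise)
preset_area_curve <- function(preset, stage, x) {
  peak <- preset$peak[[stage]]
  base <- preset$base[[stage]]
  amp <- preset$amplitude[[stage]]
  contrast <- preset$prox_contrast[[stage]]
  pb <- preset$pigment_boundary[[stage]]
  # mature stages: proximal cells are larger below the boundary; the
  # elevation is a smooth sigmoid centred on the boundary so the area
  # maximum stays a symmetric peak at the boundary itself
  late <- !is.na(pb) && contrast != 1
  lvl <- if (late) {
    base * (1 + (contrast - 1) * stats::plogis((pb - x) / 0.08))
  } else {
    rep(base, length(x))
  }
  if (length(peak) == 1L && is.na(peak)) return(lvl)
  bump <- if (length(peak) == 2L) {
    # smoothed top-hat between peak[1] and peak[2]
    w <- 0.04
    stats::plogis((x - peak[1L]) / w) * stats::plogis((peak[2L] - x) / w)
  } else {
    exp(-(x - peak)^2 / (2 * 0.07^2))
  }
  amp_eff <- if (late && length(peak) == 1L) 1.5 * contrast * base else amp
  lvl + amp_eff * bump
}

#' Generate a synthetic segmented-cell table
#'
#' Emulates the per-cell tables produced by petal segmentation: positions
#' quasi-uniform on the unit square, cell areas following the preset's
#' base-plus-bump profile along the base-to-tip axis times multiplicative
#' lognormal noise, aspect ratio and circularity with the proximal/distal
#' contrast of the measured data, and pigment flags basal of the preset
#' transition for S2L-S5. An optional lateral asymmetry term shifts the peak
#' across the width (the croissant-shaped early pattern); it is off by
#' default. Deterministic given `seed`.
#'
#' @param preset A [species_preset()] (or its name).
#' @param stage Stage label, `"S0a"` to `"S5"`.
#' @param n_cells Cells per replicate; default scales from hundreds at S0a
#'   to thousands at S2E and stays at the late-stage single-row scale after.
#' @param n_replicates Number of replicate petals (default 5).
#' @param sigma Lognormal noise sigma on areas (default 0.15).
#' @param croissant Lateral phase shift amplitude of the peak (0 disables).
#' @param seed Random seed.
#' @return A data.frame of cell records (`stage`, `replicate`, `pos_pd`,
#'   `pos_lat`, `area`, `aspect_ratio`, `circularity`, `pigmented`).
#' @export
gen_cell_table <- function(preset = species_preset("trionum_wt"),
                           stage = "S1", n_cells = NULL, n_replicates = 5L,
                           sigma = 0.15, croissant = 0, seed = 1L) {
  if (is.character(preset)) preset <- species_preset(preset)
  if (!stage %in% preset$stages) {
    stop("unknown stage '", stage, "' for preset ", preset$name, call. = FALSE)
  }
  if (n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (is.null(n_cells)) {
    n_cells <- switch(stage, S0a = 300L, S0b = 600L, S0c = 1200L, S1 = 2000L,
                      S2E = 3000L, S2L = 400L, S3 = 400L, S4 = 400L,
                      S5 = 400L)
  }
  set.seed(seed)
  cr <- preset$count_ratio[[stage]]
  pb_cr <- preset$pigment_boundary[[stage]]
  reps <- lapply(seq_len(n_replicates), function(r) {
    if (!is.na(cr)) {
      # mature stages: fewer, larger proximal cells — the proximal:distal
      # count ratio is planted by two-piece uniform position sampling
      prox <- stats::runif(n_cells) < cr / (1 + cr)
      pos_pd <- ifelse(prox, stats::runif(n_cells) * pb_cr,
                       pb_cr + stats::runif(n_cells) * (1 - pb_cr))
    } else {
      pos_pd <- stats::runif(n_cells)
    }
    pos_lat <- stats::runif(n_cells)
    peak_shift <- if (croissant > 0) croissant * (pos_lat - 0.5) else 0
    mu <- preset_area_curve(preset, stage, pos_pd - peak_shift)
    area <- mu * exp(stats::rnorm(n_cells, 0, sigma) - sigma^2 / 2)
    pb <- preset$pigment_boundary[[stage]]
    pigmented <- if (is.na(pb)) rep(NA, n_cells) else pos_pd <= pb
    # proximal cells elongate, distal cells stay rounder from S1 onward
    prox_like <- if (!is.na(pb)) pos_pd <= pb else pos_pd <= 1 / 3
    ar_mu <- ifelse(prox_like & stage %in% c("S1", "S2E", "S2L", "S3", "S4", "S5"),
                    2.2, 1.3)
    aspect_ratio <- 1 + (ar_mu - 1) * exp(stats::rnorm(n_cells, 0, 0.2))
    circularity <- pmin(1, pmax(0.05,
      ifelse(prox_like, 0.55, 0.75) + stats::rnorm(n_cells, 0, 0.08)))
    data.frame(stage = stage, replicate = r, pos_pd = pos_pd,
               pos_lat = pos_lat, area = area, aspect_ratio = aspect_ratio,
               circularity = circularity, pigmented = pigmented)
  })
  do.call(rbind, reps)
}

#' Generate a cell table with a planted area peak
#'
#' Minimal single-replicate generator used for boundary-detector recovery
#' studies: positions uniform on the unit square, areas following a Gaussian
#' bump of known centre over a flat base, times multiplicative lognormal
#' noise. The planted centre is the ground truth the detector should find.
#'
#' @param peak Planted peak position in (0, 1).
#' @param n_cells Number of cells.
#' @param base,amplitude Flat base area and bump amplitude (um^2).
#' @param width Gaussian bump standard deviation on the position axis.
#' @param sigma Lognormal noise sigma.
#' @param seed Random seed.
#' @return A data.frame of cell records (`stage` = "synthetic").
#' @export
gen_peak_table <- function(peak, n_cells = 1500L, base = 60, amplitude = 70,
                           width = 0.07, sigma = 0.15, seed = 1L) {
  if (peak <= 0 || peak >= 1) stop("peak must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  pos_pd <- stats::runif(n_cells)
  pos_lat <- stats::runif(n_cells)
  mu <- base + amplitude * exp(-(pos_pd - peak)^2 / (2 * width^2))
  area <- mu * exp(stats::rnorm(n_cells, 0, sigma) - sigma^2 / 2)
  data.frame(stage = "synthetic", replicate = 1L, pos_pd = pos_pd,
             pos_lat = pos_lat, area = area)
}

#' Generate synthetic EdU-labeled nucleus positions
#'
#' Distally biased mode draws base-to-tip positions from a tip-skewed
#' Beta(3, 1.2) law (median above 0.5, most mass in the upper half, as in
#' the wild-type early stages); uniform mode draws uniformly (as in the
#' overexpression line at S0a). Lateral positions are uniform.
#'
#' @param mode `"distal_biased"` or `"uniform"`, or a [species_preset()]
#'   plus `stage` to look the mode up.
#' @param n Nuclei per replicate.
#' @param n_replicates Number of replicate petals.
#' @param stage Stage label recorded in the output (and used for the preset
#'   lookup when `mode` is a preset).
#' @param seed Random seed.
#' @return A data.frame of EdU records (`stage`, `replicate`, `pos_pd`,
#'   `pos_lat`).
#' @export
gen_edu <- function(mode = "distal_biased", n = 200L, n_replicates = 5L,
                    stage = "S0a", seed = 1L) {
  if (inherits(mode, "species_preset")) mode <- mode$edu_mode[[stage]]
  mode <- match.arg(mode, c("distal_biased", "uniform"))
  if (n < 1L) stop("need at least one nucleus", call. = FALSE)
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    pos_pd <- if (mode == "distal_biased") {
      stats::rbeta(n, 3, 1.2)
    } else {
      stats::runif(n)
    }
    data.frame(stage = stage, replicate = r, pos_pd = pos_pd,
               pos_lat = stats::runif(n))
  })
  do.call(rbind, reps)
}

#' Forward-simulate a staged summary table with known ground truth
#'
#' Runs the tissue simulator at the given parameters and samples its
#' trajectory at the stage times rescaled to the simulation duration,
#' producing the per-stage, per-region summary table (cell counts, median
#' cell lengths, total length) that the rate-estimation pipeline consumes.
#' The generating parameters are attached as `attr(, "ground_truth")`, so
#' recovery studies can compare estimates against the truth.
#'
#' @param params A [model_params()] object.
#' @param timings A [stage_timing()] vector (hours).
#' @param init An [initial_state()] object.
#' @param seed Random seed for the simulation.
#' @return data.frame with `stage`, `time_hours` (nominal stage clock),
#'   `time_sim_days` (the simulation time actually sampled; rates intended
#'   to recover the generating parameters must be computed on this clock),
#'   `region`, `n_cells`, `median_cell_length`, `region_length`,
#'   `total_length`.
#' @export
gen_stage_series <- function(params, timings = stage_timing(),
                             init = initial_state(), seed = params$seed) {
  traj <- simulate_tissue(params, init, seed = seed)
  s <- traj$summary
  # map stage clock (hours) onto the simulation clock linearly
  frac <- (as.numeric(timings) - timings[1L]) /
    (timings[length(timings)] - timings[1L])
  t_sim <- frac * s$time[nrow(s)]
  pick <- vapply(t_sim, function(tt) which.min(abs(s$time - tt)), integer(1L))
  rows <- lapply(seq_along(timings), function(i) {
    r <- s[pick[i], ]
    data.frame(
      stage = names(timings)[i],
      time_hours = as.numeric(timings[i]),
      time_sim_days = r$time,
      region = c("proximal", "distal"),
      n_cells = c(r$nc1, r$nc0),
      median_cell_length = c(r$med_len1, r$med_len0),
      region_length = c(r$tl1, r$tl0),
      total_length = r$total_length
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- params
  out
}

#' Generate synthetic bee choice sequences
#'
#' Per bee, a sequence of Bernoulli correct/incorrect choices whose success
#' probability follows a logistic curve in the visit index, anchored at `p0`
#' on the first visit and `p_final` on the last — the shape a learning
#' forager produces under differential conditioning.
#'
#' @param p0,p_final Success probabilities at visit 1 and visit `n_visits`,
#'   both in (0, 1).
#' @param n_bees Number of bees.
#' @param n_visits Choices per bee (default 80).
#' @param seed Random seed.
#' @return A data.frame (`bee`, `visit`, `correct`).
#' @export
gen_choices <- function(p0 = 0.55, p_final = 0.82, n_bees = 20L,
                        n_visits = 80L, seed = 1L) {
  for (p in c(p0, p_final)) {
    if (p <= 0 || p >= 1) stop("probabilities must lie in (0, 1)", call. = FALSE)
  }
  if (n_bees < 1L || n_visits < 1L) stop("need at least one bee and visit",
                                         call. = FALSE)
  set.seed(seed)
  visit <- seq_len(n_visits)
  # logistic in visit index through the two anchor points
  if (n_visits == 1L) {
    pr <- rep(p0, 1L)
  } else {
    b <- (stats::qlogis(p_final) - stats::qlogis(p0)) / (n_visits - 1L)
    a <- stats::qlogis(p0) - b
    pr <- stats::plogis(a + b * visit)
  }
  do.call(rbind, lapply(seq_len(n_bees), function(bee) {
    data.frame(bee = bee, visit = visit,
               correct = stats::rbinom(n_visits, 1L, pr))
  }))
}
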