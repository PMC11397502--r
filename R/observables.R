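#' Time-binned observables of a simulated trajectory
#'
#' Reduces a trajectory to the three observables used throughout the model
#' analysis, each binned into `n_bins` equal windows of simulation time
#' (window means):
#' \describe{
#'   \item{boundary}{relative boundary position `tl1 / (tl0 + tl1)`, the
#'     proximal fraction of total tissue length;}
#'   \item{length_ratio}{mean proximal cell length over mean distal cell
#'     length, `(tl1 / nc1) / (tl0 / nc0)`;}
#'   \item{ncell_ratio}{proximal over distal cell count, `nc1 / nc0`.}
#' }
#' Because tissue length, not time, is the natural developmental coordinate,
#' each observable is additionally resampled at the time window whose mean
#' total length is nearest to `k/10` of the final length, `k = 1..10`
#' (earlier window wins ties).
#'
#' @param traj A `petal_trajectory` from [simulate_tissue()].
#' @param n_bins Number of equal time windows (default 100, i.e. 1% windows).
#' @return An object of class `observable_frame`: list with data.frames
#'   `bins` (columns `bin`, `time`, `boundary`, `length_ratio`,
#'   `ncell_ratio`, `total_length`, plus the raw `nc0`, `nc1`, `tl0`, `tl1`
#'   window means) and `resampled` (10 rows, column `frac_length`).
#' @export
compute_observables <- function(traj, n_bins = 100L) {
  s <- traj$summary
  if (nrow(s) == 0L) stop("empty trajectory", call. = FALSE)
  if (any(s$nc0 == 0) || any(s$nc1 == 0)) {
    stop("undefined ratio: a fate block is empty", call. = FALSE)
  }
  tmax <- s$time[nrow(s)]
  idx <- if (tmax == 0) rep(1L, nrow(s)) else {
    pmin(pmax(ceiling(s$time / tmax * n_bins), 1L), n_bins)
  }
  agg <- function(v) as.numeric(tapply(v, idx, mean))
  present <- sort(unique(idx))
  bins <- data.frame(
    bin = present,
    time = agg(s$time),
    nc0 = agg(s$nc0), nc1 = agg(s$nc1),
    tl0 = agg(s$tl0), tl1 = agg(s$tl1)
  )
  bins$total_length <- bins$tl0 + bins$tl1
  bins$boundary <- bins$tl1 / (bins$tl1 + bins$tl0)
  bins$length_ratio <- (bins$tl1 / bins$nc1) / (bins$tl0 / bins$nc0)
  bins$ncell_ratio <- bins$nc1 / bins$nc0
  Lf <- bins$total_length[nrow(bins)]
  targets <- seq_len(10L) / 10 * Lf
  # nearest window by total length; earlier window wins ties
  pick <- vapply(targets, function(tg) {
    d <- abs(bins$total_length - tg)
    which(d == min(d))[1L]
  }, integer(1L))
  res <- bins[pick, c("time", "boundary", "length_ratio", "ncell_ratio",
                      "total_length")]
  res$frac_length <- seq_len(10L) / 10
  rownames(res) <- NULL
  structure(list(bins = bins, resampled = res, n_bins = n_bins, n = 1L),
            class = "observable_frame")
}

#' Average observable frames across replicate simulations
#'
#' Bin-wise (and resample-point-wise) mean across replicates of the same
#' binning; records the replicate count in `$n`.
#'
#' @param frames List of `observable_frame` objects with identical binning.
#' @return An `observable_frame` of the means.
#' @export
ensemble_average <- function(frames) {
  stopifnot(length(frames) >= 1L)
  nb <- vapply(frames, function(f) f$n_bins, numeric(1))
  if (length(unique(nb)) != 1L) stop("mismatched binning", call. = FALSE)
  bsets <- lapply(frames, function(f) f$bins$bin)
  if (length(unique(vapply(bsets, paste, character(1), collapse = ","))) != 1L) {
    stop("mismatched bin sets across frames", call. = FALSE)
  }
  mean_df <- function(get) {
    dfs <- lapply(frames, get)
    out <- dfs[[1L]]
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- Reduce(`+`, lapply(dfs, function(d) d[num])) / length(dfs)
    out
  }
  structure(list(bins = mean_df(function(f) f$bins),
                 resampled = mean_df(function(f) f$resampled),
                 n_bins = frames[[1L]]$n_bins,
                 n = sum(vapply(frames, function(f) f$n, numeric(1)))),
            class = "observable_frame")
}

#' Ensemble of seeded simulations at one parameter point
#'
#' Runs `n_reps` replicates with seeds `base_seed + 0 .. n_reps - 1` and
#' returns the per-replicate final summaries together with the averaged
#' observable frame.
#'
#' @param params A [model_params()] object.
#' @param init An [initial_state()] object.
#' @param n_reps Number of replicates.
#' @param base_seed Seed of the first replicate (defaults to `params$seed`).
#' @param frames Keep and average full observable frames (set `FALSE` to
#'   record final values only, which is cheaper inside large scans).
#' @return List with `finals` (data.frame: seed, final boundary,
#'   length_ratio, ncell_ratio, total_length) and, if requested, `frame`
#'   (the `ensemble_average()` of the replicate frames).
#' @export
simulate_ensemble <- function(params, init = initial_state(), n_reps = 50L,
                              base_seed = params$seed, frames = TRUE) {
  stopifnot(n_reps >= 1L)
  seeds <- base_seed + seq_len(n_reps) - 1L
  fr <- vector("list", n_reps)
  finals <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    tr <- simulate_tissue(params, init, seed = seeds[i])
    s <- tr$summary[nrow(tr$summary), ]
    finals[[i]] <- data.frame(
      seed = seeds[i], boundary = s$boundary,
      length_ratio = (s$tl1 / s$nc1) / (s$tl0 / s$nc0),
      ncell_ratio = s$nc1 / s$nc0, total_length = s$total_length
    )
    if (frames) fr[[i]] <- compute_observables(tr)
  }
  out <- list(finals = do.call(rbind, finals))
  if (frames) {
    # frames can differ in which early bins are populated when durations
    # differ strongly; average only over frames with the modal bin set
    key <- vapply(fr, function(f) paste(f$bins$bin, collapse = ","), character(1))
    mode_key <- names(sort(table(key), decreasing = TRUE))[1L]
    out$frame <- ensemble_average(fr[key == mode_key])
  }
  out
}

#' Scan the expansion/division ratio grid
#'
#' For every combination of proximal:distal expansion-rate ratio and
#' division-rate ratio, runs a seeded ensemble and records the ensemble mean
#' of the deviation of the final boundary position from its initial value
#' (positive = boundary moves tipward) together with the final length and
#' cell-number ratios.
#'
#' @param base A [model_params()] object supplying all other parameters.
#' @param rg_ratios,rd_ratios Numeric vectors of strictly positive ratios.
#' @param n_reps Replicates per grid point.
#' @param init An [initial_state()] object.
#' @param base_seed Seed of the first replicate at every grid point.
#' @return A `scan_result`: data.frame with one row per grid point
#'   (`rg_ratio`, `rd_ratio`, `deviation`, `sd_final_boundary`,
#'   `length_ratio`, `ncell_ratio`, `n_reps`, `base_seed`); the initial
#'   boundary is stored in `attr(, "boundary0")`.
#' @examples
#' \donttest{
#' sc <- scan_ratios(model_params(), c(1, 2), c(1, 2), n_reps = 5)
#' sc[which.max(sc$deviation), ]
#' }
#' @export
scan_ratios <- function(base, rg_ratios, rd_ratios, n_reps = 50L,
                        init = initial_state(), base_seed = base$seed) {
  if (any(rg_ratios <= 0) || any(rd_ratios <= 0)) {
    stop("ratio grids must be strictly positive", call. = FALSE)
  }
  b0 <- initial_boundary(init)
  grid <- expand.grid(rg_ratio = rg_ratios, rd_ratio = rd_ratios,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- base
    p$r_g_ratio <- grid$rg_ratio[g]
    p$r_d_ratio <- grid$rd_ratio[g]
    p$r_g_proximal <- p$r_g_ratio * p$r_g_distal
    p$r_d_proximal <- p$r_d_ratio * p$r_d_distal
    ens <- tryCatch(
      simulate_ensemble(p, init, n_reps, base_seed, frames = FALSE),
      error = function(e) {
        stop("scan failed at (rg_ratio=", grid$rg_ratio[g], ", rd_ratio=",
             grid$rd_ratio[g], "): ", conditionMessage(e), call. = FALSE)
      }
    )
    f <- ens$finals
    rows[[g]] <- data.frame(
      rg_ratio = grid$rg_ratio[g], rd_ratio = grid$rd_ratio[g],
      deviation = mean(f$boundary) - b0,
      sd_final_boundary = stats::sd(f$boundary),
      length_ratio = mean(f$length_ratio),
      ncell_ratio = mean(f$ncell_ratio),
      n_reps = n_reps, base_seed = base_seed
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "boundary0") <- b0
  class(out) <- c("scan_result", "data.frame")
  out
}

initial_boundary <- function(init) init$n_proximal / init$n_cells

#' Boundary-maintenance region of a ratio scan
#'
#' Grid points whose absolute mean boundary deviation is at most `tol`. To
#' quantify the compensation between the two rates along this region, the
#' Spearman correlation between `log(rg_ratio)` and `log(rd_ratio)` over the
#' selected points is attached as `attr(, "spearman")` (NA when fewer than 3
#' points or a degenerate axis).
#'
#' @param scan A `scan_result` from [scan_ratios()].
#' @param tol Maintenance tolerance on |deviation| (default 0.05).
#' @return The selected rows (possibly zero) with the correlation attribute.
#' @export
maintenance_contour <- function(scan, tol = 0.05) {
  stopifnot(inherits(scan, "scan_result"))
  keep <- scan[abs(scan$deviation) <= tol, , drop = FALSE]
  rho <- NA_real_
  if (nrow(keep) >= 3L &&
      stats::sd(keep$rg_ratio) > 0 && stats::sd(keep$rd_ratio) > 0) {
    rho <- stats::cor(log(keep$rg_ratio), log(keep$rd_ratio),
                      method = "spearman")
  }
  attr(keep, "spearman") <- rho
  keep
}

#' Relative sensitivity of an observable to one parameter
#'
#' Ratio of the relative change of an ensemble-mean observable to the
#' relative change of a parameter: values below 1 mean the observable moved
#' proportionally less than the parameter.
#'
#' @param base A [model_params()] object.
#' @param param_name One of the numeric fields of [model_params()]
#'   (e.g. `"l_max"`).
#' @param delta_fraction Relative parameter change, e.g. `0.1` for +10%;
#'   must be non-zero.
#' @param observable_name One of `"boundary"`, `"length_ratio"`,
#'   `"ncell_ratio"` (final ensemble means).
#' @param n_reps,init,base_seed Ensemble settings as in [simulate_ensemble()].
#' @return The non-negative sensitivity ratio.
#' @export
sensitivity <- function(base, param_name, delta_fraction, observable_name,
                        n_reps = 20L, init = initial_state(),
                        base_seed = base$seed) {
  if (delta_fraction == 0) stop("delta_fraction must be non-zero", call. = FALSE)
  observable_name <- match.arg(observable_name,
                               c("boundary", "length_ratio", "ncell_ratio"))
  obs_at <- function(p) {
    mean(simulate_ensemble(p, init, n_reps, base_seed, frames = FALSE)$
           finals[[observable_name]])
  }
  args <- unclass(base)[names(formals(model_params))]
  if (!param_name %in% names(args)) {
    stop("unknown parameter: ", param_name, call. = FALSE)
  }
  o0 <- obs_at(base)
  if (o0 == 0) stop("undefined sensitivity: observable is zero at base",
                    call. = FALSE)
  args[[param_name]] <- args[[param_name]] * (1 + delta_fraction)
  o1 <- obs_at(do.call(model_params, args))
  (abs(o1 - o0) / abs(o0)) / abs(delta_fraction)
}

#' Mean percentage distance between simulated and reference observables
#'
#' Compares two observable frames at their 10 relative-length resampling
#' points: per observable the mean of `|sim - ref| / |ref|` over the 10
#' points, and the total distance is the unweighted average over the three
#' observables (boundary, length ratio, cell-number ratio).
#'
#' @param sim,ref `observable_frame` objects (ensemble averages or single
#'   runs) resampled at the same 10 relative-length points.
#' @return List with `total` (fraction) and `per_observable` (named vector).
#' @export
objective_distance <- function(sim, ref) {
  stopifnot(inherits(sim, "observable_frame"), inherits(ref, "observable_frame"))
  obs <- c("boundary", "length_ratio", "ncell_ratio")
  per <- vapply(obs, function(o) {
    s <- sim$resampled[[o]]
    r <- ref$resampled[[o]]
    if (any(r == 0)) stop("undefined percentage error: reference value is 0",
                          call. = FALSE)
    mean(abs(s - r) / abs(r))
  }, numeric(1))
  list(total = mean(per), per_observable = per)
}
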