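#' Construct a 1D tissue of cells
#'
#' The tissue is an ordered cell array from the petal base (position 1 of the
#' vectors) to the tip. Each cell carries an integer identifier, the
#' identifier of its right (tipward) neighbour (`-1L` sentinel for the
#' rightmost cell), a fate (0 = distal, 1 = proximal) and a length in um.
#' Proximal cells form one contiguous block at the base and distal cells one
#' contiguous block at the tip; because fates are inherited and daughters are
#' inserted next to their mothers, this contiguity is conserved by every
#' event.
#'
#' @param init An [initial_state()] object.
#' @return An object of class `tissue`: list with vectors `cid`, `neigh`,
#'   `fate`, `length` and scalar `time` (days).
#' @export
new_tissue <- function(init = initial_state()) {
  n <- init$n_cells
  cid <- seq_len(n)
  structure(list(
    cid = cid,
    neigh = c(cid[-1L], -1L),
    fate = c(rep(1L, init$n_proximal), rep(0L, n - init$n_proximal)),
    length = rep(init$cell_length, n),
    time = 0
  ), class = "tissue")
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("tissue: %d cells (%d proximal, %d distal), total length %.4g um, t = %.4g d\n",
              length(x$cid), sum(x$fate == 1L), sum(x$fate == 0L),
              sum(x$length), x$time))
  invisible(x)
}

#' Total tissue length
#'
#' @param tissue A `tissue` object.
#' @return Sum of cell lengths (um).
#' @export
tissue_length <- function(tissue) sum(tissue$length)

validate_tissue <- function(tissue) {
  stopifnot(inherits(tissue, "tissue"))
  if (any(tissue$length <= 0)) stop("all cell lengths must be positive", call. = FALSE)
  if (anyDuplicated(tissue$cid)) stop("cell ids must be unique", call. = FALSE)
  f <- tissue$fate
  # proximal block at base, distal block at tip
  if (is.unsorted(rev(f))) stop("fate blocks are not contiguous", call. = FALSE)
  invisible(tissue)
}

#' Deterministic per-step growth increment of a cell
#'
#' Cells expand logistically: the increment over a step of `dt` days is
#' `r_g(fate) * length * (1 - length / l_max) * dt`, so relative growth slows
#' as a cell approaches the maximum length `l_max` and vanishes there. The
#' engine clips lengths at `l_max` to guard the time discretisation.
#'
#' @param length Current cell length(s), um; must be positive and at most
#'   `l_max`.
#' @param fate Integer fate(s), 0 = distal, 1 = proximal.
#' @param params A [model_params()] object.
#' @param dt Step duration in days (defaults to `params$dt`).
#' @return Length increment(s) in um, non-negative; `length + increment`
#'   never exceeds `l_max`.
#' @examples
#' p <- model_params()
#' growth_increment(10, fate = 0L, p, dt = 1)  # 0.91 * 10 * 0.5 = 4.55
#' @export
growth_increment <- function(length, fate, params, dt = params$dt) {
  if (any(length <= 0)) stop("cell length must be positive", call. = FALSE)
  if (any(length > params$l_max)) {
    stop("cell length exceeds l_max", call. = FALSE)
  }
  inc <- fate_rg(params, fate) * length * (1 - length / params$l_max) * dt
  pmin(length + inc, params$l_max) - length
}

#' Division propensity of a cell
#'
#' A cell divides at rate `r_d(fate) * exp(-L / L0(fate))` where `L` is the
#' current total tissue length. The exponential factor shuts divisions down
#' as the tissue grows, creating the transition from a division-heavy to an
#' expansion-heavy phase; its fate-dependent length scale `L0(fate)` makes
#' the two domains exit the division phase at different tissue lengths.
#'
#' @param fate Integer fate(s), 0 = distal, 1 = proximal.
#' @param L Total tissue length (um), non-negative.
#' @param params A [model_params()] object.
#' @return Division rate(s) per day; bounded by `r_d(fate)` and strictly
#'   decreasing in `L`.
#' @examples
#' division_propensity(0L, L = 0, model_params())    # 1.1
#' division_propensity(0L, L = 30, model_params())   # 1.1 / e
#' @export
division_propensity <- function(fate, L, params) {
  if (any(L < 0)) stop("total length must be non-negative", call. = FALSE)
  fate_rd(params, fate) * exp(-L / fate_L0(params, fate))
}

#' Divide one cell of a tissue
#'
#' The mother's length is halved and a daughter of the same fate and the
#' other half-length is inserted immediately to her right; the daughter gets
#' the fresh id `n + 1` where `n` is the cell count before the division and
#' inherits the mother's right-neighbour pointer. Total tissue length and the
#' summed length of each fate block are exactly conserved.
#'
#' @param tissue A `tissue` object.
#' @param cid Identifier of the dividing cell.
#' @return The updated `tissue`.
#' @export
divide_cell <- function(tissue, cid) {
  i <- match(cid, tissue$cid)
  if (is.na(i)) stop("no cell with cid ", cid, call. = FALSE)
  n <- length(tissue$cid)
  half <- tissue$length[i] / 2
  new_cid <- n + 1L
  at <- function(v, val) append(v, val, after = i)
  tissue$length[i] <- half
  tissue$length <- at(tissue$length, half)
  tissue$fate <- at(tissue$fate, tissue$fate[i])
  tissue$cid <- at(tissue$cid, new_cid)
  tissue$neigh <- at(tissue$neigh, tissue$neigh[i])
  tissue$neigh[i] <- new_cid
  tissue
}

#' Advance the tissue by one engine step
#'
#' One fixed step of `dt` days: (1) every cell length is updated by its
#' deterministic [growth_increment()] computed from start-of-step lengths;
#' (2) each cell divides independently with probability
#' `1 - exp(-d(fate, L_start) * dt)`, where `L_start` is the start-of-step
#' total length, all divisions being applied at the end of the step in
#' base-to-tip order with sequential fresh ids; (3) time advances by `dt`.
#' The step is a deterministic function of the tissue and the R random number
#' stream, so a fixed seed reproduces a trajectory exactly.
#'
#' @param tissue A `tissue` object.
#' @param params A [model_params()] object.
#' @return The updated `tissue`.
#' @export
step_tissue <- function(tissue, params) {
  len0 <- tissue$length
  fate <- tissue$fate
  L <- sum(len0)
  # growth from start-of-step lengths, clipped at l_max
  rg <- ifelse(fate == 0L, params$r_g_distal, params$r_g_proximal)
  len <- pmin(len0 + rg * len0 * (1 - len0 / params$l_max) * params$dt,
              params$l_max)
  # per-cell division propensity from start-of-step total length
  prop <- ifelse(fate == 0L, params$r_d_distal, params$r_d_proximal) *
    exp(-L / ifelse(fate == 0L, params$L0_distal, params$L0_proximal))
  if (max(prop) * params$dt > 0.5) {
    warning("dt too coarse for current division propensities", call. = FALSE)
  }
  div <- stats::runif(length(len)) < -expm1(-prop * params$dt)
  if (any(div)) {
    n <- length(len)
    nd <- sum(div)
    reps <- 1L + div
    mother <- cumsum(reps) - reps + 1L  # positions of existing cells afterwards
    m <- n + nd
    new_len <- numeric(m)
    new_len[mother] <- ifelse(div, len / 2, len)
    new_fate <- integer(m)
    new_fate[mother] <- fate
    new_cid <- integer(m)
    new_cid[mother] <- tissue$cid
    dpos <- mother[div] + 1L
    new_len[dpos] <- len[div] / 2
    new_fate[dpos] <- fate[div]
    new_cid[dpos] <- n + seq_len(nd)  # fresh ids, base-to-tip
    tissue$length <- new_len
    tissue$fate <- new_fate
    tissue$cid <- new_cid
    tissue$neigh <- c(new_cid[-1L], -1L)
  } else {
    tissue$length <- len
  }
  tissue$time <- tissue$time + params$dt
  tissue
}

#' Simulate the tissue until the threshold total length is reached
#'
#' Starts from `init`, seeds the random number generator with `seed`, and
#' iterates [step_tissue()] until the total tissue length reaches
#' `params$L_max`. Per step the trajectory records time, cell counts and
#' summed lengths per fate (`nc0`, `nc1`, `tl0`, `tl1`), total length, the
#' relative boundary position `tl1 / (tl0 + tl1)` and the median cell length
#' per fate.
#'
#' @param params A [model_params()] object.
#' @param init An [initial_state()] object.
#' @param seed Random seed for this run (defaults to `params$seed`).
#' @param max_steps Abort with a no-progress error after this many steps;
#'   guards degenerate parameter choices (e.g. zero expansion rates) that can
#'   never reach the threshold length.
#' @param keep_final Keep the final `tissue` object in the result.
#' @return An object of class `petal_trajectory`: list with `summary` (one
#'   data.frame row per step, including the initial state), `params`, `init`,
#'   `seed` and optionally `final`.
#' @examples
#' traj <- simulate_tissue(model_params(), seed = 1)
#' tail(traj$summary$total_length, 1) >= 300
#' @export
simulate_tissue <- function(params, init = initial_state(),
                            seed = params$seed, max_steps = 50000L,
                            keep_final = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(init, "initial_state"))
  set.seed(seed)
  tis <- new_tissue(init)
  cap <- 2048L
  rec <- matrix(NA_real_, nrow = cap, ncol = 9L)
  colnames(rec) <- c("time", "n_cells", "nc0", "nc1", "tl0", "tl1",
                     "total_length", "med_len0", "med_len1")
  snap <- function(t) {
    p <- t$fate == 1L
    tl0 <- sum(t$length[!p]); tl1 <- sum(t$length[p])
    c(t$time, length(t$length), sum(!p), sum(p), tl0, tl1, tl0 + tl1,
      stats::median(t$length[!p]), stats::median(t$length[p]))
  }
  k <- 1L
  rec[k, ] <- snap(tis)
  L <- sum(tis$length)
  steps <- 0L
  while (L < params$L_max) {
    if (steps >= max_steps) {
      stop("no progress: tissue did not reach L_max within ", max_steps,
           " steps", call. = FALSE)
    }
    tis <- step_tissue(tis, params)
    steps <- steps + 1L
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      rec2 <- matrix(NA_real_, nrow = cap, ncol = 9L)
      colnames(rec2) <- colnames(rec)
      rec2[seq_len(k - 1L), ] <- rec[seq_len(k - 1L), ]
      rec <- rec2
    }
    rec[k, ] <- snap(tis)
    L <- rec[k, "total_length"]
  }
  s <- as.data.frame(rec[seq_len(k), , drop = FALSE])
  s$boundary <- s$tl1 / (s$tl0 + s$tl1)
  out <- list(summary = s, params = params, init = init, seed = seed)
  if (keep_final) out$final <- tis
  structure(out, class = "petal_trajectory")
}

#' @export
print.petal_trajectory <- function(x, ...) {
  s <- x$summary
  n <- nrow(s)
  cat(sprintf("petal trajectory: %d steps, %.3g -> %.4g um, boundary %.3f -> %.3f, %d cells final\n",
              n - 1L, s$total_length[1L], s$total_length[n],
              s$boundary[1L], s$boundary[n], as.integer(s$n_cells[n])))
  invisible(x)
}

#' Write a trajectory summary to CSV
#'
#' One row per engine step with the columns described in
#' [simulate_tissue()].
#'
#' @param traj A `petal_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$summary, path, row.names = FALSE)
  invisible(path)
}
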