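#' Model parameters for the two-fate petal growth simulator
#'
#' Bundles all rates and thresholds of the 1D cell-array model. Distal cells
#' (fate 0) carry the base rates; proximal cells (fate 1) are parameterised
#' relative to them through ratios, which is how the parameter scans explore
#' differential growth between the two bullseye domains.
#'
#' Defaults correspond to the wild-type calibration: base division rate
#' 1.1/day and base relative expansion rate 0.91/day for distal cells,
#' maximum cell length 20 um, termination threshold 300 um of total tissue
#' length, division-decay length scale `L0_distal = 0.1 * L_max`, and a
#' distal:proximal decay-scale ratio of 0.6 so the two fates exit the
#' division-heavy phase at different tissue lengths.
#'
#' @param r_g_distal Base relative expansion rate of distal cells (per day).
#' @param r_g_ratio Proximal:distal expansion-rate ratio; the proximal rate is
#'   `r_g_ratio * r_g_distal`.
#' @param r_d_distal Base division rate of distal cells (per day).
#' @param r_d_ratio Proximal:distal division-rate ratio.
#' @param l_max Maximum cell length (um); expansion is logistic towards it.
#' @param L_max Threshold total tissue length (um) at which a simulation stops.
#' @param L0_distal Length scale (um) of the exponential decay of the distal
#'   division rate with total tissue length. Default `0.1 * L_max`.
#' @param L0_ratio Proximal:distal ratio of the decay length scales
#'   (`L0_proximal = L0_ratio * L0_distal`); values below 1 make the proximal
#'   domain exit the division-heavy phase earlier (at smaller tissue
#'   lengths), as observed in the wild type where divisions persist longer
#'   in the distal region.
#' @param dt Engine time step (days); must lie in (0, 0.05].
#' @param seed Base random seed; replicate `i` of an ensemble uses `seed + i - 1`.
#' @return An object of class `model_params` (a validated list).
#' @seealso [initial_state()], [simulate_tissue()]
#' @examples
#' p <- model_params()
#' p$r_d_proximal  # equals r_d_distal at the neutral ratio
#' @export
model_params <- function(r_g_distal = 0.91, r_g_ratio = 1,
                         r_d_distal = 1.1, r_d_ratio = 1,
                         l_max = 20, L_max = 300,
                         L0_distal = 0.1 * L_max, L0_ratio = 0.6,
                         dt = 0.01, seed = 1L) {
  p <- list(
    r_g_distal = r_g_distal, r_g_ratio = r_g_ratio,
    r_d_distal = r_d_distal, r_d_ratio = r_d_ratio,
    l_max = l_max, L_max = L_max,
    L0_distal = L0_distal, L0_ratio = L0_ratio,
    dt = dt, seed = as.integer(seed)
  )
  num <- c("r_g_distal", "r_g_ratio", "r_d_distal", "r_d_ratio",
           "l_max", "L_max", "L0_distal", "L0_ratio", "dt")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
    }
  }
  # rates may be zero (degenerate pure-growth or frozen-length models);
  # geometric scales must stay strictly positive
  if (p$r_d_distal < 0 || p$r_d_ratio < 0 || p$r_g_distal < 0 ||
      p$r_g_ratio < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  pos <- c("l_max", "L_max", "L0_distal", "L0_ratio")
  for (nm in pos) {
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  if (p$dt <= 0 || p$dt > 0.05) {
    stop("dt must lie in (0, 0.05] days", call. = FALSE)
  }
  # derived per-fate values, fate 0 = distal, fate 1 = proximal
  p$r_g_proximal <- p$r_g_ratio * p$r_g_distal
  p$r_d_proximal <- p$r_d_ratio * p$r_d_distal
  p$L0_proximal <- p$L0_ratio * p$L0_distal
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-fate petal model parameters\n")
  cat(sprintf("  expansion: distal %.3g /day, proximal %.3g /day (ratio %.3g)\n",
              x$r_g_distal, x$r_g_proximal, x$r_g_ratio))
  cat(sprintf("  division:  distal %.3g /day, proximal %.3g /day (ratio %.3g)\n",
              x$r_d_distal, x$r_d_proximal, x$r_d_ratio))
  cat(sprintf("  l_max %.3g um, L_max %.3g um, L0 distal %.3g um / proximal %.3g um\n",
              x$l_max, x$L_max, x$L0_distal, x$L0_proximal))
  cat(sprintf("  dt %.3g days, seed %d\n", x$dt, x$seed))
  invisible(x)
}

#' Initial state of the simulated tissue
#'
#' The simulations start from a line of small identical cells whose fates are
#' already assigned: a proximal block at the base and a distal block towards
#' the tip. The defaults (21 cells of 0.1 um, first 7 proximal) put the fate
#' boundary at one-third of the initial tissue length, the wild-type
#' prepattern position, with an initial total length of 2.1 um.
#'
#' @param n_cells Total number of cells.
#' @param cell_length Initial length of every cell (um).
#' @param n_proximal Number of proximal cells at the base; must satisfy
#'   `0 < n_proximal < n_cells`.
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(n_cells = 21L, cell_length = 0.1, n_proximal = 7L) {
  n_cells <- as.integer(n_cells)
  n_proximal <- as.integer(n_proximal)
  if (n_cells < 2L) stop("need at least 2 cells", call. = FALSE)
  if (!is.numeric(cell_length) || cell_length <= 0) {
    stop("cell_length must be positive", call. = FALSE)
  }
  if (n_proximal <= 0L || n_proximal >= n_cells) {
    stop("n_proximal must satisfy 0 < n_proximal < n_cells", call. = FALSE)
  }
  structure(list(n_cells = n_cells, cell_length = cell_length,
                 n_proximal = n_proximal),
            class = "initial_state")
}

#' Read model parameters and initial state from a YAML or JSON config
#'
#' Keys mirror the arguments of [model_params()] and [initial_state()]; an
#' optional top-level `initial_state` block holds the latter. Unknown keys are
#' an error so typos do not silently fall back to defaults. A wild-type config
#' ships with the package under `extdata/wildtype.yaml`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with elements `params` (`model_params`) and `init`
#'   (`initial_state`).
#' @examples
#' cfg <- read_model_config(system.file("extdata", "wildtype.yaml",
#'                                      package = "bullseye"))
#' cfg$params$L_max
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)  # yaml parser also reads JSON
  init_raw <- raw$initial_state
  raw$initial_state <- NULL
  ok <- names(raw) %in% names(formals(model_params))
  if (any(!ok)) {
    stop("unknown config keys: ", paste(names(raw)[!ok], collapse = ", "),
         call. = FALSE)
  }
  init <- if (is.null(init_raw)) {
    initial_state()
  } else {
    ok <- names(init_raw) %in% names(formals(initial_state))
    if (any(!ok)) {
      stop("unknown initial_state keys: ",
           paste(names(init_raw)[!ok], collapse = ", "), call. = FALSE)
    }
    do.call(initial_state, init_raw)
  }
  list(params = do.call(model_params, raw), init = init)
}

# per-fate lookup helpers; fate is integer 0 (distal) or 1 (proximal)
fate_rg <- function(params, fate) {
  ifelse(fate == 0L, params$r_g_distal, params$r_g_proximal)
}
fate_rd <- function(params, fate) {
  ifelse(fate == 0L, params$r_d_distal, params$r_d_proximal)
}
fate_L0 <- function(params, fate) {
  ifelse(fate == 0L, params$L0_distal, params$L0_proximal)
}
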