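#' Read a segmented-cell or EdU-nucleus table
#'
#' Cell tables carry one row per segmented epidermal cell with columns
#' `stage`, `replicate`, `pos_pd` (normalized base-to-tip position, 0 =
#' base), `pos_lat` (normalized lateral position, 0/1 = margins), `area`
#' (um^2), `aspect_ratio`, `circularity` and optional logical `pigmented`.
#' EdU tables carry `stage`, `replicate`, `pos_pd`, `pos_lat`, one labeled
#' nucleus per row. Ranges are validated and offending rows reported.
#'
#' @param path CSV path.
#' @param type `"cells"` or `"edu"`.
#' @return A validated data.frame.
#' @export
read_cell_table <- function(path, type = c("cells", "edu")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (type == "cells") {
    c("stage", "replicate", "pos_pd", "pos_lat", "area")
  } else {
    c("stage", "replicate", "pos_pd", "pos_lat")
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$pos_pd < 0 | df$pos_pd > 1 | df$pos_lat < 0 | df$pos_lat > 1)
  if (type == "cells") bad <- union(bad, which(df$area <= 0))
  if (length(bad)) {
    stop("invalid rows (coordinate out of [0,1] or non-positive area): ",
         paste(utils::head(sort(bad), 10L), collapse = ", "),
         if (length(bad) > 10L) " ...", call. = FALSE)
  }
  if ("pigmented" %in% names(df)) df$pigmented <- as.logical(df$pigmented)
  df
}

#' Keep the central lateral stripe of a petal table
#'
#' Profiles along the base-to-tip axis are computed on a central stripe
#' (default 20% of the petal width) to avoid the margins.
#'
#' @param records data.frame with a `pos_lat` column.
#' @param width_fraction Stripe width as a fraction of petal width, in (0, 1].
#' @return The rows with `|pos_lat - 0.5| <= width_fraction / 2`.
#' @export
central_stripe <- function(records, width_fraction = 0.2) {
  if (width_fraction <= 0 || width_fraction > 1) {
    stop("width_fraction must lie in (0, 1]", call. = FALSE)
  }
  out <- records[abs(records$pos_lat - 0.5) <= width_fraction / 2, ,
                 drop = FALSE]
  if (nrow(out) == 0L) warning("central stripe selection is empty", call. = FALSE)
  out
}

#' Detect the pattern boundary from the cell-area profile
#'
#' Implements the window-averaged cell-area peak detector used for the early
#' (pre-pigmentation) stages: cells are binned by `pos_pd` into contiguous
#' windows (default 5%, half-open, last window closed) and averaged; empty
#' windows are filled by linear interpolation; the profile is smoothed with
#' a Savitzky-Golay filter; and the boundary is the mean centre position of
#' all windows whose smoothed value lies within `plateau_tol` (as a fraction
#' of the maximum) of the highest window. The plateau criterion makes the
#' estimate robust both for a single sharp peak and for the broad plateaus
#' seen in lines where large cells spread along the axis; it also makes the
#' result invariant to uniform rescaling of areas.
#'
#' @param records data.frame with `pos_pd` and `area` columns (typically
#'   after [central_stripe()]).
#' @param window Window width on the normalized axis (default 0.05).
#' @param plateau_tol Relative tolerance of the plateau criterion
#'   (default 0.025).
#' @param sg_length Savitzky-Golay filter length in windows (odd; default 7).
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @return List of class `boundary_estimate`: `boundary` (position in
#'   [0, 1]), `method = "area_peak"`, `windows_used` (plateau size),
#'   `profile` (data.frame of window centres, raw and smoothed means).
#' @export
detect_boundary_area <- function(records, window = 0.05, plateau_tol = 0.025,
                                 sg_length = 7L, sg_order = 2L) {
  if (nrow(records) == 0L) stop("no cells to analyse", call. = FALSE)
  nb <- round(1 / window)
  edges <- seq(0, 1, length.out = nb + 1L)
  idx <- pmin(pmax(findInterval(records$pos_pd, edges,
                                rightmost.closed = TRUE), 1L), nb)
  raw <- rep(NA_real_, nb)
  got <- tapply(records$area, idx, mean)
  raw[as.integer(names(got))] <- as.numeric(got)
  if (sum(!is.na(raw)) < 3L) {
    stop("need cells in at least 3 windows", call. = FALSE)
  }
  centers <- (edges[-1L] + edges[-(nb + 1L)]) / 2
  filled <- raw
  if (anyNA(filled)) {
    filled <- stats::approx(centers[!is.na(raw)], raw[!is.na(raw)],
                            xout = centers, rule = 2)$y
  }
  if (nb >= sg_length) {
    smoothed <- as.numeric(signal::sgolayfilt(filled, p = sg_order,
                                              n = sg_length))
  } else {
    warning("fewer windows than filter length; using unsmoothed profile",
            call. = FALSE)
    smoothed <- filled
  }
  sel <- which(smoothed >= (1 - plateau_tol) * max(smoothed))
  structure(list(boundary = mean(centers[sel]),
                 method = "area_peak",
                 windows_used = length(sel),
                 profile = data.frame(center = centers, raw = raw,
                                      filled = filled, smoothed = smoothed)),
            class = "boundary_estimate")
}

#' Detect the bullseye boundary from pigmentation flags
#'
#' For late stages the boundary is where pigmentation switches from the
#' pigmented proximal block to the unpigmented distal region: the midpoint
#' between the last pigmented and the first unpigmented cell position along
#' the base-to-tip axis.
#'
#' @param records data.frame with `pos_pd` and logical `pigmented`; rows are
#'   sorted by `pos_pd` internally. The pigmented cells must form one basal
#'   block.
#' @return A `boundary_estimate` with `method = "pigment_transition"`. If
#'   every cell is pigmented the boundary degenerates to 1 and is flagged
#'   via `degenerate = TRUE` (symmetrically 0 when none are).
#' @export
detect_boundary_pigment <- function(records) {
  if (!"pigmented" %in% names(records) || all(is.na(records$pigmented))) {
    stop("pigment flags are required", call. = FALSE)
  }
  ord <- order(records$pos_pd)
  pig <- as.logical(records$pigmented)[ord]
  pos <- records$pos_pd[ord]
  runs <- rle(pig)
  if (length(runs$values) > 2L || (length(runs$values) == 2L && !runs$values[1L])) {
    offending <- which(pig & cumsum(!pig) > 0)
    stop("pigmented cells do not form one basal block; offending rows ",
         "(sorted order): ", paste(utils::head(offending, 10L), collapse = ", "),
         call. = FALSE)
  }
  degenerate <- all(pig) || !any(pig)
  boundary <- if (all(pig)) {
    1
  } else if (!any(pig)) {
    0
  } else {
    k <- sum(pig)
    (pos[k] + pos[k + 1L]) / 2
  }
  structure(list(boundary = boundary, method = "pigment_transition",
                 windows_used = NA_integer_, degenerate = degenerate),
            class = "boundary_estimate")
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat(sprintf("boundary %.4f (%s)\n", x$boundary, x$method))
  invisible(x)
}

#' Density profile of EdU-labeled nuclei along the petal axis
#'
#' Gaussian kernel density of nucleus positions on [0, 1], reflected at both
#' boundaries so no mass leaks outside the petal, renormalized to integrate
#' to 1 on its grid. A binned histogram (counts per window) is returned for
#' count-based comparisons between genotypes.
#'
#' @param nuclei data.frame with a `pos_pd` column; at least 5 nuclei.
#' @param bandwidth Kernel bandwidth; default Silverman's rule-of-thumb.
#' @param n_grid Grid resolution.
#' @param n_bins Histogram bin count (default 10).
#' @return List of class `edu_profile`: `x`, `density`, `histogram`
#'   (data.frame of bin midpoints and counts), `bandwidth`, `n`.
#' @export
edu_pdf <- function(nuclei, bandwidth = NULL, n_grid = 512L, n_bins = 10L) {
  x <- nuclei$pos_pd
  n <- length(x)
  if (n < 5L) stop("need at least 5 nuclei", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  g <- seq(0, 1, length.out = n_grid)
  # reflection at 0 and 1: evaluate kernels of the data and its mirrors
  dens <- rowMeans(
    outer(g, x, function(t, xi) {
      stats::dnorm(t, xi, bandwidth) +
        stats::dnorm(t, -xi, bandwidth) +
        stats::dnorm(t, 2 - xi, bandwidth)
    })
  )
  # renormalize on the grid (trapezoid) to remove residual truncation error
  area <- sum((dens[-1L] + dens[-n_grid]) / 2) * (g[2L] - g[1L])
  dens <- dens / area
  edges <- seq(0, 1, length.out = n_bins + 1L)
  cnt <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                            1L), n_bins), nbins = n_bins)
  structure(list(x = g, density = dens,
                 histogram = data.frame(mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                                        count = cnt),
                 bandwidth = bandwidth, n = n),
            class = "edu_profile")
}

#' Per-region summary on either side of a boundary
#'
#' Splits cells at a boundary position into proximal (below) and distal
#' (above) regions and summarises each: cell count, median of the feature
#' (`area` by default, or a length column), plus the proximal/distal ratios
#' of medians and counts used to compare genotypes.
#'
#' @param records data.frame with `pos_pd` and the feature column.
#' @param boundary Boundary position in (0, 1).
#' @param feature Feature column name (default `"area"`).
#' @return List of class `region_summary`: `regions` (data.frame with
#'   `region`, `n_cells`, `median_feature`), `length_ratio`
#'   (proximal median / distal median), `ncell_ratio`
#'   (proximal count / distal count).
#' @export
region_summary <- function(records, boundary, feature = "area") {
  if (boundary <= 0 || boundary >= 1) {
    stop("boundary must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!feature %in% names(records)) {
    stop("no column '", feature, "' in records", call. = FALSE)
  }
  prox <- records$pos_pd <= boundary
  if (sum(prox) == 0L || sum(!prox) == 0L) {
    stop("empty region at boundary ", boundary, call. = FALSE)
  }
  v <- records[[feature]]
  med_p <- stats::median(v[prox])
  med_d <- stats::median(v[!prox])
  structure(list(
    regions = data.frame(region = c("proximal", "distal"),
                         n_cells = c(sum(prox), sum(!prox)),
                         median_feature = c(med_p, med_d)),
    length_ratio = med_p / med_d,
    ncell_ratio = sum(prox) / sum(!prox),
    feature = feature, boundary = boundary
  ), class = "region_summary")
}

#' Bullseye proportion of a petal
#'
#' Percentage of the total petal area occupied by the pigmented centre.
#'
#' @param pigmented_area Pigmented area (um^2 or any consistent unit).
#' @param total_area Total area, `>= pigmented_area`, positive.
#' @return Percentage in [0, 100].
#' @examples
#' bullseye_proportion(14.5, 100)  # 14.5
#' @export
bullseye_proportion <- function(pigmented_area, total_area) {
  if (total_area <= 0) stop("total area must be positive", call. = FALSE)
  if (pigmented_area < 0 || pigmented_area > total_area) {
    stop("pigmented area must lie in [0, total]", call. = FALSE)
  }
  100 * pigmented_area / total_area
}
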