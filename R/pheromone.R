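# The virtual-pheromone model and hourly map rendering.
#
# A pheromone source is a point with a non-negative intensity P. Its effect
# diffuses linearly in space: at distance x it is sensed with intensity
# P * (1 - x/sigma) for x <= sigma and 0 beyond; sigma is the diffusion
# range. Multiple sources superpose additively. With evaporation, a source
# created at time t_k additionally decays linearly with factor
# (1 - (t - t_k)/tau), clipped at 0; tau is the evaporation constant.

#' Parameters of the pheromone map
#'
#' @param grid_size side of the square grid in pixels (default 128)
#' @param sigma diffusion range in pixels; a source's influence falls
#'   linearly to zero at this distance
#' @param tau evaporation constant in minutes; a source's intensity decays
#'   linearly to zero after `tau` minutes (evaporation mode only)
#' @param place_positions named list place -> `c(row, col)` pixel
#'   coordinates (0-based, origin top-left, cell centers). Defaults to the
#'   quadrant centers of the grid for four places, so the four intensity
#'   lobes stay visually separable
#' @param intensity_cap positive cap `P_max` used when quantizing intensity
#'   to 8-bit grayscale; `NULL` means "derive from the data" (see
#'   [intensity_cap()])
#' @return a `pheromone_params` object
#' @export
pheromone_params <- function(grid_size = 128, sigma = 40, tau = 60,
                             place_positions = NULL, intensity_cap = NULL) {
  stopifnot(grid_size >= 2, sigma > 0, tau > 0)
  if (is.null(place_positions)) {
    q1 <- grid_size %/% 4
    q3 <- 3 * grid_size %/% 4
    place_positions <- list(P1 = c(q1, q1), P2 = c(q1, q3),
                            P3 = c(q3, q1), P4 = c(q3, q3))
  }
  for (pos in place_positions)
    stopifnot(length(pos) == 2, all(pos >= 0), all(pos <= grid_size - 1))
  if (!is.null(intensity_cap)) stopifnot(intensity_cap > 0)
  structure(list(grid_size = as.integer(grid_size), sigma = sigma, tau = tau,
                 place_positions = place_positions,
                 intensity_cap = intensity_cap),
            class = "pheromone_params")
}

#' @export
print.pheromone_params <- function(x, ...) {
  cat(sprintf("<pheromone_params> %dx%d grid, sigma = %g px, tau = %g min\n",
              x$grid_size, x$grid_size, x$sigma, x$tau))
  for (p in names(x$place_positions))
    cat(sprintf("  %s at (%g, %g)\n", p, x$place_positions[[p]][1],
                x$place_positions[[p]][2]))
  invisible(x)
}

#' Write pheromone parameters to YAML
#' @param params a `pheromone_params` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pheromone_params <- function(params, path) {
  yaml::write_yaml(list(grid_size = params$grid_size, sigma = params$sigma,
                        tau = params$tau,
                        place_positions = lapply(params$place_positions,
                                                 as.numeric),
                        intensity_cap = params$intensity_cap), path)
  invisible(path)
}

#' Read pheromone parameters from YAML
#' @param path YAML file written by [write_pheromone_params()]
#' @return a `pheromone_params` object
#' @export
read_pheromone_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  pheromone_params(grid_size = cfg$grid_size %||% 128,
                   sigma = cfg$sigma %||% 40, tau = cfg$tau %||% 60,
                   place_positions = cfg$place_positions,
                   intensity_cap = cfg$intensity_cap)
}

#' Intensity sensed at distance x from a single source
#'
#' Linear diffusion: `P * (1 - x/sigma)` for `x <= sigma`, 0 beyond;
#' continuous at `x = sigma`.
#'
#' @param P source intensity (non-negative)
#' @param x distance in pixels (non-negative, vectorized)
#' @param sigma diffusion range in pixels
#' @return sensed intensity, same length as `x`
#' @export
point_intensity <- function(P, x, sigma) {
  if (any(P < 0) || any(x < 0) || sigma <= 0)
    stop("point_intensity needs P >= 0, x >= 0, sigma > 0")
  ifelse(x <= sigma, P * (1 - x / sigma), 0)
}

#' Aggregated intensity from several sources at one point
#'
#' Superposition: the sum of each source's linearly diffused contribution.
#'
#' @param sources data.frame with columns `row`, `col`, `P` (and `t_k` in
#'   evaporation use); zero rows mean no pheromones
#' @param point numeric `c(row, col)` of the evaluation point
#' @param params a `pheromone_params`
#' @return the aggregated intensity (0 for an empty source list)
#' @export
aggregate_intensity <- function(sources, point, params) {
  if (NROW(sources) == 0) return(0)
  d <- sqrt((sources$row - point[1])^2 + (sources$col - point[2])^2)
  sum(point_intensity(sources$P, d, params$sigma))
}

#' Aggregated intensity with linear evaporation
#'
#' Each source created at time `t_k` contributes
#' `P * (1 - d/sigma) * (1 - (t - t_k)/tau)` with both factors clipped below
#' at zero: a source out of range or fully evaporated contributes nothing.
#'
#' @param sources data.frame with columns `row`, `col`, `P`, `t_k` (minutes)
#' @param point numeric `c(row, col)`
#' @param t evaluation time in minutes; must be `>= max(t_k)`
#' @param params a `pheromone_params`
#' @return the aggregated intensity
#' @export
aggregate_with_evaporation <- function(sources, point, t, params) {
  if (NROW(sources) == 0) return(0)
  if (t < max(sources$t_k)) stop("evaluation time precedes a source creation")
  d <- sqrt((sources$row - point[1])^2 + (sources$col - point[2])^2)
  space <- pmax(0, 1 - d / params$sigma)
  decay <- pmax(0, 1 - (t - sources$t_k) / params$tau)
  sum(sources$P * space * decay)
}

# One linear-diffusion kernel per place: a grid_size^2 x n_places matrix,
# column p holding max(0, 1 - d/sigma) for every pixel (column-major).
# Rendering an hour is then a single matrix-vector product, which is what
# makes scanning months of data cheap.
place_kernels <- function(params) {
  n <- params$grid_size
  px_row <- rep(0:(n - 1), times = n)   # column-major over (row, col)
  px_col <- rep(0:(n - 1), each = n)
  ker <- vapply(params$place_positions, function(pos) {
    d <- sqrt((px_row - pos[1])^2 + (px_col - pos[2])^2)
    pmax(0, 1 - d / params$sigma)
  }, numeric(n * n))
  colnames(ker) <- names(params$place_positions)
  ker
}

#' Render one hourly pheromone map
#'
#' In `"count"` mode (default) each place gets a single source whose
#' intensity equals that place's hourly event count, and the map is the
#' superposed linear-diffusion field. In `"evaporation"` mode each event is
#' a unit source created at its minute within the hour, and the field is
#' evaluated at the end of the hour with linear evaporation.
#'
#' @param counts_for_hour named numeric vector place -> count (non-negative;
#'   non-integer values are allowed, which is what hourly averaging over a
#'   reference window produces)
#' @param params a `pheromone_params`; its `intensity_cap` (or `cap`) fixes
#'   the white point of the grayscale image
#' @param mode `"count"` or `"evaporation"`
#' @param event_times in evaporation mode, named list place -> numeric
#'   minutes-within-hour of each event
#' @param cap overrides `params$intensity_cap` for quantization
#' @return a `pheromone_grid`: list with `intensity` (non-negative matrix)
#'   and `image` (integer matrix in 0..255)
#' @export
render_hourly_map <- function(counts_for_hour, params,
                              mode = c("count", "evaporation"),
                              event_times = NULL, cap = NULL) {
  mode <- match.arg(mode)
  known <- names(params$place_positions)
  if (!all(names(counts_for_hour) %in% known))
    stop("unknown place(s): ",
         paste(setdiff(names(counts_for_hour), known), collapse = ", "))
  if (any(counts_for_hour < 0)) stop("counts must be non-negative")
  n <- params$grid_size
  if (mode == "count") {
    ker <- place_kernels(params)
    p_vec <- stats::setNames(numeric(length(known)), known)
    p_vec[names(counts_for_hour)] <- counts_for_hour
    intensity <- matrix(ker %*% p_vec, nrow = n)
  } else {
    if (is.null(event_times)) stop("evaporation mode needs event_times")
    if (!all(names(event_times) %in% known))
      stop("unknown place(s) in event_times")
    src <- do.call(rbind, lapply(names(event_times), function(p) {
      tk <- event_times[[p]]
      if (length(tk) == 0) return(NULL)
      pos <- params$place_positions[[p]]
      data.frame(row = pos[1], col = pos[2], P = 1, t_k = tk)
    }))
    intensity <- matrix(0, n, n)
    if (NROW(src) > 0) {
      px_row <- rep(0:(n - 1), times = n)
      px_col <- rep(0:(n - 1), each = n)
      acc <- numeric(n * n)
      for (k in seq_len(nrow(src))) {
        d <- sqrt((px_row - src$row[k])^2 + (px_col - src$col[k])^2)
        decay <- max(0, 1 - (60 - src$t_k[k]) / params$tau)
        acc <- acc + src$P[k] * pmax(0, 1 - d / params$sigma) * decay
      }
      intensity <- matrix(acc, nrow = n)
    }
  }
  cap <- cap %||% params$intensity_cap %||% max(intensity, 1)
  new_pheromone_grid(intensity, cap)
}

new_pheromone_grid <- function(intensity, cap) {
  structure(list(intensity = intensity,
                 image = quantize_to_grayscale(intensity, cap),
                 cap = cap),
            class = "pheromone_grid")
}

#' @export
print.pheromone_grid <- function(x, ...) {
  cat(sprintf("<pheromone_grid> %dx%d, intensity max %.3g, cap %.3g\n",
              nrow(x$intensity), ncol(x$intensity), max(x$intensity), x$cap))
  invisible(x)
}

#' Quantize an intensity field to 8-bit grayscale
#'
#' `pixel = round(255 * min(intensity, P_max) / P_max)` with round-half-up,
#' so 0 maps to black, anything at or above the cap maps to white, and the
#' mapping is monotone non-decreasing.
#'
#' @param intensity non-negative numeric matrix
#' @param P_max positive white-point cap
#' @return integer matrix of the same shape with values in 0..255
#' @export
quantize_to_grayscale <- function(intensity, P_max) {
  if (is.null(P_max) || P_max <= 0) stop("P_max must be positive")
  if (any(intensity < 0)) stop("intensity must be non-negative")
  # floor(x + 0.5): round-half-up, unlike base round()'s round-half-even
  m <- floor(255 * pmin(intensity, P_max) / P_max + 0.5)
  storage.mode(m) <- "integer"
  m
}

#' Data-derived white point for grayscale quantization
#'
#' The 99th percentile of all per-place hourly counts over the processed
#' interval, so "white = maximum intensity" stays stable across days and a
#' single extreme hour does not dim everything else. Falls back to 1 when
#' the interval is empty of events.
#'
#' @param counts an `hourly_counts` object
#' @param prob quantile level (default 0.99)
#' @return a positive scalar cap
#' @export
intensity_cap <- function(counts, prob = 0.99) {
  cap <- as.numeric(stats::quantile(as.numeric(counts), prob, names = FALSE))
  if (!is.finite(cap) || cap <= 0) cap <- 1
  cap
}

#' Render the 24 hourly maps of every day
#'
#' @param counts an `hourly_counts` object
#' @param params a `pheromone_params`; if its `intensity_cap` is `NULL` the
#'   cap is derived from `counts` via [intensity_cap()]
#' @return a `day_maps` object: list (one element per day, named by date) of
#'   lists of 24 `pheromone_grid`s; the cap used is in attribute `cap`
#' @export
render_day_maps <- function(counts, params) {
  cap <- params$intensity_cap %||% intensity_cap(counts)
  ker <- place_kernels(params)
  places <- attr(counts, "places")
  stopifnot(all(places %in% colnames(ker)))
  dates <- attr(counts, "dates")
  n <- params$grid_size
  out <- lapply(seq_along(dates), function(i) {
    fields <- ker[, places, drop = FALSE] %*% counts[, , i]  # n^2 x 24
    lapply(seq_len(24), function(h)
      new_pheromone_grid(matrix(fields[, h], nrow = n), cap))
  })
  names(out) <- as.character(dates)
  structure(out, class = "day_maps", cap = cap, dates = dates)
}

#' Write hourly maps of one day as PNG files
#'
#' Files are named `YYYY-MM-DD_hHH.png`. Optionally also writes a 24-tile
#' montage (4 x 6 grid) `YYYY-MM-DD_montage.png`.
#'
#' @param day_images list of 24 `pheromone_grid`s
#' @param date the day's date (used in file names)
#' @param dir output directory (created if needed)
#' @param montage also write the 24-tile montage
#' @return character vector of written paths, invisibly
#' @export
write_day_maps_png <- function(day_images, date, dir, montage = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (h in seq_len(24)) {
    p <- file.path(dir, sprintf("%s_h%02d.png", as.character(date), h - 1))
    png::writePNG(day_images[[h]]$image / 255, p)
    paths <- c(paths, p)
  }
  if (montage) {
    n <- nrow(day_images[[1]]$image)
    tile <- matrix(0, 4 * n, 6 * n)
    for (h in seq_len(24)) {
      r <- (h - 1) %/% 6
      c_ <- (h - 1) %% 6
      tile[r * n + seq_len(n), c_ * n + seq_len(n)] <-
        day_images[[h]]$image / 255
    }
    p <- file.path(dir, sprintf("%s_montage.png", as.character(date)))
    png::writePNG(tile, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
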