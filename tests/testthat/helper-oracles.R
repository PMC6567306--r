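# Independent brute-force oracles: deliberately naive loop implementations
# sharing no code with the package, used to cross-check the vectorized
# implementations on small inputs.

oracle_filter_off <- function(df) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    is_motion_off <- df$sensor_type[i] == "motion" &&
      toupper(df$value[i]) %in% c("OFF", "0", "CLOSE", "FALSE", "ABSENT")
    keep[i] <- !is_motion_off
  }
  df[keep, , drop = FALSE]
}

oracle_debounce <- function(df, gap_s = 60) {
  keep <- logical(nrow(df))
  last_kept <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$sensor_id[i]
    t <- as.numeric(df$timestamp[i])
    if (is.null(last_kept[[id]]) || t - last_kept[[id]] >= gap_s) {
      keep[i] <- TRUE
      last_kept[[id]] <- t
    }
  }
  df[keep, , drop = FALSE]
}

oracle_mute <- function(df, mute_min = 10) {
  keep <- logical(nrow(df))
  last_kept <- list()
  for (i in seq_len(nrow(df))) {
    if (df$sensor_type[i] != "pressure") {
      keep[i] <- TRUE
      next
    }
    id <- df$sensor_id[i]
    t <- as.numeric(df$timestamp[i])
    if (is.null(last_kept[[id]]) || t - last_kept[[id]] >= mute_min * 60) {
      keep[i] <- TRUE
      last_kept[[id]] <- t
    }
  }
  df[keep, , drop = FALSE]
}

# Per-pixel, per-source evaluation of the diffusion field (and, when t is
# given, the linearly evaporated field) on an n x n grid.
oracle_field <- function(sources, n, sigma, tau = NULL, t = NULL) {
  out <- matrix(0, n, n)
  for (r in 0:(n - 1)) {
    for (c_ in 0:(n - 1)) {
      acc <- 0
      for (k in seq_len(NROW(sources))) {
        d <- sqrt((r - sources$row[k])^2 + (c_ - sources$col[k])^2)
        space <- if (d <= sigma) 1 - d / sigma else 0
        decay <- if (is.null(t)) 1 else
          max(0, 1 - (t - sources$t_k[k]) / tau)
        acc <- acc + sources$P[k] * space * decay
      }
      out[r + 1, c_ + 1] <- acc
    }
  }
  out
}

# Whole-image single-window SSIM written from the definition with explicit
# accumulation loops over pixels.
oracle_ssim <- function(x, y, k1 = 0.01, k2 = 0.03, L = 255) {
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  n <- length(x)
  sx <- 0; sy <- 0
  for (i in seq_len(n)) { sx <- sx + x[i]; sy <- sy + y[i] }
  mx <- sx / n; my <- sy / n
  vx <- 0; vy <- 0; cxy <- 0
  for (i in seq_len(n)) {
    vx <- vx + (x[i] - mx)^2
    vy <- vy + (y[i] - my)^2
    cxy <- cxy + (x[i] - mx) * (y[i] - my)
  }
  vx <- vx / n; vy <- vy / n; cxy <- cxy / n
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Exhaustive single change-point scan on a numeric vector: best split and
# whether it qualifies as a descending shift.
oracle_best_split <- function(x, min_segment = 5, min_reduction = 0.3) {
  n <- length(x)
  sse0 <- sum((x - mean(x))^2)
  best <- NA; best_sse <- Inf
  for (c_ in (min_segment + 1):(n - min_segment + 1)) {
    a <- x[1:(c_ - 1)]; b <- x[c_:n]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best_sse) { best_sse <- sse; best <- c_ }
  }
  reduction <- if (sse0 > 0) 1 - best_sse / sse0 else 0
  descending <- mean(x[best:n]) < mean(x[1:(best - 1)])
  list(split = best, reduction = reduction,
       qualifies = reduction > min_reduction && descending)
}
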