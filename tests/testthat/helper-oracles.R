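# Independent oracles used to freeze expected values. These deliberately use
# brute-force formulations, not the package's own code paths.

# Exhaustive per-pixel sort-and-pick-middle median filter with edge
# replication.
brute_median <- function(m, window) {
  r <- window %/% 2
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- pmin(pmax(i + (-r:r), 1), h)
      jj <- pmin(pmax(j + (-r:r), 1), w)
      v <- sort(as.vector(m[ii, jj]))
      out[i, j] <- v[(length(v) + 1) %/% 2]
    }
  }
  out
}

# Brute-force count of pixel centers inside an axis-aligned ellipse
# (semi-axes a, b, center cx, cy in continuous coordinates).
brute_inside_count <- function(w, h, cx, cy, a, b) {
  x <- (seq_len(w) - 0.5 - cx) / a
  y <- (seq_len(h) - 0.5 - cy) / b
  sum(outer(y^2, x^2, "+") <= 1)
}

# Analytic samples on a rotated ellipse.
ellipse_points <- function(n, cx, cy, a, b, theta, jitter_sd = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(t); y0 <- b * sin(t)
  x <- cx + cos(theta) * x0 - sin(theta) * y0
  y <- cy + sin(theta) * x0 + cos(theta) * y0
  if (jitter_sd > 0) {
    x <- x + rnorm(n, 0, jitter_sd)
    y <- y + rnorm(n, 0, jitter_sd)
  }
  cbind(x = x, y = y)
}

# Orthogonal distance from a point to an ellipse by dense parameter search
# plus local refinement.
point_ellipse_dist <- function(px, py, cx, cy, a, b, theta) {
  dx <- px - cx; dy <- py - cy
  x <- cos(theta) * dx + sin(theta) * dy
  y <- -sin(theta) * dx + cos(theta) * dy
  f <- function(t) (a * cos(t) - x)^2 + (b * sin(t) - y)^2
  tg <- seq(0, 2 * pi, length.out = 73)
  t0 <- tg[which.min(vapply(tg, f, 0))]
  sqrt(optimize(f, c(t0 - 0.2, t0 + 0.2), tol = 1e-12)$objective)
}

# Geometric (orthogonal-distance) least-squares ellipse fit, seeded at the
# true parameters; the brute-force reference for the algebraic fitter.
geometric_fit <- function(pts, start) {
  obj <- function(p) {
    if (p[3] <= 0 || p[4] <= 0) return(1e12)
    sum(vapply(seq_len(nrow(pts)), function(i) {
      point_ellipse_dist(pts[i, 1], pts[i, 2], p[1], p[2], p[3], p[4], p[5])^2
    }, 0))
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  fit$par
}

# A quiet trace for blink-removal tests: diameter series -> pupil_trace.
trace_from_diameters <- function(d, rate = 25, valid = rep(TRUE, length(d)),
                                 eye = "left") {
  n <- length(d)
  new_pupil_trace(
    tibble::tibble(
      frame_index = seq_len(n) - 1L,
      timestamp_s = (seq_len(n) - 1) / rate,
      eye = eye,
      center_x = 128, center_y = 128,
      major_px = ifelse(valid, d, NA_real_),
      minor_px = ifelse(valid, d * 0.98, NA_real_),
      orientation_rad = 0,
      valid = valid,
      fail_reason = ifelse(valid, NA_character_, "no pupil found")
    ),
    sampling_rate_hz = rate
  )
}
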