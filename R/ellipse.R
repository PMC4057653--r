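#' Pupil ellipse parameters
#'
#' The per-frame measurement result: center, orientation and full axis
#' lengths of the equivalent ellipse, plus a validity flag. Invalid results
#' (blink, occlusion, degenerate fit) carry `NA` axes and a failure reason,
#' never silent zeros.
#'
#' @param center_x,center_y Continuous pixel coordinates of the center.
#' @param major_px,minor_px Full axis lengths in pixels (`major >= minor`).
#' @param orientation_rad Major-axis angle versus the image x-axis,
#'   normalized to `(-pi/2, pi/2]`.
#' @param valid Logical validity flag.
#' @param fail_reason Reason string when invalid.
#' @return An object of class `pupil_ellipse`.
#' @export
pupil_ellipse <- function(center_x, center_y, major_px, minor_px,
                          orientation_rad, valid = TRUE,
                          fail_reason = NA_character_) {
  if (isTRUE(valid) && (is.na(major_px) || is.na(minor_px) || major_px < minor_px)) {
    abort("a valid ellipse requires major_px >= minor_px")
  }
  structure(
    list(center_x = center_x, center_y = center_y, major_px = major_px,
         minor_px = minor_px, orientation_rad = orientation_rad,
         valid = isTRUE(valid), fail_reason = fail_reason),
    class = "pupil_ellipse"
  )
}

invalid_pupil_ellipse <- function(reason) {
  pupil_ellipse(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                valid = FALSE, fail_reason = reason)
}

#' @export
print.pupil_ellipse <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "<pupil_ellipse> center (%.2f, %.2f), axes %.2f x %.2f px, theta %.3f rad\n",
      x$center_x, x$center_y, x$major_px, x$minor_px, x$orientation_rad))
  } else {
    cat(sprintf("<pupil_ellipse> invalid: %s\n", x$fail_reason))
  }
  invisible(x)
}

#' @rdname pupil_ellipse
#' @param x A `pupil_ellipse`.
#' @param ... Unused.
#' @export
tidy.pupil_ellipse <- function(x, ...) {
  tibble(center_x = x$center_x, center_y = x$center_y,
         major_px = x$major_px, minor_px = x$minor_px,
         orientation_rad = x$orientation_rad, valid = x$valid,
         fail_reason = x$fail_reason)
}

#' Fit the best ellipse to boundary points by least squares
#'
#' Direct algebraic least-squares conic fit with the ellipse-specific
#' constraint (the numerically stable Halir-Flusser formulation of the
#' Fitzgibbon method), followed by conversion of the conic coefficients to
#' geometric parameters. The fit is deterministic and needs no
#' initialization; axes are reported as full lengths (twice the semi-axes).
#'
#' @param points A two-column matrix or data frame of `(x, y)` boundary
#'   coordinates (at least 5 non-collinear points).
#' @return A [pupil_ellipse()]; invalid (with a reason) on degenerate input.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 60)
#' fit_ellipse(cbind(50 + 20 * cos(t), 40 + 10 * sin(t)))
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 5) {
    return(invalid_pupil_ellipse("too few boundary points (< 5)"))
  }
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  sx <- x - mx; sy <- y - my

  fit <- tryCatch({
    D1 <- cbind(sx^2, sx * sy, sy^2)
    D2 <- cbind(sx, sy, 1)
    S1 <- crossprod(D1)
    S2 <- crossprod(D1, D2)
    S3 <- crossprod(D2)
    Tm <- -solve(S3, t(S2))
    M <- S1 + S2 %*% Tm
    # premultiply by inv(C) of the constraint 4AC - B^2 = 1
    M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
    e <- eigen(M)
    vec <- Re(e$vectors)
    cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
    k <- which(cond > 1e-12)
    if (length(k) == 0) stop("no ellipse solution")
    a1 <- vec[, k[1]]
    c(a1, as.vector(Tm %*% a1))
  }, error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) {
    return(invalid_pupil_ellipse("degenerate point configuration"))
  }
  geom <- conic_to_geometric(fit)
  if (is.null(geom)) {
    return(invalid_pupil_ellipse("conic is not a real ellipse"))
  }
  pupil_ellipse(center_x = geom$cx + mx, center_y = geom$cy + my,
                major_px = 2 * geom$a, minor_px = 2 * geom$b,
                orientation_rad = geom$theta)
}

# Conic coefficients (A, B, C, D, E, F) -> center, semi-axes, major-axis
# angle in (-pi/2, pi/2]. Returns NULL for non-ellipse conics.
conic_to_geometric <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F <- p[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # sign-normalize so the quadratic-form matrix is positive definite
  if (A + C < 0) { A <- -A; B <- -B; C <- -C; D <- -D; E <- -E; F <- -F }
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  if (!is.finite(Fc) || Fc >= 0) return(NULL)
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  e <- eigen(M2, symmetric = TRUE)
  lam <- e$values  # decreasing; both > 0 for an ellipse
  if (any(lam <= 0)) return(NULL)
  a <- sqrt(-Fc / lam[2])  # smaller eigenvalue -> major axis
  b <- sqrt(-Fc / lam[1])
  v <- e$vectors[, 2]      # major-axis direction
  theta <- atan2(v[2], v[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(cx = cx, cy = cy, a = a, b = b, theta = theta)
}
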