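#' Retinal size of the gap
#'
#' Angular extent `gamma` subtended at the insect position `B` by the two
#' gap boundaries `A` and `C`, in the horizontal plane:
#' `alpha = atan2(Cy - By, Cx - Bx)`, `beta = atan2(Ay - By, Ax - Bx)`,
#' `gamma = |wrap(alpha - beta)|`. `atan2` keeps all quadrants valid and the
#' absolute wrapped difference makes the result independent of which
#' boundary is labelled A or C.
#'
#' @param A,C gap boundary positions `c(x, y)` in metres.
#' @param B insect position `c(x, y)` in metres.
#' @return `gamma` in radians, in \[0, pi\].
#' @examples
#' retinal_size(A = c(2, 1), C = c(2, -1), B = c(0, 0))  # 2*atan(0.5)
#' @export
retinal_size <- function(A, C, B) {
  if (all(A[1:2] == B[1:2]) || all(C[1:2] == B[1:2])) {
    stop("insect position coincides with a gap boundary", call. = FALSE)
  }
  alpha <- atan2(C[2L] - B[2L], C[1L] - B[1L])
  beta <- atan2(A[2L] - B[2L], A[1L] - B[1L])
  abs(wrap_rad(alpha - beta))
}

#' Rate of change of retinal size
#'
#' Numerical time derivative of a gamma series: central differences in the
#' interior, one-sided differences at the ends (exact for a linear series).
#'
#' @param time sample times in seconds (uniformly spaced, >= 3 samples).
#' @param gamma retinal size samples in radians.
#' @return `gamma_dot` in rad/s, same length as `gamma`.
#' @export
retinal_size_rate <- function(time, gamma) {
  n <- length(gamma)
  if (n < 3L || length(time) != n) {
    stop("need at least 3 uniformly spaced samples", call. = FALSE)
  }
  dt <- diff(time)
  if (max(abs(dt - dt[1L])) > 1e-9 * abs(dt[1L])) {
    stop("samples must be uniformly spaced", call. = FALSE)
  }
  h <- dt[1L]
  gd <- numeric(n)
  gd[1L] <- (gamma[2L] - gamma[1L]) / h
  gd[n] <- (gamma[n] - gamma[n - 1L]) / h
  if (n > 2L) gd[2:(n - 1L)] <- (gamma[3:n] - gamma[1:(n - 2L)]) / (2 * h)
  gd
}

#' Relative retinal expansion velocity
#'
#' `RREV = gamma_dot / gamma`. In the small-angle head-on limit this equals
#' the inverse time-to-contact `v / D`. Values where `gamma` falls below
#' `gamma_eps` are returned as `NA` with `defined = FALSE` rather than
#' clipped, since near-zero crossings of RREV are themselves behaviourally
#' meaningful.
#'
#' @param gamma retinal size(s) in radians (>= 0).
#' @param gamma_dot rate(s) in rad/s.
#' @param gamma_eps smallest gamma for which the ratio is considered defined.
#' @return data.frame with `rrev` (1/s) and `defined`.
#' @export
rrev <- function(gamma, gamma_dot, gamma_eps = 1e-4) {
  if (any(gamma < 0)) stop("'gamma' must be non-negative", call. = FALSE)
  defined <- gamma >= gamma_eps
  data.frame(rrev = ifelse(defined, gamma_dot / gamma, NA_real_),
             defined = defined)
}

#' Visual parameter series along a world track
#'
#' Computes, for every valid sample of a [map_track()] result, the retinal
#' size of the barrier gap, its rate of change and the relative retinal
#' expansion velocity, using the gap edge positions from the barrier
#' kinematics at each frame time. Samples at or beyond the barrier plane are
#' flagged undefined (the gap no longer subtends a forward angle).
#'
#' @param world a `world_track`.
#' @param scene a [tunnel_scene()].
#' @param kin a [barrier_kinematics()].
#' @param gamma_eps guard for the RREV ratio (radians).
#' @return a `visual_param_series`: data.frame with `time_s`, `gamma_rad`,
#'   `gamma_dot`, `rrev`, `defined`.
#' @export
visual_param_series <- function(world, scene, kin, gamma_eps = 1e-4) {
  stopifnot(inherits(scene, "tunnel_scene"), inherits(kin, "barrier_kinematics"))
  v <- which(world$valid & world$x_m < scene$barrier_x)
  if (length(v) < 3L) stop("need at least 3 valid samples before the barrier",
                           call. = FALSE)
  tt <- world$time_s[v]
  if (max(abs(diff(tt) - diff(tt)[1])) > 1e-9) {
    # invalid frames leave non-uniform gaps; interpolate the positions back
    # onto the uniform frame grid before differentiating
    tt_u <- world$time_s[min(v):max(v)]
    xs <- stats::approx(tt, world$x_m[v], xout = tt_u)$y
    ys <- stats::approx(tt, world$y_m[v], xout = tt_u)$y
    tt <- tt_u
  } else {
    xs <- world$x_m[v]; ys <- world$y_m[v]
  }
  ge <- gap_edges_at_time(kin, tt)
  gamma <- vapply(seq_along(tt), function(i) {
    retinal_size(A = c(scene$barrier_x, ge$y_fixed[i]),
                 C = c(scene$barrier_x, ge$y_moving[i]),
                 B = c(xs[i], ys[i]))
  }, numeric(1))
  gd <- retinal_size_rate(tt, gamma)
  rr <- rrev(gamma, gd, gamma_eps)
  out <- data.frame(time_s = tt, gamma_rad = gamma, gamma_dot = gd,
                    rrev = rr$rrev, defined = rr$defined)
  class(out) <- c("visual_param_series", "data.frame")
  out
}
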