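#' Derived kinematic series of a spiral trial
#'
#' Computes the per-sample and per-interval series every downstream feature
#' consumes: time differences, drawing speed, radius, unwrapped polar angle,
#' radial velocity and angular velocity.
#'
#' With samples \eqn{(x_i, y_i, t_i)} and origin \eqn{(o_x, o_y)}:
#' \deqn{speed_i = \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2} / (t_{i+1}-t_i)}
#' \deqn{r_i = \sqrt{(x_i-o_x)^2 + (y_i-o_y)^2}}
#' \deqn{RV_i = (r_{i+1}-r_i) / (t_{i+1}-t_i)}
#' \eqn{\varphi} is the four-quadrant arctangent of \eqn{(y_i-o_y, x_i-o_x)}
#' unwrapped so no step exceeds \eqn{\pi} in magnitude, and
#' \eqn{AV_i = (\varphi_{i+1}-\varphi_i) / (t_{i+1}-t_i)}.
#'
#' Per-interval series are indexed to the left endpoint (length `n - 1`).
#' If a sample coincides exactly with the origin its angle is undefined; it is
#' filled from the nearest preceding sample with a defined angle (the first
#' following one for a leading run) and a warning is raised.
#'
#' @param trial A [spiral_trial()] object (>= 2 samples).
#' @param origin `"first_sample"` (default: the first drawn point, matching
#'   the protocol instruction to start at the template centre) or a numeric
#'   length-2 point.
#' @return An object of class `kinematic_series`: list with `n`, `dt`,
#'   `speed`, `r`, `phi`, `rv`, `av`, `seg_len` (per-interval path length,
#'   px) and `origin`.
#' @examples
#' tr <- spiral_trial(x = c(0, 10, 20), y = c(0, 0, 0), t = c(0, 0.1, 0.2))
#' compute_kinematics(tr)$speed  # 100, 100
#' @export
compute_kinematics <- function(trial, origin = "first_sample") {
  stopifnot(inherits(trial, "spiral_trial"))
  s <- trial$samples
  n <- nrow(s)
  if (n < 2L) stop("degenerate trial: fewer than 2 samples", call. = FALSE)
  origin_is_first <- identical(origin, "first_sample")
  if (origin_is_first) {
    origin <- c(s$x[1L], s$y[1L])
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 2L)

  dt <- diff(s$t)
  seg_len <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  speed <- seg_len / dt

  dx <- s$x - origin[1L]
  dy <- s$y - origin[2L]
  r <- sqrt(dx^2 + dy^2)
  phi_raw <- atan2(dy, dx)
  at_origin <- dx == 0 & dy == 0
  if (any(at_origin)) {
    # the first sample coincides with a first-sample origin by construction;
    # only unexpected coincidences are worth a warning
    unexpected <- if (origin_is_first) any(at_origin[-1L]) else TRUE
    if (unexpected && !all(at_origin)) {
      warning(sprintf(
        "%d sample(s) coincide with the origin; angle carried over from a neighbour",
        sum(at_origin)))
    }
    phi_raw[at_origin] <- NA_real_
    phi_raw <- fill_na_locf(phi_raw)
    if (anyNA(phi_raw)) phi_raw[is.na(phi_raw)] <- 0
  }
  phi <- unwrap_angle(phi_raw)

  structure(
    list(n = n, dt = dt, speed = speed, r = r, phi = phi,
         rv = diff(r) / dt, av = diff(phi) / dt,
         seg_len = seg_len, origin = origin),
    class = "kinematic_series"
  )
}
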