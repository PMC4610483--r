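# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations do not perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Unwrap a phase-angle series
#'
#' Removes 2*pi discontinuities: any jump between consecutive samples larger
#' than pi in magnitude is folded back, so the returned series satisfies
#' `abs(diff(phi)) < pi` wherever the underlying motion does.
#'
#' @param phi Numeric vector of angles (radians).
#' @return Numeric vector of the same length, continuous in angle.
#' @export
unwrap_angle <- function(phi) {
  n <- length(phi)
  if (n < 2L) return(phi)
  d <- diff(phi)
  dmod <- (d + pi) %% (2 * pi) - pi
  dmod[dmod == -pi & d > 0] <- pi
  phi[1L] + c(0, cumsum(dmod))
}

# Column-wise unwrap of an angle matrix (samples x candidates); used by the
# vectorised spiral-origin objective.
unwrap_angle_cols <- function(phi) {
  n <- nrow(phi)
  if (n < 2L) return(phi)
  d <- phi[-1L, , drop = FALSE] - phi[-n, , drop = FALSE]
  dmod <- (d + pi) %% (2 * pi) - pi
  dmod[dmod == -pi & d > 0] <- pi
  cum <- apply(dmod, 2L, cumsum)
  if (n == 2L) cum <- matrix(cum, nrow = 1L)
  rbind(phi[1L, ], sweep(cum, 2L, phi[1L, ], "+"))
}

# Fill NA entries from the nearest preceding non-NA value; leading NAs are
# filled from the first non-NA value.
fill_na_locf <- function(x) {
  ok <- !is.na(x)
  if (all(ok) || !any(ok)) return(x)
  idx <- cumsum(ok)
  first <- which(ok)[1L]
  idx[idx == 0L] <- 1L
  x[which(ok)][pmax(idx, 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
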