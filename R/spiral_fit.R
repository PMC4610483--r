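# Archimedean spiral fitting in polar space and the four fit-error features.
# The error a subject makes is measured as the RMSE of the radial residuals
# r_i - (a + b * phi_i) at the drawn samples' angles; no resampling to a
# uniform angle grid is performed.

#' Least-squares Archimedean spiral fit in polar coordinates
#'
#' Fits \code{r = a + b * phi} by linear least squares. With
#' `constrain_origin = TRUE` the intercept is pinned to zero (the ideal
#' spiral must pass through the coordinate origin) and
#' `b = sum(phi * r) / sum(phi^2)`.
#'
#' @param r Radius series (px).
#' @param phi Unwrapped angle series (rad), same length, not all equal.
#' @param constrain_origin Force `a = 0`?
#' @return List of class `spiral_fit`: `a`, `b`, `rmse`, `constrained`, `n`.
#' @examples
#' phi <- seq(0, 4 * pi, length.out = 50)
#' fit_ideal_spiral(2 * phi, phi)$b  # 2
#' @export
fit_ideal_spiral <- function(r, phi, constrain_origin = FALSE) {
  n <- length(r)
  if (n < 2L || length(phi) != n) {
    stop("need matching r and phi series of length >= 2", call. = FALSE)
  }
  if (diff(range(phi)) == 0) {
    stop("all angles identical: spiral fit undefined", call. = FALSE)
  }
  if (constrain_origin) {
    a <- 0
    b <- sum(phi * r) / sum(phi^2)
  } else {
    mp <- mean(phi); mr <- mean(r)
    b <- sum((phi - mp) * (r - mr)) / sum((phi - mp)^2)
    a <- mr - b * mp
  }
  res <- r - (a + b * phi)
  structure(list(a = a, b = b, rmse = sqrt(mean(res^2)),
                 constrained = constrain_origin, n = n),
            class = "spiral_fit")
}

#' Differential-evolution hyperparameters
#'
#' Classic DE/rand/1/bin settings for the two-parameter spiral-origin search.
#' The defaults (population 20, mutation factor 0.8, crossover rate 0.9,
#' 100 generations) converge robustly on this small search space.
#'
#' @param pop_size Population size.
#' @param f Differential weight (mutation factor).
#' @param cr Crossover probability.
#' @param max_gen Maximum generations.
#' @param tol Early-stopping tolerance: the search has converged when the
#'   population objective spread falls below `tol * (1 + |best|)`.
#' @return List of class `de_control`.
#' @export
de_control <- function(pop_size = 20L, f = 0.8, cr = 0.9, max_gen = 100L,
                       tol = 1e-6) {
  structure(list(pop_size = pop_size, f = f, cr = cr, max_gen = max_gen,
                 tol = tol), class = "de_control")
}

# default DE settings, callable from contexts where `de_control` is shadowed
spiralkin_de_defaults <- function() de_control()

# DE/rand/1/bin minimiser over a box. `fn` maps a (k x d) matrix of candidate
# parameter rows to a length-k objective vector; vectorised evaluation keeps
# the per-generation cost to a handful of matrix operations.
de_optimize <- function(fn, lower, upper, control = de_control(), seed = 17L,
                        init = NULL) {
  d <- length(lower)
  np <- control$pop_size
  with_seed(seed, {
    pop <- sapply(seq_len(d), function(j) stats::runif(np, lower[j], upper[j]))
    pop <- matrix(pop, nrow = np)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      k <- min(nrow(init), np)
      pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
    }
    fit <- fn(pop)
    converged <- FALSE
    for (gen in seq_len(control$max_gen)) {
      r1 <- sample.int(np, np, replace = TRUE)
      r2 <- sample.int(np, np, replace = TRUE)
      r3 <- sample.int(np, np, replace = TRUE)
      mutant <- pop[r1, , drop = FALSE] +
        control$f * (pop[r2, , drop = FALSE] - pop[r3, , drop = FALSE])
      cross <- matrix(stats::runif(np * d) < control$cr, np, d)
      forced <- cbind(seq_len(np), sample.int(d, np, replace = TRUE))
      cross[forced] <- TRUE
      trial <- ifelse(cross, mutant, pop)
      trial <- pmin(pmax(trial, matrix(lower, np, d, byrow = TRUE)),
                    matrix(upper, np, d, byrow = TRUE))
      tfit <- fn(trial)
      better <- tfit <= fit
      pop[better, ] <- trial[better, , drop = FALSE]
      fit[better] <- tfit[better]
      if (max(fit) - min(fit) < control$tol * (1 + abs(min(fit)))) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(fit)
    spread <- max(fit) - min(fit)
    list(par = pop[best, ], value = fit[best], converged = converged,
         spread = spread)
  })
}

# Vectorised objective: RMSE of the unconstrained polar fit of a trial about
# each candidate origin (rows of O). Angles are recomputed and re-unwrapped
# about every candidate. A sample coincident with the candidate origin has an
# undefined angle and lies on every spiral through that origin, so it is
# excluded from the fit (its angle is carried over only to anchor the unwrap).
origin_objective <- function(x, y) {
  n <- length(x)
  force(x); force(y)
  function(O) {
    dx <- outer(x, O[, 1L], "-")
    dy <- outer(y, O[, 2L], "-")
    r <- sqrt(dx^2 + dy^2)
    raw <- atan2(dy, dx)
    w <- r > 0
    if (!all(w)) {
      for (j in which(colSums(!w) > 0)) {
        col <- raw[, j]
        col[!w[, j]] <- NA_real_
        raw[, j] <- fill_na_locf(col)
      }
    }
    phi <- unwrap_angle_cols(raw)
    m <- colSums(w)
    sp <- colSums(phi * w); sr <- colSums(r * w)
    spp <- colSums(phi^2 * w); spr <- colSums(phi * r * w)
    b <- (m * spr - sp * sr) / (m * spp - sp^2)
    a <- (sr - b * sp) / m
    res <- (r - sweep(sweep(phi, 2L, b, "*"), 2L, a, "+")) * w
    out <- sqrt(colSums(res^2) / m)
    out[!is.finite(out)] <- .Machine$double.xmax  # degenerate candidate
    out
  }
}

#' Search for the optimal spiral origin
#'
#' Finds the virtual optimal origin `Ou`: the translation of the drawing that
#' minimises the RMSE of the unconstrained Archimedean fit in polar space.
#' Subjects often misplace the start of the tracing; refitting about `Ou`
#' separates that translation error from genuine shape error. The search uses
#' differential evolution over the drawing's bounding box expanded by 25% on
#' each side and is deterministic given the seed.
#'
#' @param trial A [spiral_trial()] object with >= 10 samples.
#' @param control A [de_control()].
#' @param seed Integer seed of the search.
#' @return A `spiral_fit` (unconstrained, about `Ou`) with extra fields
#'   `origin` (the optimal origin) and `converged`. A non-converged search
#'   returns the best origin found with a warning.
#' @export
optimal_origin_search <- function(trial, control = de_control(), seed = 17L) {
  stopifnot(inherits(trial, "spiral_trial"))
  s <- trial$samples
  if (nrow(s) < 10L) {
    stop("origin search requires at least 10 samples", call. = FALSE)
  }
  rx <- range(s$x); ry <- range(s$y)
  mx <- 0.25 * max(diff(rx), 1e-6)
  my <- 0.25 * max(diff(ry), 1e-6)
  obj <- origin_objective(s$x, s$y)
  # seed the population with the default origin so the optimised fit can
  # never be worse than the first-sample fit
  res <- de_optimize(obj, lower = c(rx[1L] - mx, ry[1L] - my),
                     upper = c(rx[2L] + mx, ry[2L] + my),
                     control = control, seed = seed,
                     init = c(s$x[1L], s$y[1L]))
  if (!res$converged && res$spread > 0.01 * (1 + abs(res$value))) {
    # the population is still spread over clearly distinct objective values
    warning("origin search did not converge; returning best origin found")
  }
  dx <- s$x - res$par[1L]; dy <- s$y - res$par[2L]
  r <- sqrt(dx^2 + dy^2)
  phi <- unwrap_angle(atan2(dy, dx))
  ok <- r > 0
  fit <- fit_ideal_spiral(r[ok], phi[ok], constrain_origin = FALSE)
  fit$origin <- res$par
  fit$converged <- res$converged
  fit
}

#' Archimedean fit-error features of a trial
#'
#' Computes the four error features: `Err` and `Err0` are the RMSEs of the
#' unconstrained and origin-constrained polar fits about the default origin
#' (the first drawn point); `errBF` and `err0BF` are the same two errors
#' after translating the drawing so that its optimal origin `Ou` (found by
#' [optimal_origin_search()]) sits at (0, 0).
#'
#' @param trial A [spiral_trial()] object.
#' @param seed Seed of the origin search.
#' @param control A [de_control()].
#' @param origin Default-origin convention, as in [compute_kinematics()].
#' @return Named list `Err`, `Err0`, `errBF`, `err0BF`, `Ou` (the optimal
#'   origin). Trials with fewer than 10 samples get `NA` for the translated
#'   errors.
#' @export
spiral_error_features <- function(trial, seed = 17L, control = de_control(),
                                  origin = "first_sample") {
  k <- suppressWarnings(compute_kinematics(trial, origin = origin))
  # a sample at the origin has no angle and lies on every centred spiral:
  # it carries no shape information and is excluded from the residuals
  ok <- k$r > 0
  err <- fit_ideal_spiral(k$r[ok], k$phi[ok], constrain_origin = FALSE)$rmse
  err0 <- fit_ideal_spiral(k$r[ok], k$phi[ok], constrain_origin = TRUE)$rmse
  if (nrow(trial$samples) < 10L) {
    return(list(Err = err, Err0 = err0, errBF = NA_real_, err0BF = NA_real_,
                Ou = c(NA_real_, NA_real_)))
  }
  best <- optimal_origin_search(trial, control = control, seed = seed)
  s <- trial$samples
  dx <- s$x - best$origin[1L]; dy <- s$y - best$origin[2L]
  r <- sqrt(dx^2 + dy^2)
  phi <- unwrap_angle(atan2(dy, dx))
  ok2 <- r > 0
  err_bf <- best$rmse
  err0_bf <- fit_ideal_spiral(r[ok2], phi[ok2], constrain_origin = TRUE)$rmse
  list(Err = err, Err0 = err0, errBF = err_bf, err0BF = err0_bf,
       Ou = best$origin)
}
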