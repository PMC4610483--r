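#' Construct a spiral trial
#'
#' A trial is one continuous spiral tracing: ordered samples of pen position
#' (screen pixels, y increasing downward) and time. Timestamps are stored in
#' seconds in memory; the on-disk formats use milliseconds, matching the
#' recording device convention.
#'
#' Samples are sorted by time. Duplicate timestamps are collapsed to the first
#' occurrence with a warning, because zero time differences would make every
#' velocity-type quantity undefined.
#'
#' @param x,y Numeric vectors of pen coordinates (px).
#' @param t Numeric vector of timestamps (s), same length as `x`.
#' @param subject_id,occasion_id Opaque identifiers.
#' @param trial_index Integer 1-3 (the test protocol repeats the tracing three
#'   times per occasion).
#' @param group `"PD"` (patient) or `"HE"` (healthy elderly).
#' @param nominal_rate Nominal sampling frequency in Hz (default 10).
#' @param mean_impairment Optional externally supplied mean impairment score
#'   on a 0-10 scale, used to gate inclusion in classification.
#' @param label Optional simulator truth label (see [simulate_trial()]).
#' @param max_duration Maximum accepted trial duration in seconds; the
#'   protocol target is 10 s, the default cap is 15 s.
#' @return An object of class `spiral_trial`: a list with a `samples`
#'   data frame (`x`, `y`, `t`) and the metadata fields above.
#' @examples
#' tr <- spiral_trial(x = c(0, 10, 20), y = c(0, 0, 0), t = c(0, 0.1, 0.2))
#' nrow(tr$samples)
#' @export
spiral_trial <- function(x, y, t,
                         subject_id = NA_character_,
                         occasion_id = NA_character_,
                         trial_index = 1L,
                         group = c("PD", "HE"),
                         nominal_rate = 10,
                         mean_impairment = NA_real_,
                         label = NA_character_,
                         max_duration = 15) {
  group <- match.arg(group)
  if (length(x) != length(y) || length(x) != length(t)) {
    stop("x, y and t must have equal length", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(t))) {
    stop("non-finite coordinate or timestamp in trial", call. = FALSE)
  }
  ord <- order(t)
  x <- x[ord]; y <- y[ord]; t <- t[ord]
  dup <- duplicated(t)
  if (any(dup)) {
    warning(sprintf("dropping %d sample(s) with duplicate timestamps", sum(dup)))
    x <- x[!dup]; y <- y[!dup]; t <- t[!dup]
  }
  if (length(x) < 2L) {
    stop("degenerate trial: fewer than 2 distinct samples", call. = FALSE)
  }
  if (diff(range(t)) > max_duration) {
    stop(sprintf("trial duration %.2f s exceeds maximum %.2f s",
                 diff(range(t)), max_duration), call. = FALSE)
  }
  structure(
    list(
      samples = data.frame(x = x, y = y, t = t),
      subject_id = as.character(subject_id),
      occasion_id = as.character(occasion_id),
      trial_index = as.integer(trial_index),
      group = group,
      nominal_rate = nominal_rate,
      mean_impairment = mean_impairment,
      label = as.character(label)
    ),
    class = "spiral_trial"
  )
}

#' @export
print.spiral_trial <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<spiral_trial> %d samples over %.2f s (subject %s, occasion %s, trial %d, group %s)\n",
    nrow(s), diff(range(s$t)), x$subject_id, x$occasion_id, x$trial_index, x$group))
  invisible(x)
}

#' Read a spiral trial from disk
#'
#' Two dialects are supported. `"csv"`: header `x,y,t_ms`, one sample per
#' row, no metadata. `"json"`: an object with metadata fields
#' (`subject_id`, `occasion_id`, `trial_index`, `group`, `mean_impairment`,
#' optionally `label`) and a `samples` array of `{x, y, t_ms}` objects.
#' Timestamps on disk are milliseconds; they are converted to seconds.
#' Samples are sorted by time, so row order in the file is immaterial.
#'
#' @param path Path to the trial file.
#' @param dialect `"csv"` or `"json"`; defaults to the file extension.
#' @param max_duration Passed to [spiral_trial()].
#' @return A [spiral_trial()] object.
#' @export
read_trial <- function(path, dialect = c("auto", "csv", "json"),
                       max_duration = 15) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (dialect == "csv") {
    raw <- utils::read.csv(path, colClasses = "character")
    need <- c("x", "y", "t_ms")
    if (!all(need %in% names(raw))) {
      stop(sprintf("%s: expected columns x,y,t_ms", path), call. = FALSE)
    }
    num <- lapply(need, function(cn) suppressWarnings(as.numeric(raw[[cn]])))
    names(num) <- need
    bad <- which(vapply(num, anyNA, logical(1L)))
    if (length(bad)) {
      line <- which(is.na(num[[bad[1L]]]))[1L] + 1L  # +1 for header line
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, need[bad[1L]], line), call. = FALSE)
    }
    spiral_trial(num$x, num$y, num$t_ms / 1000, max_duration = max_duration)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    s <- obj$samples
    if (is.null(s) || NROW(s) < 2L) {
      stop(sprintf("%s: degenerate trial (fewer than 2 samples)", path),
           call. = FALSE)
    }
    spiral_trial(
      x = as.numeric(s$x), y = as.numeric(s$y), t = as.numeric(s$t_ms) / 1000,
      subject_id = obj$subject_id %||% NA_character_,
      occasion_id = obj$occasion_id %||% NA_character_,
      trial_index = obj$trial_index %||% 1L,
      group = obj$group %||% "PD",
      mean_impairment = obj$mean_impairment %||% NA_real_,
      label = obj$label %||% NA_character_,
      max_duration = max_duration
    )
  }
}

#' Write a spiral trial to disk
#'
#' Inverse of [read_trial()]: timestamps are written in milliseconds.
#' The JSON dialect preserves metadata; the CSV dialect stores samples only.
#' Coordinates round-trip to at least 6 decimal places.
#'
#' @param trial A [spiral_trial()] object.
#' @param path Destination path.
#' @param dialect `"csv"` or `"json"`; defaults to the file extension.
#' @return Invisibly, `path`.
#' @export
write_trial <- function(trial, path, dialect = c("auto", "csv", "json")) {
  stopifnot(inherits(trial, "spiral_trial"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  s <- trial$samples
  if (nrow(s) < 2L) stop("degenerate trial: nothing to write", call. = FALSE)
  if (dialect == "csv") {
    out <- data.frame(x = s$x, y = s$y, t_ms = s$t * 1000)
    utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      subject_id = trial$subject_id,
      occasion_id = trial$occasion_id,
      trial_index = trial$trial_index,
      group = trial$group,
      mean_impairment = trial$mean_impairment,
      label = trial$label,
      samples = data.frame(x = s$x, y = s$y, t_ms = s$t * 1000)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Generate the pre-drawn Archimedean spiral template
#'
#' The tracing template is an Archimedean spiral \code{r = pitch * phi} sampled at
#' equal angle increments from 0 to `2 * pi * turns`.
#'
#' @param center Numeric length-2 centre `(x, y)` in px.
#' @param pitch Radius growth per radian (px/rad), positive.
#' @param turns Number of revolutions, positive.
#' @param n_points Number of sampled points (>= 2).
#' @return An object of class `spiral_template`: list with `center`, `pitch`,
#'   `turns` and a `points` data frame (`x`, `y`, `phi`, `r`).
#' @examples
#' tpl <- archimedes_template(c(0, 0), pitch = 1, turns = 1, n_points = 100)
#' max(tpl$points$r)  # 2 * pi
#' @export
archimedes_template <- function(center = c(0, 0), pitch = 10, turns = 3,
                                n_points = 300) {
  if (pitch <= 0) stop("pitch must be positive", call. = FALSE)
  if (turns <= 0) stop("turns must be positive", call. = FALSE)
  if (n_points < 2L) stop("n_points must be at least 2", call. = FALSE)
  phi <- seq(0, 2 * pi * turns, length.out = n_points)
  r <- pitch * phi
  structure(
    list(center = center, pitch = pitch, turns = turns,
         points = data.frame(x = center[1L] + r * cos(phi),
                             y = center[2L] + r * sin(phi),
                             phi = phi, r = r)),
    class = "spiral_template"
  )
}
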