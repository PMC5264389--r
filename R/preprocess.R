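#' Exclusion rules for continuous rating curves
#'
#' Encodes the three curve-quality rules applied before any analysis:
#' subjects with an incomplete odorant set (they did not attend all sessions)
#' are excluded wholesale; subjects whose ratings oscillate at high frequency
#' ("chaotic" raters, presumably tracking their breathing) are excluded
#' wholesale; and individual curves whose response onset is delayed beyond
#' `delay_max_s` (17 s, i.e. 14% of the recording) are excluded one by one.
#'
#' @param delay_max_s Maximum tolerated response delay in seconds.
#' @param deadband Intensity deviation (units of the 0-100 scale) from the
#'   start level below which the subject is considered not yet responding.
#' @param sustain_samples Number of consecutive samples the deviation must
#'   persist to count as a response (robust to one-sample jitter).
#' @param chaos_threshold Direction-reversal rate (reversals/s) above which a
#'   curve is chaotic.
#' @param chaos_hysteresis Minimum opposite move (intensity units) for a
#'   direction change to count as a reversal.
#' @param chaos_smooth_s Moving-average window (s) applied before reversal
#'   counting.
#' @param subject_chaos_fraction Fraction of a subject's curves that must be
#'   chaotic for the subject to be excluded wholesale.
#' @param min_odorant_fraction A subject rating fewer than this fraction of
#'   the full odorant set is treated as not having attended all sessions.
#'   The default (0.7) sits between partial attendance (at most half the
#'   sessions, i.e. at most 50% of odorants) and the worst loss an attending
#'   subject can incur from individually delayed curves (9 of 32, i.e. 72%
#'   remaining), so the two causes never mix.
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(delay_max_s = 17,
                            deadband = 2,
                            sustain_samples = 2L,
                            chaos_threshold = 0.5,
                            chaos_hysteresis = 3,
                            chaos_smooth_s = 0.5,
                            subject_chaos_fraction = 0.5,
                            min_odorant_fraction = 0.7) {
  stopifnot(delay_max_s > 0, deadband > 0, sustain_samples >= 1,
            chaos_threshold > 0, chaos_hysteresis >= 0,
            min_odorant_fraction > 0, min_odorant_fraction <= 1)
  structure(as.list(environment()), class = "exclusion_rules")
}

#' Response delay of each curve
#'
#' The delay is the time of the first sample whose absolute deviation from
#' the start level exceeds the deadband for at least `sustain_samples`
#' consecutive samples; curves that never respond get the full recording
#' duration.
#'
#' @param curves An [intensity_curves()] object or a single numeric curve.
#' @param rules An [exclusion_rules()] list.
#' @param start_level Start level used for a bare numeric curve.
#' @return Numeric vector of delays in seconds (scalar for a single curve).
#' @export
response_delay <- function(curves, rules = exclusion_rules(),
                           start_level = 60) {
  if (is.numeric(curves) && is.null(dim(curves))) {
    curves <- intensity_curves(matrix(curves, 1),
                               data.frame(subject = "s", odorant = "o",
                                          start_level = start_level),
                               time = seq(0, by = 0.25,
                                          length.out = length(curves)))
    return(response_delay(curves, rules)[1L])
  }
  dev <- abs(curves$intensity - curves$info$start_level) > rules$deadband
  k <- rules$sustain_samples
  nt <- ncol(dev)
  sustained <- dev
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      shifted <- cbind(dev[, -seq_len(j), drop = FALSE],
                       matrix(FALSE, nrow(dev), j))
      sustained <- sustained & shifted
    }
  }
  idx <- apply(sustained, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  out <- curves$time[idx]
  out[is.na(idx)] <- max(curves$time)
  unname(out)
}

# Hysteresis-filtered direction reversal count of one smoothed trace.
count_reversals <- function(x, h) {
  n <- length(x)
  dir <- 0L
  ext <- x[1L]
  count <- 0L
  for (i in 2:n) {
    v <- x[i]
    if (dir == 0L) {
      if (v - ext >= h) { dir <- 1L; ext <- v }
      else if (ext - v >= h) { dir <- -1L; ext <- v }
    } else if (dir == 1L) {
      if (v > ext) ext <- v
      else if (ext - v >= h) { count <- count + 1L; dir <- -1L; ext <- v }
    } else {
      if (v < ext) ext <- v
      else if (v - ext >= h) { count <- count + 1L; dir <- 1L; ext <- v }
    }
  }
  count
}

#' Flag chaotic curves
#'
#' A curve is chaotic when, after a short moving-average smoothing, its rate
#' of direction reversals larger than the hysteresis amplitude exceeds
#' `rules$chaos_threshold` reversals per second. Monotone decays (even noisy
#' ones) produce essentially no qualifying reversals, while high-frequency
#' alternating ratings produce one per half period.
#'
#' @inheritParams response_delay
#' @return Logical vector (scalar for a single curve).
#' @export
is_chaotic <- function(curves, rules = exclusion_rules()) {
  if (is.numeric(curves) && is.null(dim(curves))) {
    curves <- intensity_curves(matrix(curves, 1),
                               data.frame(subject = "s", odorant = "o"),
                               time = seq(0, by = 0.25,
                                          length.out = length(curves)))
    return(is_chaotic(curves, rules)[1L])
  }
  dt <- diff(curves$time[1:2])
  k <- max(1L, round(rules$chaos_smooth_s / dt))
  duration <- diff(range(curves$time))
  kernel <- rep(1 / k, k)
  apply(curves$intensity, 1L, function(x) {
    if (k > 1L) {
      sm <- as.numeric(stats::filter(x, kernel, sides = 1L))
      sm <- sm[k:length(sm)]
    } else sm <- x
    count_reversals(sm, rules$chaos_hysteresis) / duration >
      rules$chaos_threshold
  })
}

#' Apply the exclusion rules to a set of curves
#'
#' Order of application: (1) subjects with an incomplete odorant set are
#' removed wholesale ("absent"); (2) subjects with more than
#' `subject_chaos_fraction` of their curves flagged chaotic are removed
#' wholesale; (3) remaining individual curves with a response delay above
#' `delay_max_s` are removed. Every excluded curve gets exactly one reason.
#'
#' @inheritParams response_delay
#' @return A list with `curves` (retained [intensity_curves()]) and `report`
#'   (an `exclusion_report`: counts, per-curve reasons, excluded subjects).
#' @export
apply_exclusions <- function(curves, rules = exclusion_rules()) {
  info <- curves$info
  n_input <- n_curves(curves)
  reason <- rep(NA_character_, n_input)

  per_subject <- table(info$subject)
  full_set <- length(unique(info$odorant))
  absent_subjects <- names(per_subject)[
    per_subject < rules$min_odorant_fraction * full_set]
  reason[info$subject %in% absent_subjects] <- "absent_subject"

  candidate <- is.na(reason)
  chaos_flag <- rep(FALSE, n_input)
  chaos_flag[candidate] <- is_chaotic(curves[candidate], rules)
  frac <- tapply(chaos_flag[candidate], info$subject[candidate], mean)
  chaotic_subjects <- names(frac)[frac > rules$subject_chaos_fraction]
  reason[is.na(reason) & info$subject %in% chaotic_subjects] <- "chaotic_subject"

  candidate <- is.na(reason)
  delay <- rep(NA_real_, n_input)
  delay[candidate] <- response_delay(curves[candidate], rules)
  reason[candidate & delay > rules$delay_max_s] <- "delayed_response"

  retained <- is.na(reason)
  report <- structure(list(
    n_input_curves = n_input,
    n_absent_excluded = sum(reason == "absent_subject", na.rm = TRUE),
    n_chaotic_excluded = sum(reason == "chaotic_subject", na.rm = TRUE),
    n_delay_excluded = sum(reason == "delayed_response", na.rm = TRUE),
    n_retained = sum(retained),
    absent_subjects = absent_subjects,
    chaotic_subjects = chaotic_subjects,
    reasons = data.frame(subject = info$subject, odorant = info$odorant,
                         reason = ifelse(retained, "retained", reason),
                         stringsAsFactors = FALSE)
  ), class = "exclusion_report")
  list(curves = curves[retained], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("exclusion_report:", x$n_input_curves, "input curves\n")
  cat(sprintf("  absent subjects : %d curve(s) from %d subject(s)\n",
              x$n_absent_excluded, length(x$absent_subjects)))
  cat(sprintf("  chaotic subjects: %d curve(s) from %d subject(s)\n",
              x$n_chaotic_excluded, length(x$chaotic_subjects)))
  cat(sprintf("  delayed curves  : %d curve(s)\n", x$n_delay_excluded))
  cat(sprintf("  retained        : %d curve(s)\n", x$n_retained))
  invisible(x)
}

#' Normalize curves on the intensity axis
#'
#' Divides every curve by its first sample so that all curves start at 1.
#' This removes between-odorant intensity differences present before any
#' habituation (all subjects were instructed to start at the same feedback
#' level), while preserving the shape of the decay.
#'
#' @param curves An [intensity_curves()] object.
#' @return The normalized curves (first sample of every curve equals 1).
#' @export
normalize_intensity <- function(curves) {
  first <- curves$intensity[, 1L]
  if (any(first == 0)) {
    stop_odorhab("degenerate curve(s) with zero initial intensity: row(s) ",
                 paste(utils::head(which(first == 0), 3), collapse = ", "))
  }
  out <- curves
  out$intensity <- curves$intensity / first
  out$info$start_level <- 1
  attr(out, "normalized") <- TRUE
  out
}
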