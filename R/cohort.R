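#' Generative truth for a synthetic habituation cohort
#'
#' Defines the ground-truth decay model used by [generate_cohort()]. Each
#' subject x odorant curve follows a single-exponential decay to a plateau,
#'
#'   I(t) = L * ( p + (1 - p) * exp(-lambda(o) * t) ) + s_i * (1 - exp(-lambda(o) * t)) + e(t)
#'
#' where `L` is the instructed start level (60 of 100), `p` the plateau
#' fraction retained at t -> Inf, `s_i` a subject-level shift of the
#' asymptote (random "rater" effect, zero at onset so every curve starts at
#' `L`), and `e(t)` iid Gaussian sample noise. The per-odorant decay rate is
#' log-linear in autoscaled descriptors:
#'
#'   lambda(o) = baseline * exp( sum_j beta_j * z_j(o) ),   clamped to `lambda_range`.
#'
#' A negative `beta_j` therefore means "less habituation (slower decay) when
#' descriptor j increases". The default coefficients encode the qualitative
#' structure reported for real odorants: slower decay at high vapour
#' pressure, faster decay at high molecular weight and more double bonds.
#'
#' @param driver_coefficients Named numeric vector: effect of each autoscaled
#'   descriptor on the log decay rate.
#' @param baseline_decay_rate Decay rate (1/s) of an average odorant.
#' @param plateau_fraction Fraction of the start level retained at t -> Inf.
#' @param noise_sd Sample noise standard deviation (intensity units).
#' @param rater_sd Subject random-effect standard deviation (intensity
#'   units); draws are truncated at 2.5 sd so that no subject can mask the
#'   decay entirely.
#' @param lambda_range Clamp for per-odorant decay rates (1/s). The lower
#'   bound guarantees that every clean curve leaves the response deadband
#'   well before the delay-exclusion cutoff.
#' @param chaos_amplitude Amplitude (intensity units) of the 1-Hz alternation
#'   of chaotic raters.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `generative_truth`.
#' @export
generative_truth <- function(driver_coefficients = c(Vp = -0.35, Mw = 0.25,
                                                     Db_bonds = 0.25),
                             baseline_decay_rate = 0.02,
                             plateau_fraction = 0.3,
                             noise_sd = 1,
                             rater_sd = 5,
                             lambda_range = c(0.005, 0.3),
                             chaos_amplitude = 12,
                             seed = 1L) {
  stopifnot(plateau_fraction >= 0, plateau_fraction <= 1,
            noise_sd >= 0, rater_sd >= 0,
            length(lambda_range) == 2L, lambda_range[1] > 0,
            lambda_range[1] <= lambda_range[2])
  if (is.null(names(driver_coefficients)) && length(driver_coefficients)) {
    stop_odorhab("driver_coefficients must be named by descriptor")
  }
  structure(list(driver_coefficients = driver_coefficients,
                 baseline_decay_rate = baseline_decay_rate,
                 plateau_fraction = plateau_fraction,
                 noise_sd = noise_sd,
                 rater_sd = rater_sd,
                 lambda_range = lambda_range,
                 chaos_amplitude = chaos_amplitude,
                 seed = seed),
            class = "generative_truth")
}

#' Cohort configuration for the synthetic generator
#'
#' The defaults mirror the study design: 58 recruited subjects rating 32
#' odorants at 4 Hz for 120 s starting at the 6th of 10 feedback levels
#' (intensity 60), with 3 subjects not attending all sessions, 5 chaotic
#' raters, and 69 delayed curves spread over 13 of the remaining subjects
#' (between 1 and 9 each). Responses delayed beyond 17 s are the ones the
#' exclusion stage is meant to drop, so delays are drawn inside
#' `delay_range_s` which must sit in (17, 120].
#'
#' @param n_subjects Number of recruited subjects.
#' @param odorants Descriptor table (one row per odorant) as returned by
#'   [odorant_descriptors()]; any table with an `Abb` id column plus the
#'   numeric descriptors named in the generative truth works.
#' @param n_absent_subjects Subjects attending only some sessions (their
#'   partial data is excluded wholesale downstream).
#' @param n_chaotic_subjects Subjects producing high-frequency alternating
#'   ratings.
#' @param n_delayed_curves Total number of delayed curves.
#' @param n_delayed_subjects Number of subjects the delayed curves are
#'   spread over.
#' @param delay_range_s Interval the true onset delays are drawn from.
#' @param sampling_hz Sampling frequency.
#' @param duration_s Recording duration.
#' @param start_level Instructed start intensity (0-100 scale).
#' @param sensory_coefficients Named list mapping each sensory attribute
#'   (`intensity`, `pleasantness`, `familiarity`, `trigeminality`) to a named
#'   vector of descriptor effects on the 1-9 rating scale. The default makes
#'   intensity and trigeminality rise with vapour pressure and pleasantness
#'   fall with it, reproducing the collinearity structure of the real panel.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 58L,
                          odorants = odorant_descriptors(),
                          n_absent_subjects = 3L,
                          n_chaotic_subjects = 5L,
                          n_delayed_curves = 69L,
                          n_delayed_subjects = 13L,
                          delay_range_s = c(18, 60),
                          sampling_hz = 4,
                          duration_s = 120,
                          start_level = 60,
                          sensory_coefficients = list(
                            intensity = c(Vp = 1.2),
                            trigeminality = c(Vp = 1.1),
                            pleasantness = c(Vp = -0.9),
                            familiarity = numeric(0))) {
  if (n_absent_subjects + n_chaotic_subjects > n_subjects) {
    stop_odorhab("n_absent_subjects + n_chaotic_subjects exceeds n_subjects")
  }
  n_ok <- n_subjects - n_absent_subjects - n_chaotic_subjects
  if (n_delayed_subjects > n_ok) {
    stop_odorhab("more delayed subjects requested than clean subjects exist")
  }
  if (n_delayed_curves > 0) {
    if (n_delayed_subjects < 1L ||
        n_delayed_curves > n_delayed_subjects * nrow(odorants)) {
      stop_odorhab("n_delayed_curves cannot be spread over n_delayed_subjects")
    }
    if (delay_range_s[1] <= 17 || delay_range_s[2] > duration_s) {
      stop_odorhab("delay_range_s must lie within (17, duration_s]")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 odorants = odorants,
                 n_absent_subjects = as.integer(n_absent_subjects),
                 n_chaotic_subjects = as.integer(n_chaotic_subjects),
                 n_delayed_curves = as.integer(n_delayed_curves),
                 n_delayed_subjects = as.integer(n_delayed_subjects),
                 delay_range_s = delay_range_s,
                 sampling_hz = sampling_hz,
                 duration_s = duration_s,
                 start_level = start_level,
                 sensory_coefficients = sensory_coefficients),
            class = "cohort_config")
}

#' Generate a synthetic rating cohort with known ground truth
#'
#' Produces intensity curves for every present subject x odorant pair,
#' integer 1-9 sensory ratings, and a per-curve truth log recording each
#' curve's status (`normal`, `delayed`, `chaotic`, `absent`), true decay rate
#' and true onset delay. Chaotic subjects rate a 1-Hz alternation of
#' amplitude `truth$chaos_amplitude` around the start level; delayed curves
#' hold the start level exactly until their drawn onset and then begin the
#' decay with a visible 5-unit release; absent subjects attend at most half
#' of the sessions (so their odorant set is clearly incomplete).
#'
#' @param config A [cohort_config()].
#' @param truth A [generative_truth()]; `truth$seed` drives all randomness.
#' @return A list of class `odor_cohort` with elements `curves`
#'   (an [intensity_curves()]), `ratings` (long data frame of 1-9 scores),
#'   `truth_log` (per-curve status table), `subjects` (per-subject status)
#'   and `truth` (the echoed generative truth).
#' @export
generate_cohort <- function(config = cohort_config(),
                            truth = generative_truth()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(truth, "generative_truth"))
  with_seed(truth$seed, generate_cohort_impl(config, truth))
}

generate_cohort_impl <- function(config, truth) {
  od <- config$odorants
  n_od <- nrow(od)
  time <- seq(0, config$duration_s, by = 1 / config$sampling_hz)
  nt <- length(time)
  L <- config$start_level
  p <- truth$plateau_fraction

  beta <- truth$driver_coefficients
  if (length(beta)) {
    z <- descriptor_zscores(od, names(beta))
    log_lambda <- as.vector(z %*% beta)
  } else {
    log_lambda <- rep(0, n_od)
  }
  lambda <- clamp(truth$baseline_decay_rate * exp(log_lambda),
                  truth$lambda_range[1], truth$lambda_range[2])
  names(lambda) <- od$Abb

  subj <- sprintf("S%02d", seq_len(config$n_subjects))
  status <- rep("normal", config$n_subjects)
  shuffled <- sample(subj)
  absent <- shuffled[seq_len(config$n_absent_subjects)]
  chaotic <- shuffled[config$n_absent_subjects +
                        seq_len(config$n_chaotic_subjects)]
  status[subj %in% absent] <- "absent"
  status[subj %in% chaotic] <- "chaotic"
  clean <- subj[status == "normal"]

  # Spread the delayed curves over n_delayed_subjects clean subjects,
  # each receiving between 1 and 9 of them.
  delayed_per_subj <- integer(0)
  delayed_subjects <- character(0)
  if (config$n_delayed_curves > 0) {
    ns <- config$n_delayed_subjects
    base <- config$n_delayed_curves %/% ns
    extra <- config$n_delayed_curves %% ns
    counts <- rep(base, ns) + c(rep(1L, extra), rep(0L, ns - extra))
    if (any(counts < 1L) || any(counts > 9L)) {
      stop_odorhab("delayed-curve allocation outside 1-9 per subject; ",
                   "adjust n_delayed_curves or n_delayed_subjects")
    }
    delayed_subjects <- sample(clean, ns)
    delayed_per_subj <- stats::setNames(sample(counts), delayed_subjects)
  }

  # Sessions attended by absent subjects: at most half the sessions, so
  # their curve count stays clearly below that of subjects who only lose
  # individually delayed curves.
  sessions <- if ("Pres_order" %in% names(od)) od$Pres_order else
    rep(1L, n_od)
  n_sessions <- max(sessions)
  attended <- stats::setNames(
    if (n_sessions >= 2L) {
      sample(seq_len(max(1L, n_sessions %/% 2L)),
             config$n_absent_subjects, replace = TRUE)
    } else rep(0L, config$n_absent_subjects), absent)

  s_eff <- stats::setNames(
    clamp(stats::rnorm(config$n_subjects, 0, truth$rater_sd),
          -2.5 * truth$rater_sd, 2.5 * truth$rater_sd), subj)

  rows_subject <- character(0)
  rows_odorant <- character(0)
  rows_status <- character(0)
  rows_delay <- numeric(0)
  for (s in subj) {
    st <- status[match(s, subj)]
    if (st == "absent") {
      keep <- which(sessions <= attended[[s]])
      if (!length(keep)) next
      o_ids <- od$Abb[keep]
      c_status <- rep("absent", length(o_ids))
      c_delay <- rep(NA_real_, length(o_ids))
    } else {
      o_ids <- od$Abb
      c_status <- rep(if (st == "chaotic") "chaotic" else "normal", n_od)
      c_delay <- rep(NA_real_, n_od)
      nd <- delayed_per_subj[s]
      if (!is.na(nd) && length(nd) && st == "normal") {
        idx <- sample(n_od, nd)
        c_status[idx] <- "delayed"
        c_delay[idx] <- stats::runif(nd, config$delay_range_s[1],
                                     config$delay_range_s[2])
      }
    }
    rows_subject <- c(rows_subject, rep(s, length(o_ids)))
    rows_odorant <- c(rows_odorant, o_ids)
    rows_status <- c(rows_status, c_status)
    rows_delay <- c(rows_delay, c_delay)
  }

  n <- length(rows_subject)
  lam_row <- lambda[rows_odorant]
  s_row <- s_eff[rows_subject]
  mat <- matrix(NA_real_, n, nt)
  normalish <- rows_status %in% c("normal", "absent")
  if (any(normalish)) {
    E <- exp(-outer(lam_row[normalish], time))
    mat[normalish, ] <- L * p + s_row[normalish] +
      (L * (1 - p) - s_row[normalish]) * E
    if (truth$noise_sd > 0) {
      eps <- matrix(stats::rnorm(sum(normalish) * nt, 0, truth$noise_sd),
                    sum(normalish), nt)
      eps[, 1L] <- 0  # instructed exact start at level 6
      mat[normalish, ] <- mat[normalish, ] + eps
    }
  }
  chaos_rows <- which(rows_status == "chaotic")
  if (length(chaos_rows)) {
    square <- rep(c(1, 1, -1, -1), length.out = nt)  # 1 Hz at 4 Hz sampling
    for (i in chaos_rows) {
      w <- L + truth$chaos_amplitude * square + stats::rnorm(nt, 0, 2)
      w[1L] <- L
      mat[i, ] <- w
    }
  }
  delay_rows <- which(rows_status == "delayed")
  release <- 5
  for (i in delay_rows) {
    d <- rows_delay[i]
    tau <- pmax(time - d, 0)
    Ed <- exp(-lam_row[i] * tau)
    w <- L * p + s_row[i] + (L * (1 - p) - s_row[i]) * Ed - release * Ed
    post <- time >= d
    w[!post] <- L
    if (truth$noise_sd > 0) {
      w[post] <- w[post] + stats::rnorm(sum(post), 0, truth$noise_sd)
    }
    mat[i, ] <- w
  }
  mat <- clamp(mat, 0, 100)

  curves <- intensity_curves(mat,
                             data.frame(subject = rows_subject,
                                        odorant = rows_odorant,
                                        start_level = L,
                                        stringsAsFactors = FALSE),
                             time)

  ratings <- generate_ratings(config, subj[status != "absent"])

  truth_log <- data.frame(subject = rows_subject, odorant = rows_odorant,
                          status = rows_status,
                          true_lambda = unname(lam_row),
                          true_delay_s = rows_delay,
                          stringsAsFactors = FALSE)
  subjects <- data.frame(subject = subj, status = status,
                         subject_effect = unname(s_eff),
                         stringsAsFactors = FALSE)
  subjects$status[subjects$subject %in% names(delayed_per_subj)] <- "delayed"

  structure(list(curves = curves, ratings = ratings, truth_log = truth_log,
                 subjects = subjects, truth = truth, config = config,
                 lambda = lambda),
            class = "odor_cohort")
}

# Integer 1-9 sensory ratings correlated with designated descriptors.
generate_ratings <- function(config, raters) {
  od <- config$odorants
  vars <- names(config$sensory_coefficients)
  all_drivers <- unique(unlist(lapply(config$sensory_coefficients, names)))
  z <- if (length(all_drivers)) descriptor_zscores(od, all_drivers) else NULL
  out <- expand.grid(subject = raters, odorant = od$Abb,
                     stringsAsFactors = FALSE)
  subj_shift <- stats::setNames(stats::rnorm(length(raters), 0, 0.5), raters)
  for (v in vars) {
    gamma <- config$sensory_coefficients[[v]]
    mu <- rep(5, nrow(od))
    if (length(gamma)) mu <- mu + as.vector(z[, names(gamma), drop = FALSE] %*% gamma)
    val <- mu[match(out$odorant, od$Abb)] + subj_shift[out$subject] +
      stats::rnorm(nrow(out), 0, 0.8)
    out[[v]] <- as.integer(clamp(round(val), 1, 9))
  }
  out
}

#' @export
print.odor_cohort <- function(x, ...) {
  cat("odor_cohort:", n_curves(x$curves), "curves,",
      nrow(x$subjects), "recruited subjects,",
      length(unique(x$truth_log$odorant)), "odorants\n")
  print(table(x$truth_log$status))
  invisible(x)
}

#' Write a cohort's artifacts to disk
#'
#' Writes the long-format recordings CSV, the descriptor CSV, the ratings CSV
#' and a JSON sidecar with the generative truth and per-curve status log.
#'
#' @param cohort An `odor_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recordings(cohort$curves, file.path(dir, "recordings.csv"))
  data.table::fwrite(cohort$config$odorants, file.path(dir, "descriptors.csv"))
  data.table::fwrite(cohort$ratings, file.path(dir, "ratings.csv"))
  truth <- cohort$truth
  sidecar <- list(truth = truth[setdiff(names(truth), "class")],
                  lambda = as.list(cohort$lambda),
                  subjects = cohort$subjects,
                  truth_log = cohort$truth_log)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
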