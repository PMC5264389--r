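#' Container for continuous intensity rating curves
#'
#' An `intensity_curves` object holds one intensity trace per subject x
#' odorant pair on a common uniform time grid (by default 4 Hz over 120 s,
#' i.e. 481 samples at 250 ms spacing). Ratings live on a 0-100 intensity
#' scale until [normalize_intensity()] rescales them relative to the onset.
#'
#' @param intensity Numeric matrix, one row per curve, one column per sample.
#' @param info Data frame with one row per curve: `subject`, `odorant` and
#'   `start_level` columns.
#' @param time Numeric vector of sample times in seconds (strictly increasing,
#'   uniform spacing).
#' @return An object of class `intensity_curves`.
#' @export
intensity_curves <- function(intensity, info,
                             time = seq(0, 120, by = 0.25)) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity)) stop_odorhab("intensity must be numeric")
  if (nrow(intensity) != nrow(info)) {
    stop_odorhab("intensity and info disagree on the number of curves")
  }
  if (ncol(intensity) != length(time)) {
    stop_odorhab("intensity has ", ncol(intensity), " samples per curve but ",
                 "the time grid has ", length(time))
  }
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
    stop_odorhab("time grid must be strictly increasing and uniform")
  }
  stopifnot(all(c("subject", "odorant") %in% names(info)))
  if (is.null(info$start_level)) info$start_level <- intensity[, 1L]
  rownames(intensity) <- NULL
  structure(list(intensity = intensity,
                 info = as.data.frame(info, stringsAsFactors = FALSE),
                 time = time),
            class = "intensity_curves")
}

#' @export
print.intensity_curves <- function(x, ...) {
  cat(sprintf(paste0("intensity_curves: %d curves x %d samples ",
                     "(%.2f s to %.2f s, %.0f Hz)\n"),
              nrow(x$intensity), length(x$time), min(x$time), max(x$time),
              1 / diff(x$time[1:2])))
  cat(sprintf("  subjects: %d   odorants: %d\n",
              length(unique(x$info$subject)), length(unique(x$info$odorant))))
  if (isTRUE(attr(x, "normalized"))) cat("  normalized on the intensity axis\n")
  invisible(x)
}

#' @export
`[.intensity_curves` <- function(x, i, ...) {
  out <- intensity_curves(x$intensity[i, , drop = FALSE],
                          x$info[i, , drop = FALSE], x$time)
  attr(out, "normalized") <- attr(x, "normalized")
  out
}

#' Number of curves
#' @param x An `intensity_curves` object.
#' @export
n_curves <- function(x) nrow(x$intensity)

#' Write curves as a long-format recordings CSV
#'
#' Columns: `subject_id`, `odorant_id`, `time_s`, `intensity`.
#'
#' @param x An `intensity_curves` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(x, path) {
  n <- n_curves(x)
  long <- data.table::data.table(
    subject_id = rep(x$info$subject, each = length(x$time)),
    odorant_id = rep(x$info$odorant, each = length(x$time)),
    time_s = rep(x$time, times = n),
    intensity = as.vector(t(x$intensity))
  )
  data.table::fwrite(long, path)
  invisible(path)
}

#' Parse a long-format recordings CSV into curves
#'
#' Expects columns `subject_id`, `odorant_id`, `time_s`, `intensity`; builds
#' one curve per (subject, odorant) pair. Intensities must lie in \[0, 100\]
#' and each pair must sit on the same uniform time grid. Pairs whose sample
#' count differs from the modal curve length are dropped with a warning
#' (irregular recordings are flagged, not resampled).
#'
#' @param path CSV path.
#' @return An `intensity_curves` object.
#' @export
parse_recordings <- function(path) {
  if (!file.exists(path)) stop_odorhab("recordings file not found: ", path)
  long <- data.table::fread(path)
  required <- c("subject_id", "odorant_id", "time_s", "intensity")
  missing <- setdiff(required, names(long))
  if (length(missing)) {
    stop_odorhab("recordings file is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  if (!is.numeric(long$intensity)) {
    stop_odorhab("non-numeric intensity values in recordings file")
  }
  if (anyNA(long$intensity)) {
    stop_odorhab("missing intensity values in row(s) ",
                 paste(utils::head(which(is.na(long$intensity)), 3),
                       collapse = ", "))
  }
  out_of_range <- which(long$intensity < 0 | long$intensity > 100)
  if (length(out_of_range)) {
    stop_odorhab("intensity outside [0, 100] at row(s) ",
                 paste(utils::head(out_of_range, 3), collapse = ", "),
                 " (first value ", long$intensity[out_of_range[1]], ")")
  }
  dup <- duplicated(long[, c("subject_id", "odorant_id", "time_s")])
  if (any(dup)) {
    stop_odorhab("duplicated (subject, odorant, time) at row ", which(dup)[1])
  }
  key <- paste(long$subject_id, long$odorant_id, sep = "\r")
  lens <- table(key)
  n_keep <- as.integer(stats::median(lens))
  bad <- names(lens)[lens != n_keep]
  if (length(bad)) {
    warning(length(bad), " curve(s) with irregular length dropped",
            call. = FALSE)
    long <- long[!key %in% bad, ]
    key <- key[!key %in% bad]
  }
  ord <- order(key, long$time_s, method = "radix")
  long <- long[ord, ]
  ukey <- unique(key[ord])
  time <- long$time_s[seq_len(n_keep)]
  mat <- matrix(long$intensity, ncol = n_keep, byrow = TRUE)
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  info <- data.frame(subject = parts[, 1], odorant = parts[, 2],
                     stringsAsFactors = FALSE)
  intensity_curves(mat, info, time)
}
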