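#' k-means clustering of habituation curves
#'
#' Clusters (normalized) intensity curves with squared-Euclidean k-means,
#' using k-means++ seeding and keeping the best of `n_restarts` runs by the
#' within-cluster sum of squares. Deterministic under a fixed seed.
#'
#' @param curves An [intensity_curves()] object (normally after
#'   [normalize_intensity()]).
#' @param k Number of clusters.
#' @param n_restarts Number of seeded restarts.
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return A `centroid_set`: list with `k`, `centers` (k x n_samples),
#'   `assignment`, `tot_withinss`, `size`, `time`, and (after
#'   [label_centroids()]) a `labels` vector naming each centroid
#'   `low_hab` / `mid_hab` / `high_hab`.
#' @export
kmeans_curves <- function(curves, k, n_restarts = 50L, seed = 1L,
                          iter_max = 100L) {
  x <- curves$intensity
  if (k > nrow(x)) stop_odorhab("k = ", k, " exceeds the ", nrow(x),
                                " available curves")
  if (k < 1L) stop_odorhab("k must be >= 1")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers0 <- kmeanspp_init(x, k)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers0, iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop_odorhab("k-means failed on every restart")
    structure(list(k = k,
                   centers = unname(best$centers),
                   assignment = unname(best$cluster),
                   tot_withinss = best$tot.withinss,
                   withinss = best$withinss,
                   size = best$size,
                   time = curves$time,
                   labels = NULL),
              class = "centroid_set")
  })
}

# k-means++ seeding: spread initial centers with probability proportional to
# squared distance from the nearest already-chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' @export
print.centroid_set <- function(x, ...) {
  cat("centroid_set: k =", x$k, " sizes:", paste(x$size, collapse = "/"),
      " tot.withinss:", format(x$tot_withinss, digits = 6), "\n")
  if (!is.null(x$labels)) cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette across candidate numbers of clusters
#'
#' Runs [kmeans_curves()] for each k in `k_range` and reports the mean
#' silhouette width under the Euclidean distance, the criterion used to pick
#' the number of habituation profiles (k = 3 in the study design).
#'
#' @inheritParams kmeans_curves
#' @param k_range Integer vector of candidate k (all must satisfy
#'   2 <= k <= n - 1).
#' @return Named numeric vector: mean silhouette per k.
#' @export
silhouette_profile <- function(curves, k_range = 2:6, n_restarts = 20L,
                               seed = 1L) {
  n <- n_curves(curves)
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop_odorhab("k_range must lie within [2, n_curves - 1]")
  }
  d <- stats::dist(curves$intensity)
  out <- vapply(k_range, function(k) {
    cs <- kmeans_curves(curves, k, n_restarts = n_restarts, seed = seed)
    sil <- cluster::silhouette(cs$assignment, d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  stats::setNames(out, as.character(k_range))
}

#' Label three centroids as low / mid / high habituation
#'
#' Orders the k = 3 centroids by their terminal intensity (mean over the last
#' `terminal_s` seconds): the centroid retaining the most intensity shows the
#' least habituation (`low_hab`), the one retaining the least shows the most
#' (`high_hab`). Ties are broken by total area under the curve; an exact tie
#' is an error.
#'
#' @param cs A `centroid_set` with k = 3.
#' @param terminal_s Length (s) of the terminal window.
#' @return The `centroid_set` with a `labels` vector
#'   (`low_hab`/`mid_hab`/`high_hab`) aligned with the centroid rows.
#' @export
label_centroids <- function(cs, terminal_s = 30) {
  if (cs$k != 3L) stop_odorhab("labelling requires k = 3 centroids")
  window <- cs$time >= (max(cs$time) - terminal_s)
  terminal <- rowMeans(cs$centers[, window, drop = FALSE])
  auc <- rowSums(cs$centers)
  if (anyDuplicated(terminal)) {
    if (anyDuplicated(cbind(terminal, auc))) {
      stop_odorhab("centroids are exactly tied; cannot label habituation order")
    }
  }
  ord <- order(-terminal, -auc)  # most retained intensity first
  labels <- character(3L)
  labels[ord] <- c("low_hab", "mid_hab", "high_hab")
  cs$labels <- labels
  cs
}

#' City-block distance of every curve to each labelled centroid
#'
#' For each curve, the distance to a centroid is the sum over all samples of
#' the absolute intensity difference. The columns are ordered
#' `d_low`, `d_mid`, `d_high` by centroid label.
#'
#' @param curves An [intensity_curves()] object.
#' @param cs A labelled `centroid_set` (see [label_centroids()]).
#' @return Data frame: `subject`, `odorant`, `d_low`, `d_mid`, `d_high`.
#' @export
cityblock_to_centroids <- function(curves, cs) {
  if (is.null(cs$labels)) stop_odorhab("centroid set must be labelled first")
  if (ncol(curves$intensity) != ncol(cs$centers)) {
    stop_odorhab("curve length (", ncol(curves$intensity),
                 ") does not match centroid length (", ncol(cs$centers), ")")
  }
  idx <- match(c("low_hab", "mid_hab", "high_hab"), cs$labels)
  d <- sapply(idx, function(i) {
    rowSums(abs(sweep(curves$intensity, 2L, cs$centers[i, ])))
  })
  d <- matrix(d, ncol = 3L, dimnames = list(NULL, c("d_low", "d_mid", "d_high")))
  cbind(curves$info[, c("subject", "odorant")], as.data.frame(d))
}

#' Build the habituation space from per-curve centroid distances
#'
#' Each odorant's coordinates are the medians, over its retained curves, of
#' the city-block distances to the low/mid/high habituation centroids. A
#' larger coordinate means less similarity to that habituation profile.
#'
#' @param distances Data frame from [cityblock_to_centroids()].
#' @param odorants Optional character vector of all expected odorant ids;
#'   ids with zero retained curves are dropped with a warning.
#' @return A `habituation_space`: data frame with one row per odorant and
#'   columns `odorant`, `d_low`, `d_mid`, `d_high`; the per-curve distance
#'   table is kept in the `"curve_distances"` attribute for the mixed models.
#' @export
build_habituation_space <- function(distances, odorants = NULL) {
  stopifnot(all(c("odorant", "d_low", "d_mid", "d_high") %in% names(distances)))
  empty <- setdiff(odorants, unique(distances$odorant))
  if (length(empty)) {
    warning("odorant(s) without retained curves excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  agg <- stats::aggregate(distances[, c("d_low", "d_mid", "d_high")],
                          by = list(odorant = distances$odorant),
                          FUN = stats::median)
  agg <- agg[order(agg$odorant), ]
  rownames(agg) <- NULL
  structure(agg, class = c("habituation_space", "data.frame"),
            curve_distances = distances)
}

#' @export
print.habituation_space <- function(x, ...) {
  cat("habituation_space:", nrow(x), "odorants ",
      "(median city-block distance to low/mid/high habituation centroids)\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
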