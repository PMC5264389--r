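make_curves <- function(mat, time = seq(0, by = 0.25,
                                        length.out = ncol(mat))) {
  intensity_curves(mat, data.frame(subject = paste0("s", seq_len(nrow(mat))),
                                   odorant = "o"), time)
}

test_that("k-means basics: k = 1 mean, best-of-restarts, bundle recovery", {
  set.seed(31)
  mat <- matrix(rnorm(20 * 50, mean = 50), 20, 50)
  curves <- make_curves(mat)
  cs1 <- kmeans_curves(curves, 1, n_restarts = 3, seed = 1)
  expect_equal(as.vector(cs1$centers), colMeans(mat), tolerance = 1e-12)

  # two well-separated bundles
  bundle <- rbind(matrix(rnorm(10 * 50, 20), 10, 50),
                  matrix(rnorm(10 * 50, 80), 10, 50))
  bc <- make_curves(bundle)
  cs2 <- kmeans_curves(bc, 2, n_restarts = 5, seed = 1)
  expect_length(unique(cs2$assignment[1:10]), 1L)
  expect_length(unique(cs2$assignment[11:20]), 1L)
  expect_false(cs2$assignment[1] == cs2$assignment[11])

  # the returned solution is at least as good as any single restart
  multi <- kmeans_curves(curves, 3, n_restarts = 20, seed = 5)
  singles <- vapply(1:10, function(s) {
    kmeans_curves(curves, 3, n_restarts = 1, seed = s)$tot_withinss
  }, numeric(1))
  expect_true(all(multi$tot_withinss <= singles + 1e-9))

  expect_error(kmeans_curves(curves, 21), "exceeds")
})

test_that("clustering is deterministic under a fixed seed", {
  coh <- clean_cohort(seed = 33, n_subjects = 3)
  nc <- normalize_intensity(coh$curves)
  a <- kmeans_curves(nc, 3, n_restarts = 5, seed = 9)
  b <- kmeans_curves(nc, 3, n_restarts = 5, seed = 9)
  expect_identical(a$centers, b$centers)
  expect_identical(a$assignment, b$assignment)
})

test_that("silhouette profile matches a brute-force oracle and finds k = 3", {
  # hand-made points: two tight trios far apart
  pts <- rbind(matrix(c(0, 0, 0.1, 0, 0, 0.1), 3, 2, byrow = TRUE),
               matrix(c(10, 10, 10.1, 10, 10, 10.1), 3, 2, byrow = TRUE))
  curves <- make_curves(pts)
  prof <- silhouette_profile(curves, k_range = 2, n_restarts = 5, seed = 1)
  cs <- kmeans_curves(curves, 2, n_restarts = 5, seed = 1)
  oracle <- silhouette_brute(dist(pts), cs$assignment)
  expect_equal(unname(prof["2"]), oracle, tolerance = 1e-12)

  # mutually equidistant degenerate points give mean silhouette ~ 0
  eq <- make_curves(diag(6))
  prof_eq <- silhouette_profile(eq, k_range = 2, n_restarts = 5, seed = 1)
  expect_lt(abs(prof_eq["2"]), 1e-8)

  expect_error(silhouette_profile(curves, k_range = 1), "k_range")

  # three separated decay families: silhouette argmax at k = 3
  coh <- three_family_cohort(seed = 35)
  nc <- normalize_intensity(coh$curves)
  prof3 <- silhouette_profile(nc, k_range = 2:5, n_restarts = 10, seed = 1)
  expect_equal(names(which.max(prof3)), "3")
})

test_that("centroid labelling follows terminal intensity", {
  time <- seq(0, 120, by = 0.25)
  centers <- rbind(1 - 0.1 * time / 120,   # ends at 0.9
                   1 - 0.5 * time / 120,   # ends at 0.5
                   1 - 0.9 * time / 120)   # ends at 0.1
  cs <- structure(list(k = 3L, centers = centers, time = time,
                       assignment = rep(1:3, 2), labels = NULL),
                  class = "centroid_set")
  lab <- label_centroids(cs)
  expect_identical(lab$labels, c("low_hab", "mid_hab", "high_hab"))

  # a flat centroid at 1.0 shows no decrement: low habituation
  cs$centers <- rbind(rep(1, 481), 1 - 0.5 * time / 120, 1 - 0.9 * time / 120)
  expect_identical(label_centroids(cs)$labels[1], "low_hab")

  cs$centers <- rbind(rep(1, 481), rep(1, 481), 1 - 0.5 * time / 120)
  expect_error(label_centroids(cs), "tied")

  # synthetic three-family cohort: labels match the decay-rate order
  coh <- three_family_cohort(seed = 37)
  nc <- normalize_intensity(coh$curves)
  cs3 <- label_centroids(kmeans_curves(nc, 3, n_restarts = 10, seed = 1))
  for (od in c("slow", "mid", "fast")) {
    rows <- nc$info$odorant == od
    major <- as.integer(names(which.max(table(cs3$assignment[rows]))))
    expected <- c(slow = "low_hab", mid = "mid_hab", fast = "high_hab")[[od]]
    expect_identical(cs3$labels[major], expected)
  }
})

test_that("city-block distances match the brute-force oracle", {
  coh <- clean_cohort(seed = 39, n_subjects = 2)
  nc <- normalize_intensity(coh$curves)
  cs <- label_centroids(kmeans_curves(nc, 3, n_restarts = 5, seed = 1))
  d <- cityblock_to_centroids(nc, cs)

  # identity and constant-offset checks
  ctr_curves <- intensity_curves(cs$centers,
                                 data.frame(subject = "c", odorant = 1:3),
                                 cs$time)
  d_ctr <- cityblock_to_centroids(ctr_curves, cs)
  low_row <- match("low_hab", cs$labels)
  expect_equal(d_ctr$d_low[low_row], 0, tolerance = 1e-12)

  shifted <- ctr_curves
  shifted$intensity <- shifted$intensity + 0.1
  d_shift <- cityblock_to_centroids(shifted, cs)
  expect_equal(d_shift$d_low[low_row], 48.1, tolerance = 1e-9)

  # random pairs vs loop-summed oracle
  for (i in c(1, 10, 25)) {
    expect_equal(d$d_mid[i],
                 cityblock_brute(nc$intensity[i, ],
                                 cs$centers[match("mid_hab", cs$labels), ]),
                 tolerance = 1e-9)
  }

  # metric properties on random triples
  set.seed(40)
  for (r in 1:5) {
    idx <- sample(n_curves(nc), 3)
    x <- nc$intensity[idx[1], ]; y <- nc$intensity[idx[2], ]
    z <- nc$intensity[idx[3], ]
    expect_equal(cityblock_brute(x, y), cityblock_brute(y, x))
    expect_lte(cityblock_brute(x, z),
               cityblock_brute(x, y) + cityblock_brute(y, z) + 1e-9)
  }

  expect_error(cityblock_to_centroids(make_curves(matrix(1, 2, 5)), cs),
               "length")
})

test_that("relabelling centroids permutes but never alters distances", {
  coh <- clean_cohort(seed = 41, n_subjects = 2)
  nc <- normalize_intensity(coh$curves)
  cs <- label_centroids(kmeans_curves(nc, 3, n_restarts = 5, seed = 1))
  d1 <- cityblock_to_centroids(nc, cs)
  cs_perm <- cs
  perm <- c(2, 3, 1)
  cs_perm$centers <- cs$centers[perm, ]
  cs_perm$labels <- cs$labels[perm]
  d2 <- cityblock_to_centroids(nc, cs_perm)
  expect_equal(d1[c("d_low", "d_mid", "d_high")],
               d2[c("d_low", "d_mid", "d_high")])
})

test_that("habituation space takes per-odorant medians", {
  d <- data.frame(subject = c("a", "a", "b", "b", "c", "c"),
                  odorant = rep(c("x", "y"), 3),
                  d_low = c(1, 10, 2, 20, 3, 30),
                  d_mid = c(4, 40, 5, 50, 6, 60),
                  d_high = c(7, 70, 8, 80, 9, 90))
  sp <- build_habituation_space(d)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$d_low, c(2, 20))   # middle order statistic, odd n
  expect_equal(sp$d_mid, c(5, 50))

  one <- build_habituation_space(d[1:2, ])
  expect_equal(one$d_low, d$d_low[1:2])

  expect_warning(build_habituation_space(d, odorants = c("x", "y", "ghost")),
                 "ghost")

  # lower decay rate => closer to the low-habituation centroid
  coh <- three_family_cohort(seed = 43)
  nc <- normalize_intensity(coh$curves)
  cs <- label_centroids(kmeans_curves(nc, 3, n_restarts = 10, seed = 1))
  sp3 <- build_habituation_space(cityblock_to_centroids(nc, cs))
  expect_lt(sp3$d_low[sp3$odorant == "slow"],
            sp3$d_low[sp3$odorant == "fast"])
  expect_lt(sp3$d_high[sp3$odorant == "fast"],
            sp3$d_high[sp3$odorant == "slow"])
})
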