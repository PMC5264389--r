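# Shared fixture builders (all generated in code at test time).

# A small contaminated cohort for exclusion arithmetic: 12 recruited
# subjects, 1 absent, 2 chaotic, 5 delayed curves over 2 subjects.
small_cohort <- function(seed = 11, noise_sd = 1) {
  cfg <- cohort_config(n_subjects = 12, n_absent_subjects = 1,
                       n_chaotic_subjects = 2, n_delayed_curves = 5,
                       n_delayed_subjects = 2)
  generate_cohort(cfg, generative_truth(seed = seed, noise_sd = noise_sd))
}

# A clean cohort without any contamination.
clean_cohort <- function(seed = 7, n_subjects = 6,
                         odorants = odorant_descriptors(), ...) {
  cfg <- cohort_config(n_subjects = n_subjects, odorants = odorants,
                       n_absent_subjects = 0, n_chaotic_subjects = 0,
                       n_delayed_curves = 0, n_delayed_subjects = 0)
  generate_cohort(cfg, generative_truth(seed = seed, ...))
}

# Three well-separated decay families (decay rates 0.002 / 0.02 / 0.2 per s)
# rated by `n_per` subjects each: the constructed case where silhouette
# analysis should pick k = 3 and labels should follow the decay-rate order.
three_family_cohort <- function(seed, n_per = 15) {
  od <- data.frame(Abb = c("slow", "mid", "fast"), rate = c(1, 2, 3))
  cfg <- cohort_config(n_subjects = n_per, odorants = od,
                       n_absent_subjects = 0, n_chaotic_subjects = 0,
                       n_delayed_curves = 0, n_delayed_subjects = 0,
                       sensory_coefficients = list())
  tr <- generative_truth(driver_coefficients = c(rate = log(10)),
                         baseline_decay_rate = 0.02, noise_sd = 1,
                         rater_sd = 1, lambda_range = c(0.002, 0.25),
                         seed = seed)
  generate_cohort(cfg, tr)
}

# Parameter-recovery cohort: 64 synthetic odorants with 13 iid standard
# normal descriptors (D1-D3 drive the decay rate, D4-D13 are nuisance), a
# 4-level categorical and pure-noise sensory ratings; 16 subjects.
recovery_cohort <- function(seed) {
  set.seed(seed + 500000L)
  od <- data.frame(Abb = sprintf("O%02d", 1:64))
  for (j in 1:13) od[[paste0("D", j)]] <- rnorm(64)
  od$grp <- sample(LETTERS[1:4], 64, replace = TRUE)
  cfg <- cohort_config(n_subjects = 16, odorants = od,
                       n_absent_subjects = 0, n_chaotic_subjects = 0,
                       n_delayed_curves = 0, n_delayed_subjects = 0,
                       sensory_coefficients = list(
                         intensity = numeric(0), pleasantness = numeric(0),
                         familiarity = numeric(0), trigeminality = numeric(0)))
  tr <- generative_truth(driver_coefficients = c(D1 = -0.8, D2 = 0.7,
                                                 D3 = 0.7),
                         baseline_decay_rate = 0.03, noise_sd = 3,
                         rater_sd = 5, lambda_range = c(0.002, 0.5),
                         seed = seed)
  list(cohort = generate_cohort(cfg, tr), descriptors = od)
}

# Run the clustering -> habituation space -> PLS -> VIP chain on a recovery
# cohort and report whether the drivers hold the top-3 VIPs with the correct
# directions (D1: less habituation when up; D2, D3: when down).
recovery_result <- function(seed) {
  rc <- recovery_cohort(seed)
  nc <- normalize_intensity(rc$cohort$curves)
  cs <- label_centroids(kmeans_curves(nc, 3, n_restarts = 5, seed = seed))
  dd <- cityblock_to_centroids(nc, cs)
  sp <- build_habituation_space(dd)
  X <- assemble_x(rc$descriptors, rc$cohort$ratings,
                  numeric_vars = paste0("D", 1:13), categorical_vars = "grp")
  Y <- assemble_y(sp, odorant_order = rownames(X))
  f <- fit_pls(autoscale(X), autoscale(Y), 4)
  v <- odorhab::vip(f)
  det <- interpret_pls(f)$determinants
  dirs <- stats::setNames(det$direction, det$variable)
  list(top3 = setequal(names(sort(v, decreasing = TRUE))[1:3],
                       c("D1", "D2", "D3")),
       signs = identical(unname(dirs[c("D1", "D2", "D3")]),
                         c("up", "down", "down")))
}

# Balanced distance-style data with no odorant effect and a subject random
# intercept, for type-I calibration of the mixed model.
null_lmm_data <- function(seed, n_subjects = 20, n_odorants = 8,
                          subject_sd = 1) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("s%02d", seq_len(n_subjects)),
                   odorant = sprintf("o%02d", seq_len(n_odorants)),
                   stringsAsFactors = FALSE)
  eff <- stats::setNames(rnorm(n_subjects, 0, subject_sd),
                         unique(d$subject))
  d$d_low <- 10 + eff[d$subject] + rnorm(nrow(d))
  d$d_mid <- d$d_low
  d$d_high <- d$d_low
  d
}
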