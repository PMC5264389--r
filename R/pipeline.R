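#' Configuration of the end-to-end habituation pipeline
#'
#' Collects the paths and thresholds of every stage. With `recordings = NULL`
#' the pipeline simulates its own cohort ([generate_cohort()]); otherwise it
#' reads the recordings, descriptor and ratings CSVs.
#'
#' @param recordings,descriptors,ratings Input CSV paths (all `NULL` to
#'   simulate).
#' @param out_dir Output directory for every intermediate artifact; `NULL`
#'   keeps everything in memory.
#' @param cohort,truth Simulation settings (see [cohort_config()] and
#'   [generative_truth()]).
#' @param rules Exclusion thresholds ([exclusion_rules()]).
#' @param k Number of habituation clusters.
#' @param k_range Candidate k for the silhouette profile (`NULL` skips it).
#' @param n_restarts k-means restarts.
#' @param seed Seed for clustering (and OAV synthesis if needed).
#' @param alpha Significance level of the pairwise comparisons.
#' @param ncomp_max Largest PLS component count tried (`NULL` = maximum
#'   supported by the data).
#' @param lw_threshold,loading_threshold,vip_threshold Interpretation
#'   thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(recordings = NULL, descriptors = NULL,
                            ratings = NULL, out_dir = NULL,
                            cohort = cohort_config(),
                            truth = generative_truth(),
                            rules = exclusion_rules(),
                            k = 3L, k_range = 2:6, n_restarts = 50L,
                            seed = 1L, alpha = 0.05, ncomp_max = NULL,
                            lw_threshold = 0.3, loading_threshold = 0.2,
                            vip_threshold = 1) {
  stopifnot(k >= 2L, alpha > 0, alpha < 1,
            lw_threshold > 0, loading_threshold > 0, vip_threshold > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full habituation analysis pipeline
#'
#' Stages: data (simulate or parse) -> exclusions + normalization ->
#' clustering (optional silhouette profile, k-means, centroid labelling,
#' city-block distances, habituation space) -> mixed models per coordinate
#' with FDR pairwise comparisons -> design matrices -> PLS with
#' leave-one-out component selection, explained variance, VIP and
#' interpretation. When `config$out_dir` is set every intermediate artifact
#' is written as CSV/JSON together with a run manifest.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with every stage's result.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) data.table::fwrite(as.data.frame(df),
                                              file.path(out_dir, name))
  }
  emit_json <- function(x, name) {
    if (!is.null(out_dir)) jsonlite::write_json(
      x, file.path(out_dir, name), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  # -- stage: data ----------------------------------------------------------
  simulated <- is.null(config$recordings)
  if (simulated) {
    message("stage data: simulating cohort")
    cohort <- generate_cohort(config$cohort, config$truth)
    curves <- cohort$curves
    descriptors <- config$cohort$odorants
    ratings <- cohort$ratings
  } else {
    message("stage data: parsing recordings")
    for (f in c(config$recordings, config$descriptors, config$ratings)) {
      if (!is.null(f) && !file.exists(f)) {
        stop_odorhab("input file not found: ", f)
      }
    }
    cohort <- NULL
    curves <- parse_recordings(config$recordings)
    descriptors <- odorant_descriptors(config$descriptors)
    ratings <- if (!is.null(config$ratings)) {
      as.data.frame(data.table::fread(config$ratings))
    }
  }

  # -- stage: preprocess ----------------------------------------------------
  message("stage preprocess: exclusions + normalization")
  excl <- apply_exclusions(curves, config$rules)
  retained <- normalize_intensity(excl$curves)
  emit(excl$report$reasons, "exclusion_reasons.csv")
  emit_json(excl$report[c("n_input_curves", "n_absent_excluded",
                          "n_chaotic_excluded", "n_delay_excluded",
                          "n_retained", "absent_subjects",
                          "chaotic_subjects")], "exclusion_report.json")
  if (!is.null(out_dir)) {
    write_recordings(retained, file.path(out_dir, "retained_curves.csv"))
  }

  # -- stage: clustering ----------------------------------------------------
  message("stage cluster: k-means habituation profiles")
  sil <- NULL
  if (!is.null(config$k_range)) {
    sil <- silhouette_profile(retained, config$k_range,
                              n_restarts = max(5L, config$n_restarts %/% 5L),
                              seed = config$seed)
    emit(data.frame(k = as.integer(names(sil)), mean_silhouette = sil),
         "silhouette_profile.csv")
  }
  cs <- label_centroids(kmeans_curves(retained, config$k,
                                      n_restarts = config$n_restarts,
                                      seed = config$seed))
  distances <- cityblock_to_centroids(retained, cs)
  space <- build_habituation_space(distances,
                                   odorants = unique(curves$info$odorant))
  emit(cbind(label = cs$labels, as.data.frame(cs$centers)), "centroids.csv")
  emit(distances, "curve_distances.csv")
  emit(as.data.frame(space), "habituation_space.csv")

  # -- stage: mixed models --------------------------------------------------
  message("stage regress: mixed models per coordinate")
  lmm <- lapply(c(low = "low", mid = "mid", high = "high"), function(coord) {
    fit <- fit_odorant_lmm(distances, coord)
    pw <- pairwise_fdr(fit, alpha = config$alpha)
    list(fit = fit, pairwise = pw)
  })
  omnibus <- do.call(rbind, lapply(lmm, function(l) {
    data.frame(coordinate = l$fit$coordinate, F = l$fit$F,
               num_df = l$fit$num_df, den_df = l$fit$den_df,
               p_value = l$fit$p_value,
               n_significant_pairs = l$pairwise$n_significant)
  }))
  rownames(omnibus) <- NULL
  emit(omnibus, "lmm_omnibus.csv")
  for (coord in names(lmm)) {
    emit(lmm[[coord]]$pairwise$table, paste0("lmm_pairwise_", coord, ".csv"))
  }

  # -- stage: PLS -----------------------------------------------------------
  message("stage report: design matrices + PLS")
  if (anyNA(descriptors$OAV)) {
    descriptors <- synthesize_oav(descriptors, seed = config$seed)
  }
  retained_subjects <- unique(retained$info$subject)
  ratings_used <- if (!is.null(ratings) && "subject" %in% names(ratings)) {
    ratings[ratings$subject %in% retained_subjects, ]
  } else ratings
  X <- assemble_x(descriptors, ratings_used)
  keep <- rownames(X) %in% space$odorant
  X <- X[keep, , drop = FALSE]
  Y <- assemble_y(space, odorant_order = rownames(X))
  rmsep <- loo_rmsep(X, Y, ncomp_max = config$ncomp_max)
  ncomp <- select_components(rmsep)
  fit <- fit_pls(autoscale(X), autoscale(Y), ncomp$global)
  ev <- explained_variance(fit)
  v <- vip(fit)
  interp <- interpret_pls(fit, config$lw_threshold,
                          config$loading_threshold, config$vip_threshold)
  emit(cbind(odorant = rownames(X), as.data.frame(unclass(X))), "X_matrix.csv")
  emit(cbind(odorant = rownames(Y), as.data.frame(Y)), "Y_matrix.csv")
  emit_json(attr(X, "meta"), "X_metadata.json")
  emit(cbind(component = rownames(rmsep), as.data.frame(rmsep)), "rmsep.csv")
  emit(data.frame(component = names(ev$X), X = ev$X,
                  as.data.frame(ev$Y)), "explained_variance.csv")
  emit(data.frame(variable = names(v), vip = v), "vip.csv")
  emit(cbind(variable = rownames(fit$weights),
             as.data.frame(fit$weights)), "loading_weights.csv")
  emit(interp$determinants, "determinants.csv")
  emit_json(list(per_response = as.list(ncomp$per_response),
                 global = ncomp$global), "selected_components.json")

  manifest <- list(
    package = "odorhab",
    version = as.character(utils::packageVersion("odorhab")),
    seed = config$seed,
    simulated = simulated,
    n_input_curves = excl$report$n_input_curves,
    n_retained = excl$report$n_retained,
    n_samples_per_curve = length(retained$time),
    n_odorants = nrow(space),
    k = config$k,
    silhouette = as.list(sil),
    ncomp_global = ncomp$global,
    x_dim = dim(X),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  emit_json(manifest, "manifest.json")

  structure(list(cohort = cohort, exclusion = excl$report,
                 curves = retained, silhouette = sil, centroids = cs,
                 distances = distances, space = space, lmm = lmm,
                 omnibus = omnibus, X = X, Y = Y, rmsep = rmsep,
                 ncomp = ncomp, fit = fit, explained = ev, vip = v,
                 interpretation = interp, manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  curves: %d retained of %d (%d samples each)\n",
              x$manifest$n_retained, x$manifest$n_input_curves,
              x$manifest$n_samples_per_curve))
  cat(sprintf("  clustering: k = %d; PLS components: %d; X: %d x %d\n",
              x$manifest$k, x$manifest$ncomp_global,
              x$manifest$x_dim[1], x$manifest$x_dim[2]))
  print(x$omnibus)
  print(x$interpretation)
  invisible(x)
}
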