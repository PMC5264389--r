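#' Mixed model for odorant differences in one habituation coordinate
#'
#' Fits, by maximum likelihood, a linear mixed model of one centroid-distance
#' coordinate on the odorant factor with a subject random intercept:
#' `distance ~ odorant, random = ~ 1 | subject`. The omnibus F for the
#' odorant factor (conditional F-test) says whether odorants differ in their
#' similarity to that habituation profile.
#'
#' @param distances Per-curve distance table from
#'   [cityblock_to_centroids()] (columns `subject`, `odorant`, `d_low`,
#'   `d_mid`, `d_high`).
#' @param coordinate Which coordinate to model: `"low"`, `"mid"` or `"high"`.
#' @return An `odorant_lmm`: list with the `nlme::lme` fit, the coordinate,
#'   and the omnibus `F`, `num_df`, `den_df`, `p_value`.
#' @export
fit_odorant_lmm <- function(distances, coordinate = c("low", "mid", "high")) {
  coordinate <- match.arg(coordinate)
  col <- paste0("d_", coordinate)
  stopifnot(all(c("subject", "odorant", col) %in% names(distances)))
  dat <- data.frame(subject = factor(distances$subject),
                    odorant = factor(distances$odorant),
                    distance = distances[[col]])
  if (nlevels(dat$odorant) < 2L) {
    stop_odorhab("need at least two odorants to test odorant differences")
  }
  if (nlevels(dat$subject) < 2L) {
    stop_odorhab("need at least two subjects for a subject random effect")
  }
  # do.call embeds the data object in the call so emmeans can recover it.
  fit <- do.call(nlme::lme,
                 list(fixed = distance ~ odorant, random = ~ 1 | subject,
                      data = dat, method = "ML"))
  an <- stats::anova(fit)
  row <- an["odorant", ]
  structure(list(fit = fit, coordinate = coordinate,
                 F = unname(row[["F-value"]]),
                 num_df = unname(row[["numDF"]]),
                 den_df = unname(row[["denDF"]]),
                 p_value = unname(row[["p-value"]])),
            class = "odorant_lmm")
}

#' @export
print.odorant_lmm <- function(x, ...) {
  cat(sprintf("odorant_lmm (%s hab): F[%d, %d] = %.2f, p = %.3g\n",
              x$coordinate, x$num_df, x$den_df, x$F, x$p_value))
  invisible(x)
}

#' FDR-corrected pairwise odorant comparisons
#'
#' All pairwise contrasts of the odorant means from the mixed-model fit
#' (Tukey-style all-pairs contrasts), with Benjamini-Hochberg adjustment of
#' the contrast p-values and a count of contrasts significant at `alpha`.
#'
#' @param x An `odorant_lmm` from [fit_odorant_lmm()].
#' @param alpha Significance level on the adjusted p-values.
#' @return A list with `table` (contrast, estimate, SE, df, t, p, adjusted p)
#'   and `n_significant`.
#' @export
pairwise_fdr <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "odorant_lmm"))
  emm <- emmeans::emmeans(x$fit, "odorant")
  tab <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  tab$p_adj <- stats::p.adjust(tab$p.value, method = "BH")
  list(table = tab,
       n_significant = sum(tab$p_adj < alpha),
       alpha = alpha,
       coordinate = x$coordinate)
}
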