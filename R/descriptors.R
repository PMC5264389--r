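#' Physicochemical descriptors of the 32 study odorants
#'
#' Loads the packaged descriptor table: one row per odorant with its CAS
#' number, abbreviation, name, accessible surface area (`ASA`), carbon chain
#' length (`C_chain`), hydrophobicity (`logP`), number of double bonds
#' (`Db_bonds`), number of conformers (`Conformers`), molecular weight (`Mw`),
#' saturated vapour pressure (`Vp`), olfactory family (`Ofamily`, 10 levels),
#' chemical family (`Cfamily`, 7 levels) and presentation session
#' (`Pres_order`, 4 levels).
#'
#' The odor activity value (`OAV`, ratio of the delivered concentration to the
#' detection threshold) is not distributed with the molecules' descriptor
#' sheet; the column is returned as `NA` and can be filled with a synthetic
#' stand-in via [synthesize_oav()]. `Pres_order` is likewise a synthetic
#' assignment of each odorant to one of the four testing sessions (odorants of
#' similar vapour pressure are grouped, mimicking iso-intensity session
#' design).
#'
#' @param path Path to a descriptor CSV. Defaults to the packaged fixture.
#' @return A `data.frame` with 32 rows and the columns above plus `OAV` (NA).
#' @export
#' @examples
#' d <- odorant_descriptors()
#' d[d$Abb == "Hex", c("Vp", "Mw", "C_chain", "logP")]
odorant_descriptors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "odorant_descriptors.csv",
                        package = "odorhab", mustWork = TRUE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("CAS", "Abb", "Name", "ASA", "C_chain", "logP", "Db_bonds",
                "Conformers", "Mw", "Vp", "Ofamily", "Cfamily", "Pres_order")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop_odorhab("descriptor table is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  num <- c("ASA", "C_chain", "logP", "Db_bonds", "Conformers", "Mw", "Vp")
  for (v in num) {
    if (!is.numeric(d[[v]]) || anyNA(d[[v]])) {
      stop_odorhab("descriptor integrity failure in field '", v,
                   "': non-numeric or missing values")
    }
  }
  if (anyDuplicated(d$Abb)) {
    stop_odorhab("descriptor integrity failure in field 'Abb': duplicated ids")
  }
  if (!"OAV" %in% names(d)) d$OAV <- NA_real_
  d
}

#' Synthesize odor activity values from vapour pressure
#'
#' The OAV of the study odorants is withheld from the published descriptor
#' table, but OAV is by definition tied to volatility (it is the ratio of
#' headspace concentration to detection threshold). This generates a
#' synthetic, clearly-labelled stand-in: log10(OAV) follows a linear trend in
#' the standardized log10 vapour pressure plus lognormal scatter, giving OAVs
#' spanning roughly 1-1000 with the most volatile odorants at the top.
#'
#' @param descriptors Descriptor table from [odorant_descriptors()].
#' @param seed Integer seed for the scatter; `NULL` leaves the RNG alone.
#' @param sd Standard deviation of the log10 scatter.
#' @return The descriptor table with the `OAV` column filled.
#' @export
synthesize_oav <- function(descriptors, seed = 1L, sd = 0.3) {
  lvp <- log10(descriptors$Vp)
  z <- (lvp - mean(lvp)) / stats::sd(lvp)
  with_seed(seed, {
    descriptors$OAV <- 10 ^ (1.5 + 0.7 * z + stats::rnorm(length(z), 0, sd))
  })
  descriptors
}

# Autoscaled numeric descriptor columns (internal; used by the generator).
descriptor_zscores <- function(descriptors, vars) {
  bad <- setdiff(vars, names(descriptors))
  if (length(bad)) {
    stop_odorhab("unknown descriptor variable(s): ", paste(bad, collapse = ", "))
  }
  z <- sapply(vars, function(v) {
    x <- descriptors[[v]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop_odorhab("descriptor '", v, "' has zero variance; cannot autoscale")
    }
    (x - mean(x)) / s
  })
  z <- matrix(z, nrow = nrow(descriptors),
              dimnames = list(descriptors$Abb, vars))
  z
}
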