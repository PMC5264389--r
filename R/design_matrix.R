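#' Assemble the explanatory (X) matrix
#'
#' Builds one row per odorant from 15 explanatory variables: 8 physicochemical
#' numerics (`ASA`, `C_chain`, `logP`, `Db_bonds`, `Conformers`, `Mw`, `Vp`,
#' `OAV`), 4 sensory attributes (per-odorant means of the 1-9 panel ratings),
#' and 3 categoricals (`Cfamily`, `Ofamily`, `Pres_order`) expanded into a
#' disjunctive (one-indicator-per-level) table. Because partial least squares
#' sees every indicator as a separate column, each indicator is divided by
#' its variable's level count so that no categorical variable is overweighted
#' relative to a single numeric column. On the study schema this yields
#' 12 + 7 + 10 + 4 = 33 columns.
#'
#' @param descriptors Descriptor table (see [odorant_descriptors()]) with a
#'   filled `OAV` column ([synthesize_oav()] provides a stand-in).
#' @param ratings Long ratings table (`subject`, `odorant`, plus the sensory
#'   columns), or an already-aggregated per-odorant table with an `odorant`
#'   column. `NULL` drops the sensory block.
#' @param numeric_vars,categorical_vars,sensory_vars Schema control.
#' @return Numeric matrix (odorants x columns) with row names from `Abb` and
#'   a `"meta"` attribute (data frame: column, source variable, is_indicator,
#'   rescale factor).
#' @export
assemble_x <- function(descriptors, ratings = NULL,
                       numeric_vars = c("ASA", "C_chain", "logP", "Db_bonds",
                                        "Conformers", "Mw", "Vp", "OAV"),
                       categorical_vars = c("Cfamily", "Ofamily", "Pres_order"),
                       sensory_vars = c("intensity", "pleasantness",
                                        "familiarity", "trigeminality")) {
  ids <- descriptors$Abb
  blocks <- list()
  meta <- list()
  for (v in numeric_vars) {
    x <- descriptors[[v]]
    if (is.null(x)) stop_odorhab("descriptor variable '", v, "' is missing")
    if (anyNA(x)) {
      stop_odorhab("variable '", v, "' has missing values",
                   if (v == "OAV") " (synthesize_oav() provides a stand-in)")
    }
    blocks[[v]] <- x
    meta[[v]] <- data.frame(column = v, source = v, is_indicator = FALSE,
                            rescale = 1)
  }
  if (!is.null(ratings) && length(sensory_vars)) {
    if (!"odorant" %in% names(ratings)) {
      stop_odorhab("ratings must have an 'odorant' column")
    }
    per_subject <- "subject" %in% names(ratings)
    for (v in sensory_vars) {
      if (is.null(ratings[[v]])) {
        stop_odorhab("sensory variable '", v, "' is missing from ratings")
      }
      m <- if (per_subject) {
        tapply(ratings[[v]], ratings$odorant, mean)
      } else stats::setNames(ratings[[v]], ratings$odorant)
      if (!all(ids %in% names(m))) {
        stop_odorhab("ratings are missing odorant(s): ",
                     paste(setdiff(ids, names(m)), collapse = ", "))
      }
      blocks[[v]] <- as.numeric(m[ids])
      meta[[v]] <- data.frame(column = v, source = v, is_indicator = FALSE,
                              rescale = 1)
    }
  }
  for (v in categorical_vars) {
    x <- descriptors[[v]]
    if (is.null(x)) stop_odorhab("categorical variable '", v, "' is missing")
    if (anyNA(x)) {
      stop_odorhab("categorical variable '", v, "' has a missing level for ",
                   "odorant ", ids[which(is.na(x))[1]])
    }
    levels_v <- sort(unique(as.character(x)))
    L <- length(levels_v)
    for (lev in levels_v) {
      cn <- paste(v, lev, sep = ".")
      blocks[[cn]] <- as.numeric(as.character(x) == lev) / L
      meta[[cn]] <- data.frame(column = cn, source = v, is_indicator = TRUE,
                               rescale = L)
    }
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- ids
  attr(X, "meta") <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  X
}

#' Assemble the response (Y) matrix
#'
#' Three columns per odorant: the median city-block distances to the low,
#' mid and high habituation centroids (`lowhab`, `midhab`, `highhab`). A
#' larger value means a larger distance, i.e. a LOWER similarity to that
#' habituation profile — interpretation of the regression must carry this
#' orientation.
#'
#' @param space A `habituation_space` from [build_habituation_space()].
#' @param odorant_order Character vector giving the row order that matches
#'   the X matrix (typically `rownames(X)`).
#' @return Numeric matrix (odorants x 3) with columns `lowhab`, `midhab`,
#'   `highhab`.
#' @export
assemble_y <- function(space, odorant_order = space$odorant) {
  if (!setequal(odorant_order, space$odorant) ||
      length(odorant_order) != nrow(space)) {
    stop_odorhab("odorant_order does not match the habituation space rows")
  }
  idx <- match(odorant_order, space$odorant)
  Y <- as.matrix(space[idx, c("d_low", "d_mid", "d_high")])
  dimnames(Y) <- list(odorant_order, c("lowhab", "midhab", "highhab"))
  Y
}

#' Autoscale a matrix (mean-center and unit-variance columns)
#'
#' Centers each column and divides by its standard deviation (n - 1
#' denominator). The means and scales are stored in the standard
#' `"scaled:center"` / `"scaled:scale"` attributes so the transform can be
#' inverted exactly.
#'
#' @param M Numeric matrix.
#' @param center,scale Logical switches (both on for autoscaling).
#' @return The scaled matrix with centering/scaling attributes.
#' @export
autoscale <- function(M, center = TRUE, scale = TRUE) {
  M <- as.matrix(M)
  if (scale) {
    sds <- apply(M, 2L, stats::sd)
    zero <- which(!is.finite(sds) | sds == 0)
    if (length(zero)) {
      nm <- colnames(M)[zero] %||% as.character(zero)
      stop_odorhab("zero-variance column(s): ", paste(nm, collapse = ", "))
    }
  }
  out <- scale(M, center = center, scale = scale)
  keep <- attributes(M)[setdiff(names(attributes(M)), c("dim", "dimnames"))]
  for (a in names(keep)) attr(out, a) <- keep[[a]]
  out
}

#' Invert an autoscaling transform
#'
#' @param M A matrix returned by [autoscale()].
#' @return The matrix on its original scale.
#' @export
unscale <- function(M) {
  ctr <- attr(M, "scaled:center")
  scl <- attr(M, "scaled:scale")
  out <- M
  if (!is.null(scl)) out <- sweep(out, 2L, scl, `*`)
  if (!is.null(ctr)) out <- sweep(out, 2L, ctr, `+`)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}
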