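#' Multi-response partial least squares regression (kernel algorithm)
#'
#' Fits a PLS2 regression of an autoscaled response matrix Y (here the three
#' habituation coordinates) on an autoscaled predictor matrix X, using the
#' kernel formulation: each component's weight vector is the dominant left
#' singular vector of the cross-product matrix X'Y of the deflated data,
#' which is algebraically equivalent to NIPALS up to per-component sign.
#' Components are sign-fixed so that the predictor with the largest absolute
#' weight has a positive weight (purely presentational; all derived
#' quantities are sign-invariant).
#'
#' @param X Autoscaled predictor matrix (n x p).
#' @param Y Autoscaled response matrix (n x q) or vector.
#' @param ncomp Number of components (at most `min(n - 1, p)`).
#' @return A `pls_fit`: list with `weights` W (p x A, unit-norm columns),
#'   `x_loadings` P (p x A), `y_loadings` Q (q x A), `scores` T (n x A,
#'   mutually orthogonal columns), `coefficients` (p x q x A array of
#'   regression coefficients using 1..a components), `explained_x` /
#'   `explained_y` (percent variance per component), `ss_component`
#'   (response sum of squares captured per component, pooled over responses
#'   and split per response in `ss_component_by_y`), `fitted` (n x q at
#'   `ncomp`), and the data dimensions.
#' @export
fit_pls <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop_odorhab("X and Y disagree on the number of rows")
  if (all(X == 0)) stop_odorhab("X is identically zero; nothing to fit")
  if (ncomp < 1L || ncomp > min(n - 1L, p)) {
    stop_odorhab("ncomp must lie in [1, min(n - 1, p)] = [1, ",
                 min(n - 1L, p), "]")
  }
  xn <- colnames(X) %||% paste0("x", seq_len(p))
  yn <- colnames(Y) %||% paste0("y", seq_len(q))

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); TT <- matrix(0, n, ncomp)
  ssx_total <- sum(X^2)
  ssy_total <- colSums(Y^2)
  Xa <- X; Ya <- Y
  for (a in seq_len(ncomp)) {
    S <- crossprod(Xa, Ya)
    if (sum(S^2) < 1e-300) {
      stop_odorhab("X'Y vanished at component ", a,
                   "; reduce ncomp (rank exhausted)")
    }
    w <- if (q == 1L) S[, 1L] else svd(S, nu = 1L, nv = 0L)$u[, 1L]
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w  # sign convention
    t_a <- as.vector(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- as.vector(crossprod(Xa, t_a)) / tt
    q_a <- as.vector(crossprod(Ya, t_a)) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    Ya <- Ya - tcrossprod(t_a, q_a)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a; TT[, a] <- t_a
  }
  dimnames(W) <- dimnames(P) <- list(xn, paste0("comp", seq_len(ncomp)))
  dimnames(Q) <- list(yn, colnames(W))
  dimnames(TT) <- list(rownames(X), colnames(W))

  tss <- colSums(TT^2)
  # Regression coefficients for models with 1..a components.
  B <- array(0, dim = c(p, q, ncomp), dimnames = list(xn, yn, colnames(W)))
  R <- W %*% solve(crossprod(P, W))  # transforms X directly to scores
  for (a in seq_len(ncomp)) {
    B[, , a] <- R[, seq_len(a), drop = FALSE] %*%
      t(Q[, seq_len(a), drop = FALSE])
  }
  explained_x <- 100 * tss * colSums(P^2) / ssx_total
  ss_by_y <- t(Q^2) * tss                      # A x q: SS captured per response
  explained_y <- 100 * sweep(ss_by_y, 2L, ssy_total, `/`)
  dimnames(explained_y) <- list(colnames(W), yn)
  structure(list(weights = W, x_loadings = P, y_loadings = Q, scores = TT,
                 coefficients = B,
                 projection = R,
                 explained_x = stats::setNames(explained_x, colnames(W)),
                 explained_y = explained_y,
                 ss_component = rowSums(ss_by_y),
                 ss_component_by_y = ss_by_y,
                 fitted = TT %*% t(Q),
                 ncomp = ncomp, n = n, p = p, q = q,
                 x_names = xn, y_names = yn),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("pls_fit: %d components, n = %d, p = %d, q = %d\n",
              x$ncomp, x$n, x$p, x$q))
  cat("  cumulative X variance explained:",
      sprintf("%.1f%%", sum(x$explained_x)), "\n")
  cat("  cumulative Y variance explained:",
      paste(sprintf("%s %.1f%%", x$y_names, colSums(x$explained_y)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a PLS fit
#'
#' @param object A `pls_fit`.
#' @param newdata Matrix on the same (autoscaled) predictor scale.
#' @param ncomp Number of components to use.
#' @param ... Unused.
#' @return Predicted response matrix on the (autoscaled) response scale.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = object$p)
  newdata %*% object$coefficients[, , ncomp]
}

#' Leave-one-out RMSEP per component and response
#'
#' For each left-out sample the autoscaling of X and Y is re-estimated on the
#' training fold (no leakage), the model refitted, and the prediction
#' returned to the original response units. `rmsep[a, r]` is the root mean
#' squared error of prediction of response r with a components.
#'
#' @param X,Y Unscaled predictor and response matrices.
#' @param ncomp_max Largest number of components (at most `min(n - 2, p)` so
#'   every fold can support it).
#' @return Matrix (ncomp_max x q) of RMSEP values in original Y units.
#' @export
loo_rmsep <- function(X, Y, ncomp_max = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L) stop_odorhab("leave-one-out needs at least 3 samples")
  ncomp_max <- ncomp_max %||% min(n - 2L, ncol(X))
  if (ncomp_max > min(n - 2L, ncol(X))) {
    stop_odorhab("ncomp_max must not exceed min(n - 2, p) = ",
                 min(n - 2L, ncol(X)))
  }
  sq_err <- array(0, dim = c(ncomp_max, ncol(Y), n))
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    # columns constant within the training fold (e.g. a categorical level
    # whose only member was left out) carry no in-fold information: drop them
    keep <- apply(Xi, 2L, function(x) stats::sd(x) > 0)
    Xtr <- autoscale(Xi[, keep, drop = FALSE])
    Ytr <- autoscale(Y[-i, , drop = FALSE])
    fit <- fit_pls(Xtr, Ytr, min(ncomp_max, sum(keep)))
    xi <- (X[i, keep] - attr(Xtr, "scaled:center")) /
      attr(Xtr, "scaled:scale")
    for (a in seq_len(ncomp_max)) {
      yi_hat <- as.vector(xi %*% fit$coefficients[, , min(a, fit$ncomp)]) *
        attr(Ytr, "scaled:scale") + attr(Ytr, "scaled:center")
      sq_err[a, , i] <- (Y[i, ] - yi_hat)^2
    }
  }
  out <- sqrt(apply(sq_err, c(1L, 2L), mean))
  dimnames(out) <- list(paste0("comp", seq_len(ncomp_max)),
                        colnames(Y) %||% paste0("y", seq_len(ncol(Y))))
  out
}

#' Choose the number of components from an RMSEP matrix
#'
#' Per response, the component count minimising RMSEP (smallest count on
#' ties); globally, the maximum over responses, so the retained model serves
#' every response at its best cross-validated error.
#'
#' @param rmsep Matrix from [loo_rmsep()].
#' @return List with `per_response` (named integer vector) and `global`.
#' @export
select_components <- function(rmsep) {
  per <- apply(rmsep, 2L, which.min)
  list(per_response = per, global = max(per))
}

#' Explained variance per component
#'
#' X side: share of the total (autoscaled) X sum of squares captured by each
#' component's rank-one reconstruction. Y side: incremental R-squared of the
#' a-component model over the (a-1)-component model, per response. Both in
#' percent; cumulative sums are non-decreasing.
#'
#' @param fit A `pls_fit`.
#' @return List with `X` (per-component %), `Y` (component x response %),
#'   and their cumulative versions.
#' @export
explained_variance <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  list(X = fit$explained_x,
       Y = fit$explained_y,
       cumulative_X = cumsum(fit$explained_x),
       cumulative_Y = apply(fit$explained_y, 2L, cumsum))
}

#' Variable importance in the projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SS_a * w_ja^2 / sum_a SS_a ), with unit-norm
#' weight vectors and SS_a the response sum of squares captured by component
#' a. By default SS pools the three responses (multi-response VIP); a
#' per-response variant returns one VIP column per response. The
#' normalisation identity sum_j VIP_j^2 = p holds exactly.
#'
#' @param fit A `pls_fit`.
#' @param ncomp Number of components entering the score (default: all).
#' @param pooled Pool SS over responses (default) or return per-response VIPs.
#' @return Named numeric vector of VIPs (or a p x q matrix if
#'   `pooled = FALSE`).
#' @export
vip <- function(fit, ncomp = fit$ncomp, pooled = TRUE) {
  stopifnot(inherits(fit, "pls_fit"), ncomp >= 1, ncomp <= fit$ncomp)
  a <- seq_len(ncomp)
  W2 <- fit$weights[, a, drop = FALSE]^2
  if (pooled) {
    ss <- fit$ss_component[a]
    if (sum(ss) <= 0) stop_odorhab("model explains no response variance")
    out <- sqrt(fit$p * as.vector(W2 %*% ss) / sum(ss))
    return(stats::setNames(out, fit$x_names))
  }
  ssq <- fit$ss_component_by_y[a, , drop = FALSE]
  out <- sapply(seq_len(fit$q), function(r) {
    ss <- ssq[, r]
    if (sum(ss) <= 0) stop_odorhab("model explains no variance of response ",
                                   fit$y_names[r])
    sqrt(fit$p * as.vector(W2 %*% ss) / sum(ss))
  })
  dimnames(out) <- list(fit$x_names, fit$y_names)
  out
}

#' Interpret a PLS fit: component composition and determinant ranking
#'
#' Per component, lists the responses whose (unit-normalised) loading exceeds
#' `loading_threshold` and the predictors whose loading weight exceeds
#' `lw_threshold`, with signs. Predictors with VIP above `vip_threshold` are
#' ranked into a determinants table giving, for each, the component of
#' maximal contribution and the direction of its effect on habituation.
#'
#' Orientation: the responses are DISTANCES to the habituation centroids, so
#' a predictor whose regression coefficient on `lowhab` is negative brings
#' odorants closer to the low-habituation profile as it increases — reported
#' as "less habituation when the variable increases" (`direction = "up"`).
#'
#' @param fit A `pls_fit`.
#' @param lw_threshold Loading-weight threshold for predictors.
#' @param loading_threshold Loading threshold for responses.
#' @param vip_threshold VIP threshold for the determinants table.
#' @param ncomp Number of components to interpret.
#' @return A `pls_interpretation`: list with `components` (per-component
#'   flagged responses/predictors with signed values), `determinants`
#'   (ranked VIP table with `direction`: `"up"` = less habituation when the
#'   variable rises, `"down"` = less habituation when it falls) and the
#'   thresholds used.
#' @export
interpret_pls <- function(fit, lw_threshold = 0.3, loading_threshold = 0.2,
                          vip_threshold = 1, ncomp = fit$ncomp) {
  stopifnot(inherits(fit, "pls_fit"))
  a_seq <- seq_len(ncomp)
  comps <- lapply(a_seq, function(a) {
    qn <- fit$y_loadings[, a]
    qn <- qn / sqrt(sum(qn^2))            # unit-normalised response loadings
    w <- fit$weights[, a]
    list(component = a,
         responses = qn[abs(qn) > loading_threshold],
         predictors = w[abs(w) > lw_threshold])
  })
  v <- vip(fit, ncomp = ncomp)
  sel <- which(v > vip_threshold)
  contrib <- fit$weights[, a_seq, drop = FALSE]^2 *
    rep(fit$ss_component[a_seq], each = fit$p)
  max_comp <- apply(contrib, 1L, which.max)
  r_low <- match("lowhab", fit$y_names, nomatch = 1L)
  # Direction read on the variable's max-contribution component: the sign of
  # w_j * q_low there says whether the variable moves odorants towards
  # (product < 0) or away from the low-habituation profile. Stable under
  # collinearity (unlike full regression-coefficient signs) and invariant to
  # joint component sign flips.
  wq_low <- fit$weights[cbind(seq_len(fit$p), max_comp)] *
    fit$y_loadings[r_low, max_comp]
  det <- data.frame(variable = fit$x_names[sel],
                    vip = unname(v[sel]),
                    component = unname(max_comp[sel]),
                    direction = ifelse(wq_low[sel] < 0, "up", "down"),
                    stringsAsFactors = FALSE)
  det <- det[order(-det$vip), ]
  rownames(det) <- NULL
  structure(list(components = comps, determinants = det,
                 thresholds = c(loading_weight = lw_threshold,
                                loading = loading_threshold,
                                vip = vip_threshold),
                 ncomp = ncomp),
            class = "pls_interpretation")
}

#' @export
print.pls_interpretation <- function(x, ...) {
  cat("pls_interpretation (", x$ncomp, " components)\n", sep = "")
  for (cc in x$components) {
    cat(sprintf("  comp %d: responses [%s]  predictors [%s]\n", cc$component,
                paste(sprintf("%s %+0.2f", names(cc$responses), cc$responses),
                      collapse = ", "),
                paste(sprintf("%s %+0.2f", names(cc$predictors), cc$predictors),
                      collapse = ", ")))
  }
  if (nrow(x$determinants)) {
    cat("  determinants (VIP > ", x$thresholds[["vip"]],
        "; direction = change giving LESS habituation):\n", sep = "")
    print.data.frame(x$determinants, row.names = FALSE)
  } else cat("  no variable passed the VIP threshold\n")
  invisible(x)
}
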