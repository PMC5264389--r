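# Independent oracles used to cross-check the implementation.

# Classic iterative NIPALS PLS2 (power iteration on the deflated data) --
# algorithmically independent of the kernel/SVD route in fit_pls().
nipals_pls2 <- function(X, Y, A) {
  W <- P <- TT <- NULL
  Q <- NULL
  Xa <- X; Ya <- Y
  for (a in seq_len(A)) {
    u <- Ya[, 1L]
    w <- NULL
    for (it in 1:1000) {
      w <- as.vector(crossprod(Xa, u)); w <- w / sqrt(sum(w^2))
      t_a <- as.vector(Xa %*% w)
      q <- as.vector(crossprod(Ya, t_a)) / sum(t_a^2)
      u_new <- as.vector(Ya %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < 1e-28) { u <- u_new; break }
      u <- u_new
    }
    t_a <- as.vector(Xa %*% w)
    p <- as.vector(crossprod(Xa, t_a)) / sum(t_a^2)
    q <- as.vector(crossprod(Ya, t_a)) / sum(t_a^2)
    Xa <- Xa - tcrossprod(t_a, p)
    Ya <- Ya - tcrossprod(t_a, q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q); TT <- cbind(TT, t_a)
  }
  list(W = W, P = P, Q = Q, TT = TT)
}

# Align the sign of each oracle component with a reference matrix column.
align_signs <- function(M, ref) {
  for (a in seq_len(ncol(M))) {
    if (sum(M[, a] * ref[, a]) < 0) M[, a] <- -M[, a]
  }
  M
}

# Brute-force mean silhouette from a distance matrix and cluster labels.
silhouette_brute <- function(D, cl) {
  D <- as.matrix(D)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i]); own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Loop-summed city-block distance between two vectors.
cityblock_brute <- function(x, y) {
  total <- 0
  for (i in seq_along(x)) total <- total + abs(x[i] - y[i])
  total
}

# Naive leave-one-out RMSEP: refit per left-out sample via fit_pls but with
# all bookkeeping (fold scaling, unscaling, error pooling) done by hand.
loo_rmsep_brute <- function(X, Y, A) {
  n <- nrow(X)
  err <- array(0, c(A, ncol(Y), n))
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]; Yt <- Y[-i, , drop = FALSE]
    mx <- colMeans(Xt); sx <- apply(Xt, 2, sd)
    my <- colMeans(Yt); sy <- apply(Yt, 2, sd)
    ft <- fit_pls(scale(Xt), scale(Yt), A)
    xi <- (X[i, ] - mx) / sx
    for (a in seq_len(A)) {
      yh <- as.vector(xi %*% ft$coefficients[, , a]) * sy + my
      err[a, , i] <- (Y[i, ] - yh)^2
    }
  }
  sqrt(apply(err, c(1, 2), mean))
}

# Direct evaluation of the VIP formula from a fit's raw pieces.
vip_brute <- function(W, TT, Q) {
  p <- nrow(W); A <- ncol(W)
  ss <- vapply(seq_len(A),
               function(a) sum(Q[, a]^2) * sum(TT[, a]^2), numeric(1))
  out <- numeric(p)
  for (j in seq_len(p)) {
    num <- 0
    for (a in seq_len(A)) num <- num + ss[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    out[j] <- sqrt(p * num / sum(ss))
  }
  out
}
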