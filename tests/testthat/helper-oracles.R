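# Small fixture builders and independent oracles used across the suite.

tiny_table <- function(values, taxa = NULL, samples = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(taxa)) taxa <- paste0("ASV", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  storage.mode(values) <- "integer"
  dimnames(values) <- list(taxa, samples)
  count_table(values, ...)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group splits
wilcox_enum_p <- function(x, y) {
  v <- c(x, y)
  n <- length(v)
  r <- rank(v)
  splits <- utils::combn(n, length(x))
  w_obs <- sum(r[seq_along(x)])
  w_all <- apply(splits, 2L, function(ix) sum(r[ix]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# two-sided Fisher p by direct hypergeometric enumeration
# (probability-ordering convention, as the exact conditional test defines)
fisher_enum_p <- function(a_present, a_absent, b_present, b_absent) {
  n_a <- a_present + a_absent
  n_b <- b_present + b_absent
  k <- a_present + b_present
  x <- max(0, k - n_b):min(k, n_a)
  pr <- stats::dhyper(x, n_a, n_b, k)
  obs <- stats::dhyper(a_present, n_a, n_b, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# independent sequential pseudo-F computation: explicit centring matrix
# and normal-equation projections (different algebra from the package's
# QR/trace implementation)
oracle_permanova_F <- function(Dmat, data, terms) {
  n <- nrow(Dmat)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (Dmat^2) %*% J
  hat <- function(X) X %*% MASS::ginv(crossprod(X)) %*% t(X)
  mm <- stats::model.matrix(stats::reformulate(terms), data)
  assign <- attr(mm, "assign")
  K <- length(terms)
  tr <- function(M) sum(diag(M))
  cum <- numeric(K)
  df <- integer(K)
  prev <- 1L
  for (k in seq_len(K)) {
    X <- mm[, assign <= k, drop = FALSE]
    cum[k] <- tr(hat(X) %*% G)
    rk <- qr(X)$rank
    df[k] <- rk - prev
    prev <- rk
  }
  SS <- diff(c(0, cum))
  SS_res <- tr(G) - cum[K]
  df_res <- n - prev
  list(F = (SS / df) / (SS_res / df_res), SS = SS, SS_res = SS_res,
       R2 = SS / tr(G), df = df, df_res = df_res)
}

# exhaustive permutation p for the first term, via the oracle F path
oracle_permanova_exhaustive_p <- function(Dmat, data, terms) {
  n <- nrow(Dmat)
  perms <- anthosphere:::all_permutations(n)
  Fobs <- oracle_permanova_F(Dmat, data, terms)$F
  cnt <- rep(0, length(terms))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    Fp <- oracle_permanova_F(Dmat[p, p], data, terms)$F
    cnt <- cnt + (Fp >= Fobs - 1e-12)
  }
  cnt / nrow(perms)
}

# Euclidean distance matrix from a coordinate matrix
euclid_dist <- function(xy, ids = NULL) {
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(xy)))
  m <- as.matrix(stats::dist(xy))
  dimnames(m) <- list(ids, ids)
  dist_matrix(m, metric = "euclidean")
}
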