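#' Distance matrix container
#'
#' @param mat Square symmetric numeric matrix with zero diagonal and
#'   matching row/column sample names.
#' @param metric Metric tag (e.g. `"bray_curtis"`).
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(mat, metric = "bray_curtis") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("distance matrix must be square",
                                   call. = FALSE)
  if (is.null(rownames(mat))) stop("distance matrix needs sample names",
                                   call. = FALSE)
  if (max(abs(mat - t(mat))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(mat)) > 1e-12)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  colnames(mat) <- rownames(mat)
  structure(list(sample_ids = rownames(mat), values = mat, metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %s, %d samples\n", x$metric,
              length(x$sample_ids)))
  invisible(x)
}

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

subset_dist <- function(D, ids) {
  dist_matrix(D$values[ids, ids, drop = FALSE], metric = D$metric)
}

#' Bray-Curtis dissimilarities between samples
#'
#' Samples are first converted to within-sample relative abundances, so
#' for samples \eqn{j,k}:
#' \deqn{BC_{jk} = 1 - \sum_i \min(p_{ij}, p_{ik}).}
#'
#' @param table A `count_table`; counts are normalised internally.
#' @return A `dist_matrix` with values in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table$values) < 2L) stop("need at least two samples",
                                    call. = FALSE)
  rel <- to_relative(table)
  d <- vegan::vegdist(t(rel$values), method = "bray")
  dist_matrix(as.matrix(d), metric = "bray_curtis")
}

gower_center <- function(mat) {
  a <- -0.5 * mat^2
  n <- nrow(a)
  rm <- rowMeans(a)
  cm <- colMeans(a)
  sweep(sweep(a, 1L, rm), 2L, cm) + mean(a)
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centred matrix of
#' \eqn{-\tfrac12 d^2}. Coordinates are returned for positive axes only;
#' negative eigenvalues (semimetric input such as Bray-Curtis) are
#' reported, not silently dropped.
#'
#' @param D A `dist_matrix` (or square symmetric matrix).
#' @return An `ordination` list: `eigenvalues` (all, descending),
#'   `coordinates` (samples x positive axes), `prop_explained`
#'   (per positive axis, of the positive total), `n_negative`.
#' @export
pcoa <- function(D) {
  if (!inherits(D, "dist_matrix")) D <- dist_matrix(as.matrix(D))
  n <- length(D$sample_ids)
  if (n < 3L) stop("pcoa needs at least 3 samples", call. = FALSE)
  G <- gower_center(D$values)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- D$sample_ids
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(eigenvalues = e$values,
                 coordinates = coords,
                 prop_explained = e$values[pos] / sum(e$values[pos]),
                 n_negative = sum(e$values < -tol),
                 trace = sum(diag(G))),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d positive axes, %d negative eigenvalues\n",
              nrow(x$coordinates), ncol(x$coordinates), x$n_negative))
  invisible(x)
}

#' Sequential (Type-I) PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a dissimilarity matrix over an
#' ordered list of model terms. Terms absorb variation in entry order
#' (each sum of squares is the increment of the nested projection trace),
#' so more specific factors should be entered first and general ones
#' last. Pseudo-F for term k is \eqn{(SS_k/df_k)/(SS_{res}/df_{res})};
#' p-values come from free permutation of sample labels,
#' \eqn{p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})}.
#'
#' @param D A `dist_matrix`.
#' @param meta A `sample_frame` (or data frame with `sample_id`).
#' @param terms Character vector of metadata columns, in entry order.
#'   Character columns are treated as factors, numeric columns as
#'   single-df linear regressors. Samples with missing values in any
#'   term are dropped with a warning.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Seed for the permutation draw.
#' @param exhaustive If `TRUE`, enumerate all `n! - 1` non-identity
#'   permutations instead of sampling (only for small n); the p-value is
#'   then exact.
#' @return A `permanova_table`: data frame `table` with one row per term
#'   plus `Residual` and `Total` (`df`, `SS`, `R2`, `F`, `p`), and the
#'   permutation settings.
#' @export
permanova <- function(D, meta, terms, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE) {
  stopifnot(inherits(D, "dist_matrix"))
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) {
    stop("metadata needs a 'sample_id' column", call. = FALSE)
  }
  if (length(terms) == 0L) stop("no model terms given", call. = FALSE)
  missing_cols <- setdiff(terms, colnames(meta))
  if (length(missing_cols)) {
    stop("metadata lacks term column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(D$sample_ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata is missing samples present in the distance matrix",
         call. = FALSE)
  }
  complete <- stats::complete.cases(meta[, terms, drop = FALSE])
  if (!all(complete)) {
    warning(sum(!complete), " sample(s) dropped for missing term values")
    meta <- meta[complete, , drop = FALSE]
    D <- subset_dist(D, meta$sample_id)
  }
  n <- nrow(meta)
  dat <- meta[, terms, drop = FALSE]
  for (tm in terms) {
    if (is.character(dat[[tm]]) || is.logical(dat[[tm]])) {
      dat[[tm]] <- factor(dat[[tm]])
    }
    if (is.factor(dat[[tm]])) {
      dat[[tm]] <- droplevels(dat[[tm]])
      if (nlevels(dat[[tm]]) < 2L) {
        stop("term '", tm, "' has a single level", call. = FALSE)
      }
    }
  }
  G <- gower_center(D$values)
  trG <- sum(diag(G))

  # nested hat matrices H_1 (term 1) ... H_K (all terms)
  mm <- stats::model.matrix(stats::reformulate(terms), dat)
  assign <- attr(mm, "assign")
  K <- length(terms)
  H <- vector("list", K)
  df <- integer(K)
  prev_rank <- 1L  # intercept
  for (k in seq_len(K)) {
    X <- mm[, assign <= k, drop = FALSE]
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    H[[k]] <- tcrossprod(Q)
    df[k] <- q$rank - prev_rank
    prev_rank <- q$rank
  }
  if (any(df == 0L)) {
    stop("term '", terms[which(df == 0L)[1L]],
         "' is aliased with earlier terms", call. = FALSE)
  }
  df_res <- n - prev_rank
  if (df_res < 1L) {
    stop("more model degrees of freedom than samples - 1", call. = FALSE)
  }
  # center the hat matrices against the intercept so traces are SS
  one <- matrix(1 / n, n, n)
  stat_for <- function(Gp) {
    cum <- vapply(H, function(h) sum((h - one) * Gp), numeric(1))
    SS <- diff(c(0, cum))
    SS_res <- trG - cum[K]
    (SS / df) / (SS_res / df_res)
  }
  cum_obs <- vapply(H, function(h) sum((h - one) * G), numeric(1))
  SS <- diff(c(0, cum_obs))
  SS_res <- trG - cum_obs[K]
  Fobs <- (SS / df) / (SS_res / df_res)

  if (exhaustive) {
    perms <- all_permutations(n)[-1L, , drop = FALSE]
  } else {
    perms <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
    })
  }
  counts <- numeric(K)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    Fp <- stat_for(G[p, p])
    counts <- counts + (Fp >= Fobs - 1e-12)
  }
  pvals <- (1 + counts) / (1 + nrow(perms))

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(SS, SS_res, trG),
    R2 = c(SS / trG, SS_res / trG, 1),
    F = c(Fobs, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n_perm = nrow(perms), seed = seed,
                 exhaustive = exhaustive, n_samples = n),
            class = "permanova_table")
}

#' @export
print.permanova_table <- function(x, ...) {
  cat(sprintf("<permanova_table> %d samples, %d permutations%s\n",
              x$n_samples, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export a PERMANOVA table as TSV
#'
#' Columns follow the conventional factor-table layout:
#' Factor, R2, p-value, df, F-value.
#'
#' @param x A `permanova_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_permanova <- function(x, path) {
  stopifnot(inherits(x, "permanova_table"))
  tab <- x$table
  out <- data.frame(Factor = tab$term, R2 = tab$R2, `p-value` = tab$p,
                    df = tab$df, `F-value` = tab$F, check.names = FALSE)
  write_tsv(out, path)
  invisible(path)
}

#' Multivariate homogeneity of group dispersions
#'
#' Wraps [vegan::betadisper()]: samples are embedded by principal
#' coordinates, each sample's distance to its group centre (spatial
#' median by default) is computed with the negative-eigenvalue
#' correction, and a one-way ANOVA tests equality of mean distances.
#' Groups with fewer than two samples are excluded with a warning.
#'
#' @param D A `dist_matrix`.
#' @param groups Group labels, aligned with `D`'s samples (or named).
#' @param center `"spatial_median"` or `"centroid"`.
#' @return A `dispersion_result`: per-sample `distances`, `group_means`,
#'   ANOVA `F` and `p`, `center`, pairwise Tukey contrasts, and the
#'   underlying `betadisper` object.
#' @export
dispersion <- function(D, groups, center = c("spatial_median", "centroid")) {
  stopifnot(inherits(D, "dist_matrix"))
  center <- match.arg(center)
  groups <- align_groups(groups, D$sample_ids)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    D <- subset_dist(D, D$sample_ids[keep])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) {
    stop("need at least two groups with >= 2 samples", call. = FALSE)
  }
  bd <- vegan::betadisper(as.dist.dist_matrix(D), groups,
                          type = if (center == "spatial_median") "median"
                                 else "centroid")
  an <- stats::anova(bd)
  tk <- stats::TukeyHSD(bd)$group
  structure(list(distances = bd$distances,
                 groups = groups,
                 group_means = tapply(bd$distances, groups, mean),
                 F = an$`F value`[1L], p = an$`Pr(>F)`[1L],
                 center = center,
                 pairwise = data.frame(contrast = rownames(tk),
                                       diff = tk[, "diff"],
                                       p_adj = tk[, "p adj"],
                                       row.names = NULL),
                 betadisper = bd),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result> center = %s, F = %.4g, p = %.4g\n",
              x$center, x$F, x$p))
  print(round(x$group_means, 4))
  invisible(x)
}

align_groups <- function(groups, ids) {
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups))) {
      stop("group labels missing for some samples", call. = FALSE)
    }
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("`groups` length does not match the number of samples",
         call. = FALSE)
  }
  factor(as.character(groups))
}

#' Within-group pairwise dissimilarities
#'
#' Returns every within-group pairwise value (for boxplots and rank
#' tests), not just per-group means.
#'
#' @param D A `dist_matrix`.
#' @param groups Group labels aligned with `D`'s samples (or named).
#' @return A list with `pairs` (data frame `group`, `sample_a`,
#'   `sample_b`, `dissimilarity`) and `group_means`.
#' @export
within_group_beta <- function(D, groups) {
  stopifnot(inherits(D, "dist_matrix"))
  groups <- align_groups(groups, D$sample_ids)
  res <- list()
  for (g in levels(groups)) {
    ids <- D$sample_ids[groups == g]
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2L)
    res[[g]] <- data.frame(
      group = g, sample_a = cmb[1L, ], sample_b = cmb[2L, ],
      dissimilarity = D$values[cbind(cmb[1L, ], cmb[2L, ])],
      stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no group has two or more samples", call. = FALSE)
  pairs <- do.call(rbind, res)
  rownames(pairs) <- NULL
  list(pairs = pairs,
       group_means = tapply(pairs$dissimilarity, pairs$group, mean))
}

#' Distance-based redundancy analysis on numeric constraints
#'
#' Constrained analysis of principal coordinates: the Gower-centred
#' coordinates are regressed on centred numeric covariates (via
#' [vegan::capscale()]) and the constrained variation is tested by
#' permuting constraint rows.
#'
#' @param D A `dist_matrix`.
#' @param constraint Numeric vector (aligned or named) or data frame of
#'   numeric covariates.
#' @param n_perm Number of permutations for the pseudo-F test.
#' @param seed Permutation seed.
#' @return A `dbrda_result`: constraint names, constrained eigenvalues
#'   and their proportion of total variation, unconstrained eigenvalues,
#'   permutation `F` and `p`.
#' @export
dbrda_constrained <- function(D, constraint, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(D, "dist_matrix"))
  if (is.null(dim(constraint))) {
    constraint <- data.frame(constraint = as.numeric(
      if (!is.null(names(constraint))) constraint[D$sample_ids]
      else constraint))
  }
  constraint <- as.data.frame(constraint)
  if (nrow(constraint) != length(D$sample_ids)) {
    stop("constraint length does not match the number of samples",
         call. = FALSE)
  }
  if (!all(vapply(constraint, is.numeric, logical(1)))) {
    stop("constraints must be numeric", call. = FALSE)
  }
  if (anyNA(constraint)) {
    keep <- stats::complete.cases(constraint)
    warning(sum(!keep), " sample(s) dropped for missing constraint values")
    constraint <- constraint[keep, , drop = FALSE]
    D <- subset_dist(D, D$sample_ids[keep])
  }
  if (any(vapply(constraint, function(x) stats::var(x) == 0, logical(1)))) {
    stop("constraint is constant", call. = FALSE)
  }
  rownames(constraint) <- D$sample_ids
  mod <- vegan::capscale(as.dist.dist_matrix(D) ~ ., data = constraint)
  an <- with_seed(seed, stats::anova(mod, permutations = n_perm))
  # capscale reports mean-square (inertia/(n-1)) eigenvalues; rescale to
  # the total-SS scale that pcoa() uses so the two are comparable
  n <- length(D$sample_ids)
  structure(list(constraint_names = colnames(constraint),
                 constrained_eig = mod$CCA$eig * (n - 1),
                 constrained_prop = sum(mod$CCA$eig) / mod$tot.chi,
                 unconstrained_eig = mod$CA$eig * (n - 1),
                 F = an$F[1L], p = an$`Pr(>F)`[1L],
                 n_perm = n_perm, seed = seed),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf(
    "<dbrda_result> constraints: %s; proportion = %.4f, F = %.4g, p = %.4g\n",
    paste(x$constraint_names, collapse = ", "), x$constrained_prop,
    x$F, x$p))
  invisible(x)
}

#' Export a distance matrix as square TSV
#'
#' @param D A `dist_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist <- function(D, path) {
  stopifnot(inherits(D, "dist_matrix"))
  df <- data.frame(sample_id = D$sample_ids, D$values, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}
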