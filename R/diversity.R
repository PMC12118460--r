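#' Per-sample alpha diversity
#'
#' Computes, per sample, observed richness (taxa with count > 0), the
#' Simpson concentration \eqn{\sum_i p_i^2} and the inverse Simpson
#' index \eqn{1/\sum_i p_i^2}, with \eqn{p_i} the within-sample relative
#' abundances. The inverse Simpson index is the effective number of
#' equally abundant taxa; it equals richness exactly when the sample is
#' perfectly even.
#'
#' @param table A `count_table` (counts or relative mode).
#' @param metrics Character subset of
#'   `c("richness", "inverse_simpson", "simpson")`.
#' @return Data frame with one row per sample: `sample_id` plus one
#'   column per requested metric.
#' @export
#' @examples
#' m <- matrix(c(10L, 10L, 10L, 10L), 4, 1,
#'             dimnames = list(paste0("t", 1:4), "S1"))
#' alpha_diversity(count_table(m))  # inverse_simpson = 4
alpha_diversity <- function(table,
                            metrics = c("richness", "inverse_simpson",
                                        "simpson")) {
  stopifnot(inherits(table, "count_table"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  v <- table$values
  cs <- colSums(v)
  if (any(cs == 0)) {
    stop("sample '", colnames(v)[which(cs == 0)[1L]],
         "' has zero total abundance", call. = FALSE)
  }
  p <- sweep(v, 2L, cs, "/")
  out <- data.frame(sample_id = colnames(v), stringsAsFactors = FALSE)
  if ("richness" %in% metrics) out$richness <- colSums(v > 0)
  d2 <- colSums(p^2)
  if ("simpson" %in% metrics) out$simpson <- d2
  if ("inverse_simpson" %in% metrics) out$inverse_simpson <- 1 / d2
  rownames(out) <- NULL
  out
}

#' Analytic rarefaction curves
#'
#' Expected richness when subsampling each sample without replacement to
#' depth \eqn{d}:
#' \deqn{E[S_d] = \sum_i \left[1 - \binom{T - x_i}{d} / \binom{T}{d}\right]}
#' with \eqn{T} the sample read total and \eqn{x_i} the taxon counts.
#' Depths exceeding a sample's total yield `NA` (no extrapolation).
#'
#' @param table A `count_table` in counts mode.
#' @param depths Increasing vector of integer depths.
#' @return Data frame: `sample_id`, `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(table, depths) {
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) {
    stop("rarefaction_curve() requires counts mode", call. = FALSE)
  }
  depths <- as.integer(depths)
  if (any(depths < 1L) || is.unsorted(depths, strictly = TRUE)) {
    stop("`depths` must be strictly increasing positive integers",
         call. = FALSE)
  }
  v <- table$values
  res <- expand.grid(sample_id = colnames(v), depth = depths,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$expected_richness <- NA_real_
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    x <- x[x > 0]
    total <- sum(x)
    for (d in depths) {
      if (d > total) next
      # log-space ratio of binomials; exact for these modest totals
      miss <- exp(lchoose(total - x, d) - lchoose(total, d))
      miss[total - x < d] <- 0
      val <- sum(1 - miss)
      res$expected_richness[res$sample_id == colnames(v)[j] &
                              res$depth == d] <- val
    }
  }
  res
}

#' Nonparametric group comparison of per-sample values
#'
#' Two methods mirror common amplicon practice:
#' `"kruskal_dunn_bonferroni"` runs a tie-corrected Kruskal-Wallis
#' omnibus test followed by Dunn pairwise z tests with Bonferroni
#' adjustment (always computed, whatever the omnibus p);
#' `"wilcoxon_rank_sum"` is a two-sided two-group Wilcoxon rank-sum
#' test, exact when group sizes permit and no ties are present,
#' otherwise the tie-corrected normal approximation.
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Group labels, same length as `values`.
#' @param method `"kruskal_dunn_bonferroni"` or `"wilcoxon_rank_sum"`.
#' @return A `group_test` list: `method`, `omnibus`
#'   (`statistic`, `df`, `p`; Kruskal-Wallis only), and `comparisons`,
#'   a data frame with `group_a`, `group_b`, `statistic`, `p_raw`,
#'   `p_adj`.
#' @export
group_compare <- function(values, groups,
                          method = c("kruskal_dunn_bonferroni",
                                     "wilcoxon_rank_sum")) {
  method <- match.arg(method)
  if (length(values) != length(groups)) {
    stop("`values` and `groups` lengths differ", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (nlevels(groups) < 2L || any(sizes == 0L)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  constant <- length(unique(values)) == 1L

  if (method == "wilcoxon_rank_sum") {
    if (nlevels(groups) != 2L) {
      stop("wilcoxon_rank_sum requires exactly two groups", call. = FALSE)
    }
    ga <- levels(groups)[1L]
    gb <- levels(groups)[2L]
    x <- values[groups == ga]
    y <- values[groups == gb]
    if (constant) {
      cmp <- data.frame(group_a = ga, group_b = gb,
                        statistic = length(x) * length(y) / 2,
                        p_raw = 1, p_adj = 1, stringsAsFactors = FALSE)
      return(structure(list(method = method, omnibus = NULL,
                            comparisons = cmp), class = "group_test"))
    }
    ties <- anyDuplicated(values) > 0L
    use_exact <- !ties && (length(x) + length(y)) <= 20L
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact)
    )
    cmp <- data.frame(group_a = ga, group_b = gb,
                      statistic = unname(wt$statistic),
                      p_raw = wt$p.value, p_adj = wt$p.value,
                      stringsAsFactors = FALSE)
    return(structure(list(method = method, omnibus = NULL,
                          comparisons = cmp), class = "group_test"))
  }

  # Kruskal-Wallis omnibus + Dunn pairwise z with Bonferroni
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  n_pairs <- ncol(pairs)
  if (constant) {
    omnibus <- list(statistic = 0, df = nlevels(groups) - 1L, p = 1)
    cmp <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                      statistic = 0, p_raw = 1, p_adj = 1,
                      stringsAsFactors = FALSE)
    return(structure(list(method = method, omnibus = omnibus,
                          comparisons = cmp), class = "group_test"))
  }
  kw <- stats::kruskal.test(values, groups)
  r <- rank(values)  # midranks
  n <- length(values)
  mean_rank <- tapply(r, groups, mean)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  var_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  z <- p_raw <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt(var_base * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[k] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  cmp <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                    statistic = z, p_raw = p_raw,
                    p_adj = pmin(1, p_raw * n_pairs),
                    stringsAsFactors = FALSE)
  omnibus <- list(statistic = unname(kw$statistic),
                  df = unname(kw$parameter), p = kw$p.value)
  structure(list(method = method, omnibus = omnibus, comparisons = cmp),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test>", x$method, "\n")
  if (!is.null(x$omnibus)) {
    cat(sprintf("  Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
                x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  }
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
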