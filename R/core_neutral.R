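#' Occupancy and mean relative abundance per taxon
#'
#' Occupancy is the fraction of samples in which a taxon is detected
#' (count > 0); mean relative abundance is the arithmetic mean of the
#' taxon's within-sample proportions, zeros included. Taxa absent from
#' every sample are dropped.
#'
#' @param table A `count_table` in counts mode with at least 2 samples.
#' @return An `occupancy_abundance` data frame: `taxon`, `occupancy`,
#'   `mean_rel_abund`; attribute `n_samples`.
#' @export
occupancy_abundance <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) {
    stop("occupancy_abundance() requires counts mode", call. = FALSE)
  }
  v <- table$values
  if (ncol(v) < 2L) {
    stop("occupancy needs at least two samples", call. = FALSE)
  }
  cs <- colSums(v)
  if (any(cs == 0)) {
    stop("sample '", colnames(v)[which(cs == 0)[1L]], "' has zero reads",
         call. = FALSE)
  }
  p <- sweep(v, 2L, cs, "/")
  occ <- rowMeans(v > 0)
  keep <- occ > 0
  out <- data.frame(taxon = rownames(v)[keep],
                    occupancy = occ[keep],
                    mean_rel_abund = rowMeans(p)[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_samples") <- ncol(v)
  class(out) <- c("occupancy_abundance", "data.frame")
  out
}

#' Rank taxa by joint occupancy and abundance
#'
#' The ranking score is \eqn{o_i + p_i / \max_j p_j}: occupancy plus
#' mean relative abundance rescaled to \[0, 1\] so neither axis
#' dominates. Ties are broken by higher abundance, then taxon id.
#' An occupancy-only ranking is available for comparison.
#'
#' @param occab An `occupancy_abundance` result.
#' @param method `"score"` (default, joint) or `"occupancy"`.
#' @return The input data frame with `score` and `rank` columns, sorted
#'   by rank.
#' @export
rank_core_taxa <- function(occab, method = c("score", "occupancy")) {
  stopifnot(inherits(occab, "occupancy_abundance"))
  method <- match.arg(method)
  if (nrow(occab) == 0L) stop("empty occupancy table", call. = FALSE)
  score <- if (method == "score") {
    occab$occupancy + occab$mean_rel_abund / max(occab$mean_rel_abund)
  } else {
    occab$occupancy
  }
  ord <- order(-score, -occab$mean_rel_abund, occab$taxon)
  out <- occab[ord, , drop = FALSE]
  out$score <- score[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_samples") <- attr(occab, "n_samples")
  class(out) <- c("occupancy_abundance", "data.frame")
  out
}

#' Core microbiome by the occupancy-abundance elbow criterion
#'
#' Taxa are added in rank order and the cumulative fraction of mean
#' pairwise Bray-Curtis similarity they explain is tracked: with
#' relative abundances \eqn{p}, each sample pair contributes
#' \eqn{\sum_{i \le k} \min(p_{ij}, p_{ik})} against the full-table
#' similarity \eqn{\sum_i \min(p_{ij}, p_{ik})}. The core is the last
#' rank whose relative gain \eqn{(C_k - C_{k-1})/C_k} still meets
#' `gain_threshold` (default 2%).
#'
#' @param table A `count_table` in counts mode (>= 2 samples).
#' @param ranked Ranked taxa from [rank_core_taxa()]; computed from
#'   `table` when `NULL`. Must cover all taxa present in the table.
#' @param gain_threshold Minimum relative gain to stay in the core
#'   (default 0.02).
#' @return A `core_result`: `ranking` (taxon, rank, score, core flag),
#'   `curve` (cumulative explained similarity per rank), `elbow_rank`,
#'   `core_taxa`, `gain_threshold`.
#' @export
core_by_elbow <- function(table, ranked = NULL, gain_threshold = 0.02) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table$values) < 2L) stop("need at least two samples",
                                    call. = FALSE)
  if (is.null(ranked)) ranked <- rank_core_taxa(occupancy_abundance(table))
  stopifnot(inherits(ranked, "occupancy_abundance"),
            !is.null(ranked$rank))
  present <- rownames(table$values)[rowSums(table$values > 0) > 0]
  if (!all(present %in% ranked$taxon)) {
    stop("`ranked` does not cover all taxa present in the table",
         call. = FALSE)
  }
  rel <- to_relative(subset_table(table, taxa = present))
  p <- rel$values[ranked$taxon, , drop = FALSE]
  n <- ncol(p)
  pairs <- utils::combn(n, 2L)
  # taxa x pairs matrix of shared mass min(p_ij, p_ik)
  M <- pmin(p[, pairs[1L, ], drop = FALSE], p[, pairs[2L, ], drop = FALSE])
  full <- mean(colSums(M))
  if (full <= 0) {
    stop("samples share no taxa; similarity-based core is undefined",
         call. = FALSE)
  }
  cum <- apply(M, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
  curve <- unname(rowMeans(cum)) / full
  gains <- (curve - c(0, curve[-length(curve)])) / curve
  gains[curve == 0] <- 0
  ok <- which(gains >= gain_threshold)
  elbow <- if (length(ok)) max(ok) else 1L
  ranking <- ranked
  ranking$core <- ranking$rank <= elbow
  structure(list(ranking = ranking, curve = curve, elbow_rank = elbow,
                 core_taxa = ranking$taxon[ranking$core],
                 gain_threshold = gain_threshold),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("<core_result> %d core taxa of %d (elbow at rank %d, threshold %.3g)\n",
              length(x$core_taxa), length(x$curve), x$elbow_rank,
              x$gain_threshold))
  invisible(x)
}

#' Export a core result as TSV
#'
#' @param x A `core_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_core <- function(x, path) {
  stopifnot(inherits(x, "core_result"))
  df <- data.frame(taxon = x$ranking$taxon,
                   occupancy = x$ranking$occupancy,
                   mean_rel_abund = x$ranking$mean_rel_abund,
                   rank = x$ranking$rank,
                   score = x$ranking$score,
                   core_flag = x$ranking$core,
                   cum_similarity = x$curve[x$ranking$rank])
  write_tsv(df, path)
  invisible(path)
}

#' Sloan neutral-model occupancy prediction
#'
#' Expected detection frequency of a taxon with metacommunity relative
#' abundance `p` under the neutral model with migration parameter `m`
#' and sampling depth `N` reads. The taxon's latent relative abundance
#' is \eqn{\pi \sim Beta(Nmp,\, Nm(1-p))}; two detection conventions
#' are offered:
#' \describe{
#'   \item{`"multinomial"` (default)}{exact probability of at least one
#'     read when `N` reads are drawn multinomially from \eqn{\pi}:
#'     \deqn{\hat o(p) = 1 - E[(1-\pi)^N]
#'           = 1 - B(Nmp,\, Nm(1-p)+N) / B(Nmp,\, Nm(1-p)).}
#'     This is the detection probability a rarefied count table actually
#'     realises, so fitting with it recovers the generating `m` without
#'     bias.}
#'   \item{`"threshold"`}{the classic detection-limit approximation with
#'     \eqn{d = 1/N}:
#'     \deqn{\hat o(p) = 1 - I(d;\, Nmp,\, Nm(1-p))}
#'     with \eqn{I} the regularised incomplete beta function. This is
#'     the form commonly fitted in the microbiome literature; it treats
#'     detection as certain above the limit and impossible below, which
#'     inflates fitted `m` on multinomially sampled counts.}
#' }
#'
#' @param p Metacommunity relative abundance(s) in (0, 1).
#' @param m Migration parameter (> 0).
#' @param N Reads per sample.
#' @param detection `"multinomial"` or `"threshold"` (see above).
#' @return Predicted occupancy, same length as `p`.
#' @export
neutral_occupancy <- function(p, m, N,
                              detection = c("multinomial", "threshold")) {
  stopifnot(m > 0, N >= 1)
  detection <- match.arg(detection)
  a <- N * m * p
  b <- N * m * (1 - p)
  if (detection == "threshold") {
    1 - stats::pbeta(1 / N, a, b)
  } else {
    1 - exp(lbeta(a, b + N) - lbeta(a, b))
  }
}

#' Fit the Sloan neutral community model to occupancy data
#'
#' Samples are rarefied to a common depth `N` (the model's sampling
#' depth; samples below `N` are dropped with a warning), occupancy and
#' mean relative abundance are computed on the rarefied table, and the
#' migration parameter is estimated by bounded nonlinear least squares
#' of observed against predicted occupancy. Fit quality is the
#' generalised \eqn{R^2 = 1 - SSE/SST} (negative when the model fits
#' worse than a flat mean) and \eqn{RMSE = \sqrt{SSE/(S-1)}} over the
#' `S` taxa. Each taxon is labelled `above`, `neutral` or `below`
#' according to the Wilson 95% binomial interval around its predicted
#' occupancy (trials = number of samples).
#'
#' @param table A `count_table` in counts mode.
#' @param N Rarefaction depth / model sampling depth (default 500).
#' @param seed Seed for the internal rarefaction.
#' @param rarefy_input Set `FALSE` when `table` is already at a common
#'   depth `N`.
#' @param detection Detection convention passed to
#'   [neutral_occupancy()]; `"multinomial"` (default) or
#'   `"threshold"`.
#' @return A `neutral_fit`: `m` (estimate), `N`, `detection_limit`,
#'   `taxa` (data frame with observed/predicted occupancy, Wilson
#'   bounds, partition), `r_squared`, `rmse`, `sse`, `converged`,
#'   `n_samples`.
#' @export
fit_neutral <- function(table, N = 500L, seed = 1L, rarefy_input = TRUE,
                        detection = c("multinomial", "threshold")) {
  detection <- match.arg(detection)
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) stop("fit_neutral() requires counts mode",
                              call. = FALSE)
  if (rarefy_input) {
    cs <- colSums(table$values)
    low <- cs < N
    if (all(low)) stop("no sample reaches depth ", N, call. = FALSE)
    if (any(low)) {
      warning(sum(low), " sample(s) below depth ", N, " dropped")
      table <- subset_table(table, samples = !low)
    }
    table <- rarefy(table, depth = N, seed = seed)
  }
  occab <- occupancy_abundance(table)
  fit <- fit_neutral_curve(occab$occupancy, occab$mean_rel_abund, N = N,
                           n_samples = attr(occab, "n_samples"),
                           taxa = occab$taxon, detection = detection)
  fit
}

#' Fit the neutral model to an occupancy-abundance curve directly
#'
#' Lower-level interface used by [fit_neutral()] and handy when
#' occupancies come from elsewhere.
#'
#' @param occupancy Observed occupancy per taxon, in (0, 1\].
#' @param p Mean relative abundance per taxon.
#' @param N Sampling depth (reads per sample).
#' @param n_samples Number of samples behind the occupancies (Wilson
#'   interval trials).
#' @param taxa Optional taxon ids.
#' @param detection Detection convention passed to
#'   [neutral_occupancy()].
#' @return A `neutral_fit` (see [fit_neutral()]).
#' @export
fit_neutral_curve <- function(occupancy, p, N, n_samples, taxa = NULL,
                              detection = c("multinomial", "threshold")) {
  detection <- match.arg(detection)
  if (length(occupancy) != length(p)) {
    stop("occupancy and abundance lengths differ", call. = FALSE)
  }
  if (length(occupancy) < 10L) {
    stop("fewer than 10 taxa; the neutral fit is unidentifiable",
         call. = FALSE)
  }
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_along(occupancy))
  d <- 1 / N
  sse_of <- function(m) {
    sum((occupancy - neutral_occupancy(p, m, N, detection))^2)
  }
  fit <- tryCatch(
    stats::nls(occupancy ~ neutral_occupancy(p, m, N, detection),
               start = list(m = 0.1), lower = 1e-6, upper = 10,
               algorithm = "port",
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # port can stall on flat boundaries; a bounded golden-section search
    # on the same SSE objective is the fallback before giving up
    opt <- stats::optimize(sse_of, interval = c(1e-6, 10), tol = 1e-10)
    if (!is.finite(opt$objective)) {
      stop("neutral fit did not converge: ", conditionMessage(fit),
           call. = FALSE)
    }
    m_hat <- opt$minimum
    converged <- TRUE
  } else {
    m_hat <- stats::coef(fit)[["m"]]
    converged <- fit$convInfo$isConv %||% TRUE
  }
  pred <- neutral_occupancy(p, m_hat, N, detection)
  sse <- sum((occupancy - pred)^2)
  sst <- sum((occupancy - mean(occupancy))^2)
  r2 <- 1 - sse / sst
  rmse <- sqrt(sse / (length(occupancy) - 1))
  ci <- wilson_interval(pred, n_samples)
  partition <- ifelse(occupancy > ci$upper, "above",
                      ifelse(occupancy < ci$lower, "below", "neutral"))
  structure(list(m = m_hat, N = N, detection_limit = d,
                 detection = detection,
                 taxa = data.frame(taxon = taxa, occupancy = occupancy,
                                   mean_rel_abund = p, predicted = pred,
                                   lower = ci$lower, upper = ci$upper,
                                   partition = partition,
                                   stringsAsFactors = FALSE),
                 r_squared = r2, rmse = rmse, sse = sse,
                 converged = converged, n_samples = n_samples),
            class = "neutral_fit")
}

# Wilson score interval for a binomial proportion
wilson_interval <- function(phat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf(
    "<neutral_fit> m = %.4g, N = %d, R2 = %.3f, RMSE = %.4f (%d taxa, %d samples)\n",
    x$m, as.integer(x$N), x$r_squared, x$rmse, nrow(x$taxa), x$n_samples))
  cat("  partition:", paste(names(table(x$taxa$partition)),
                            table(x$taxa$partition),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Export a neutral fit (per-taxon TSV + JSON summary)
#'
#' @param x A `neutral_fit`.
#' @param tsv_path Path for the per-taxon table (`NULL` to skip).
#' @param json_path Path for the JSON summary (`NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_neutral_fit <- function(x, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "neutral_fit"))
  if (!is.null(tsv_path)) write_tsv(x$taxa, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(m = x$m, N = x$N, detection_limit = x$detection_limit,
           r_squared = x$r_squared, rmse = x$rmse, sse = x$sse,
           n_taxa = nrow(x$taxa), n_samples = x$n_samples,
           converged = x$converged),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
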