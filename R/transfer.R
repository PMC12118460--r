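#' Taxa present on foragers in an environment
#'
#' Union of taxa with at least one read in any forager sample of the
#' environment; forager presence is read-depth free by design.
#'
#' @param table A `count_table` in counts mode.
#' @param meta A `sample_frame` with `role` and `environment`.
#' @param environment Environment to pool foragers over.
#' @return Character vector of taxon ids.
#' @export
forager_presence <- function(table, meta, environment) {
  stopifnot(inherits(table, "count_table"))
  meta <- as.data.frame(meta)
  ids <- meta$sample_id[!is.na(meta$role) & meta$role == "forager" &
                          !is.na(meta$environment) &
                          meta$environment == environment]
  ids <- intersect(ids, sample_ids(table))
  if (!length(ids)) {
    stop("no forager samples in environment '", environment, "'",
         call. = FALSE)
  }
  v <- table$values[, ids, drop = FALSE]
  rownames(v)[rowSums(v >= 1) > 0]
}

#' Pollinator-to-flower transfer index
#'
#' For each flower sample, the proportion of its distinct ASVs with more
#' than `min_count` reads (eligibility is judged on the flower side
#' only) that also occur, with at least one read, in any forager sample
#' of the same environment. Flowers with no eligible ASV are flagged
#' `defined = FALSE` and excluded from the per-environment summaries.
#'
#' @param table A `count_table` in counts mode containing flower and
#'   forager samples.
#' @param meta A `sample_frame` with `role` and `environment` for the
#'   table's samples.
#' @param min_count Flower-side read threshold; eligible means strictly
#'   more than this many reads (default 3).
#' @return A `transfer_result`: `flowers` (data frame `sample_id`,
#'   `environment`, `n_eligible`, `n_shared`, `index`, `defined`),
#'   `summary` (per environment: mean/min index and flower counts over
#'   defined flowers), `min_count`.
#' @export
transfer_index <- function(table, meta, min_count = 3L) {
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) stop("transfer_index() requires counts mode",
                              call. = FALSE)
  meta <- as.data.frame(meta)
  meta <- meta[meta$sample_id %in% sample_ids(table), , drop = FALSE]
  fl <- meta[!is.na(meta$role) & meta$role == "flower", , drop = FALSE]
  if (!nrow(fl)) stop("no flower samples in metadata", call. = FALSE)
  envs <- unique(fl$environment[!is.na(fl$environment)])
  presence <- lapply(stats::setNames(envs, envs), function(e) {
    forager_presence(table, meta, e)
  })
  rows <- lapply(seq_len(nrow(fl)), function(i) {
    sid <- fl$sample_id[i]
    env <- fl$environment[i]
    counts <- table$values[, sid]
    eligible <- names(counts)[counts > min_count]
    shared <- intersect(eligible, presence[[env]])
    data.frame(sample_id = sid, environment = env,
               n_eligible = length(eligible), n_shared = length(shared),
               index = if (length(eligible)) length(shared) / length(eligible)
                       else NA_real_,
               defined = length(eligible) > 0L, stringsAsFactors = FALSE)
  })
  flowers <- do.call(rbind, rows)
  if (any(!flowers$defined)) {
    warning(sum(!flowers$defined),
            " flower(s) with no eligible ASV excluded from summaries")
  }
  def <- flowers[flowers$defined, , drop = FALSE]
  summary <- do.call(rbind, lapply(split(def, def$environment), function(d) {
    data.frame(environment = d$environment[1L], n_flowers = nrow(d),
               mean_index = mean(d$index), min_index = min(d$index),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(flowers = flowers, summary = summary,
                 min_count = min_count),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %d flowers (min_count = %d)\n",
              nrow(x$flowers), x$min_count))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-taxon prevalence comparison between two groups (Fisher)
#'
#' Presence (count >= 1) of each taxon is cross-tabulated against a
#' two-level grouping and tested with the exact two-sided Fisher test;
#' odds ratios follow the conditional maximum-likelihood convention
#' (zero cells give 0 or infinity). Benjamini-Hochberg adjusted
#' p-values are reported alongside the raw ones.
#'
#' @param table A `count_table` in counts mode.
#' @param meta A `sample_frame` covering the table's samples.
#' @param grouping Name of a metadata column with exactly two non-empty
#'   groups among the table's samples (samples with a missing value are
#'   dropped).
#' @param rank `"asv"` (test ASVs as-is) or `"genus"` (aggregate by
#'   genus first; requires taxonomy).
#' @return A `prevalence_result` data frame: `taxon`, presence/absence
#'   counts per group, `odds_ratio`, `p_raw`, `p_bh`; attributes
#'   `groups` and `group_sizes`.
#' @export
prevalence_fisher <- function(table, meta, grouping,
                              rank = c("asv", "genus")) {
  stopifnot(inherits(table, "count_table"))
  rank <- match.arg(rank)
  meta <- as.data.frame(meta)
  if (!grouping %in% colnames(meta)) {
    stop("metadata lacks column '", grouping, "'", call. = FALSE)
  }
  meta <- meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
  g <- meta[[grouping]]
  keep <- !is.na(g)
  if (!all(keep)) {
    table <- subset_table(table, samples = keep)
    g <- g[keep]
  }
  g <- factor(as.character(g))
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("'", grouping, "' must define exactly two non-empty groups",
         call. = FALSE)
  }
  if (rank == "genus") table <- aggregate_by_rank(table, "genus")
  v <- table$values
  a_ids <- g == levels(g)[1L]
  n_a <- sum(a_ids); n_b <- sum(!a_ids)
  res <- lapply(rownames(v), function(tx) {
    pres <- v[tx, ] >= 1
    a_p <- sum(pres[a_ids]); b_p <- sum(pres[!a_ids])
    ft <- stats::fisher.test(matrix(c(a_p, n_a - a_p, b_p, n_b - b_p), 2L),
                             alternative = "two.sided")
    data.frame(taxon = tx, a_present = a_p, a_absent = n_a - a_p,
               b_present = b_p, b_absent = n_b - b_p,
               odds_ratio = unname(ft$estimate), p_raw = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  rownames(out) <- NULL
  attr(out, "groups") <- levels(g)
  attr(out, "group_sizes") <- c(n_a, n_b)
  class(out) <- c("prevalence_result", "data.frame")
  out
}

#' Export a transfer result as TSV
#'
#' @param x A `transfer_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfer <- function(x, path) {
  stopifnot(inherits(x, "transfer_result"))
  write_tsv(x$flowers, path)
  invisible(path)
}
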