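#' ASV count table
#'
#' The central data container of the package: a taxa-by-samples matrix of
#' non-negative values, either raw read counts or within-sample relative
#' abundances, with optional per-taxon taxonomy and representative
#' sequences. Taxa are rows and samples are columns, the usual amplicon
#' convention.
#'
#' @param values Numeric matrix, taxa in rows, samples in columns. Must
#'   carry unique row and column names (taxon and sample identifiers).
#' @param taxonomy Optional data frame of rank labels with one row per
#'   taxon (row names are taxon ids) and columns among
#'   `domain, phylum, class, order, family, genus`.
#' @param sequences Optional named character vector of representative
#'   nucleotide sequences, names are taxon ids.
#' @param is_relative Logical; `TRUE` when `values` are within-sample
#'   relative abundances (each column sums to 1), `FALSE` for raw counts.
#' @return An object of class `count_table`.
#' @export
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("ASV1", "ASV2"), c("S1", "S2")))
#' count_table(m)
count_table <- function(values, taxonomy = NULL, sequences = NULL,
                        is_relative = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("count table is empty", call. = FALSE)
  }
  tx <- rownames(values)
  sm <- colnames(values)
  if (is.null(tx) || is.null(sm)) {
    stop("`values` must have taxon row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(tx)) {
    stop("duplicate taxon id: ", tx[duplicated(tx)][1L], call. = FALSE)
  }
  if (anyDuplicated(sm)) {
    stop("duplicate sample id: ", sm[duplicated(sm)][1L], call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    bad <- which(is.na(values) | values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative or missing value at taxon '%s', sample '%s'",
                 tx[bad[1L]], sm[bad[2L]]), call. = FALSE)
  }
  if (!is_relative && any(values != floor(values))) {
    bad <- which(values != floor(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                 tx[bad[1L]], sm[bad[2L]]), call. = FALSE)
  }
  if (is_relative) {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9)) {
      stop("relative-abundance columns must sum to 1: sample '",
           sm[which(abs(cs - 1) > 1e-9)[1L]], "' does not", call. = FALSE)
    }
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(tx %in% rownames(taxonomy))) {
      stop("taxonomy is missing entries for some taxa", call. = FALSE)
    }
    taxonomy <- taxonomy[tx, , drop = FALSE]
  }
  if (!is.null(sequences)) {
    sequences <- sequences[tx]
    names(sequences) <- tx
  }
  structure(list(values = values, taxonomy = taxonomy,
                 sequences = sequences, is_relative = isTRUE(is_relative)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d taxa x %d samples (%s mode)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_relative) "relative" else "counts"))
  if (!is.null(x$taxonomy)) {
    cat("  taxonomy ranks:", paste(colnames(x$taxonomy), collapse = ", "), "\n")
  }
  if (!is.null(x$sequences)) cat("  representative sequences attached\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$values)

#' Taxon identifiers of a count table
#' @param table A `count_table`.
#' @return Character vector of taxon ids in row order.
#' @export
taxon_ids <- function(table) rownames(table$values)

#' Sample identifiers of a count table
#' @param table A `count_table`.
#' @return Character vector of sample ids in column order.
#' @export
sample_ids <- function(table) colnames(table$values)

#' Subset a count table by taxa and/or samples
#'
#' @param table A `count_table`.
#' @param taxa Character or logical/integer index of taxa to keep.
#' @param samples Character or logical/integer index of samples to keep.
#' @return A `count_table` restricted to the selection; taxonomy and
#'   sequences are subset accordingly.
#' @export
subset_table <- function(table, taxa = NULL, samples = NULL) {
  stopifnot(inherits(table, "count_table"))
  v <- table$values
  if (!is.null(taxa)) v <- v[taxa, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  tax <- table$taxonomy
  if (!is.null(tax)) tax <- tax[rownames(v), , drop = FALSE]
  seqs <- table$sequences
  if (!is.null(seqs)) seqs <- seqs[rownames(v)]
  count_table(v, taxonomy = tax, sequences = seqs,
              is_relative = table$is_relative)
}

#' Convert counts to within-sample relative abundances
#'
#' Divides each sample column by its read total, the normalisation under
#' which Bray-Curtis dissimilarities and mean relative abundances are
#' computed throughout the package.
#'
#' @param table A `count_table` in counts mode.
#' @return A `count_table` in relative mode; every column sums to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) return(table)
  cs <- colSums(table$values)
  if (any(cs == 0)) {
    stop("sample '", colnames(table$values)[which(cs == 0)[1L]],
         "' has zero total count", call. = FALSE)
  }
  count_table(sweep(table$values, 2L, cs, "/"), taxonomy = table$taxonomy,
              sequences = table$sequences, is_relative = TRUE)
}

#' Rarefy samples to a common read depth
#'
#' Subsamples reads without replacement within each sample so that every
#' column sums exactly to `depth`. Deterministic for a given seed.
#'
#' @param table A `count_table` in counts mode.
#' @param depth Target reads per sample.
#' @param seed Integer seed controlling the subsampling.
#' @return A rarefied `count_table` in counts mode (taxa left with no
#'   reads anywhere are retained as zero rows; drop them with
#'   [subset_table()] if needed).
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) stop("rarefy() requires counts mode", call. = FALSE)
  depth <- as.integer(depth)
  cs <- colSums(table$values)
  low <- cs < depth
  if (any(low)) {
    stop("samples below rarefaction depth ", depth, ": ",
         paste(colnames(table$values)[low], collapse = ", "), call. = FALSE)
  }
  v <- table$values
  out <- with_seed(seed, {
    o <- v
    for (j in seq_len(ncol(v))) {
      reads <- rep.int(seq_len(nrow(v)), v[, j])
      keep <- sample(reads, depth, replace = FALSE)
      o[, j] <- tabulate(keep, nbins = nrow(v))
    }
    o
  })
  storage.mode(out) <- "integer"
  count_table(out, taxonomy = table$taxonomy, sequences = table$sequences,
              is_relative = FALSE)
}

#' Apply the standard ASV-table quality filters
#'
#' Applies, in this fixed order: (1) removal of organellar taxa
#' (chloroplast/mitochondrial labels at any rank), (2) removal of taxa
#' whose representative sequence exceeds `max_asv_len` bases, (3) removal
#' of samples whose remaining read total falls below `min_reads`, and
#' finally removal of taxa left with no reads in any retained sample.
#' The order matters: sample read totals are evaluated after the taxon
#' filters, so a sample can be discarded because most of its reads were
#' organellar.
#'
#' @param table A `count_table` in counts mode.
#' @param min_reads Minimum retained reads per sample; samples with
#'   strictly fewer are discarded (default 500).
#' @param max_asv_len Maximum representative-sequence length in bases;
#'   longer taxa are discarded (default 260). Ignored (with a note in the
#'   report) when the table carries no sequences.
#' @param drop_organellar Drop taxa whose taxonomy matches
#'   "chloroplast" or "mitochondri" (case-insensitive) at any rank.
#' @return A list with elements `table` (the filtered `count_table`) and
#'   `report` (character vectors `organellar`, `too_long`,
#'   `low_depth_samples`, `empty_taxa` naming what was dropped).
#' @export
filter_dataset <- function(table, min_reads = 500L, max_asv_len = 260L,
                           drop_organellar = TRUE) {
  stopifnot(inherits(table, "count_table"))
  if (table$is_relative) {
    stop("filter_dataset() requires counts mode", call. = FALSE)
  }
  report <- list(organellar = character(), too_long = character(),
                 low_depth_samples = character(), empty_taxa = character())
  cur <- table

  if (drop_organellar) {
    if (is.null(cur$taxonomy)) {
      stop("drop_organellar = TRUE but the table has no taxonomy",
           call. = FALSE)
    }
    lab <- apply(cur$taxonomy, 1L, function(r) {
      paste(r[!is.na(r)], collapse = ";")
    })
    org <- grepl("chloroplast|mitochondri", lab, ignore.case = TRUE)
    report$organellar <- taxon_ids(cur)[org]
    if (any(org)) cur <- subset_table(cur, taxa = !org)
  }

  if (!is.null(cur$sequences) && !is.null(max_asv_len)) {
    len <- nchar(cur$sequences)
    long <- !is.na(len) & len > max_asv_len
    report$too_long <- taxon_ids(cur)[long]
    if (any(long)) cur <- subset_table(cur, taxa = !long)
  }

  cs <- colSums(cur$values)
  low <- cs < min_reads
  report$low_depth_samples <- sample_ids(cur)[low]
  if (all(low)) {
    stop("all samples fall below ", min_reads, " reads after taxon filters",
         call. = FALSE)
  }
  if (any(low)) cur <- subset_table(cur, samples = !low)

  empty <- rowSums(cur$values) == 0
  report$empty_taxa <- taxon_ids(cur)[empty]
  if (any(empty)) cur <- subset_table(cur, taxa = !empty)

  list(table = cur, report = report)
}

#' Aggregate a count table at a taxonomic rank
#'
#' Sums counts of taxa sharing the same label at the requested rank.
#' Taxa with a missing or empty label at that rank are excluded (not
#' binned into an "unclassified" group) and counted in the
#' `excluded_taxa` attribute of the result, so downstream prevalence
#' tests reflect classified reads only.
#'
#' @param table A `count_table` with taxonomy.
#' @param rank One of `phylum, class, order, family, genus`.
#' @return A `count_table` whose rows are rank labels; attribute
#'   `excluded_taxa` holds the ids dropped for lacking a label.
#' @export
aggregate_by_rank <- function(table,
                              rank = c("genus", "family", "order",
                                       "class", "phylum")) {
  stopifnot(inherits(table, "count_table"))
  rank <- match.arg(rank)
  if (is.null(table$taxonomy) || !rank %in% colnames(table$taxonomy)) {
    stop("table has no taxonomy at rank '", rank, "'", call. = FALSE)
  }
  if (table$is_relative) {
    stop("aggregate_by_rank() requires counts mode; aggregate before ",
         "normalising", call. = FALSE)
  }
  lab <- as.character(table$taxonomy[[rank]])
  missing <- is.na(lab) | lab == ""
  excluded <- taxon_ids(table)[missing]
  if (all(missing)) stop("no taxa classified at rank '", rank, "'",
                         call. = FALSE)
  v <- table$values[!missing, , drop = FALSE]
  agg <- rowsum(v, group = lab[!missing])
  storage.mode(agg) <- "integer"
  out <- count_table(agg, is_relative = FALSE)
  attr(out, "excluded_taxa") <- excluded
  out
}
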