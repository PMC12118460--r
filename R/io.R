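#' Read an ASV count table
#'
#' TSV layout: first column `asv_id` (taxon identifiers), remaining
#' columns one per sample with integer counts; tab-separated, UTF-8.
#' BIOM files (classic JSON or 2.1 HDF5) are read through the
#' `biomformat` package with the observation axis as taxa.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @return A `count_table` in counts mode, file order preserved.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(check_integer_counts(m, path)))
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L) stop("empty count table: ", path,
                                           call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate taxon id '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  }
  sm <- colnames(df)[-1L]
  if (anyDuplicated(sm)) {
    stop("duplicate sample id '", sm[duplicated(sm)][1L], "' in ", path,
         call. = FALSE)
  }
  m <- matrix(NA_integer_, nrow(df), length(sm),
              dimnames = list(ids, sm))
  for (j in seq_along(sm)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) | num < 0 | num != floor(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "invalid count '%s' at taxon '%s', sample '%s' in %s",
        raw[i], ids[i], sm[j], path), call. = FALSE)
    }
    m[, j] <- as.integer(num)
  }
  count_table(m)
}

check_integer_counts <- function(m, path) {
  if (any(m < 0) || any(m != floor(m))) {
    stop("non-integer or negative counts in ", path, call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Write an ASV count table
#'
#' @param table A `count_table`.
#' @param path Output path.
#' @param format `"tsv"` or `"biom"` (classic JSON BIOM via `biomformat`).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom")) {
  stopifnot(inherits(table, "count_table"))
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("writing BIOM requires the 'biomformat' package", call. = FALSE)
    }
    biomformat::write_biom(biomformat::make_biom(table$values), path)
    return(invisible(path))
  }
  df <- data.frame(asv_id = taxon_ids(table), table$values,
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# controlled vocabularies of the study design
ROLE_LEVELS <- c("flower", "forager", "hive_bee", "nurse_bee", "pupa")
ENVIRONMENT_LEVELS <- c("wild", "open_field", "tunnel", "greenhouse")

#' Construct and validate a sample metadata frame
#'
#' @param df Data frame with a `sample_id` column; recognised columns
#'   (`role`, `environment`, `farmer`, `netted`, `surface_area`,
#'   `treated`, `substrate`, `commercial_pollination`, `organic`,
#'   `heated`, `professional`, `days_in_transit`, `read_count`) are
#'   validated, any other columns are retained untouched.
#' @return A `sample_frame` (a validated data frame).
#' @export
sample_frame <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id '",
         df$sample_id[duplicated(df$sample_id)][1L], "' in metadata",
         call. = FALSE)
  }
  check_vocab <- function(col, levels) {
    if (!col %in% colnames(df)) return()
    val <- df[[col]]
    val[val == ""] <- NA
    bad <- !is.na(val) & !val %in% levels
    if (any(bad)) {
      stop(sprintf("invalid %s '%s'; allowed values: {%s}", col,
                   val[bad][1L], paste(levels, collapse = ", ")),
           call. = FALSE)
    }
    df[[col]] <<- val
  }
  check_vocab("role", ROLE_LEVELS)
  check_vocab("environment", ENVIRONMENT_LEVELS)
  for (col in c("netted", "treated", "substrate", "commercial_pollination",
                "organic", "heated")) {
    if (col %in% colnames(df) && !is.logical(df[[col]])) {
      val <- tolower(as.character(df[[col]]))
      val[val == ""] <- NA
      ok <- is.na(val) | val %in% c("true", "false", "yes", "no", "t", "f")
      if (!all(ok)) {
        stop(sprintf("invalid %s '%s'; expected a logical value", col,
                     df[[col]][!ok][1L]), call. = FALSE)
      }
      df[[col]] <- val %in% c("true", "yes", "t") & !is.na(val)
      df[[col]][is.na(val)] <- NA
    }
  }
  for (col in c("surface_area", "days_in_transit", "read_count")) {
    if (col %in% colnames(df)) {
      val <- df[[col]]
      if (!is.numeric(val)) {
        val[val == ""] <- NA
        num <- suppressWarnings(as.numeric(val))
        if (any(!is.na(val) & is.na(num))) {
          stop(sprintf("invalid numeric %s '%s'", col,
                       val[!is.na(val) & is.na(num)][1L]), call. = FALSE)
        }
        val <- num
      }
      if (any(!is.na(val) & val < 0)) {
        stop(col, " must be non-negative", call. = FALSE)
      }
      if (col == "surface_area" && any(!is.na(val) & val == 0)) {
        stop("surface_area must be positive or missing", call. = FALSE)
      }
      df[[col]] <- val
    }
  }
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' Read a sample metadata TSV
#'
#' Missing cells (empty strings) become `NA`, never zero.
#'
#' @param path Path to a TSV with a `sample_id` column.
#' @return A `sample_frame`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sample_frame(df)
}

#' Write sample metadata as TSV
#'
#' @param meta A `sample_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write_tsv(as.data.frame(meta), path)
  invisible(path)
}

#' Read a taxonomy TSV
#'
#' Expected columns: `asv_id` plus any of
#' `domain, phylum, class, order, family, genus`.
#'
#' @param path Path to the TSV.
#' @return Data frame of rank labels, row names are taxon ids.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"asv_id" %in% colnames(df)) {
    stop("taxonomy must contain an 'asv_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$asv_id)) {
    stop("duplicate asv_id in taxonomy", call. = FALSE)
  }
  rownames(df) <- df$asv_id
  df$asv_id <- NULL
  df
}
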