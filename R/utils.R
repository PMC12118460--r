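#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a caller-supplied seed fully determines the result
#' and the caller's global random state is left untouched.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' All permutations of 1..n
#'
#' Recursive enumeration used for exhaustive permutation tests on very
#' small sample sets (n! rows; capped at n = 8).
#'
#' @param n Number of elements.
#' @return An `n! x n` integer matrix, one permutation per row; the first
#'   row is the identity.
#' @keywords internal
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive permutations limited to n <= 8", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  # reorder so the identity comes first (convenient for callers)
  idx <- which(apply(out, 1L, function(p) all(p == seq_len(n))))
  out[c(idx, setdiff(seq_len(nrow(out)), idx)), , drop = FALSE]
}

#' Write a data frame as a plain TSV file
#'
#' @param x Data frame.
#' @param path Output path.
#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
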