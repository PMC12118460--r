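test_that("count table TSV round-trips identically and errors are specific", {
  tb <- tiny_table(matrix(c(5L, 1L, 0L, 2L), 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tb, path)
  back <- read_count_table(path)
  expect_identical(back$values, tb$values)

  # duplicated taxon id named in the error
  writeLines(c("asv_id\tS1\tS2", "ASV1\t1\t2", "ASV1\t3\t4"), path)
  expect_error(read_count_table(path), "ASV1")

  # negative cell cited with its position
  writeLines(c("asv_id\tS1\tS2", "ASV1\t1\t2", "ASV2\t-3\t4"), path)
  expect_error(read_count_table(path), "ASV2.*S1")

  # empty table rejected
  writeLines("asv_id\tS1", path)
  expect_error(read_count_table(path), "empty")
})

test_that("random tables round-trip through TSV and BIOM", {
  skip_if_not_installed("biomformat")
  set.seed(42)
  for (i in 1:5) {
    v <- matrix(rpois(30, 4), 6, 5,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:5)))
    storage.mode(v) <- "integer"
    tb <- count_table(v)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_count_table(tb, tsv)
    expect_identical(read_count_table(tsv)$values, v)
    biom <- withr::local_tempfile(fileext = ".biom")
    suppressWarnings(write_count_table(tb, biom, format = "biom"))
    got <- read_count_table(biom, format = "biom")
    expect_identical(got$values[rownames(v), colnames(v)], v)
  }
})

test_that("metadata vocabulary is enforced and missing values stay missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trole\tenvironment\tsurface_area",
               "A\tflower\tgreenhouse\t12.5",
               "B\tforager\ttunnel\t"), path)
  meta <- read_metadata(path)
  expect_s3_class(meta, "sample_frame")
  expect_equal(meta$surface_area, c(12.5, NA))

  writeLines(c("sample_id\tenvironment", "A\tpolytunnel"), path)
  expect_error(read_metadata(path),
               "wild, open_field, tunnel, greenhouse")

  writeLines(c("sample_id", "A", "A"), path)
  expect_error(read_metadata(path), "duplicate sample id")

  writeLines(c("id\tenvironment", "A\twild"), path)
  expect_error(read_metadata(path), "sample_id")
})

test_that("filter_dataset applies its stages in the documented order", {
  # taxa: organellar, long-sequence, and two clean ones; sample S2 only
  # stays above the floor because its organellar reads don't count
  v <- matrix(c(
    400L, 450L,   # chloroplast-annotated
    0L,  30L,     # 261-base sequence
    80L, 400L,    # clean
    40L, 100L),   # clean
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("t", 1:4), c("S1", "S2")))
  tax <- data.frame(order = c("Chloroplast", "Rhizobiales",
                              "Rhizobiales", "Rhizobiales"),
                    row.names = paste0("t", 1:4))
  seqs <- c(t1 = strrep("A", 250), t2 = strrep("A", 261),
            t3 = strrep("A", 260), t4 = strrep("A", 100))
  tb <- count_table(v, taxonomy = tax, sequences = seqs)
  res <- filter_dataset(tb, min_reads = 500L)
  expect_equal(res$report$organellar, "t1")
  expect_equal(res$report$too_long, "t2")     # 261 removed, 260 kept
  expect_equal(res$report$low_depth_samples, "S1")  # 120 < 500 post-filter
  expect_equal(sample_ids(res$table), "S2")
  expect_setequal(taxon_ids(res$table), c("t3", "t4"))

  # boundary: exactly 500 reads is retained, 499 is not
  v2 <- matrix(c(499L, 500L), 1, 2,
               dimnames = list("t1", c("A", "B")))
  res2 <- filter_dataset(count_table(v2), drop_organellar = FALSE)
  expect_equal(sample_ids(res2$table), "B")

  expect_error(filter_dataset(tiny_table(matrix(1L)), drop_organellar = TRUE),
               "taxonomy")
  expect_error(filter_dataset(tiny_table(matrix(10L)),
                              drop_organellar = FALSE),
               "below")
})

test_that("to_relative normalises, preserves zeros, and is scale invariant", {
  tb <- tiny_table(matrix(c(3L, 1L, 0L, 5L), 2, 2))
  rel <- to_relative(tb)
  expect_equal(rel$values[, 1], c(ASV1 = 0.75, ASV2 = 0.25))
  expect_true(rel$is_relative)
  expect_equal(unname(colSums(rel$values)), c(1, 1))
  expect_equal(rel$values["ASV1", 2], 0)

  scaled <- tiny_table(tb$values * 10L)
  expect_equal(to_relative(scaled)$values, rel$values)

  expect_error(to_relative(tiny_table(matrix(c(1L, 0L), 1, 2))), "S2")
})

test_that("rarefy conserves depth, support, and is seed-deterministic", {
  set.seed(7)
  v <- matrix(rpois(40, 40), 8, 5,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  storage.mode(v) <- "integer"
  tb <- count_table(v)
  r1 <- rarefy(tb, depth = 100, seed = 7)
  expect_true(all(colSums(r1$values) == 100))
  expect_true(all(r1$values <= v))            # never invents reads
  expect_true(all(r1$values[v == 0] == 0))    # support preserved
  expect_identical(rarefy(tb, 100, seed = 7)$values, r1$values)
  expect_false(identical(rarefy(tb, 100, seed = 8)$values, r1$values))
  expect_error(rarefy(tb, depth = 10000, seed = 1), "s1")
})

test_that("aggregate_by_rank sums counts and reports unassigned taxa", {
  v <- matrix(c(2L, 3L, 4L), 3, 1,
              dimnames = list(paste0("t", 1:3), "S1"))
  tax <- data.frame(genus = c("Sphingomonas", "Sphingomonas", NA),
                    row.names = paste0("t", 1:3))
  tb <- count_table(v, taxonomy = tax)
  agg <- aggregate_by_rank(tb, "genus")
  expect_equal(agg$values["Sphingomonas", "S1"], 5L)
  expect_equal(attr(agg, "excluded_taxa"), "t3")
  # conservation: retained reads = input minus excluded
  expect_equal(sum(agg$values), sum(v) - 4L)
  expect_error(aggregate_by_rank(tiny_table(matrix(1L)), "genus"),
               "taxonomy")
})
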