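test_that("bray-curtis has the documented range, symmetry, and hand value", {
  tb <- tiny_table(cbind(c(1L, 1L, 0L), c(2L, 0L, 0L)))
  D <- bray_curtis(tb)
  # p_a = [.5,.5,0], p_b = [1,0,0]: shared mass 0.5
  expect_equal(D$values["S1", "S2"], 0.5)

  ident <- tiny_table(cbind(c(3L, 1L), c(6L, 2L)))   # same composition
  expect_equal(bray_curtis(ident)$values["S1", "S2"], 0)
  disjoint <- tiny_table(cbind(c(4L, 0L), c(0L, 9L)))
  expect_equal(bray_curtis(disjoint)$values["S1", "S2"], 1)

  set.seed(2)
  v <- matrix(rpois(48, 5), 8, 6,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:6)))
  v[, 1][v[, 1] == 0] <- 1L
  storage.mode(v) <- "integer"
  D2 <- bray_curtis(count_table(v))
  expect_true(all(D2$values >= 0 & D2$values <= 1))
  expect_equal(D2$values, t(D2$values))
  expect_equal(unname(diag(D2$values)), rep(0, 6))
})

test_that("pcoa reproduces euclidean geometry and reports negative axes", {
  # collinear 1-D points: single positive axis, distances reproduced
  D <- euclid_dist(matrix(c(0, 1, 3), 3, 1))
  ord <- pcoa(D)
  pos <- sum(ord$eigenvalues > 1e-8 * max(ord$eigenvalues))
  expect_equal(pos, 1L)
  expect_equal(as.matrix(dist(ord$coordinates[, 1])),
               unname(D$values), ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(sum(ord$eigenvalues), ord$trace, tolerance = 1e-8)

  # three equidistant samples: two equal positive eigenvalues
  m <- matrix(1, 3, 3) - diag(3)
  dimnames(m) <- list(paste0("x", 1:3), paste0("x", 1:3))
  ord2 <- pcoa(dist_matrix(m))
  expect_equal(ord2$eigenvalues[1], ord2$eigenvalues[2], tolerance = 1e-10)

  # agreement with ape's implementation on a Bray-Curtis matrix
  skip_if_not_installed("ape")
  set.seed(4)
  v <- matrix(rpois(60, 6) + 1L, 10, 6,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  D3 <- bray_curtis(count_table(v))
  ord3 <- pcoa(D3)
  ref <- ape::pcoa(as.dist(D3$values))
  expect_equal(ord3$eigenvalues[seq_len(ncol(ord3$coordinates))],
               unname(ref$values$Eigenvalues[seq_len(ncol(ord3$coordinates))]),
               tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0.5, 0, 1, 1, 2, 0), 3, 3,
                           dimnames = list(1:3, 1:3))), "symmetric")
})

test_that("permanova matches vegan's decomposition and is label-invariant", {
  set.seed(10)
  sim <- gen_grouped(synthetic_spec(n_taxa = 60, n_samples = 8,
                                    effect = 0.5, seed = 77))
  D <- bray_curtis(sim$table)
  meta <- sim$meta
  meta$cov <- rnorm(nrow(meta))
  pt <- permanova(D, meta, terms = c("group", "cov"), n_perm = 99,
                  seed = 1)
  ref <- vegan::adonis2(as.dist(D$values) ~ group + cov,
                        data = as.data.frame(meta), by = "terms",
                        permutations = 2)
  expect_equal(pt$table$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(pt$table$F[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(pt$table$R2[1:2], ref$R2[1:2], tolerance = 1e-8)
  expect_equal(sum(pt$table$SS[1:3]), pt$table$SS[4], tolerance = 1e-8)
  expect_equal(sum(pt$table$R2[1:3]), 1, tolerance = 1e-10)

  # permuting sample order with labels attached changes nothing
  perm <- sample(length(D$sample_ids))
  D2 <- dist_matrix(D$values[perm, perm])
  pt2 <- permanova(D2, meta, terms = c("group", "cov"), n_perm = 99,
                   seed = 1)
  expect_equal(pt2$table$SS, pt$table$SS, tolerance = 1e-10)
  expect_equal(pt2$table$F[1:2], pt$table$F[1:2], tolerance = 1e-10)
})

test_that("exhaustive permanova p equals the enumeration oracle (n <= 7)", {
  skip_if_not_installed("MASS")
  # perfect separation, 2+2: p must be exactly 1/3
  xy <- matrix(c(0, 0, 0, 0.1, 5, 0, 5, 0.1), 4, 2, byrow = TRUE)
  D <- euclid_dist(xy)
  meta <- data.frame(sample_id = D$sample_ids,
                     g = c("a", "a", "b", "b"))
  pt <- permanova(D, meta, terms = "g", exhaustive = TRUE)
  expect_equal(pt$table$p[1], 1 / 3)

  set.seed(21)
  for (n in c(5L, 6L, 7L)) {
    xy <- matrix(rnorm(2 * n), n, 2)
    D <- euclid_dist(xy)
    g <- rep(c("a", "b"), length.out = n)
    meta <- data.frame(sample_id = D$sample_ids, g = g)
    pt <- permanova(D, meta, terms = "g", exhaustive = TRUE)
    oracle <- oracle_permanova_exhaustive_p(D$values, meta, "g")
    expect_equal(pt$table$p[1], oracle, tolerance = 1e-12)
  }
})

test_that("perfectly separated duplicated samples give R2 = 1", {
  v <- cbind(a1 = c(10L, 0L), a2 = c(10L, 0L),
             b1 = c(0L, 10L), b2 = c(0L, 10L))
  rownames(v) <- c("t1", "t2")
  D <- bray_curtis(count_table(v))
  meta <- data.frame(sample_id = colnames(v), g = c("a", "a", "b", "b"))
  pt <- permanova(D, meta, terms = "g", n_perm = 99, seed = 1)
  expect_equal(pt$table$R2[1], 1, tolerance = 1e-10)
  expect_equal(pt$table$SS[2], 0, tolerance = 1e-10)
})

test_that("permanova validates terms and drops incomplete samples", {
  D <- euclid_dist(matrix(rnorm(12), 6, 2))
  meta <- data.frame(sample_id = D$sample_ids,
                     g = c("a", "a", "a", "b", "b", NA),
                     single = "only")
  expect_warning(pt <- permanova(D, meta, terms = "g", n_perm = 19),
                 "dropped")
  expect_equal(pt$n_samples, 5L)
  expect_error(permanova(D, meta, terms = "single"), "single level")
  expect_error(permanova(D, meta, terms = "missing_col"), "missing_col")
  meta$overfit <- factor(paste0("l", 1:6))
  expect_error(permanova(D, meta, terms = "overfit"), "degrees of freedom")
})

test_that("dispersion detects planted spread and respects symmetry", {
  # mirror-image groups: identical internal geometry -> F ~ 0
  xy <- rbind(matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE),
              matrix(c(10, 0, 11, 0, 10, 1), 3, 2, byrow = TRUE))
  D <- euclid_dist(xy)
  dr <- dispersion(D, rep(c("a", "b"), each = 3), center = "centroid")
  expect_lt(dr$F, 1e-10)
  expect_equal(unname(dr$group_means[1]), unname(dr$group_means[2]),
               tolerance = 1e-10)

  # centroid distances equal plain euclidean distances to the group mean
  set.seed(11)
  xy2 <- matrix(rnorm(40), 20, 2)
  g2 <- rep(c("a", "b"), each = 10)
  D2 <- euclid_dist(xy2)
  dr2 <- dispersion(D2, g2, center = "centroid")
  manual <- vapply(seq_len(20), function(i) {
    ctr <- colMeans(xy2[g2 == g2[i], , drop = FALSE])
    sqrt(sum((xy2[i, ] - ctr)^2))
  }, numeric(1))
  expect_equal(unname(dr2$distances), manual, tolerance = 1e-8)

  # tight vs spread cluster ordering
  sim <- gen_grouped(synthetic_spec(n_taxa = 80, n_samples = 10,
                                    effect = 0, dispersion = c(1, 4),
                                    seed = 5))
  D3 <- bray_curtis(sim$table)
  dr3 <- dispersion(D3, setNames(sim$meta$group, sim$meta$sample_id))
  expect_lt(dr3$group_means[["group1"]], dr3$group_means[["group2"]])

  expect_warning(
    dispersion(D2, c(rep(c("a", "b"), each = 9), "c", "d")),
    "fewer than 2")
})

test_that("within_group_beta partitions exactly the within-group pairs", {
  set.seed(12)
  v <- matrix(rpois(35, 6) + 1L, 5, 7,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:7)))
  D <- bray_curtis(count_table(v))
  g <- c("a", "a", "a", "b", "b", "b", "b")
  wg <- within_group_beta(D, g)
  expect_equal(sum(wg$pairs$group == "a"), 3L)   # C(3,2)
  expect_equal(sum(wg$pairs$group == "b"), 6L)   # C(4,2)
  # every pair appears exactly once with the right value
  for (r in seq_len(nrow(wg$pairs))) {
    expect_equal(wg$pairs$dissimilarity[r],
                 D$values[wg$pairs$sample_a[r], wg$pairs$sample_b[r]])
  }
  ident <- tiny_table(cbind(a = c(2L, 2L), b = c(4L, 4L), c = c(1L, 1L)))
  wg2 <- within_group_beta(bray_curtis(ident), rep("g", 3))
  expect_equal(wg2$pairs$dissimilarity, rep(0, 3))
})

test_that("dbrda recovers a pcoa axis used as its own constraint", {
  set.seed(13)
  xy <- matrix(rnorm(30), 15, 2)
  D <- euclid_dist(xy)
  ord <- pcoa(D)
  res <- dbrda_constrained(D, ord$coordinates[, 1], n_perm = 99, seed = 1)
  expect_equal(unname(res$constrained_eig[1]), ord$eigenvalues[1],
               tolerance = 1e-8)

  # constraint orthogonal to all positive axes explains ~ nothing
  qorth <- qr.resid(qr(cbind(1, ord$coordinates)), rnorm(15))
  if (sd(qorth) > 0) {
    res2 <- dbrda_constrained(D, qorth, n_perm = 99, seed = 1)
    expect_lt(res2$constrained_prop, 1e-8)
  }
  expect_error(dbrda_constrained(D, rep(1, 15)), "constant")
})

test_that("dbrda permutation p is roughly uniform under the null", {
  set.seed(14)
  v <- matrix(rpois(200, 8) + 1L, 20, 10,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  D <- bray_curtis(count_table(v))
  ps <- vapply(1:200, function(i) {
    dbrda_constrained(D, rnorm(10), n_perm = 49, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
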