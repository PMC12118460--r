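#' Specification for the synthetic community generators
#'
#' Collects the parameters the seeded generators share. Defaults are the
#' reference simulation conditions used throughout the package's
#' validation: 200 taxa, 50 samples at a fixed depth of 500 reads (the
#' neutral model's sampling depth), a log-normal metacommunity with
#' sdlog 2 (a realistically heavy-tailed rank-abundance curve),
#' migration m = 0.15, and, where groups are involved, a mixing weight
#' of 0.5 toward group-specific metacommunities.
#'
#' @param n_taxa Number of taxa in the metacommunity.
#' @param n_samples Samples per group/role/environment.
#' @param reads Reads per sample (fixed depth N).
#' @param m Migration parameter of the neutral sampling model (> 0).
#' @param meta_meanlog,meta_sdlog Log-normal parameters of the
#'   metacommunity relative abundances (normalised after drawing).
#' @param n_groups Number of groups for [gen_grouped()].
#' @param effect Group effect size in \[0, 1\]: mixing weight toward an
#'   independent group-specific metacommunity.
#' @param dispersion Per-group dispersion multiplier (recycled); the
#'   Dirichlet concentration is divided by it, so 2 doubles the
#'   within-group spread relative to 1.
#' @param sharing Fraction of eligible flower taxa planted into forager
#'   samples by [gen_flower_forager()].
#' @param min_count Flower-side eligibility threshold used when planting
#'   shared taxa (matches [transfer_index()]).
#' @param n_foragers Forager samples per environment.
#' @param n_specialist Forager-specialist taxa absent from flowers.
#' @param n_core Taxa forming a high-abundance metacommunity head
#'   (0 disables the planted core).
#' @param core_share Total metacommunity mass of the planted head.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_taxa = 200L, n_samples = 50L, reads = 500L,
                           m = 0.15, meta_meanlog = 0, meta_sdlog = 2,
                           n_groups = 2L, effect = 0.5, dispersion = 1,
                           sharing = 0.4, min_count = 3L,
                           n_foragers = 5L, n_specialist = 30L,
                           n_core = 0L, core_share = 0.5, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (m <= 0) stop("`m` must be > 0", call. = FALSE)
  if (effect < 0 || effect > 1) stop("`effect` must lie in [0, 1]",
                                     call. = FALSE)
  if (sharing < 0 || sharing > 1) stop("`sharing` must lie in [0, 1]",
                                       call. = FALSE)
  if (reads < 1) stop("`reads` must be >= 1", call. = FALSE)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples),
                 reads = as.integer(reads), m = m,
                 meta_meanlog = meta_meanlog, meta_sdlog = meta_sdlog,
                 n_groups = as.integer(n_groups), effect = effect,
                 dispersion = dispersion, sharing = sharing,
                 min_count = as.integer(min_count),
                 n_foragers = as.integer(n_foragers),
                 n_specialist = as.integer(n_specialist),
                 n_core = as.integer(n_core), core_share = core_share,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# log-normal metacommunity, optionally with a planted high-mass head
draw_metacommunity <- function(spec, taxa) {
  p <- stats::rlnorm(length(taxa), spec$meta_meanlog, spec$meta_sdlog)
  p <- p / sum(p)
  names(p) <- taxa
  if (spec$n_core > 0L) {
    head_ids <- seq_len(spec$n_core)
    p[head_ids] <- spec$core_share / spec$n_core
    p[-head_ids] <- p[-head_ids] / sum(p[-head_ids]) * (1 - spec$core_share)
  }
  p
}

# Dirichlet-multinomial sampling of the Sloan stationary distribution:
# alpha_i = N*m*p_i gives Beta(Nmp_i, Nm(1-p_i)) marginal abundances
sample_communities <- function(p, m, reads, n_samples, dispersion = 1,
                               sample_names) {
  alpha <- reads * m * p / dispersion
  out <- matrix(0L, length(p), n_samples,
                dimnames = list(names(p), sample_names))
  for (j in seq_len(n_samples)) {
    g <- stats::rgamma(length(p), shape = alpha)
    while (sum(g) <= 0) g <- stats::rgamma(length(p), shape = alpha)
    out[, j] <- stats::rmultinom(1L, reads, g / sum(g))[, 1L]
  }
  out
}

taxon_names <- function(n, prefix = "ASV") {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

#' Simulate a neutrally assembled community
#'
#' Draws a log-normal metacommunity `p`, then for each sample a local
#' composition from Dirichlet(N m p) and counts from
#' Multinomial(N, composition). By construction the marginal per-taxon
#' relative abundance is Beta(N m p_i, N m (1 - p_i)) — exactly the
#' stationary distribution whose detection frequency
#' [neutral_occupancy()] predicts, so generator and fitter are
#' counterparts.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `table` (a `count_table`, all column sums equal
#'   `spec$reads`) and `truth` (`p`, `m`, `N`).
#' @export
gen_neutral <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    taxa <- taxon_names(spec$n_taxa)
    p <- draw_metacommunity(spec, taxa)
    v <- sample_communities(p, spec$m, spec$reads, spec$n_samples,
                            sample_names = sprintf("S%03d",
                                                   seq_len(spec$n_samples)))
    list(table = count_table(v),
         truth = list(p = p, m = spec$m, N = spec$reads))
  })
}

#' Simulate grouped communities with compositional and dispersion effects
#'
#' Group g samples from metacommunity
#' \eqn{p_g = (1-\epsilon) p + \epsilon q_g} with independent
#' group-specific \eqn{q_g}, and Dirichlet concentration divided by the
#' group's dispersion multiplier (multiplier 2 = twice the within-group
#' spread).
#'
#' @param spec A `synthetic_spec` (`n_groups`, `effect`, `dispersion`).
#' @return List with `table`, `meta` (a `sample_frame` with `group`,
#'   `farmer`, `role`, `environment` columns) and `truth`.
#' @export
gen_grouped <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_groups < 2L) stop("need >= 2 groups", call. = FALSE)
  disp <- rep_len(spec$dispersion, spec$n_groups)
  with_seed(spec$seed, {
    taxa <- taxon_names(spec$n_taxa)
    p <- draw_metacommunity(spec, taxa)
    blocks <- vector("list", spec$n_groups)
    p_groups <- vector("list", spec$n_groups)
    for (g in seq_len(spec$n_groups)) {
      q <- stats::rlnorm(spec$n_taxa, spec$meta_meanlog, spec$meta_sdlog)
      q <- q / sum(q)
      pg <- (1 - spec$effect) * p + spec$effect * q
      p_groups[[g]] <- pg
      blocks[[g]] <- sample_communities(
        pg, spec$m, spec$reads, spec$n_samples, dispersion = disp[g],
        sample_names = sprintf("G%d_S%03d", g, seq_len(spec$n_samples)))
    }
    v <- do.call(cbind, blocks)
    meta <- sample_frame(data.frame(
      sample_id = colnames(v),
      group = rep(paste0("group", seq_len(spec$n_groups)),
                  each = spec$n_samples),
      farmer = rep(paste0("farmer", seq_len(spec$n_groups)),
                   each = spec$n_samples),
      role = "flower", environment = "open_field",
      stringsAsFactors = FALSE))
    list(table = count_table(v), meta = meta,
         truth = list(p = p, p_groups = p_groups, m = spec$m,
                      effect = spec$effect, dispersion = disp))
  })
}

# plant forager samples containing a fraction `sharing` of the eligible
# flower taxa of one environment, plus forager-specialist taxa; exactly
# round(s * K) of the K eligible taxa are planted so the realised
# per-environment sharing fraction is s by construction, and every
# forager carries the full pool at the same read depth as the flowers
build_foragers <- function(flower_counts, spec, env, specialist_ids) {
  eligible_union <- rownames(flower_counts)[
    apply(flower_counts > spec$min_count, 1L, any)]
  n_sel <- round(spec$sharing * length(eligible_union))
  selected <- if (n_sel > 0) sample(eligible_union, n_sel) else character()
  pool <- c(selected, specialist_ids)
  fv <- matrix(0L, length(pool), spec$n_foragers,
               dimnames = list(pool, sprintf("%s_F%02d", env,
                                             seq_len(spec$n_foragers))))
  depth <- max(spec$reads, length(pool) + 1L)
  for (j in seq_len(spec$n_foragers)) {
    w <- stats::rgamma(length(pool), shape = 1)
    fv[, j] <- stats::rmultinom(1L, depth - length(pool),
                                w / sum(w))[, 1L] + 1L
  }
  list(values = fv, selected = selected)
}

merge_counts <- function(blocks) {
  taxa <- unique(unlist(lapply(blocks, rownames)))
  samples <- unlist(lapply(blocks, colnames))
  v <- matrix(0L, length(taxa), length(samples),
              dimnames = list(taxa, samples))
  for (b in blocks) v[rownames(b), colnames(b)] <- b
  v
}

#' Simulate a pollinator-exclusion experiment (flowers + foragers)
#'
#' Two environments (`open_field`, `tunnel`) of flowers are generated
#' from environment-specific metacommunities; half the flowers are
#' flagged netted. Forager samples are then built to contain a planted
#' fraction `sharing` of the environment's eligible flower taxa
#' (flower count > `min_count`), plus forager-specialist taxa absent
#' from flowers, so the realised [transfer_index()] has known
#' expectation `sharing`.
#'
#' Flowers here default to strong drift (m = 0.05): individual flowers
#' are ephemeral, weakly coupled habitats, which also keeps their
#' eligible ASV sets largely distinct.
#'
#' @param spec A `synthetic_spec`; `n_samples` is flowers per
#'   environment.
#' @param m Migration parameter for the flower communities (default
#'   0.05, overriding `spec$m`).
#' @return List with `table`, `meta` and `truth` (per-environment
#'   planted shared taxa and the sharing fraction).
#' @export
gen_flower_forager <- function(spec, m = 0.05) {
  stopifnot(inherits(spec, "synthetic_spec"))
  envs <- c("open_field", "tunnel")
  with_seed(spec$seed, {
    taxa <- taxon_names(spec$n_taxa)
    p <- draw_metacommunity(spec, taxa)
    specialist_ids <- taxon_names(spec$n_specialist, prefix = "FSP")
    blocks <- list()
    meta_rows <- list()
    truth <- list(sharing = spec$sharing, selected = list())
    for (env in envs) {
      q <- stats::rlnorm(spec$n_taxa, spec$meta_meanlog, spec$meta_sdlog)
      q <- q / sum(q)
      pe <- (1 - spec$effect) * p + spec$effect * q
      names(pe) <- taxa
      fl <- sample_communities(
        pe, m, spec$reads, spec$n_samples,
        sample_names = sprintf("%s_FL%03d", env, seq_len(spec$n_samples)))
      fo <- build_foragers(fl, spec, env, specialist_ids)
      truth$selected[[env]] <- fo$selected
      blocks <- c(blocks, list(fl, fo$values))
      meta_rows[[env]] <- data.frame(
        sample_id = c(colnames(fl), colnames(fo$values)),
        role = c(rep("flower", ncol(fl)), rep("forager", ncol(fo$values))),
        environment = env,
        netted = c(rep(c(TRUE, FALSE), length.out = ncol(fl)),
                   rep(NA, ncol(fo$values))),
        stringsAsFactors = FALSE)
    }
    v <- merge_counts(blocks)
    meta <- sample_frame(do.call(rbind, meta_rows))
    list(table = count_table(v), meta = meta, truth = truth)
  })
}

#' Simulate a community with a planted core and rare noise taxa
#'
#' Ten structured taxa are present in (almost) every sample and jointly
#' hold the stated share of the reads; the remaining noise taxa are rare
#' (per-sample presence probability `noise_presence`, so occupancy stays
#' low) and share the rest. This is the reference fixture for validating
#' [core_by_elbow()]: the correct answer is exactly the planted set.
#'
#' @param seed Mandatory integer seed.
#' @param n_core Number of planted core taxa (default 10).
#' @param n_noise Number of noise taxa (default 200).
#' @param n_samples Samples (default 20).
#' @param reads Reads per sample (default 1000).
#' @param core_share Fraction of each sample's reads carried by the core
#'   (default 0.85).
#' @param noise_presence Per-sample presence probability of each noise
#'   taxon (default 0.05, keeping noise occupancy at or below ~0.1).
#' @return List with `table` and `truth` (`core` ids).
#' @export
gen_planted_core <- function(seed, n_core = 10L, n_noise = 200L,
                             n_samples = 20L, reads = 1000L,
                             core_share = 0.85, noise_presence = 0.05) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  with_seed(seed, {
    core_ids <- sprintf("CORE%02d", seq_len(n_core))
    noise_ids <- sprintf("NOISE%03d", seq_len(n_noise))
    v <- matrix(0L, n_core + n_noise, n_samples,
                dimnames = list(c(core_ids, noise_ids),
                                sprintf("S%03d", seq_len(n_samples))))
    n_core_reads <- round(reads * core_share)
    for (j in seq_len(n_samples)) {
      w <- stats::rgamma(n_core, shape = 50)  # near-even core
      v[seq_len(n_core), j] <- stats::rmultinom(1L, n_core_reads,
                                                w / sum(w))[, 1L]
      present <- stats::runif(n_noise) < noise_presence
      if (any(present)) {
        wn <- stats::rgamma(sum(present), shape = 1)
        v[n_core + which(present), j] <-
          stats::rmultinom(1L, reads - n_core_reads, wn / sum(wn))[, 1L]
      }
    }
    list(table = count_table(v), truth = list(core = core_ids))
  })
}

#' Simulate a full multi-environment study
#'
#' One dataset emulating a multi-environment flower/forager survey:
#' per-environment migration parameters (wild communities track the
#' regional metacommunity most closely, greenhouse least), a planted
#' 10-taxon high-abundance core per environment, planted flower-forager
#' sharing, and sub-500-read decoy samples that downstream filtering
#' must remove. All sample depths except the decoys are `reads_full`.
#'
#' @param seed Mandatory integer seed.
#' @param m_env Named per-environment migration parameters.
#' @param n_flowers Flowers per environment.
#' @param n_foragers Foragers per environment.
#' @param n_taxa Tail (non-core, non-specialist) taxa shared across
#'   environments.
#' @param reads_full Depth of regular samples.
#' @param reads_decoy Depth of decoy samples (below the 500-read floor).
#' @param n_decoys Decoy flower samples per environment.
#' @param sharing Planted flower-forager sharing fraction.
#' @return List with `table`, `meta` and `truth` (`m` per environment,
#'   planted `core` sets, `sharing`, decoy sample ids).
#' @export
gen_study <- function(seed,
                      m_env = c(wild = 0.4, open_field = 0.2,
                                tunnel = 0.08, greenhouse = 0.05),
                      n_flowers = 15L, n_foragers = 4L, n_taxa = 200L,
                      reads_full = 1000L, reads_decoy = 300L,
                      n_decoys = 2L, sharing = 0.4) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  envs <- names(m_env)
  with_seed(seed, {
    tail_taxa <- taxon_names(n_taxa)
    specialist_ids <- taxon_names(30L, prefix = "FSP")
    blocks <- list()
    meta_rows <- list()
    truth <- list(m = m_env, core = list(), sharing = sharing,
                  decoys = character())
    for (env in envs) {
      core_ids <- sprintf("CORE_%s_%02d", env, 1:10)
      taxa <- c(core_ids, tail_taxa)
      p <- stats::rlnorm(n_taxa, 0, 2)
      p <- p / sum(p) * 0.4
      p <- c(stats::setNames(rep(0.6 / 10, 10), core_ids),
             stats::setNames(p, tail_taxa))
      truth$core[[env]] <- core_ids
      fl <- sample_communities(
        p, m_env[[env]], reads_full, n_flowers,
        sample_names = sprintf("%s_FL%03d", env, seq_len(n_flowers)))
      spec_env <- synthetic_spec(n_taxa = length(taxa), seed = seed,
                                 sharing = sharing, reads = reads_full,
                                 n_foragers = n_foragers)
      fo <- build_foragers(fl, spec_env, env, specialist_ids)
      dec <- sample_communities(
        p, m_env[[env]], reads_decoy, n_decoys,
        sample_names = sprintf("%s_decoy%02d", env, seq_len(n_decoys)))
      truth$decoys <- c(truth$decoys, colnames(dec))
      truth$selected[[env]] <- fo$selected
      blocks <- c(blocks, list(fl, fo$values, dec))
      meta_rows[[env]] <- data.frame(
        sample_id = c(colnames(fl), colnames(fo$values), colnames(dec)),
        role = c(rep("flower", ncol(fl)), rep("forager", ncol(fo$values)),
                 rep("flower", ncol(dec))),
        environment = env,
        farmer = paste0(env, "_farm",
                        rep_len(1:2, ncol(fl) + ncol(fo$values) + ncol(dec))),
        netted = c(rep(c(TRUE, FALSE), length.out = ncol(fl)),
                   rep(NA, ncol(fo$values)),
                   rep(c(TRUE, FALSE), length.out = ncol(dec))),
        stringsAsFactors = FALSE)
    }
    v <- merge_counts(blocks)
    meta_df <- do.call(rbind, meta_rows)
    meta_df$read_count <- colSums(v)[meta_df$sample_id]
    meta <- sample_frame(meta_df)
    list(table = count_table(v), meta = meta, truth = truth)
  })
}
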