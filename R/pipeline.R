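#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file; see [run_pipeline()] for the
#'   recognised fields.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

pipeline_defaults <- function() {
  list(
    filter = list(min_reads = 500L, max_asv_len = 260L,
                  drop_organellar = TRUE),
    group = "environment",
    permanova = list(terms = NULL, n_perm = 999L),
    dispersion = list(center = "spatial_median"),
    neutral = list(N = 500L),
    core = list(gain_threshold = 0.02),
    transfer = list(min_count = 3L),
    prevalence = list(grouping = NULL, rank = "asv"),
    stages = c("filter", "alpha", "beta", "dispersion", "core_neutral",
               "transfer", "prevalence")
  )
}

#' Run the full analysis pipeline on a table + metadata pair
#'
#' Orchestrates the package's analyses in the order
#' filter -> alpha diversity -> beta/ordination (PERMANOVA) ->
#' dispersion -> core/neutral per group -> transfer -> prevalence,
#' writing one TSV/JSON artifact per stage plus a run manifest and a
#' log. Every number written comes from the corresponding exported
#' operation; identical config + seed gives identical outputs.
#'
#' Community-level stages (alpha, beta, dispersion, core/neutral) run on
#' flower samples grouped by the `group` column (default
#' `environment`); the transfer stage uses flower and forager samples
#' together and is skipped with a logged notice when no foragers are
#' present.
#'
#' @param config A named list (or path to a YAML file). Fields:
#'   `input` (`counts`, `metadata`, optional `taxonomy` paths — or
#'   in-memory `table` / `meta` objects), `output_dir`, `seed`
#'   (mandatory), and optional stage settings `filter`
#'   (`min_reads`, `max_asv_len`, `drop_organellar`), `group`,
#'   `permanova` (`terms`, `n_perm`), `dispersion` (`center`),
#'   `neutral` (`N`), `core` (`gain_threshold`), `transfer`
#'   (`min_count`), `prevalence` (`grouping`, `rank`), `stages`.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  defaults <- pipeline_defaults()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[sub]])) {
          config[[nm]][[sub]] <- defaults[[nm]][[sub]]
        }
      }
    }
  }
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  if (is.null(config$output_dir)) stop("config must set output_dir",
                                       call. = FALSE)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  note <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  config_echo <- config
  if (!is.null(config_echo$input)) {
    paths <- Filter(is.character, config_echo$input)
    objs <- setdiff(names(config_echo$input), names(paths))
    config_echo$input <- c(paths,
                           if (length(objs)) {
                             list(in_memory = paste(objs, collapse = ","))
                           })
  }
  manifest <- list(config = config_echo,
                   package_version = as.character(
                     utils::packageVersion("anthosphere")),
                   seed = config$seed, stages = list())
  seed <- as.integer(config$seed)

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) {
      manifest$stages[[name]] <<- list(status = "disabled")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       seconds = round(elapsed, 3))
      write_manifest()
      stop("stage ", name, ": ", conditionMessage(res), call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(status = "ok",
                                       seconds = round(elapsed, 3)),
                                  if (is.list(res)) res)
    invisible(res)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  # --- inputs -------------------------------------------------------
  inp <- config$input
  table <- if (!is.null(inp[["table"]])) inp[["table"]] else {
    tax <- if (!is.null(inp[["taxonomy"]])) read_taxonomy(inp[["taxonomy"]])
    tb <- read_count_table(inp[["counts"]],
                           format = inp[["format"]] %||% "tsv")
    if (!is.null(tax)) tb$taxonomy <- tax[taxon_ids(tb), , drop = FALSE]
    tb
  }
  meta <- if (!is.null(inp[["meta"]])) inp[["meta"]] else {
    read_metadata(inp[["metadata"]])
  }
  note(sprintf("input: %d taxa x %d samples", nrow(table$values),
               ncol(table$values)))

  # --- filter -------------------------------------------------------
  filtered <- table
  run_stage("filter", function() {
    fc <- config$filter
    drop_org <- isTRUE(fc$drop_organellar) && !is.null(table$taxonomy)
    if (isTRUE(fc$drop_organellar) && is.null(table$taxonomy)) {
      note("filter: no taxonomy attached, organellar filter skipped")
    }
    fr <- filter_dataset(table, min_reads = fc$min_reads,
                         max_asv_len = fc$max_asv_len,
                         drop_organellar = drop_org)
    filtered <<- fr$table
    rep_df <- data.frame(
      category = names(fr$report),
      n_dropped = vapply(fr$report, length, integer(1)),
      ids = vapply(fr$report, paste, character(1), collapse = ","))
    write_tsv(rep_df, file.path(out_dir, "filter_report.tsv"))
    note(sprintf("filter: %d taxa x %d samples retained",
                 nrow(filtered$values), ncol(filtered$values)))
    list(n_taxa = nrow(filtered$values), n_samples = ncol(filtered$values))
  })
  meta <- meta[meta$sample_id %in% sample_ids(filtered), , drop = FALSE]
  group_col <- config$group
  flowers <- if ("role" %in% colnames(meta)) {
    meta$sample_id[!is.na(meta$role) & meta$role == "flower"]
  } else sample_ids(filtered)
  ftab <- subset_table(filtered, samples = sample_ids(filtered) %in% flowers)
  fgroups <- NULL
  if (group_col %in% colnames(meta)) {
    fgroups <- stats::setNames(
      as.data.frame(meta)[match(sample_ids(ftab), meta$sample_id),
                          group_col],
      sample_ids(ftab))
  }

  # --- alpha --------------------------------------------------------
  run_stage("alpha", function() {
    al <- alpha_diversity(ftab)
    long <- stats::reshape(al, direction = "long",
                           varying = setdiff(colnames(al), "sample_id"),
                           v.names = "value", timevar = "metric",
                           times = setdiff(colnames(al), "sample_id"),
                           idvar = "sample_id")
    rownames(long) <- NULL
    write_tsv(long[order(long$sample_id, long$metric), ],
              file.path(out_dir, "alpha.tsv"))
    if (!is.null(fgroups) && length(unique(stats::na.omit(fgroups))) >= 2) {
      gt <- group_compare(al$inverse_simpson, fgroups,
                          method = "kruskal_dunn_bonferroni")
      write_tsv(gt$comparisons, file.path(out_dir, "alpha_tests.tsv"))
    } else {
      note("alpha: fewer than 2 groups, group tests skipped")
    }
    list(n_samples = nrow(al))
  })

  # --- beta ---------------------------------------------------------
  D <- NULL
  run_stage("beta", function() {
    D <<- bray_curtis(ftab)
    write_dist(D, file.path(out_dir, "distance.tsv"))
    ord <- pcoa(D)
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates[, seq_len(min(4L,
                           ncol(ord$coordinates))), drop = FALSE],
                         check.names = FALSE)
    write_tsv(coords, file.path(out_dir, "pcoa.tsv"))
    terms <- config$permanova$terms
    if (is.null(terms) && !is.null(fgroups)) terms <- group_col
    if (!is.null(terms)) {
      pt <- permanova(D, meta, terms = terms,
                      n_perm = config$permanova$n_perm, seed = seed)
      write_permanova(pt, file.path(out_dir, "permanova.tsv"))
    } else {
      note("beta: no PERMANOVA terms configured, model skipped")
    }
    wg <- within_group_beta(D, fgroups)
    write_tsv(wg$pairs, file.path(out_dir, "within_beta.tsv"))
    list(n_samples = length(D$sample_ids))
  })

  # --- dispersion ---------------------------------------------------
  run_stage("dispersion", function() {
    dr <- dispersion(D, fgroups, center = config$dispersion$center)
    write_tsv(data.frame(sample_id = names(dr$distances),
                         group = as.character(dr$groups),
                         distance = dr$distances),
              file.path(out_dir, "dispersion_distances.tsv"))
    write_tsv(data.frame(group = names(dr$group_means),
                         mean_distance = as.numeric(dr$group_means),
                         F = dr$F, p = dr$p),
              file.path(out_dir, "dispersion.tsv"))
    list(F = dr$F, p = dr$p)
  })

  # --- core + neutral per group ------------------------------------
  run_stage("core_neutral", function() {
    envs <- unique(stats::na.omit(as.character(fgroups)))
    fitted <- list()
    for (e in envs) {
      sub <- subset_table(ftab, samples = !is.na(fgroups) & fgroups == e)
      if (ncol(sub$values) < 3L) {
        note("core_neutral: group '", e, "' has < 3 samples, skipped")
        next
      }
      occab <- occupancy_abundance(sub)
      write_tsv(occab, file.path(out_dir, paste0("occupancy_", e, ".tsv")))
      cr <- core_by_elbow(sub,
                          gain_threshold = config$core$gain_threshold)
      write_core(cr, file.path(out_dir, paste0("core_", e, ".tsv")))
      Nfit <- config$neutral$N
      if (sum(colSums(sub$values) >= Nfit) >= 3L) {
        nf <- suppressWarnings(fit_neutral(sub, N = Nfit, seed = seed))
        write_neutral_fit(nf,
                          tsv_path = file.path(out_dir,
                                               paste0("neutral_", e, ".tsv")),
                          json_path = file.path(out_dir,
                                                paste0("neutral_", e,
                                                       ".json")))
        fitted[[e]] <- nf$m
      } else {
        note("core_neutral: group '", e,
             "' has too few samples at depth ", Nfit,
             ", neutral fit skipped")
      }
    }
    list(groups = envs, m = fitted)
  })

  # --- transfer -----------------------------------------------------
  run_stage("transfer", function() {
    has_foragers <- "role" %in% colnames(meta) &&
      any(!is.na(meta$role) & meta$role == "forager")
    if (!has_foragers) {
      note("transfer: no forager samples, stage skipped")
      return(list(skipped = TRUE))
    }
    tr <- suppressWarnings(transfer_index(filtered, meta,
                                          min_count =
                                            config$transfer$min_count))
    write_transfer(tr, file.path(out_dir, "transfer.tsv"))
    write_tsv(tr$summary, file.path(out_dir, "transfer_summary.tsv"))
    list(n_flowers = nrow(tr$flowers))
  })

  # --- prevalence ---------------------------------------------------
  run_stage("prevalence", function() {
    grouping <- config$prevalence$grouping
    if (is.null(grouping)) {
      note("prevalence: no grouping configured, stage skipped")
      return(list(skipped = TRUE))
    }
    gvals <- as.data.frame(meta)[match(sample_ids(ftab), meta$sample_id),
                                 grouping]
    if (length(unique(stats::na.omit(gvals))) != 2L) {
      note("prevalence: '", grouping,
           "' does not define two groups, stage skipped")
      return(list(skipped = TRUE))
    }
    pr <- prevalence_fisher(ftab, meta, grouping = grouping,
                            rank = config$prevalence$rank)
    write_tsv(as.data.frame(pr), file.path(out_dir, "prevalence.tsv"))
    list(n_taxa = nrow(pr))
  })

  write_manifest()
  note("pipeline complete")
  invisible(manifest)
}
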