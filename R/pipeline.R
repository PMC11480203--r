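#' Run the full synthetic-data pipeline
#'
#' Orchestrates every stage end to end on synthetic inputs: simulate
#' (genome, peaks, TSS, binding counts, expression, cohorts, screen) ->
#' replicate-conservative peak sets and overlap categories -> spike-in
#' normalization and differential binding for both factors -> co-occupancy
#' stratification -> TSS-distance permutation eFDR -> top-induced gene
#' selection and fuzzy clustering -> dual-signature survival screen -> RSA
#' screen scoring.  Every stage's tabular outputs are written under
#' `outdir` (BED/TSV/JSON), the effective configuration is echoed, and a
#' machine-readable `summary.json` collects the headline numbers.  Rerunning
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param config A [sim_config()], a named list of overrides, or a path to a
#'   YAML/JSON file of overrides.
#' @param outdir Output directory (created if needed).
#' @param n_draws Permutation draws for the eFDR stage (default 10,000).
#' @return The summary list, invisibly; also written as
#'   `file.path(outdir, "summary.json")`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("run_"),
                         n_draws = 10000) {
  config <- as_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e) {
      note("stage %-12s FAILED: %s", name, conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    note("stage %-12s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  failed <- function(x) inherits(x, "stage_error")
  summary <- list(package = "cooccupy", seed = config$seed, stages = list())

  jsonlite::write_json(config[order(names(config))],
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sim <- stage("simulate", {
    genome <- make_genome(config)
    land <- simulate_peak_landscape(genome, config)
    counts_a <- simulate_binding_counts(land$truth, config)
    cfg_b <- config; cfg_b$seed <- sub_seed(config$seed, 97)
    counts_b <- simulate_binding_counts(land$truth, cfg_b)
    exprs <- simulate_expression(config)
    cohorts <- simulate_cohort(config)
    screen <- simulate_screen(config)
    readr::write_tsv(land$tss, file.path(outdir, "tss.tsv"))
    write_bed(land$truth, file.path(outdir, "sites_truth.bed"))
    readr::write_tsv(counts_a$counts, file.path(outdir, "counts_factorA.tsv"))
    readr::write_tsv(counts_b$counts, file.path(outdir, "counts_factorB.tsv"))
    readr::write_tsv(exprs$de, file.path(outdir, "de_table.tsv"))
    readr::write_tsv(screen$counts, file.path(outdir, "sgrna_counts.tsv"))
    jsonlite::write_json(
      list(peak_categories = as.list(table(land$truth$category)),
           diff_regions = sum(counts_a$truth$is_diff),
           tyi_genes = sum(exprs$truth$is_tyi),
           screen_hits = sum(screen$truth$is_hit)),
      file.path(outdir, "truth_summary.json"), auto_unbox = TRUE)
    list(genome = genome, land = land, counts_a = counts_a,
         counts_b = counts_b, exprs = exprs, cohorts = cohorts,
         screen = screen)
  })
  if (failed(sim)) {
    summary$stages$simulate <- list(status = "failed", message = sim$message)
    return(finish_pipeline(summary, outdir, log_lines))
  }
  summary$stages$simulate <- list(
    status = "ok",
    n_sites = nrow(sim$land$truth),
    n_tss = nrow(sim$land$tss),
    n_tyi_genes = sum(sim$exprs$truth$is_tyi)
  )

  peaks <- stage("peaks", {
    reps <- function(which_tf) {
      map(sort(unique(sim$land$peaks$replicate)), function(r) {
        filter(sim$land$peaks, .data$tf == which_tf, .data$replicate == r)
      })
    }
    cons_a <- intersect_replicates(reps("A"))
    cons_b <- intersect_replicates(reps("B"))
    venn <- categorize_overlap(list(A = cons_a, B = cons_b))
    write_bed(cons_a, file.path(outdir, "conservative_factorA.bed"))
    write_bed(cons_b, file.path(outdir, "conservative_factorB.bed"))
    readr::write_tsv(venn$venn, file.path(outdir, "venn_counts.tsv"))
    list(cons_a = cons_a, cons_b = cons_b, venn = venn)
  })
  summary$stages$peaks <- if (failed(peaks)) {
    list(status = "failed", message = peaks$message)
  } else {
    list(status = "ok",
         n_conservative_a = nrow(peaks$cons_a),
         n_conservative_b = nrow(peaks$cons_b),
         venn = setNames(as.list(peaks$venn$venn$n),
                         peaks$venn$venn$combination))
  }

  dbr <- stage("dbr", {
    run_one <- function(cnt) {
      norm <- normalize_counts(cnt$counts, cnt$tallies)
      test_differential(norm, cnt$design, contrast = c("ON", "OFF"))
    }
    dbr_a <- run_one(sim$counts_a)
    dbr_b <- run_one(sim$counts_b)
    strata <- stratify_peaks(dbr_a, dbr_b, labels = c("A", "B"))
    readr::write_tsv(dbr_a, file.path(outdir, "dbr_factorA.tsv"))
    readr::write_tsv(dbr_b, file.path(outdir, "dbr_factorB.tsv"))
    readr::write_tsv(strata, file.path(outdir, "peak_strata.tsv"))
    list(dbr_a = dbr_a, dbr_b = dbr_b, strata = strata)
  })
  summary$stages$dbr <- if (failed(dbr)) {
    list(status = "failed", message = dbr$message)
  } else {
    list(status = "ok",
         n_dbr_a = sum(dbr$dbr_a$direction != "ns"),
         n_dbr_b = sum(dbr$dbr_b$direction != "ns"),
         strata = setNames(as.list(attr(dbr$strata, "counts")$n),
                           attr(dbr$strata, "counts")$category))
  }

  efdr <- stage("efdr", {
    if (failed(dbr)) abort("differential-binding stage failed upstream.")
    sites <- sim$land$truth |>
      select(-"category") |>
      inner_join(dbr$strata, by = c(name = "region")) |>
      filter(.data$category != "none")
    if (dplyr::n_distinct(sites$category) < 2) {
      abort("need at least two non-empty DBR strata for the distance eFDR.")
    }
    dist_tab <- map(split(sites, sites$category), function(s) {
      closest_distance(sim$land$tss, s) |>
        mutate(category = s$category[1])
    }) |> list_rbind() |>
      filter(!is.na(.data$distance))
    peak_counts <- count(sites, .data$category)
    obs_cat <- peak_counts$category[which.min(peak_counts$n)]
    obs <- dist_tab$distance[dist_tab$category == obs_cat]
    pool <- dist_tab$distance[dist_tab$category != obs_cat]
    res <- efdr_test(obs, pool, n_draws = n_draws,
                     seed = sub_seed(config$seed, 11))
    readr::write_tsv(select(dist_tab, "gene", "category", "distance"),
                     file.path(outdir, "tss_distances.tsv"))
    jsonlite::write_json(tidy(res), file.path(outdir, "efdr.json"),
                         auto_unbox = FALSE, digits = NA)
    list(result = res, observed_category = obs_cat)
  })
  summary$stages$efdr <- if (failed(efdr)) {
    list(status = "failed", message = efdr$message)
  } else {
    list(status = "ok", observed_category = efdr$observed_category,
         d = efdr$result$statistic, efdr = efdr$result$efdr,
         at_floor = efdr$result$at_floor)
  }

  clusters <- stage("clusters", {
    tyi <- select_tyi(sim$exprs$de)
    z <- zscore_expr(filter(sim$exprs$expr, .data$gene %in% tyi$gene))
    fit <- fuzzy_cmeans(z, c = 3, seed = sub_seed(config$seed, 12))
    summ <- summarize_clusters(z, fit, sim$exprs$samples)
    readr::write_tsv(tidy(fit), file.path(outdir, "cluster_memberships.tsv"))
    readr::write_tsv(summ, file.path(outdir, "cluster_group_means.tsv"))
    list(tyi = tyi, fit = fit, summary = summ)
  })
  summary$stages$clusters <- if (failed(clusters)) {
    list(status = "failed", message = clusters$message)
  } else {
    list(status = "ok", n_selected = nrow(clusters$tyi),
         cluster_sizes = as.list(table(clusters$fit$labels$cluster)),
         converged = clusters$fit$converged)
  }

  surv <- stage("survival", {
    res <- dual_signature_screen(sim$cohorts$cohorts,
                                 sim$cohorts$signatures$sig1,
                                 sim$cohorts$signatures$sig2)
    readr::write_tsv(res, file.path(outdir, "survival_screen.tsv"))
    res
  })
  summary$stages$survival <- if (failed(surv)) {
    list(status = "failed", message = surv$message)
  } else {
    list(status = "ok", n_cohorts = nrow(surv),
         flagged_sig1 = surv$cohort[surv$sig1_flag],
         flagged_sig2 = surv$cohort[surv$sig2_flag])
  }

  rsa <- stage("screen", {
    norm <- normalize_depth(sim$screen$counts,
                            lib_sizes = sim$screen$lib_sizes)
    lfc <- sgrna_log2fc(norm)
    res <- rsa_score(lfc)
    readr::write_tsv(res, file.path(outdir, "rsa_scores.tsv"))
    top <- head(res$gene, max(1, round(0.05 * nrow(res))))
    hits <- sim$screen$truth$gene[sim$screen$truth$is_hit]
    list(result = res, recovered = sum(hits %in% top), planted = length(hits))
  })
  summary$stages$screen <- if (failed(rsa)) {
    list(status = "failed", message = rsa$message)
  } else {
    list(status = "ok", planted_hits = rsa$planted,
         recovered_in_top5pct = rsa$recovered)
  }

  finish_pipeline(summary, outdir, log_lines)
}

finish_pipeline <- function(summary, outdir, log_lines) {
  ok <- validate_run_summary(summary)
  if (!isTRUE(ok)) warn(paste("summary fails its schema:", ok))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(summary)
}

as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    abort("`config` must be a sim_config, a named list, or a YAML/JSON path.",
          class = "cooccupy_invalid_config")
  }
  do.call(sim_config, config)
}

#' Validate a pipeline summary against the package's schema
#'
#' Structural validation of a [run_pipeline()] summary against the JSON
#' schema shipped at `inst/schema/run-summary.schema.json`: required
#' top-level fields, and a `status` for every reported stage.
#'
#' @param summary A summary list (or path to a `summary.json`).
#' @return `TRUE` if valid, otherwise a character description of the first
#'   violation.
#' @export
validate_run_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  if (!is.list(summary)) return("summary is not an object")
  for (field in c("package", "seed", "stages")) {
    if (is.null(summary[[field]])) {
      return(sprintf("missing required field `%s`", field))
    }
  }
  if (!is.list(summary$stages)) return("`stages` is not an object")
  for (nm in names(summary$stages)) {
    st <- summary$stages[[nm]]
    if (is.null(st$status) ||
        !st$status %in% c("ok", "failed", "skipped")) {
      return(sprintf("stage `%s` has no valid `status`", nm))
    }
  }
  TRUE
}
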