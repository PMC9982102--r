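#' Pipeline configuration
#'
#' Bundles the input paths and analysis settings for [run_pipeline()].
#' Configurations can also be read from a YAML file with
#' [read_pipeline_config()]; values given there mirror these arguments.
#'
#' @param vcf,gff,design,plots Input paths: multi-sample parent VCF, GFF3
#'   gene models, cross design CSV (`female`, `male`), plot-level phenotype
#'   CSV (`entry_id`, `entry_type`, `location`, `replication`, `gy`).
#' @param parents Optional parent CSV (`sample`, `role`, `group`) enabling
#'   heterotic-group aggregation.
#' @param outdir Output directory for stage tables and the report.
#' @param filter A [filter_config()].
#' @param promoter_len Promoter length (bp) for [build_region_index()].
#' @param scope Heterosis scope: `"across"` or `"per_location"` tables are
#'   always both written; this selects which one feeds the correlations.
#' @param alpha Significance level for the LSD.
#' @param top_k Size of the top-cross summary.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, gff, design, plots, outdir,
                            parents = NULL,
                            filter = filter_config(),
                            promoter_len = 1000,
                            scope = c("across", "per_location"),
                            alpha = 0.05,
                            top_k = 10) {
  scope <- match.arg(scope)
  structure(
    list(vcf = vcf, gff = gff, design = design, plots = plots,
         parents = parents, outdir = outdir, filter = filter,
         promoter_len = promoter_len, scope = scope, alpha = alpha,
         top_k = top_k),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys match the arguments of [pipeline_config()]; filter
#' thresholds sit under a `filter:` mapping with [filter_config()] argument
#' names.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. `outdir = ...`); an
#'   override wins over the file value.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  raw <- modifyList(raw, list(...))
  fl <- do.call(filter_config, raw$filter %||% list())
  raw$filter <- NULL
  do.call(pipeline_config, c(raw, list(filter = fl)))
}

#' Run the full heterosis-prediction pipeline
#'
#' Executes filter, annotate, score, heterosis and correlate stages on the
#' configured inputs; writes one TSV per stage plus a markdown summary
#' report (`report.md`: ANOVA table, LSD, per-parent means, correlation
#' tables, top-cross summary) and a `pipeline.log` with stage timings and
#' record counts. Any stage failure aborts with the stage name.
#'
#' @param cfg A [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with every stage result and the output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("vcf", "gff", "design", "plots")) {
    if (!file.exists(cfg[[f]])) {
      abort(paste0("input file for `", f, "` not found: ", cfg[[f]]))
    }
  }
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    inform(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
    })
    log_msg(sprintf("stage %-10s done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  out_path <- function(name) file.path(cfg$outdir, name)

  crosses <- readr::read_csv(cfg$design, show_col_types = FALSE)
  plots <- readr::read_csv(cfg$plots, show_col_types = FALSE)
  parents <- if (!is.null(cfg$parents)) {
    readr::read_csv(cfg$parents, show_col_types = FALSE)
  }

  gm <- stage("filter", {
    raw <- read_vcf(cfg$vcf)
    log_msg("read ", nrow(raw$sites), " SNP sites x ", length(raw$samples),
            " samples")
    fl <- filter_variants(raw, cfg$filter)
    log_msg(nrow(fl$sites), " sites pass filters")
    write_vcf(fl, out_path("filtered.vcf"))
    fl
  })

  annotated <- stage("annotate", {
    idx <- build_region_index(cfg$gff, promoter_len = cfg$promoter_len)
    ann <- annotate_matrix(gm, idx)
    log_msg(sum(ann$is_peus), " PEUS SNPs of ", nrow(ann), " sites")
    readr::write_tsv(ann, out_path("peus_annotation.tsv"))
    write_peus_bed(idx, out_path("peus_regions.bed"))
    list(idx = idx, ann = ann)
  })

  scores <- stage("score", {
    sc <- score_all(gm, annotated$ann, crosses)
    log_msg(nrow(sc), " crosses scored")
    readr::write_tsv(sc, out_path("scores.tsv"))
    sc
  })

  het <- stage("heterosis", {
    across <- compute_heterosis(plots, crosses, scope = "across")
    per_loc <- compute_heterosis(plots, crosses, scope = "per_location")
    anova_tbl <- anova_line_tester(plots, crosses)
    lsd_val <- lsd(anova_tbl,
                   n_per_mean = prod(glance(anova_tbl)$n_locations,
                                     glance(anova_tbl)$n_reps),
                   alpha = cfg$alpha)
    readr::write_tsv(across, out_path("heterosis.tsv"))
    readr::write_tsv(per_loc, out_path("heterosis_per_location.tsv"))
    readr::write_tsv(tidy(anova_tbl), out_path("anova.tsv"))
    log_msg("ANOVA error df ", glance(anova_tbl)$df_error,
            ", LSD(", cfg$alpha, ") = ", sprintf("%.3f", lsd_val))
    list(across = across, per_location = per_loc, anova = anova_tbl,
         lsd = lsd_val)
  })

  correl <- stage("correlate", {
    by_cross <- predictor_correlations(scores, het$across, by = "none")
    by_line <- predictor_correlations(scores, het$across, by = "female")
    by_tester <- predictor_correlations(scores, het$across, by = "male")
    per_loc <- het$per_location |>
      group_by(.data$location) |>
      group_modify(~ predictor_correlations(scores, .x, by = "none")) |>
      ungroup()
    cmp <- compare_strata <- {
      wide <- per_loc |>
        select("location", "predictor", "response", "r") |>
        tidyr::pivot_wider(names_from = "predictor", values_from = "r")
      compare_correlations(wide$n_het_peus, wide$gd)
    }
    all_tbl <- bind_rows(
      mutate(by_cross, grouping = "cross"),
      mutate(by_line, grouping = "line"),
      mutate(by_tester, grouping = "tester"),
      mutate(per_loc, grouping = paste0("cross@", .data$location))
    )
    readr::write_tsv(all_tbl, out_path("correlations.tsv"))
    k <- min(cfg$top_k, nrow(het$across))
    top <- top_crosses(het$across, response = "f1_mean", k = k)
    log_msg("correlations over ", nrow(scores), " crosses; top-", k,
            " summary computed")
    list(by_cross = by_cross, by_line = by_line, by_tester = by_tester,
         per_location = per_loc, comparison = cmp, top = top)
  })

  report <- out_path("report.md")
  writeLines(render_report(gm, annotated$ann, scores, het, correl, cfg), report)
  writeLines(log_lines, out_path("pipeline.log"))
  log_msg("report written to ", report)

  invisible(list(gm = gm, annotation = annotated$ann, index = annotated$idx,
                 scores = scores, heterosis = het, correlations = correl,
                 outdir = cfg$outdir))
}

md_table <- function(df, digits = 4) {
  df <- as_tibble(df) |>
    mutate(across(where(is.numeric), ~ signif(.x, digits)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

render_report <- function(gm, ann, scores, het, correl, cfg) {
  g <- glance(het$anova)
  c(
    "# Heterosis prediction report",
    "",
    sprintf("- filtered SNPs: %d; PEUS SNPs: %d", nrow(ann), sum(ann$is_peus)),
    sprintf("- crosses scored: %d; samples: %d", nrow(scores),
            length(gm$samples)),
    sprintf("- LSD(alpha = %s, n = %d) = %.3f t/ha", cfg$alpha,
            g$n_locations * g$n_reps, het$lsd),
    "",
    "## Line x tester ANOVA (grain yield)",
    "",
    md_table(tidy(het$anova)),
    "",
    "## Predictor correlations (across locations)",
    "",
    md_table(bind_rows(
      mutate(correl$by_cross, grouping = "cross"),
      mutate(correl$by_line, grouping = "line"),
      mutate(correl$by_tester, grouping = "tester")
    )),
    "",
    "## Per-location correlations and predictor comparison",
    "",
    md_table(correl$per_location),
    "",
    md_table(correl$comparison),
    "",
    "## Top crosses by mean yield",
    "",
    md_table(correl$top$top |>
               select("female", "male", "f1_mean", "mph", "bph")),
    "",
    "### Parent membership among top crosses",
    "",
    md_table(correl$top$parents)
  )
}
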