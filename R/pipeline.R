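#' Default pipeline configuration for the synthetic demo
#'
#' @param seed Top-level integer seed (required, flows into every stage).
#' @param n_genes,... Overrides forwarded to [sim_config()].
#' @return A `pipeline_config` list with `parameters` (span, window,
#'   promoter_span, pseudocount, p_thresh, fc_thresh, hilbert_order,
#'   hilbert_aggregation) and a `simulation` block.
#' @export
demo_config <- function(seed, ...) {
  cfg <- list(
    demo = TRUE,
    seed = as.integer(seed),
    parameters = list(span = 5000, window = 200, promoter_span = 2000,
                      pseudocount = 1.0, p_thresh = 0.01, fc_thresh = 2,
                      hilbert_order = 5, hilbert_aggregation = "sum"),
    simulation = sim_config(seed = seed, ...)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Non-demo configs must name all input paths (`annotation`, `expression`,
#' `sample_map`, and a `tags` map of sample name to BED path with `mark` and
#' `cell_type` fields). Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("demo", "seed", "parameters", "simulation", "paths")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(raw$seed)) stop("config must set `seed`")
  cfg <- list(demo = isTRUE(raw$demo), seed = as.integer(raw$seed),
              parameters = utils::modifyList(
                demo_config(raw$seed)$parameters, raw$parameters %||% list()),
              paths = raw$paths)
  if (cfg$demo) {
    sim_args <- raw$simulation %||% list()
    sim_args$seed <- raw$seed
    if (!is.null(sim_args$class_proportions)) {
      sim_args$class_proportions <- unlist(sim_args$class_proportions)
    }
    cfg$simulation <- do.call(sim_config, sim_args)
  }
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$parameters
  pos <- c(span = p$span, window = p$window, promoter_span = p$promoter_span,
           p_thresh = p$p_thresh, fc_thresh = p$fc_thresh,
           hilbert_order = p$hilbert_order)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) stop("parameters must be positive: ", paste(bad, collapse = ", "))
  if (isTRUE(config$demo)) {
    validate_sim_config(config$simulation)
  } else {
    need <- c("annotation", "expression", "sample_map")
    missing_keys <- setdiff(need, names(config$paths))
    if (length(missing_keys)) {
      stop("non-demo config missing path(s): ",
           paste(missing_keys, collapse = ", "))
    }
    for (f in unlist(config$paths[need])) {
      if (!file.exists(f)) stop("input path does not exist: ", f)
    }
  }
  invisible(config)
}

# tiny FNV-1a over the deparsed config, for the run manifest
config_fingerprint <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; stay in double arithmetic
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Run the full analysis pipeline
#'
#' Demo mode simulates the study from `config$simulation`, writes its inputs,
#' then runs the complete analysis: per-gene mark densities (promoter-window
#' H3K4me3, gene-body H3K27me3) and mark fold changes vs the somatic
#' baseline; TSS profiles and profile correlations against the ESC reference;
#' a Hilbert grid of chr1 H3K4me3 per cell type; expression contrasts
#' (ESC-vs-somatic, iPSCp-vs-somatic, iPSC-vs-ESC); responder classification
#' with truth bookkeeping, stratum correlations and class mark summaries;
#' DEG overlap; and sample clustering. All tables are written as TSV, the
#' dendrogram as Newick, plus a run manifest and a plain-text report.
#' Identical config and seed reproduce every output byte for byte.
#'
#' @param config A `pipeline_config` from [demo_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a `pipeline_result` list with all in-memory objects
#'   (`study`, `densities`, `contrasts`, `responders`, `summary`,
#'   `correlations`, `overlap`, `dendrogram`, `files`).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  par <- config$parameters
  stage <- "load inputs"
  result <- try({
    if (isTRUE(config$demo)) {
      stage <- "simulate"
      study <- simulate_study(config$simulation)
      write_study(study, file.path(out_dir, "inputs"))
      annotation <- study$annotation
      tags <- study$tags
      expr <- study$expression
      truth <- study$truth
    } else {
      annotation <- read_annotation_bed(config$paths$annotation)
      expr <- read_expr_tsv(config$paths$expression, config$paths$sample_map)
      tags <- list()
      for (tg in config$paths$tags %||% list()) {
        lib <- load_tags(tg$bed, mark = tg$mark, cell_type = tg$cell_type,
                         sample = paste(tg$cell_type, tg$mark, sep = "_"))
        tags[[tg$mark]][[tg$cell_type]] <- lib
      }
      truth <- NULL
      study <- NULL
    }

    stage <- "quantify"
    densities <- list()
    for (m in names(tags)) {
      for (ct in names(tags[[m]])) {
        densities[[ct]][[m]] <- gene_density(
          tags[[m]][[ct]], annotation,
          region = if (m == "H3K4me3") "promoter" else "body",
          promoter_span = par$promoter_span)
      }
    }
    mark_fc <- list()
    if (all(c("ESC", "somatic", "iPSCp") %in% names(densities))) {
      for (m in histone_marks()) {
        mark_fc[[paste0(m, "_ESC_vs_somatic")]] <-
          mark_log2fc(densities$ESC[[m]], densities$somatic[[m]],
                      par$pseudocount)
        mark_fc[[paste0(m, "_iPSCp_vs_somatic")]] <-
          mark_log2fc(densities$iPSCp[[m]], densities$somatic[[m]],
                      par$pseudocount)
        mark_fc[[paste0(m, "_iPSC_vs_ESC")]] <-
          mark_log2fc(densities$iPSC[[m]], densities$ESC[[m]],
                      par$pseudocount)
      }
    }

    stage <- "profiles"
    profiles <- list(); prof_cor <- list()
    if ("H3K4me3" %in% names(tags)) {
      for (ct in names(tags$H3K4me3)) {
        profiles[[ct]] <- tss_profile(tags$H3K4me3[[ct]], annotation,
                                      span = par$span, window = par$window)
      }
      if ("ESC" %in% names(profiles)) {
        for (ct in setdiff(names(profiles), "ESC")) {
          prof_cor[[paste0("ESC_vs_", ct)]] <-
            profile_correlation(profiles$ESC, profiles[[ct]])$r
        }
      }
    }

    stage <- "hilbert"
    grids <- list()
    if ("H3K4me3" %in% names(tags)) {
      for (ct in names(tags$H3K4me3)) {
        lib <- tags$H3K4me3[[ct]]
        if (!"chr1" %in% names(lib$positions)) next
        len <- lib$chrom_lengths[["chr1"]] %||%
          (max(lib$positions[["chr1"]], 0) + 1)
        grids[[ct]] <- signal_to_grid(lib, "chr1", len,
                                      order = par$hilbert_order,
                                      aggregation = par$hilbert_aggregation)
        write_hilbert_tsv(grids[[ct]],
                          file.path(out_dir, paste0("hilbert_H3K4me3_", ct, ".tsv")))
      }
    }

    stage <- "contrasts"
    contrasts <- list(
      ESC_vs_somatic = call_degs(expr, "ESC", "somatic",
                                 par$p_thresh, par$fc_thresh),
      iPSCp_vs_somatic = call_degs(expr, "iPSCp", "somatic",
                                   par$p_thresh, par$fc_thresh),
      iPSC_vs_ESC = call_degs(expr, "iPSC", "ESC",
                              par$p_thresh, par$fc_thresh))
    for (nm in names(contrasts)) {
      write_contrast_tsv(contrasts[[nm]],
                         file.path(out_dir, paste0("contrast_", nm, ".tsv")))
    }

    stage <- "classify"
    responders <- classify_responders(contrasts$ESC_vs_somatic,
                                      contrasts$iPSCp_vs_somatic)
    if (!is.null(truth)) responders <- add_truth(responders, truth)
    write_responder_tsv(responders, file.path(out_dir, "responders.tsv"))
    correlations <- list(
      down = class_fc_correlation(contrasts$ESC_vs_somatic,
                                  contrasts$iPSCp_vs_somatic, "down"),
      up = class_fc_correlation(contrasts$ESC_vs_somatic,
                                contrasts$iPSCp_vs_somatic, "up"))
    summary_tbl <- NULL
    if (length(densities)) {
      summary_tbl <- class_mark_summary(responders, densities)
      write_tsv(summary_tbl, file.path(out_dir, "class_mark_summary.tsv"))
    }
    categories <- NULL
    if (length(mark_fc)) {
      categories <- fc_category_percentages(mark_fc$H3K4me3_iPSC_vs_ESC,
                                            mark_fc$H3K27me3_iPSC_vs_ESC,
                                            contrasts$iPSC_vs_ESC)
      write_tsv(categories$table, file.path(out_dir, "fc_integration_iPSC_vs_ESC.tsv"))
    }
    overlap <- deg_overlap(contrasts[c("ESC_vs_somatic", "iPSCp_vs_somatic")],
                           direction = "any")

    stage <- "cluster"
    hc <- cluster_samples(expr)
    dendrogram_newick(hc, file.path(out_dir, "sample_dendrogram.nwk"))

    stage <- "report"
    counts <- attr(responders, "class_counts")
    report <- c(
      "pipeline report",
      "===============",
      paste0("seed: ", config$seed),
      paste0("genes: ", nrow(annotation)),
      paste0("samples: ", ncol(expr$values)),
      "",
      "responder class counts (class x stratum):",
      utils::capture.output(print(counts)),
      "",
      sprintf("fold-change correlation, down stratum: r = %.3f",
              correlations$down),
      sprintf("fold-change correlation, up stratum:   r = %.3f",
              correlations$up),
      if (!is.null(categories)) {
        sprintf("iPSC vs ESC expression: %.1f%% up, %.1f%% down, %.1f%% unchanged",
                categories$percentages["up"], categories$percentages["down"],
                categories$percentages["unchanged"])
      },
      if (length(prof_cor)) {
        c("", "H3K4me3 TSS profile correlations vs ESC:",
          sprintf("  %s: r = %.3f", names(prof_cor), unlist(prof_cor)))
      },
      sprintf("DEG overlap ESC/iPSCp contrasts: %d common of %d in union (%.1f%%)",
              overlap$n_common, overlap$n_union, 100 * overlap$fraction_common))
    writeLines(report, file.path(out_dir, "report.txt"))
    manifest <- c(
      paste0("config_fingerprint: ", config_fingerprint(config)),
      paste0("seed: ", config$seed),
      paste0("demo: ", isTRUE(config$demo)),
      paste0("package: epiresponder ",
             as.character(utils::packageVersion("epiresponder"))))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))

    list(study = study, annotation = annotation, densities = densities,
         mark_fc = mark_fc, profiles = profiles,
         profile_correlations = prof_cor, grids = grids,
         contrasts = contrasts, responders = responders,
         summary = summary_tbl, categories = categories,
         correlations = correlations, overlap = overlap, dendrogram = hc,
         out_dir = out_dir)
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    writeLines(paste0("INCOMPLETE at stage: ", stage),
               file.path(out_dir, "INCOMPLETE"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(result, "condition")$message)
  }
  class(result) <- "pipeline_result"
  invisible(result)
}
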