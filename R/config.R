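#' Simulation configuration
#'
#' Builds and validates the configuration that drives the synthetic study
#' generator. The defaults describe the miniature study used throughout the
#' package: 2,000 genes on 2 x 10 Mb chromosomes, 200,000 tags per ChIP
#' library, a narrow 2 kb H3K4me3 peak at the TSS and a broad H3K27me3 domain
#' over the gene body at 8-fold enrichment over background, and microarray-like
#' log2 expression with 3 replicates per cell type, a 2.0 log2 effect and
#' residual noise sd 0.25.
#'
#' @param n_genes Number of genes to place.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_chromosomes Number of chromosomes.
#' @param class_proportions Named numeric vector over the planted gene classes
#'   (`somatic_specific`, `esc_specific`, `early_responder`, `late_responder`,
#'   `divergent_up`, `divergent_down`, `housekeeping`); must sum to 1.
#' @param tags_per_library Tags sampled per ChIP library (fixed depth).
#' @param peak_width_k4 Width in bp of the TSS-centered H3K4me3 peak.
#' @param domain_width_k27 Width in bp of the H3K27me3 domain, or `"body"`
#'   (default) to cover the gene body.
#' @param enrichment_fold Per-bp tag rate in enriched regions relative to
#'   background; must exceed 1.
#' @param n_replicates Expression replicates per cell type (>= 2).
#' @param expr_base_mean Baseline log2 expression of an "off" gene.
#' @param expr_effect Mean log2 expression increment of an "on" gene.
#' @param expr_effect_jitter Half-width of the per-gene uniform jitter on the
#'   effect size (log2 units); gene effects are shared across cell types, so
#'   the two reprogramming contrasts inherit correlated fold changes the way
#'   real expression data do.
#' @param expr_noise_sd Replicate-level Gaussian noise sd (log2 units).
#' @param seed Integer seed; required, no silent default.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       chrom_length = 1e7,
                       n_chromosomes = 2L,
                       class_proportions = c(somatic_specific = 0.15,
                                             esc_specific = 0.15,
                                             early_responder = 0.10,
                                             late_responder = 0.10,
                                             divergent_up = 0.05,
                                             divergent_down = 0.05,
                                             housekeeping = 0.40),
                       tags_per_library = 200000L,
                       peak_width_k4 = 2000L,
                       domain_width_k27 = "body",
                       enrichment_fold = 8,
                       n_replicates = 3L,
                       expr_base_mean = 6,
                       expr_effect = 2,
                       expr_effect_jitter = 0.4,
                       expr_noise_sd = 0.25,
                       seed) {
  if (missing(seed)) {
    stop("`seed` must be given explicitly; the generator has no default seed")
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    chrom_length = as.numeric(chrom_length),
    n_chromosomes = as.integer(n_chromosomes),
    class_proportions = class_proportions,
    tags_per_library = as.integer(tags_per_library),
    peak_width_k4 = as.numeric(peak_width_k4),
    domain_width_k27 = domain_width_k27,
    enrichment_fold = as.numeric(enrichment_fold),
    n_replicates = as.integer(n_replicates),
    expr_base_mean = as.numeric(expr_base_mean),
    expr_effect = as.numeric(expr_effect),
    expr_effect_jitter = as.numeric(expr_effect_jitter),
    expr_noise_sd = as.numeric(expr_noise_sd),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config Object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$class_proportions
  known <- c("somatic_specific", "esc_specific", "early_responder",
             "late_responder", "divergent_up", "divergent_down",
             "housekeeping")
  if (is.null(names(p)) || !all(names(p) %in% known)) {
    stop("class_proportions must be named with classes among: ",
         paste(known, collapse = ", "))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ", format(sum(p)), ")")
  }
  if (any(p < 0)) stop("class_proportions must be non-negative")
  if (config$n_genes < 0) stop("n_genes must be >= 0")
  pos <- c(chrom_length = config$chrom_length,
           n_chromosomes = config$n_chromosomes,
           tags_per_library = config$tags_per_library,
           peak_width_k4 = config$peak_width_k4,
           n_replicates = config$n_replicates)
  bad <- names(pos)[pos <= 0]
  if (length(bad)) stop("strictly positive required: ", paste(bad, collapse = ", "))
  if (!identical(config$domain_width_k27, "body") &&
      (!is.numeric(config$domain_width_k27) || config$domain_width_k27 <= 0)) {
    stop("domain_width_k27 must be \"body\" or a positive width in bp")
  }
  if (config$enrichment_fold <= 1) stop("enrichment_fold must exceed 1")
  if (config$expr_noise_sd < 0) stop("expr_noise_sd must be >= 0")
  if (config$expr_effect <= 0) stop("expr_effect must be > 0")
  if (config$expr_effect_jitter < 0 ||
      config$expr_effect_jitter >= config$expr_effect) {
    stop("expr_effect_jitter must lie in [0, expr_effect)")
  }
  if (is.na(config$seed)) stop("seed must be a finite integer")
  invisible(config)
}

#' Cell types of the reprogramming panel
#'
#' Fixed panel emulated by the generator: a somatic fibroblast state, a
#' partially reprogrammed iPSC (iPSCp), a fully reprogrammed iPSC, and the
#' embryonic stem cell reference.
#' @return Character vector of the four cell-type labels.
#' @export
cell_types <- function() c("somatic", "iPSCp", "iPSC", "ESC")

#' Histone marks handled by the tag simulator and quantifier
#' @return Character vector of the two mark labels.
#' @export
histone_marks <- function() c("H3K4me3", "H3K27me3")

# Deterministic per-stage seed derived from the top-level seed, so every
# simulation stage draws from its own named substream.
stage_seed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 65536
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483629)
}
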