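#' Simulate a miniature genome annotation
#'
#' Places non-overlapping gene loci on equally sized chromosomes. Each
#' chromosome is divided into equal slots, one gene per slot, with the gene's
#' start uniformly jittered inside its slot; lengths are uniform on
#' [2 kb, 10 kb] (capped by the slot). Strands are assigned ~50/50 and the TSS
#' sits at the strand-appropriate end. Coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return A [gene_annotation()] with `config$n_genes` rows.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  if (config$n_genes == 0L) {
    return(gene_annotation(character(), character(), numeric(), numeric(),
                           character()))
  }
  set.seed(stage_seed(config$seed, "genome"))
  n_chrom <- config$n_chromosomes
  per_chrom <- rep(config$n_genes %/% n_chrom, n_chrom)
  extra <- config$n_genes %% n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  min_len <- 2000
  max_len <- 10000
  rows <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    slot <- floor(config$chrom_length / ng)
    if (slot <= min_len) {
      stop("chromosome too short to place ", ng, " non-overlapping genes of ",
           ">= ", min_len, " bp on ", config$chrom_length, " bp")
    }
    len_hi <- min(max_len, slot - 1)
    len <- floor(stats::runif(ng, min_len, len_hi + 1))
    offset <- floor(stats::runif(ng) * (slot - len))
    start <- (seq_len(ng) - 1) * slot + offset
    strand <- ifelse(stats::runif(ng) < 0.5, "+", "-")
    rows[[ci]] <- data.frame(chrom = paste0("chr", ci), start = start,
                             end = start + len, strand = strand,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gene_annotation(gene_id = sprintf("gene%04d", seq_len(nrow(df))),
                  chrom = df$chrom, start = df$start, end = df$end,
                  strand = df$strand)
}

# Per-class expected expression states ("on"/"off") across the panel
# (somatic, iPSCp, iPSC, ESC), per direction stratum where relevant.
planted_states <- function(class, direction) {
  switch(class,
    housekeeping    = c("on", "on", "on", "on"),
    somatic_specific = c("on", "off", "off", "off"),
    esc_specific    = c("off", "off", "on", "on"),
    early_responder = if (direction == "up") c("off", "on", "on", "on")
                      else c("on", "off", "off", "off"),
    late_responder  = if (direction == "up") c("off", "off", "on", "on")
                      else c("on", "on", "off", "off"),
    divergent_up    = c("off", "on", "off", "off"),
    divergent_down  = c("on", "off", "on", "on"),
    stop("unknown class: ", class)
  )
}

# Classification each planted class is expected to receive from the two
# contrasts against the somatic baseline.
planted_expectation <- function(class, direction) {
  switch(class,
    housekeeping    = c("unchanged", "none"),
    somatic_specific = c("convergent", "down"),
    esc_specific    = c("resistant", "up"),
    early_responder = c("convergent", direction),
    late_responder  = c("resistant", direction),
    divergent_up    = c("divergent", "up"),
    divergent_down  = c("divergent", "down"))
}

#' Assign planted truth classes and expected states
#'
#' Draws one class per gene (a multinomial draw under
#' `config$class_proportions`), a direction stratum where the class has one,
#' and a per-gene effect size (`expr_effect` plus uniform jitter). Fills the
#' expected expression state per cell type and the expected H3K4me3/H3K27me3
#' state (active genes are K4-high; silenced genes carry the repressive
#' K27-high state), plus the classification each gene is expected to receive
#' downstream (`expected_class`, `expected_stratum`).
#'
#' @param annotation A non-empty [gene_annotation()].
#' @param config A [sim_config()].
#' @return A `truth_table` data.frame, one row per gene.
#' @export
assign_truth <- function(annotation, config) {
  validate_sim_config(config)
  stopifnot(inherits(annotation, "gene_annotation"))
  if (nrow(annotation) == 0) stop("annotation must be non-empty")
  set.seed(stage_seed(config$seed, "truth"))
  n <- nrow(annotation)
  p <- config$class_proportions
  cls <- sample(names(p), n, replace = TRUE, prob = p)
  dir <- rep("none", n)
  responder <- cls %in% c("early_responder", "late_responder")
  dir[responder] <- ifelse(stats::runif(sum(responder)) < 0.5, "up", "down")
  dir[cls == "somatic_specific"] <- "down"
  dir[cls == "esc_specific"] <- "up"
  dir[cls == "divergent_up"] <- "up"
  dir[cls == "divergent_down"] <- "down"
  effect <- config$expr_effect +
    stats::runif(n, -config$expr_effect_jitter, config$expr_effect_jitter)
  cts <- cell_types()
  states <- t(mapply(planted_states, cls, dir))
  expectation <- t(mapply(planted_expectation, cls, dir))
  truth <- data.frame(gene_id = annotation$gene_id, class = cls,
                      direction = dir, effect_size = effect,
                      stringsAsFactors = FALSE)
  for (i in seq_along(cts)) truth[[paste0("expr_", cts[i])]] <- states[, i]
  for (i in seq_along(cts)) {
    truth[[paste0("k4_", cts[i])]] <- ifelse(states[, i] == "on", "high", "low")
    truth[[paste0("k27_", cts[i])]] <- ifelse(states[, i] == "off", "high", "low")
  }
  truth$expected_class <- expectation[, 1]
  truth$expected_stratum <- expectation[, 2]
  rownames(truth) <- NULL
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' Simulate a ChIP tag library
#'
#' Samples `tags_per_library` tag positions from a background/enrichment
#' mixture: the genome is cut into disjoint segments (enriched regions of
#' genes whose planted state for this mark and cell type is "high", merged,
#' plus the background in between), each segment gets weight
#' `length x rate` with rate `enrichment_fold` inside enriched regions and 1
#' outside, and the fixed library size is allocated across segments by one
#' exact multinomial draw. H3K4me3 enrichment is a `peak_width_k4` window
#' centered on the TSS; H3K27me3 covers the gene body (or a fixed-width
#' domain if `domain_width_k27` is numeric). Tags are single bp positions.
#'
#' @param annotation A [gene_annotation()].
#' @param truth The matching `truth_table` from [assign_truth()].
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @param cell_type One of [cell_types()].
#' @param config A [sim_config()].
#' @return A [tag_library()] with sorted positions per chromosome.
#' @export
simulate_tags <- function(annotation, truth, mark, cell_type, config) {
  validate_sim_config(config)
  if (!mark %in% histone_marks()) stop("unknown mark: ", mark)
  if (!cell_type %in% cell_types()) stop("unknown cell type: ", cell_type)
  if (!setequal(truth$gene_id, annotation$gene_id)) {
    stop("truth table must cover all annotated genes")
  }
  set.seed(stage_seed(config$seed, paste("tags", mark, cell_type)))
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  state_col <- paste0(ifelse(mark == "H3K4me3", "k4_", "k27_"), cell_type)
  truth <- truth[match(annotation$gene_id, truth$gene_id), ]
  high <- truth[[state_col]] == "high"
  if (mark == "H3K4me3") {
    half <- config$peak_width_k4 / 2
    rs <- pmax(0, annotation$tss - half)
    re <- pmin(L, annotation$tss + half)
  } else if (identical(config$domain_width_k27, "body")) {
    rs <- annotation$start
    re <- annotation$end
  } else {
    mid <- (annotation$start + annotation$end) / 2
    rs <- pmax(0, mid - config$domain_width_k27 / 2)
    re <- pmin(L, mid + config$domain_width_k27 / 2)
  }
  seg_chrom <- character(0); seg_start <- numeric(0)
  seg_end <- numeric(0); seg_rate <- numeric(0)
  for (ch in chroms) {
    sel <- which(high & annotation$chrom == ch)
    if (length(sel)) {
      ir <- IRanges::reduce(IRanges::IRanges(start = rs[sel] + 1,
                                             end = re[sel]))
      gp <- IRanges::gaps(ir, start = 1, end = L)
      es <- IRanges::start(ir) - 1; ee <- IRanges::end(ir)
      gs <- IRanges::start(gp) - 1; ge <- IRanges::end(gp)
      # cover residual ends if the enriched set touches neither boundary side
      seg_chrom <- c(seg_chrom, rep(ch, length(es) + length(gs)))
      seg_start <- c(seg_start, es, gs)
      seg_end <- c(seg_end, ee, ge)
      seg_rate <- c(seg_rate, rep(config$enrichment_fold, length(es)),
                    rep(1, length(gs)))
    } else {
      seg_chrom <- c(seg_chrom, ch)
      seg_start <- c(seg_start, 0)
      seg_end <- c(seg_end, L)
      seg_rate <- c(seg_rate, 1)
    }
  }
  width <- seg_end - seg_start
  keep <- width > 0
  seg_chrom <- seg_chrom[keep]; seg_start <- seg_start[keep]
  width <- width[keep]; seg_rate <- seg_rate[keep]
  w <- width * seg_rate
  counts <- as.vector(stats::rmultinom(1, config$tags_per_library, prob = w))
  pos <- lapply(seq_along(counts), function(i) {
    if (counts[i] == 0) return(numeric(0))
    seg_start[i] + pmin(floor(stats::runif(counts[i]) * width[i]),
                        width[i] - 1)
  })
  positions <- lapply(chroms, function(ch) {
    sort(unlist(pos[seg_chrom == ch], use.names = FALSE))
  })
  names(positions) <- chroms
  tag_library(positions, sample = paste(cell_type, mark, sep = "_"),
              mark = mark, cell_type = cell_type,
              chrom_lengths = stats::setNames(rep(L, length(chroms)), chroms))
}

#' Simulate a replicate expression matrix
#'
#' Microarray-like log2 expression: each gene's value in each sample is
#' `expr_base_mean + effect_size * [state == "on"] + N(0, expr_noise_sd)`,
#' with the gene's planted effect size shared across all cell types and
#' `n_replicates` independent replicates per cell type.
#'
#' @param truth A `truth_table` from [assign_truth()].
#' @param config A [sim_config()]; `n_replicates` must be >= 2 so the
#'   downstream ANOVA has within-group variance.
#' @return An [expr_matrix()] (genes x samples) with its sample map.
#' @export
simulate_expression <- function(truth, config) {
  validate_sim_config(config)
  if (config$n_replicates < 2) {
    stop("n_replicates must be >= 2 (ANOVA needs within-group variance)")
  }
  set.seed(stage_seed(config$seed, "expression"))
  n <- nrow(truth)
  cts <- cell_types()
  cols <- list()
  sample_names <- character(0)
  map_ct <- character(0); map_rep <- integer(0)
  for (ct in cts) {
    on <- truth[[paste0("expr_", ct)]] == "on"
    mu <- config$expr_base_mean + truth$effect_size * on
    for (r in seq_len(config$n_replicates)) {
      cols[[length(cols) + 1L]] <- mu + stats::rnorm(n, 0, config$expr_noise_sd)
      sample_names <- c(sample_names, paste0(ct, "_rep", r))
      map_ct <- c(map_ct, ct); map_rep <- c(map_rep, r)
    }
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(truth$gene_id, sample_names)
  expr_matrix(values, data.frame(sample = sample_names, cell_type = map_ct,
                                 replicate = map_rep, stringsAsFactors = FALSE))
}

#' Simulate the full synthetic study
#'
#' Convenience wrapper generating annotation, truth table, one tag library
#' per mark and cell type, and the replicate expression matrix, all from one
#' config and seed (each stage draws from its own named substream, so the
#' whole bundle is reproducible byte for byte).
#'
#' @param config A [sim_config()].
#' @param marks Marks to simulate tag libraries for (default both).
#' @return A list of class `sim_study` with elements `config`, `annotation`,
#'   `truth`, `tags` (nested list `tags[[mark]][[cell_type]]`), `expression`.
#' @export
simulate_study <- function(config, marks = histone_marks()) {
  annotation <- simulate_genome(config)
  truth <- assign_truth(annotation, config)
  tags <- lapply(marks, function(m) {
    libs <- lapply(cell_types(), function(ct) {
      simulate_tags(annotation, truth, m, ct, config)
    })
    stats::setNames(libs, cell_types())
  })
  names(tags) <- marks
  expr <- simulate_expression(truth, config)
  structure(list(config = config, annotation = annotation, truth = truth,
                 tags = tags, expression = expr),
            class = "sim_study")
}

#' Write a simulated study to plain-text files
#'
#' Writes the annotation as BED6, each tag library as BED3 (one 1-bp record
#' per tag) with a sidecar TSV of library sizes, the expression matrix and its
#' sample map as TSV, and the truth table as TSV.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(annotation = file.path(dir, "annotation.bed"))
  write_annotation_bed(study$annotation, files[["annotation"]])
  sizes <- data.frame(sample = character(0), mark = character(0),
                      cell_type = character(0), total_tags = integer(0))
  for (m in names(study$tags)) {
    for (ct in names(study$tags[[m]])) {
      lib <- study$tags[[m]][[ct]]
      f <- file.path(dir, paste0("tags_", m, "_", ct, ".bed"))
      write_tags_bed(lib, f)
      files[[paste0("tags_", m, "_", ct)]] <- f
      sizes <- rbind(sizes, data.frame(sample = lib$sample, mark = m,
                                       cell_type = ct,
                                       total_tags = lib$total_tags))
    }
  }
  files[["library_sizes"]] <- file.path(dir, "library_sizes.tsv")
  write_tsv(sizes, files[["library_sizes"]])
  files[["expression"]] <- file.path(dir, "expression.tsv")
  write_expr_tsv(study$expression, files[["expression"]],
                 file.path(dir, "sample_map.tsv"))
  files[["sample_map"]] <- file.path(dir, "sample_map.tsv")
  files[["truth"]] <- file.path(dir, "truth.tsv")
  write_tsv(study$truth, files[["truth"]])
  invisible(files)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
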