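test_that("genome simulation places valid, non-overlapping loci", {
  cfg <- small_config(seed = 3, n_genes = 100L, chrom_length = 1e7,
                      n_chromosomes = 2L)
  ann <- simulate_genome(cfg)
  expect_s3_class(ann, "gene_annotation")
  expect_equal(nrow(ann), 100L)
  expect_true(all(ann$end - ann$start >= 2000))
  expect_true(all(ann$start >= 0 & ann$end <= cfg$chrom_length))
  expect_true(all(ann$tss >= ann$start & ann$tss < ann$end))
  # all-pairs overlap check within each chromosome
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    n_overlap <- 0L
    for (i in seq_len(nrow(a) - 1)) {
      for (j in (i + 1):nrow(a)) {
        if (a$start[i] < a$end[j] && a$start[j] < a$end[i]) {
          n_overlap <- n_overlap + 1L
        }
      }
    }
    expect_identical(n_overlap, 0L)
  }
})

test_that("genome simulation handles empty, deterministic and impossible cases", {
  expect_equal(nrow(simulate_genome(small_config(seed = 1, n_genes = 0L))), 0L)
  cfg <- small_config(seed = 1, n_genes = 100L)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  expect_error(simulate_genome(sim_config(n_genes = 2000L, chrom_length = 1e6,
                                          n_chromosomes = 1L, seed = 1)),
               "too short")
})

test_that("truth assignment follows proportions and the planted-state rules", {
  expect_error(sim_config(seed = 1, class_proportions = c(housekeeping = 0.9)),
               "sum to 1")
  cfg <- small_config(seed = 5, n_genes = 40L,
                      class_proportions = c(housekeeping = 1.0))
  ann <- simulate_genome(cfg)
  truth <- assign_truth(ann, cfg)
  expect_true(all(truth$class == "housekeeping"))
  for (ct in cell_types()) {
    expect_true(all(truth[[paste0("expr_", ct)]] == "on"))
    expect_true(all(truth[[paste0("k4_", ct)]] == "high"))
  }
  # determinism
  expect_identical(truth, assign_truth(ann, cfg))

  # realized early_responder count is a multinomial draw: within the exact
  # binomial 99% interval at n = 2000, p = 0.1
  st <- default_study()
  ci <- qbinom(c(0.005, 0.995), 2000, 0.1)
  n_early <- sum(st$truth$class == "early_responder")
  expect_gte(n_early, ci[1])
  expect_lte(n_early, ci[2])
})

test_that("planted responder states follow the class invariants", {
  truth <- default_study()$truth
  early <- truth[truth$class == "early_responder", ]
  # ESC-like everywhere except the somatic cell type
  expect_true(all(early$expr_iPSCp == early$expr_ESC))
  expect_true(all(early$expr_iPSC == early$expr_ESC))
  expect_true(all(early$expr_somatic != early$expr_ESC))
  late <- truth[truth$class == "late_responder", ]
  expect_true(all(late$expr_iPSCp == late$expr_somatic))
  expect_true(all(late$expr_iPSC == late$expr_ESC))
  expect_true(all(late$expr_somatic != late$expr_ESC))
  div <- truth[truth$class %in% c("divergent_up", "divergent_down"), ]
  expect_true(all(div$expr_somatic == div$expr_ESC))
  expect_true(all(div$expr_iPSCp != div$expr_somatic))
})

test_that("tag simulation conserves counts and respects bounds", {
  cfg <- small_config(seed = 11, tags_per_library = 10000L)
  ann <- simulate_genome(cfg)
  truth <- assign_truth(ann, cfg)
  lib <- simulate_tags(ann, truth, "H3K4me3", "ESC", cfg)
  expect_equal(lib$total_tags, 10000)
  pos <- unlist(lib$positions)
  expect_length(pos, 10000L)
  expect_true(all(pos >= 0 & pos < cfg$chrom_length))
  expect_false(any(vapply(lib$positions, is.unsorted, logical(1))))
  expect_identical(lib, simulate_tags(ann, truth, "H3K4me3", "ESC", cfg))
  expect_error(simulate_tags(ann, truth, "H3K9me3", "ESC", cfg), "unknown mark")
  expect_error(simulate_tags(ann, truth, "H3K4me3", "HeLa", cfg),
               "unknown cell type")
})

test_that("tags are uniform in the no-enrichment limit", {
  # chi-square goodness of fit on 100 equal bins, alpha = 0.001, 20 seeds
  rejections <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 20L, chrom_length = 1e6, n_chromosomes = 1L,
                      tags_per_library = 10000L, enrichment_fold = 1 + 1e-12,
                      seed = s)
    ann <- simulate_genome(cfg)
    truth <- assign_truth(ann, cfg)
    lib <- simulate_tags(ann, truth, "H3K4me3", "ESC", cfg)
    bins <- table(cut(lib$positions$chr1, breaks = seq(0, 1e6, length.out = 101),
                      right = FALSE))
    p <- suppressWarnings(chisq.test(as.vector(bins))$p.value)
    if (p < 0.001) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("K4-high TSS windows are denser than background", {
  cfg <- sim_config(n_genes = 20L, chrom_length = 1e6, n_chromosomes = 1L,
                    tags_per_library = 10000L, enrichment_fold = 8,
                    class_proportions = c(housekeeping = 1.0), seed = 42)
  ann <- simulate_genome(cfg)
  truth <- assign_truth(ann, cfg)
  lib <- simulate_tags(ann, truth, "H3K4me3", "ESC", cfg)
  w <- cfg$peak_width_k4
  peak_counts <- vapply(seq_len(nrow(ann)), function(g) {
    brute_count(lib$positions$chr1, ann$tss[g] - w / 2, ann$tss[g] + w / 2)
  }, numeric(1))
  peak_density <- mean(peak_counts) / w
  background_density <- lib$total_tags / cfg$chrom_length
  expect_gt(peak_density, background_density)
})

test_that("expression simulation matches its construction", {
  cfg <- small_config(seed = 9, expr_noise_sd = 0, expr_effect_jitter = 0)
  ann <- simulate_genome(cfg)
  truth <- assign_truth(ann, cfg)
  expr <- simulate_expression(truth, cfg)
  # zero noise: replicates identical within each cell type
  for (ct in cell_types()) {
    cols <- which(expr$sample_map$cell_type == ct)
    for (j in cols[-1]) {
      expect_identical(expr$values[, j], expr$values[, cols[1]])
    }
  }
  # on minus off equals the configured effect exactly
  diff_genes <- truth$expr_somatic != truth$expr_ESC
  d <- expr$values[diff_genes, which(expr$sample_map$cell_type == "somatic")[1]] -
       expr$values[diff_genes, which(expr$sample_map$cell_type == "ESC")[1]]
  expect_true(all(abs(abs(d) - cfg$expr_effect) < 1e-12))
  expect_error(simulate_expression(truth, small_config(seed = 9, n_replicates = 1L)),
               "n_replicates")
})

test_that("planted effect recovers at the configured magnitude", {
  # Monte Carlo: mean absolute on-vs-off group difference ~ 2.0 +- 0.05
  st <- default_study()
  expr <- st$expression
  truth <- st$truth
  diff_genes <- truth$expr_somatic != truth$expr_ESC
  som <- rowMeans(expr$values[diff_genes,
                              expr$sample_map$cell_type == "somatic"])
  esc <- rowMeans(expr$values[diff_genes,
                              expr$sample_map$cell_type == "ESC"])
  expect_lt(abs(mean(abs(som - esc)) - 2.0), 0.05)
})

test_that("full study bundle is deterministic and round-trips to disk", {
  cfg <- small_config(seed = 13)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1, st2)
  dir <- withr::local_tempdir()
  files <- write_study(st1, dir)
  ann <- read_annotation_bed(files[["annotation"]])
  expect_equal(ann$start, st1$annotation$start)
  expect_equal(ann$strand, st1$annotation$strand)
  lib <- load_tags(files[["tags_H3K4me3_ESC"]])
  expect_equal(lib$positions$chr1, st1$tags$H3K4me3$ESC$positions$chr1)
  expr <- read_expr_tsv(files[["expression"]], files[["sample_map"]])
  expect_equal(expr$values, st1$expression$values, tolerance = 1e-9)
})
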