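# Shared fixtures and independent oracles used across the suite.

# Memoized default synthetic study (the package's standard scenario, seed 7).
.fixture_env <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_study(sim_config(seed = 7))
  }
  .fixture_env$study
}

# Small, fast config for structural tests.
small_config <- function(seed, ...) {
  args <- utils::modifyList(list(n_genes = 60L, chrom_length = 2e6,
                                 n_chromosomes = 1L,
                                 tags_per_library = 20000L, seed = seed),
                            list(...))
  do.call(sim_config, args)
}

# Brute-force window counter: counts tags in [a, b) by direct comparison.
brute_count <- function(positions, a, b) sum(positions >= a & positions < b)

# Brute-force TSS profile: naive O(genes x windows x tags) counting.
brute_tss_profile <- function(tags, annotation, span, window) {
  n_win <- 2 * span / window
  out <- matrix(0, nrow(annotation), n_win)
  for (g in seq_len(nrow(annotation))) {
    p <- tags$positions[[annotation$chrom[g]]]
    if (is.null(p)) next
    starts <- annotation$tss[g] - span + (seq_len(n_win) - 1) * window
    cnt <- vapply(starts, function(a) brute_count(p, a, a + window), numeric(1))
    if (annotation$strand[g] == "-") cnt <- rev(cnt)
    out[g, ] <- cnt / (tags$total_tags / 1e7)
  }
  rownames(out) <- annotation$gene_id
  out
}

# Brute-force per-gene density.
brute_gene_density <- function(tags, annotation, region, promoter_span = 2000) {
  vapply(seq_len(nrow(annotation)), function(g) {
    if (region == "body") {
      a <- annotation$start[g]; b <- annotation$end[g]
    } else {
      a <- annotation$tss[g] - promoter_span
      b <- annotation$tss[g] + promoter_span
    }
    p <- tags$positions[[annotation$chrom[g]]]
    cnt <- if (is.null(p)) 0 else brute_count(p, a, b)
    cnt / ((b - a) / 1000) / (tags$total_tags / 1e7)
  }, numeric(1))
}

# Random small instance (annotation + tag library) for counting oracles.
random_instance <- function(n_genes = 50, n_tags = 2000, L = 1e5) {
  start <- sort(sample.int(L - 6000, n_genes))
  len <- sample(2000:5000, n_genes, replace = TRUE)
  ann <- gene_annotation(paste0("g", seq_len(n_genes)), rep("chrA", n_genes), start,
                         start + len,
                         sample(c("+", "-"), n_genes, replace = TRUE))
  lib <- tag_library(list(chrA = sort(sample.int(L, n_tags, replace = TRUE) - 1)))
  list(annotation = ann, tags = lib)
}

# Independent recursive Hilbert construction: returns the (x, y) sequence of
# the order-k curve built from four transformed copies of the order-(k-1)
# curve (transpose, shift up, shift up-right, reverse transpose).
hilbert_recursive <- function(order) {
  xy <- matrix(0, 1, 2)
  for (k in seq_len(order)) {
    s <- 2^(k - 1)
    q1 <- cbind(xy[, 2], xy[, 1])
    q2 <- cbind(xy[, 1], xy[, 2] + s)
    q3 <- cbind(xy[, 1] + s, xy[, 2] + s)
    q4 <- cbind(2 * s - 1 - xy[, 2], s - 1 - xy[, 1])
    xy <- rbind(q1, q2, q3, q4)
  }
  data.frame(x = xy[, 1], y = xy[, 2])
}

# Relative-path md5 fingerprint of a pipeline output directory.
pipeline_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  h
}

# Minimal hand-built contrast_result for set-logic tests.
fake_contrast <- function(gene_ids, direction, log2fc = NULL) {
  direction <- rep(direction, length.out = length(gene_ids))
  if (is.null(log2fc)) {
    log2fc <- ifelse(direction == "up", 2, ifelse(direction == "down", -2, 0))
  }
  structure(data.frame(gene_id = gene_ids, log2fc = log2fc, fc = 2^log2fc,
                       p_value = ifelse(direction == "none", 0.5, 1e-6),
                       is_deg = direction != "none", direction = direction,
                       stringsAsFactors = FALSE),
            class = c("contrast_result", "data.frame"))
}

# Small expression matrix from an explicit gene x sample value matrix.
make_expr <- function(values, cell_types_per_col) {
  expr_matrix(values, data.frame(sample = colnames(values),
                                 cell_type = cell_types_per_col,
                                 replicate = stats::ave(seq_along(cell_types_per_col),
                                                        cell_types_per_col,
                                                        FUN = seq_along)))
}
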