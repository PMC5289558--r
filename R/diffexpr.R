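#' Expression matrix with sample map
#'
#' Log2-scale gene x sample matrix plus the map assigning each sample to a
#' cell-type group and replicate. No missing values are allowed; gene ids
#' (rownames) must be unique and every sample must belong to exactly one
#' group.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample names).
#' @param sample_map data.frame with columns `sample`, `cell_type`,
#'   `replicate`, one row per column of `values`, same order.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, sample_map) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique gene-id rownames")
  }
  if (is.null(colnames(values))) stop("values must have sample colnames")
  stopifnot(is.data.frame(sample_map),
            all(c("sample", "cell_type", "replicate") %in% names(sample_map)))
  if (!identical(as.character(sample_map$sample), colnames(values))) {
    stop("sample_map rows must match the columns of values, in order")
  }
  structure(list(values = values, sample_map = sample_map),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      paste(unique(x$sample_map$cell_type), collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read an expression matrix as TSV
#'
#' The matrix TSV has a `gene_id` column followed by one column per sample;
#' the sample map TSV has columns `sample`, `cell_type`, `replicate`.
#'
#' @param expr An [expr_matrix()].
#' @param path Matrix TSV path.
#' @param map_path Sample-map TSV path.
#' @return Paths invisibly; `read_expr_tsv` returns an [expr_matrix()].
#' @export
write_expr_tsv <- function(expr, path, map_path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write_tsv(df, path)
  write_tsv(expr$sample_map, map_path)
  invisible(c(path, map_path))
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path, map_path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (anyNA(df)) stop("missing values in expression TSV ", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  map <- data.table::fread(map_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  expr_matrix(values, map)
}

#' Quantile normalization across samples
#'
#' Forces every sample's value distribution onto the common reference (the
#' across-sample mean of sorted columns), the standard transform for
#' comparing expression data from different platforms or labs. Ties within a
#' column receive the mean of the reference values they span. When several
#' matrices are given they are first restricted to their common gene
#' universe, then normalized jointly.
#'
#' @param ... One or more [expr_matrix()] objects (or plain numeric matrices
#'   with gene rownames).
#' @return A single normalized [expr_matrix()] (or plain matrix if all
#'   inputs were plain) over the shared gene universe, columns in input
#'   order.
#' @export
quantile_normalize <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !inherits(inputs[[1]], "expr_matrix") && !is.matrix(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  if (!length(inputs)) stop("no input matrices")
  plain <- all(vapply(inputs, is.matrix, logical(1)))
  mats <- lapply(inputs, function(x) if (inherits(x, "expr_matrix")) x$values else x)
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (!length(genes)) stop("empty gene intersection across input matrices")
  joint <- do.call(cbind, lapply(mats, function(m) m[genes, , drop = FALSE]))
  norm <- limma::normalizeQuantiles(joint, ties = TRUE)
  dimnames(norm) <- dimnames(joint)
  if (plain) return(norm)
  maps <- lapply(inputs, function(x) {
    if (inherits(x, "expr_matrix")) {
      x$sample_map
    } else {
      data.frame(sample = colnames(x), cell_type = NA_character_,
                 replicate = NA_integer_)
    }
  })
  expr_matrix(norm, do.call(rbind, maps))
}

#' One-way ANOVA p-value
#'
#' Classical fixed-effects one-way F test across k groups:
#' `F = MS_between / MS_within` on (k-1, N-k) degrees of freedom, with the
#' degenerate cases resolved exactly: zero between-group sum of squares gives
#' p = 1, and zero within-group variance with a real group difference gives
#' p = 0.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return The upper-tail p-value.
#' @export
anova_p <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 values")
  k <- length(groups)
  n_total <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(sizes * means) / n_total
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  if (ssb == 0) return(1)
  if (ssw == 0) return(0)
  f <- (ssb / (k - 1)) / (ssw / (n_total - k))
  stats::pf(f, k - 1, n_total - k, lower.tail = FALSE)
}

#' Call differentially expressed genes between two groups
#'
#' The DEG rule used throughout: one-way ANOVA p-value below `p_thresh`
#' jointly with a linear fold change of at least `fc_thresh` (i.e.
#' `|log2FC| >= log2(fc_thresh)`), where the log2 fold change is the
#' difference of group means of log2 values (a geometric-mean fold change on
#' the linear scale). Defaults are p < 0.01 and fold change >= 2.
#'
#' @param expr An [expr_matrix()].
#' @param group_a,group_b Cell-type group labels from the sample map; the
#'   fold change is `group_a` minus `group_b` ("up" = higher in `group_a`).
#' @param p_thresh,fc_thresh DEG thresholds (p strict, linear FC inclusive).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()];
#'   `"none"` (default) applies the raw-p rule.
#' @return A `contrast_result` data.frame: `gene_id`, `log2fc`, `fc`
#'   (signed linear fold change, 2^log2fc), `p_value`, `is_deg`, `direction`
#'   in (`"up"`, `"down"`, `"none"`), with the contrast recorded in
#'   attributes.
#' @export
call_degs <- function(expr, group_a, group_b, p_thresh = 0.01, fc_thresh = 2,
                      adjust = "none") {
  stopifnot(inherits(expr, "expr_matrix"))
  cols_a <- which(expr$sample_map$cell_type == group_a)
  cols_b <- which(expr$sample_map$cell_type == group_b)
  if (!length(cols_a)) stop("group not present in sample map: ", group_a)
  if (!length(cols_b)) stop("group not present in sample map: ", group_b)
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop("both groups need >= 2 replicates")
  }
  a <- expr$values[, cols_a, drop = FALSE]
  b <- expr$values[, cols_b, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(a)),
              function(i) anova_p(list(a[i, ], b[i, ])), numeric(1))
  p_used <- stats::p.adjust(p, method = adjust)
  is_deg <- p_used < p_thresh & abs(log2fc) >= log2(fc_thresh)
  direction <- ifelse(!is_deg, "none", ifelse(log2fc > 0, "up", "down"))
  res <- data.frame(gene_id = rownames(expr$values), log2fc = log2fc,
                    fc = 2^log2fc, p_value = p, is_deg = is_deg,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, group_a = group_a, group_b = group_b, p_thresh = p_thresh,
            fc_thresh = fc_thresh, adjust = adjust,
            class = c("contrast_result", "data.frame"))
}

#' Joint multi-group ANOVA p-values
#'
#' One-way ANOVA spanning all cell types at once, for users who prefer a
#' single omnibus test over pairwise contrasts.
#'
#' @param expr An [expr_matrix()].
#' @param groups Cell-type labels to span (default: all in the sample map).
#' @return Named numeric vector of per-gene p-values.
#' @export
anova_p_joint <- function(expr, groups = unique(expr$sample_map$cell_type)) {
  stopifnot(inherits(expr, "expr_matrix"))
  cols <- lapply(groups, function(g) which(expr$sample_map$cell_type == g))
  if (any(lengths(cols) < 2)) stop("every group needs >= 2 replicates")
  vapply(seq_len(nrow(expr$values)), function(i) {
    anova_p(lapply(cols, function(cc) expr$values[i, cc]))
  }, numeric(1)) |> stats::setNames(rownames(expr$values))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of sample columns on Euclidean distance with
#' complete linkage — the combination whose merge heights are monotone
#' non-decreasing toward the root. Samples are ordered lexicographically
#' before clustering so distance ties resolve deterministically.
#'
#' @param expr An [expr_matrix()] with >= 2 samples.
#' @return An [stats::hclust] tree over the samples.
#' @export
cluster_samples <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr$values) < 2) stop("need >= 2 samples to cluster")
  m <- t(expr$values[, order(colnames(expr$values)), drop = FALSE])
  stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the complete-linkage merge heights.
#'
#' @param hc An [stats::hclust] tree.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write a contrast result as TSV
#' @param contrast A `contrast_result` from [call_degs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast_tsv <- function(contrast, path) {
  write_tsv(as.data.frame(contrast), path)
}
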