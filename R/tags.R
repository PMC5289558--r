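#' ChIP tag library
#'
#' A sample's mapped tag positions (single bp per tag, 0-based), stored as a
#' sorted numeric vector per chromosome, with the library size used for
#' density normalization.
#'
#' @param positions Named list, chromosome -> sorted vector of tag positions.
#' @param total_tags Library size; defaults to the number of stored positions.
#'   An override larger than the stored count is allowed (e.g. when tags on
#'   unquantified contigs were dropped).
#' @param sample,mark,cell_type Optional labels carried as metadata.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return An object of class `tag_library`.
#' @export
tag_library <- function(positions, total_tags = NULL, sample = NA_character_,
                        mark = NA_character_, cell_type = NA_character_,
                        chrom_lengths = NULL) {
  stopifnot(is.list(positions))
  if (length(positions) && is.null(names(positions))) {
    stop("positions must be a named (chromosome) list")
  }
  positions <- lapply(positions, function(p) {
    p <- as.numeric(p)
    if (is.unsorted(p)) p <- sort(p)
    p
  })
  n_stored <- sum(vapply(positions, length, integer(1)))
  if (is.null(total_tags)) total_tags <- n_stored
  structure(list(positions = positions, total_tags = as.numeric(total_tags),
                 sample = sample, mark = mark, cell_type = cell_type,
                 chrom_lengths = chrom_lengths),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library:", x$sample, "\n  chromosomes:",
      length(x$positions), "\n  total tags:", x$total_tags, "\n")
  invisible(x)
}

#' Load a tag library from a BED file
#'
#' Each BED3/BED6 record contributes one tag at the interval midpoint
#' (floor of (start + end) / 2, 0-based). The library size is the record
#' count unless overridden.
#'
#' @param bed_path Path to a BED3+ file of mapped tags.
#' @param library_size_override Optional library size replacing the record
#'   count in the normalization constant.
#' @param ... Metadata passed to [tag_library()] (`sample`, `mark`, ...).
#' @return A [tag_library()].
#' @export
load_tags <- function(bed_path, library_size_override = NULL, ...) {
  dt <- read_bed(bed_path, min_fields = 3L)
  if (nrow(dt) == 0) {
    warning("empty tag file: ", bed_path)
    return(tag_library(list(), total_tags = library_size_override %||% 0, ...))
  }
  mid <- floor((dt[[2]] + dt[[3]]) / 2)
  positions <- split(mid, dt[[1]])
  tag_library(positions, total_tags = library_size_override %||% nrow(dt), ...)
}

#' Write a tag library as BED3
#'
#' One record per tag, `chrom  p  p+1`, so midpoints round-trip exactly.
#' @param tags A [tag_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags_bed <- function(tags, path) {
  stopifnot(inherits(tags, "tag_library"))
  chunks <- lapply(names(tags$positions), function(ch) {
    p <- tags$positions[[ch]]
    if (!length(p)) return(NULL)
    data.frame(ch, format_bp(p), format_bp(p + 1))
  })
  bed <- do.call(rbind, chunks)
  if (is.null(bed)) bed <- data.frame(character(0), character(0), character(0))
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of sorted positions p with p < x (positions and x integral)
n_below <- function(x, p) findInterval(x - 1, p)

#' Normalized tag-density profile around transcription start sites
#'
#' For each gene, tiles `[TSS - span, TSS + span)` with half-open windows of
#' `window` bp, counts tags per window, and normalizes to tags per window per
#' 10 million tags. For minus-strand genes the window axis is reversed, so
#' columns always run upstream to downstream in transcription orientation.
#'
#' @param tags A [tag_library()] with `total_tags > 0`.
#' @param annotation A [gene_annotation()].
#' @param span Half-width of the profiled region in bp; must be a multiple of
#'   `window`.
#' @param window Window size in bp (the 200 bp convention by default).
#' @return A `density_matrix`: genes x windows numeric matrix, column names
#'   giving the window start offset from the TSS in transcription
#'   orientation; attributes `span`, `window`, `norm_constant`, `sample`.
#' @export
tss_profile <- function(tags, annotation, span = 5000, window = 200) {
  stopifnot(inherits(tags, "tag_library"), inherits(annotation, "gene_annotation"))
  if (span %% window != 0) stop("window must divide span")
  if (tags$total_tags <= 0) stop("tag library has total_tags = 0")
  n_win <- as.integer(2 * span / window)
  norm <- tags$total_tags / 1e7
  mat <- matrix(0, nrow(annotation), n_win,
                dimnames = list(annotation$gene_id,
                                seq(-span, span - window, by = window)))
  missing_chroms <- character(0)
  for (ch in unique(annotation$chrom)) {
    rows <- which(annotation$chrom == ch)
    p <- tags$positions[[ch]]
    if (is.null(p)) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    bounds <- outer(annotation$tss[rows] - span, seq(0, 2 * span, by = window), "+")
    f <- matrix(n_below(as.vector(bounds), p), nrow = length(rows))
    counts <- f[, -1, drop = FALSE] - f[, -(n_win + 1), drop = FALSE]
    mat[rows, ] <- counts / norm
  }
  neg <- annotation$strand == "-"
  if (any(neg)) mat[neg, ] <- mat[neg, n_win:1, drop = FALSE]
  if (length(missing_chroms)) {
    warning("chromosome(s) absent from tag library (rows set to zero): ",
            paste(missing_chroms, collapse = ", "))
  }
  structure(mat, span = span, window = window, norm_constant = 1e7,
            sample = tags$sample, class = c("density_matrix", class(mat)))
}

#' Normalized per-gene tag density
#'
#' Counts tags over each gene's body (`[start, end)`) or promoter
#' (`[TSS - promoter_span, TSS + promoter_span)`) and reports
#' tags/kb/10 million tags.
#'
#' @inheritParams tss_profile
#' @param region `"body"` or `"promoter"`.
#' @param promoter_span Promoter half-width in bp.
#' @return A `gene_density`: named numeric vector (gene id -> density), with
#'   attributes `region`, `promoter_span`, `sample`.
#' @export
gene_density <- function(tags, annotation, region = c("body", "promoter"),
                         promoter_span = 2000) {
  region <- match.arg(region)
  stopifnot(inherits(tags, "tag_library"), inherits(annotation, "gene_annotation"))
  if (tags$total_tags <= 0) stop("tag library has total_tags = 0")
  if (region == "body") {
    a <- annotation$start; b <- annotation$end
  } else {
    a <- annotation$tss - promoter_span; b <- annotation$tss + promoter_span
  }
  counts <- numeric(nrow(annotation))
  missing_chroms <- character(0)
  for (ch in unique(annotation$chrom)) {
    rows <- which(annotation$chrom == ch)
    p <- tags$positions[[ch]]
    if (is.null(p)) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    counts[rows] <- n_below(b[rows], p) - n_below(a[rows], p)
  }
  if (length(missing_chroms)) {
    warning("chromosome(s) absent from tag library (densities set to zero): ",
            paste(missing_chroms, collapse = ", "))
  }
  dens <- counts / ((b - a) / 1000) / (tags$total_tags / 1e7)
  structure(stats::setNames(dens, annotation$gene_id), region = region,
            promoter_span = if (region == "promoter") promoter_span else NA,
            sample = tags$sample, class = "gene_density")
}

#' Per-gene log2 fold change of mark densities
#'
#' `log2((a + pseudocount) / (b + pseudocount))`; the pseudocount (in density
#' units) bounds the ratio for zero-density genes, so the result is finite
#' everywhere.
#'
#' @param a,b `gene_density` vectors over the same gene universe.
#' @param pseudocount Density added to both numerator and denominator.
#' @return Named numeric vector of log2 fold changes (a over b).
#' @export
mark_log2fc <- function(a, b, pseudocount = 1.0) {
  ga <- names(a); gb <- names(b)
  if (!identical(sort(ga), sort(gb))) {
    miss <- c(setdiff(ga, gb), setdiff(gb, ga))
    stop("gene universes differ; missing from one side: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  b <- b[ga]
  stats::setNames(log2((as.numeric(a) + pseudocount) /
                         (as.numeric(b) + pseudocount)), ga)
}

#' Correlation between two tag-density profiles
#'
#' Pearson correlation over all flattened cells of two equally shaped
#' density matrices, plus the per-window-column correlation vector. A
#' constant input has no defined correlation and yields `NA`, never 0.
#'
#' @param x,y `density_matrix` objects of identical shape and gene order.
#' @return List with `r` (scalar) and `by_window` (one r per column).
#' @export
profile_correlation <- function(x, y) {
  if (!all(dim(x) == dim(y))) {
    stop("profiles have different shapes: ", paste(dim(x), collapse = "x"),
         " vs ", paste(dim(y), collapse = "x"))
  }
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y))) {
    stop("profiles have different gene order")
  }
  safe_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(u, v)
  }
  list(r = safe_cor(as.vector(unclass(x)), as.vector(unclass(y))),
       by_window = vapply(seq_len(ncol(x)),
                          function(j) safe_cor(x[, j], y[, j]), numeric(1)))
}
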