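#' Gene annotation table
#'
#' Constructs the annotation container used by every windowing operation:
#' one row per gene with 0-based half-open coordinates, a strand, and the
#' strand-appropriate transcription start site (start on `+`, end - 1 on `-`).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome name per gene.
#' @param start,end Integer 0-based half-open interval per gene (start < end).
#' @param strand `"+"` or `"-"` per gene.
#' @return A `gene_annotation` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(strand) == n)
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique")
  if (n > 0 && any(start >= end)) {
    stop("start must be < end for all genes; offending: ",
         paste(utils::head(gene_id[start >= end], 5), collapse = ", "))
  }
  if (n > 0 && !all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ann <- data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
                    strand = strand,
                    tss = ifelse(strand == "+", start, end - 1),
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write / read a gene annotation as BED6
#'
#' BED6 columns are chrom, start, end, name (gene id), score (0), strand,
#' with the package's 0-based half-open convention preserved verbatim.
#'
#' @param annotation A `gene_annotation`.
#' @param path File path.
#' @return `write_annotation_bed` returns `path` invisibly;
#'   `read_annotation_bed` returns a `gene_annotation`.
#' @export
write_annotation_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  bed <- data.frame(annotation$chrom, format_bp(annotation$start),
                    format_bp(annotation$end), annotation$gene_id, 0L,
                    annotation$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  dt <- read_bed(path, min_fields = 6L)
  gene_annotation(gene_id = dt[[4]], chrom = dt[[1]], start = dt[[2]],
                  end = dt[[3]], strand = dt[[6]])
}

# bp coordinates are written without scientific notation so BED files
# round-trip exactly.
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Shared line-validated BED reader (whitespace-delimited, no header).
# Reports 1-based line numbers for malformed records.
read_bed <- function(path, min_fields) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(data.table::data.table())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  if (nrow(dt) == 0) return(dt)
  if (ncol(dt) < min_fields) {
    stop("BED file ", path, " has ", ncol(dt), " columns; need >= ", min_fields)
  }
  s <- suppressWarnings(as.numeric(dt[[2]]))
  e <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(s) | is.na(e) | s < 0 | s >= e)
  if (length(bad)) {
    stop("malformed BED record(s) in ", path, " at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (start/end not numeric, negative, or start >= end)")
  }
  dt[[2]] <- s
  dt[[3]] <- e
  dt
}
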