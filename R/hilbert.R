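#' Hilbert curve index to grid coordinates
#'
#' Maps 1-D curve indices onto a 2^order x 2^order grid along the Hilbert
#' space-filling curve, with the classic "U" base motif
#' d = 0..3 -> (0,0), (0,1), (1,1), (1,0). The mapping is a bijection and
#' consecutive indices always land on 4-neighbor cells, which is what makes
#' the curve useful for displaying chromosome-wide signal: genomic
#' neighborhoods stay visual neighborhoods.
#'
#' @param order Curve order k >= 1; the grid has 4^k cells.
#' @param d Vector of 0-based curve indices in `[0, 4^order)`.
#' @return A data.frame with integer columns `x`, `y` (0-based).
#' @export
hilbert_d2xy <- function(order, d) {
  if (order < 1) stop("order must be >= 1")
  n_cells <- 4^order
  d <- as.numeric(d)
  if (any(d < 0 | d >= n_cells | d != floor(d))) {
    stop("d must be integer in [0, ", n_cells, ")")
  }
  x <- numeric(length(d)); y <- numeric(length(d))
  t <- d
  s <- 1
  while (s < 2^order) {
    rx <- floor(t / 2) %% 2
    ry <- floor(t) %% 2
    ry <- as.numeric(xor(ry == 1, rx == 1))
    # rotate the quadrant contents
    flip <- ry == 0 & rx == 1
    x[flip] <- s - 1 - x[flip]
    y[flip] <- s - 1 - y[flip]
    swap <- ry == 0
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
    x <- x + s * rx
    y <- y + s * ry
    t <- floor(t / 4)
    s <- s * 2
  }
  data.frame(x = as.integer(x), y = as.integer(y))
}

#' Project chromosome-wide tag signal onto a Hilbert grid
#'
#' Splits one chromosome into 4^order equal half-open bins, aggregates the
#' tag signal within each bin, and places bin i's value at
#' `hilbert_d2xy(order, i)`. With `aggregation = "sum"` the grid total equals
#' the chromosome's tag count; `"mean"` reports tags per bp within the bin;
#' `"max"` reports the maximum per-bp tag count inside the bin.
#'
#' @param tags A [tag_library()].
#' @param chrom Chromosome to plot.
#' @param chrom_length Chromosome length in bp.
#' @param order Curve order (grid 2^order x 2^order); default 9 suits a full
#'   chromosome, smaller orders suit tests and thumbnails.
#' @param aggregation `"mean"`, `"max"` or `"sum"`.
#' @param normalized If `TRUE`, values are additionally divided by
#'   `total_tags / 1e7` (per-10M-tags scale).
#' @return A `hilbert_grid`: 2^order x 2^order matrix with attributes
#'   `order`, `bin_size`, `aggregation`, `chrom`.
#' @export
signal_to_grid <- function(tags, chrom, chrom_length, order = 9,
                           aggregation = c("mean", "max", "sum"),
                           normalized = FALSE) {
  aggregation <- match.arg(aggregation)
  if (order < 1) stop("order must be >= 1")
  stopifnot(inherits(tags, "tag_library"), chrom_length > 0)
  if (!chrom %in% names(tags$positions)) {
    stop("chromosome not present in tag library: ", chrom)
  }
  n_bins <- 4^order
  side <- 2^order
  p <- tags$positions[[chrom]]
  bin <- pmin(floor(p * n_bins / chrom_length), n_bins - 1)
  counts <- tabulate(bin + 1, nbins = n_bins)
  bin_bp <- chrom_length / n_bins
  vals <- switch(aggregation,
    sum = counts,
    mean = counts / bin_bp,
    max = {
      v <- numeric(n_bins)
      if (length(p)) {
        per_pos <- table(p)
        pos_bin <- pmin(floor(as.numeric(names(per_pos)) * n_bins / chrom_length),
                        n_bins - 1)
        mx <- tapply(as.numeric(per_pos), pos_bin, max)
        v[as.integer(names(mx)) + 1] <- mx
      }
      v
    })
  if (normalized) vals <- vals / (tags$total_tags / 1e7)
  xy <- hilbert_d2xy(order, seq_len(n_bins) - 1)
  grid <- matrix(0, side, side)
  grid[cbind(xy$x + 1, xy$y + 1)] <- vals
  structure(grid, order = order, bin_size = bin_bp, aggregation = aggregation,
            chrom = chrom, class = c("hilbert_grid", class(grid)))
}

#' Write a Hilbert grid as a TSV matrix
#'
#' @param grid A `hilbert_grid` from [signal_to_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hilbert_tsv <- function(grid, path) {
  utils::write.table(unclass(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render a Hilbert grid to PNG
#'
#' Simple grayscale-to-heat rendering via [graphics::image()]; intended for
#' quick visual inspection, not publication figures.
#'
#' @param grid A `hilbert_grid`.
#' @param path Output PNG path.
#' @param ... Passed to [graphics::image()].
#' @return `path`, invisibly.
#' @export
plot_hilbert_png <- function(grid, path, ...) {
  grDevices::png(path, width = 512, height = 512)
  on.exit(grDevices::dev.off())
  graphics::image(unclass(grid), useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(path)
}
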