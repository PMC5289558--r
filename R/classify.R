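#' Classify genes into convergent, resistant, divergent, unchanged
#'
#' The core set logic of the reprogramming-responder analysis. Two contrasts
#' against the somatic baseline are combined per direction stratum:
#' \itemize{
#'   \item \strong{convergent} (early responder): DEG in ESC-vs-somatic AND
#'     DEG in iPSCp-vs-somatic in the same direction — the partial iPSC has
#'     already reached the ESC expression state;
#'   \item \strong{resistant} (late responder): DEG in ESC-vs-somatic but not
#'     (in that direction) in iPSCp-vs-somatic — still somatic in the partial
#'     iPSC;
#'   \item \strong{divergent}: DEG in iPSCp-vs-somatic but not (in that
#'     direction) in ESC-vs-somatic — regulated only in the partial iPSC;
#'   \item \strong{unchanged}: DEG in neither contrast.
#' }
#' A gene DEG-up in one contrast and DEG-down in the other is recorded twice
#' (resistant in the ESC direction's stratum, divergent in the iPSCp
#' direction's stratum) and flagged `conflict`.
#'
#' @param esc_vs_somatic,ipscp_vs_somatic `contrast_result` objects from
#'   [call_degs()] over the same gene universe: fully reprogrammed/embryonic
#'   state vs somatic baseline, and partially reprogrammed state vs the same
#'   baseline.
#' @return A `responder_table` data.frame with columns `gene_id`, `class`,
#'   `stratum`, `esc_log2fc`, `esc_p`, `ipscp_log2fc`, `ipscp_p`, `conflict`;
#'   attribute `class_counts` tabulates class x stratum.
#' @export
classify_responders <- function(esc_vs_somatic, ipscp_vs_somatic) {
  e <- esc_vs_somatic
  i <- ipscp_vs_somatic
  if (!setequal(e$gene_id, i$gene_id)) {
    miss <- c(setdiff(e$gene_id, i$gene_id), setdiff(i$gene_id, e$gene_id))
    stop("gene universes differ between contrasts; e.g. ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  i <- i[match(e$gene_id, i$gene_id), ]
  ed <- e$direction
  id <- i$direction
  base <- data.frame(gene_id = e$gene_id, esc_log2fc = e$log2fc,
                     esc_p = e$p_value, ipscp_log2fc = i$log2fc,
                     ipscp_p = i$p_value, stringsAsFactors = FALSE)
  conflict <- (ed == "up" & id == "down") | (ed == "down" & id == "up")
  cls <- character(nrow(base)); stratum <- character(nrow(base))
  cls[ed == "none" & id == "none"] <- "unchanged"
  stratum[ed == "none" & id == "none"] <- "none"
  same <- !conflict & ed != "none" & ed == id
  cls[same] <- "convergent"; stratum[same] <- ed[same]
  res <- !conflict & ed != "none" & id == "none"
  cls[res] <- "resistant"; stratum[res] <- ed[res]
  div <- !conflict & ed == "none" & id != "none"
  cls[div] <- "divergent"; stratum[div] <- id[div]
  out <- cbind(base, class = cls, stratum = stratum, conflict = conflict)
  if (any(conflict)) {
    # one record per stratum: resistant in the ESC direction, divergent in
    # the iPSCp direction
    cf <- base[conflict, , drop = FALSE]
    rec1 <- cbind(cf, class = "resistant", stratum = ed[conflict],
                  conflict = TRUE)
    rec2 <- cbind(cf, class = "divergent", stratum = id[conflict],
                  conflict = TRUE)
    out <- rbind(out[!conflict, , drop = FALSE], rec1, rec2)
    out <- out[order(match(out$gene_id, e$gene_id)), ]
  }
  rownames(out) <- NULL
  counts <- table(class = out$class, stratum = out$stratum)
  structure(out, class_counts = counts,
            class = c("responder_table", "data.frame"))
}

#' Attach planted truth classes for recovery evaluation
#'
#' @param table A `responder_table`.
#' @param truth A `truth_table` from [assign_truth()].
#' @return The table with `truth_class`, `truth_expected_class`,
#'   `truth_expected_stratum` columns appended.
#' @export
add_truth <- function(table, truth) {
  idx <- match(table$gene_id, truth$gene_id)
  if (anyNA(idx)) stop("truth table does not cover all classified genes")
  table$truth_class <- truth$class[idx]
  table$truth_expected_class <- truth$expected_class[idx]
  table$truth_expected_stratum <- truth$expected_stratum[idx]
  table
}

#' Precision and recall of class recovery against planted truth
#'
#' Precision: of the genes called `called_class`, the fraction whose planted
#' states imply that class. Recall: of the genes planted as `truth_class`,
#' the fraction called `called_class`.
#'
#' @param table A `responder_table` with truth columns (see [add_truth()]).
#' @param called_class Classification label to evaluate.
#' @param truth_class Planted generator class (default: evaluate against the
#'   expected classification implied by the planted states).
#' @return Named numeric vector `precision`, `recall`, `n_called`, `n_truth`.
#' @export
recovery_stats <- function(table, called_class,
                           truth_class = NULL) {
  stopifnot("truth_expected_class" %in% names(table))
  called <- table$class == called_class
  if (is.null(truth_class)) {
    pos <- table$truth_expected_class == called_class
  } else {
    pos <- table$truth_class == truth_class
  }
  c(precision = if (any(called)) mean(pos[called]) else NA_real_,
    recall = if (any(pos)) mean(called[pos]) else NA_real_,
    n_called = sum(called), n_truth = sum(pos))
}

#' Fold-change correlation within a DEG stratum
#'
#' Pearson correlation between the ESC-vs-somatic and iPSCp-vs-somatic log2
#' fold changes, restricted to the ESC-vs-somatic DEGs of one direction —
#' the quantity whose down/up asymmetry indicates that repression of the
#' somatic program runs ahead of activation of the ESC program in partially
#' reprogrammed cells.
#'
#' @param esc_vs_somatic,ipscp_vs_somatic `contrast_result`s over the same
#'   universe.
#' @param stratum `"up"` or `"down"`: which ESC-vs-somatic DEG set to use.
#' @return Pearson r, or `NA` with a warning when fewer than 3 genes qualify.
#' @export
class_fc_correlation <- function(esc_vs_somatic, ipscp_vs_somatic,
                                 stratum = c("down", "up")) {
  stratum <- match.arg(stratum)
  e <- esc_vs_somatic; i <- ipscp_vs_somatic
  if (!setequal(e$gene_id, i$gene_id)) stop("gene universes differ")
  i <- i[match(e$gene_id, i$gene_id), ]
  sel <- e$is_deg & e$direction == stratum
  if (sum(sel) < 3) {
    warning("fewer than 3 genes in the ", stratum, " stratum; returning NA")
    return(NA_real_)
  }
  stats::cor(e$log2fc[sel], i$log2fc[sel])
}

#' Class-wise histone-mark summary
#'
#' Mean and median gene-level mark density per responder class x direction
#' stratum x cell type x mark — the tabular form of the bar comparison that
#' shows, e.g., convergent-up genes carrying more H3K4me3 in pluripotent
#' states and convergent-down genes carrying more H3K27me3 there.
#'
#' @param table A `responder_table`.
#' @param densities Nested named list `densities[[cell_type]][[mark]]`, each
#'   a `gene_density` from [gene_density()] covering the classified universe.
#' @return A `class_summary` data.frame: `class`, `stratum`, `cell_type`,
#'   `mark`, `n`, `mean_density`, `median_density`.
#' @export
class_mark_summary <- function(table, densities) {
  stopifnot(inherits(table, "responder_table") || is.data.frame(table))
  for (ct in names(densities)) {
    if (!all(histone_marks() %in% names(densities[[ct]]))) {
      stop("missing mark density for cell type ", ct)
    }
  }
  strata <- unique(table[, c("class", "stratum")])
  rows <- list()
  for (r in seq_len(nrow(strata))) {
    genes <- table$gene_id[table$class == strata$class[r] &
                           table$stratum == strata$stratum[r]]
    for (ct in names(densities)) {
      for (m in histone_marks()) {
        d <- densities[[ct]][[m]]
        if (!all(genes %in% names(d))) {
          stop("density for ", ct, "/", m, " does not cover the universe")
        }
        v <- as.numeric(d[genes])
        rows[[length(rows) + 1L]] <- data.frame(
          class = strata$class[r], stratum = strata$stratum[r],
          cell_type = ct, mark = m, n = length(genes),
          mean_density = mean(v), median_density = stats::median(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("class_summary", "data.frame")
  out
}

#' Expression-direction percentages with mark fold-change table
#'
#' Percentage of genes called up, down, or unchanged under the DEG rule in a
#' contrast, together with the joint per-gene table of H3K4me3 and H3K27me3
#' log2 fold changes and the expression call — the data behind a
#' fold-change integration scatter with its inset pie.
#'
#' @param k4_fc,k27_fc Named log2 fold-change vectors from [mark_log2fc()].
#' @param expr_contrast A `contrast_result` over the same gene universe.
#' @return List with `percentages` (named `up`, `down`, `unchanged`, summing
#'   to 100) and `table` (`gene_id`, `k4_log2fc`, `k27_log2fc`,
#'   `expr_log2fc`, `direction`).
#' @export
fc_category_percentages <- function(k4_fc, k27_fc, expr_contrast) {
  ids <- expr_contrast$gene_id
  if (!setequal(names(k4_fc), ids) || !setequal(names(k27_fc), ids)) {
    stop("gene universes of mark fold changes and contrast differ")
  }
  d <- expr_contrast$direction
  pct <- c(up = 100 * mean(d == "up"), down = 100 * mean(d == "down"),
           unchanged = 100 * mean(d == "none"))
  list(percentages = pct,
       table = data.frame(gene_id = ids, k4_log2fc = as.numeric(k4_fc[ids]),
                          k27_log2fc = as.numeric(k27_fc[ids]),
                          expr_log2fc = expr_contrast$log2fc, direction = d,
                          stringsAsFactors = FALSE))
}

#' DEG-set overlap across contrasts
#'
#' Sizes, pairwise intersections, full intersection/union, and the fraction
#' of the union shared by all contrasts, for DEG sets of one direction.
#'
#' @param contrasts Named list of >= 2 `contrast_result`s over one universe.
#' @param direction `"up"`, `"down"` or `"any"`.
#' @return List with `sizes`, `pairwise` (intersection-count matrix),
#'   `n_common`, `n_union`, `fraction_common` and, for two contrasts,
#'   `pct_common` (100 x common / union).
#' @export
deg_overlap <- function(contrasts, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (length(contrasts) < 2) stop("need >= 2 contrasts")
  universe <- contrasts[[1]]$gene_id
  for (cc in contrasts[-1]) {
    if (!setequal(cc$gene_id, universe)) stop("gene universes differ")
  }
  sets <- lapply(contrasts, function(cc) {
    sel <- if (direction == "any") cc$is_deg else cc$direction == direction
    cc$gene_id[sel]
  })
  if (is.null(names(sets))) names(sets) <- paste0("contrast", seq_along(sets))
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    pairwise[a, b] <- length(intersect(sets[[a]], sets[[b]]))
  }
  common <- Reduce(intersect, sets)
  un <- Reduce(union, sets)
  out <- list(sizes = lengths(sets), pairwise = pairwise,
              n_common = length(common), n_union = length(un),
              fraction_common = if (length(un)) length(common) / length(un) else 0)
  if (k == 2) out$pct_common <- 100 * out$fraction_common
  out
}

#' Write a responder table as TSV
#' @param table A `responder_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responder_tsv <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}
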