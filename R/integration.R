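# Differential-expression gene selection, ChIP promoter-window coverage,
# and the fused per-gene evidence matrix behind the integration heatmap.
# The DE model itself is not fitted here: the table (gene, log2fc,
# adjusted p) is consumed as produced by a dedicated DE package.

#' Read a differential-expression results table
#'
#' TSV with header columns `gene_id`, `log2fc`, `p_adj`; `p_adj` may be
#' missing (NA) for genes removed by independent filtering.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those three columns.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p_adj")
  if (!all(need %in% names(df)))
    stop("DE table must have header columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in DE table")
  ok <- is.na(df$p_adj) | (df$p_adj >= 0 & df$p_adj <= 1)
  if (!all(ok)) stop("p_adj outside [0, 1]")
  df[, need]
}

#' DEG selection configuration
#'
#' @param fdr_threshold Adjusted-p cutoff; selection is strict
#'   (`p_adj < fdr_threshold`).  Default 0.01.
#' @param lfc_threshold Minimum `|log2fc|`; default 0, i.e. no fold-change
#'   filter (selection relies on the DE model's own dispersion handling).
#' @return Object of class `deg_selection_config`.
#' @export
deg_selection_config <- function(fdr_threshold = 0.01, lfc_threshold = 0) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, lfc_threshold >= 0)
  structure(list(fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold),
            class = "deg_selection_config")
}

#' Select differentially expressed genes
#'
#' A gene is selected iff its adjusted p is present and strictly below the
#' FDR threshold and `|log2fc| >= lfc_threshold`.  Records with missing
#' `p_adj` are never selected.
#'
#' @param table DE data.frame from [read_de_table()].
#' @param config A [deg_selection_config()].
#' @return data.frame of selected genes with columns `gene_id`, `log2fc`,
#'   `p_adj`, `direction` (`"up"` or `"down"`), sorted by `gene_id`.
#' @export
select_degs <- function(table, config = deg_selection_config()) {
  if (anyDuplicated(table$gene_id)) stop("duplicate gene_id in DE table")
  sel <- !is.na(table$p_adj) & table$p_adj < config$fdr_threshold &
    abs(table$log2fc) >= config$lfc_threshold
  out <- table[sel, c("gene_id", "log2fc", "p_adj"), drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# round half away from zero (208/215 = 96.74 -> 97)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarise a DEG selection
#'
#' @param selected data.frame from [select_degs()].
#' @return List with `total`, `up`, `down`, `up_pct` (percentage of
#'   up-regulated genes, rounded half away from zero; `NA` when nothing is
#'   selected), `min_abs_lfc`, `max_abs_lfc`.
#' @export
deg_summary <- function(selected) {
  total <- nrow(selected)
  if (total == 0L)
    return(list(total = 0L, up = 0L, down = 0L, up_pct = NA_real_,
                min_abs_lfc = NA_real_, max_abs_lfc = NA_real_))
  up <- sum(selected$direction == "up")
  list(total = total, up = up, down = total - up,
       up_pct = round_half_up(100 * up / total),
       min_abs_lfc = min(abs(selected$log2fc)),
       max_abs_lfc = max(abs(selected$log2fc)))
}

#' ChIP promoter-window configuration
#'
#' @param upstream Nt upstream of the ATG (default 200).
#' @param into_gene Nt into the coding sequence (default 50).
#' @return Object of class `chip_window_config`.
#' @export
chip_window_config <- function(upstream = 200L, into_gene = 50L) {
  stopifnot(upstream > 0, into_gene > 0)
  structure(list(upstream = as.integer(upstream),
                 into_gene = as.integer(into_gene)),
            class = "chip_window_config")
}

#' Mean ChIP coverage over a gene's promoter window
#'
#' Arithmetic mean of per-base coverage over the strand-aware window from
#' `upstream` nt before the ATG to `into_gene` nt inside the gene
#' (`[ATG-200, ATG+50)` by default).  Windows running off the contig are
#' clipped and averaged over the remaining bases.
#'
#' @param track A `coverage_track` (ChIP coverage; orientation-agnostic).
#' @param gene One-row annotation (list or data.frame row).
#' @param config A [chip_window_config()].
#' @return The mean coverage (numeric scalar).
#' @export
chip_window_mean <- function(track, gene, config = chip_window_config()) {
  L <- length(track$values)
  if (gene$strand == "+") {
    lo <- gene$start - config$upstream
    hi <- gene$start + config$into_gene
  } else {
    lo <- gene$end - config$into_gene
    hi <- gene$end + config$upstream
  }
  lo <- max(lo, 0L); hi <- min(hi, L)
  if (lo >= hi) stop("ChIP window does not intersect the contig for ",
                     gene$gene_id)
  mean(track$values[(lo + 1L):hi])
}

#' Read a two-column binary/categorical side table
#'
#' TSV with header `gene_id`, `value`; used for the literature-derived
#' per-gene annotations (essentiality, cell-cycle regulation, methylation
#' dependence, COG category), which the pipeline treats as opaque inputs.
#'
#' @param path Path to the TSV.
#' @return data.frame with `gene_id` and `value`.
#' @export
read_side_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "value") %in% names(df)))
    stop("side table must have header columns gene_id, value")
  df[, c("gene_id", "value")]
}

#' Fuse all evidence into the per-gene annotation matrix
#'
#' One row per annotated gene, combining differential expression, MAPS
#' candidacy across experiments, transcription-factor box presence, motif
#' counts in the upstream region, ChIP promoter coverage and the binary
#' side annotations.  Genes absent from a side input get the neutral
#' default (FALSE / 0 / NA).
#'
#' @param annotations Annotation data.frame (defines the row set).
#' @param degs data.frame from [select_degs()].
#' @param maps_candidates List of character vectors, one per MAPS
#'   experiment, each the candidate gene ids of that experiment.
#' @param full_site,half_site Per-gene site tables from
#'   [assign_sites_to_genes()] (full and half TF box; either may be NULL).
#' @param motif_counts Named integer vector: motif occurrences upstream of
#'   each gene (NULL for none).
#' @param chip_means Named numeric vector of [chip_window_mean()] values.
#' @param essential,cell_cycle,methylation,cog Side data.frames from
#'   [read_side_table()] (logical `value` for the first three; text for
#'   `cog`).  Any may be NULL.
#' @return data.frame of class `gene_annotation_matrix`, one row per gene,
#'   sorted by `gene_id`.
#' @export
build_matrix <- function(annotations, degs, maps_candidates = list(),
                         full_site = NULL, half_site = NULL,
                         motif_counts = NULL, chip_means = NULL,
                         essential = NULL, cell_cycle = NULL,
                         methylation = NULL, cog = NULL) {
  ids <- sort(annotations$gene_id)
  lookup_flag <- function(tab) {
    if (is.null(tab)) return(rep(FALSE, length(ids)))
    v <- tab$value[match(ids, tab$gene_id)]
    v <- as.logical(v)
    v[is.na(v)] <- FALSE
    v
  }
  site_flag <- function(st) {
    if (is.null(st)) return(rep(FALSE, length(ids)))
    v <- st$has_site[match(ids, st$gene_id)]
    v[is.na(v)] <- FALSE
    v
  }
  di <- match(ids, degs$gene_id)
  is_deg <- !is.na(di)
  log2fc <- ifelse(is_deg, degs$log2fc[di], NA_real_)
  direction <- ifelse(is_deg, degs$direction[di], "none")
  mp <- integer(length(ids))
  for (cand in maps_candidates) mp <- mp + as.integer(ids %in% cand)
  mc <- if (is.null(motif_counts)) integer(length(ids)) else {
    v <- as.integer(motif_counts[ids]); v[is.na(v)] <- 0L; v
  }
  cm <- if (is.null(chip_means)) rep(NA_real_, length(ids)) else
    as.numeric(chip_means[ids])
  cg <- if (is.null(cog)) rep(NA_character_, length(ids)) else {
    v <- as.character(cog$value[match(ids, cog$gene_id)]); v
  }
  m <- data.frame(gene_id = ids, is_deg = is_deg, log2fc = log2fc,
                  direction = direction, maps_positive_count = mp,
                  ctra_full_site = site_flag(full_site),
                  ctra_half_site = site_flag(half_site),
                  gggg_upstream_count = mc, chip_mean = cm,
                  essential = lookup_flag(essential),
                  cell_cycle_regulated = lookup_flag(cell_cycle),
                  methylation_dependent = lookup_flag(methylation),
                  cog = cg, stringsAsFactors = FALSE)
  rownames(m) <- NULL
  class(m) <- c("gene_annotation_matrix", "data.frame")
  m
}

#' @export
print.gene_annotation_matrix <- function(x, ...) {
  cat(sprintf("Gene annotation matrix: %d genes, %d DEGs, %d MAPS-positive\n",
              nrow(x), sum(x$is_deg), sum(x$maps_positive_count > 0)))
  NextMethod()
}

#' Restrict the matrix to DEGs (the heatmap row set)
#' @param m A `gene_annotation_matrix`.
#' @return The DEG-only subset, same class.
#' @export
matrix_deg_rows <- function(m) {
  out <- m[m$is_deg, , drop = FALSE]
  rownames(out) <- NULL
  out
}
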