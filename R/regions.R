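# Per-gene region model: 5' UTR (TSS-anchored with a 100-nt fallback),
# gene BODY (the annotated extent), and a fixed 3' UTR window running from
# 50 nt inside the coding end to 200 nt downstream.  All coordinates are
# 0-based half-open; regions of neighbouring genes may overlap and are
# scored independently.

#' Region-definition rules
#'
#' Constants of the region model.  The 5' UTR of a gene is the interval
#' from its experimentally determined TSS to the gene start when that
#' distance is at least `utr5_min_len` nt; otherwise (no TSS, or a short
#' TSS-derived UTR) it is the `utr5_default_len` nt immediately upstream of
#' the start.  The 3' UTR is the fixed window from `utr3_into_gene` nt
#' inside the 3' end of the feature to `utr3_downstream` nt beyond it.
#'
#' @param utr5_default_len Fallback 5' UTR length, nt (default 100).
#' @param utr5_min_len Minimum accepted TSS-derived UTR length, nt
#'   (default 100; shorter ones are replaced by the fallback).
#' @param utr3_into_gene Portion of the 3' UTR window inside the gene, nt
#'   (default 50).
#' @param utr3_downstream Portion downstream of the gene, nt (default 200).
#' @return An object of class `region_rules`.
#' @export
region_rules <- function(utr5_default_len = 100L, utr5_min_len = 100L,
                         utr3_into_gene = 50L, utr3_downstream = 200L) {
  r <- list(utr5_default_len = as.integer(utr5_default_len),
            utr5_min_len = as.integer(utr5_min_len),
            utr3_into_gene = as.integer(utr3_into_gene),
            utr3_downstream = as.integer(utr3_downstream))
  if (any(unlist(r) <= 0L)) stop("all region rule lengths must be > 0")
  structure(r, class = "region_rules")
}

# Clip [start, end) to a linear contig, or wrap on a circular genome.
# Returns list(start, end, truncated).  Wrapped regions keep out-of-range
# coordinates (callers take them modulo length when extracting).
clip_region <- function(start, end, genome) {
  if (genome$circular)
    return(list(start = start, end = end, truncated = FALSE))
  s <- max(start, 0L); e <- min(end, genome$length)
  if (s >= e) stop("region entirely outside the contig")
  list(start = s, end = e, truncated = (s != start || e != end))
}

region_row <- function(gene, kind, start, end, truncated) {
  data.frame(gene_id = gene$gene_id, kind = kind, seq_id = gene$seq_id,
             start = as.integer(start), end = as.integer(end),
             strand = gene$strand, truncated = truncated,
             stringsAsFactors = FALSE)
}

#' Define the 5' UTR region of one gene
#'
#' @param gene One-row annotation data.frame (or list) with `gene_id`,
#'   `seq_id`, `start`, `end`, `strand`.
#' @param tss Optional 0-based TSS position (the +1 nucleotide) for this
#'   gene, `NULL`/`NA` if unknown.
#' @param rules A [region_rules()] object.
#' @param genome A `genome_sequence` (for edge truncation).
#' @return One-row region data.frame (`gene_id`, `kind = "UTR5"`, `seq_id`,
#'   `start`, `end`, `strand`, `truncated`).  The interval is half-open at
#'   the gene start, so UTR5 and BODY are disjoint.
#' @export
define_utr5 <- function(gene, tss = NULL, rules = region_rules(), genome) {
  use_tss <- !is.null(tss) && !is.na(tss)
  if (gene$strand == "+") {
    anchor <- gene$start
    if (use_tss) {
      if (tss > anchor) stop("TSS downstream of gene start for ", gene$gene_id)
      if (anchor - tss >= rules$utr5_min_len) {
        cl <- clip_region(tss, anchor, genome)
        return(region_row(gene, "UTR5", cl$start, cl$end, cl$truncated))
      }
    }
    cl <- clip_region(anchor - rules$utr5_default_len, anchor, genome)
  } else {
    anchor <- gene$end                  # start codon side on the minus strand
    if (use_tss) {
      if (tss < anchor - 1L) stop("TSS downstream of gene start for ", gene$gene_id)
      if (tss + 1L - anchor >= rules$utr5_min_len) {
        cl <- clip_region(anchor, tss + 1L, genome)
        return(region_row(gene, "UTR5", cl$start, cl$end, cl$truncated))
      }
    }
    cl <- clip_region(anchor, anchor + rules$utr5_default_len, genome)
  }
  region_row(gene, "UTR5", cl$start, cl$end, cl$truncated)
}

#' Define the 3' UTR region of one gene
#'
#' The window runs from `utr3_into_gene` nt inside the 3' end of the
#' feature to `utr3_downstream` nt beyond it (250 nt total under the
#' defaults).  Genes shorter than `utr3_into_gene` have the window clipped
#' at the gene's far end and flagged `truncated`.
#'
#' @inheritParams define_utr5
#' @return One-row region data.frame with `kind = "UTR3"`.
#' @export
define_utr3 <- function(gene, rules = region_rules(), genome) {
  glen <- gene$end - gene$start
  short <- glen < rules$utr3_into_gene
  if (gene$strand == "+") {
    s <- if (short) gene$start else gene$end - rules$utr3_into_gene
    cl <- clip_region(s, gene$end + rules$utr3_downstream, genome)
  } else {
    e <- if (short) gene$end else gene$start + rules$utr3_into_gene
    cl <- clip_region(gene$start - rules$utr3_downstream, e, genome)
  }
  region_row(gene, "UTR3", cl$start, cl$end, cl$truncated || short)
}

#' Build the full region set for an annotation
#'
#' One UTR5, one BODY and one UTR3 per gene.  BODY is the annotated extent
#' exactly; ncRNA features are treated like CDS.  No de-overlapping is
#' performed: each region is scored independently downstream.
#'
#' @param annotations Annotation data.frame from [read_gff()].
#' @param tss_table Optional TSS data.frame from [read_tss_table()].
#' @param rules A [region_rules()] object.
#' @param genome A `genome_sequence`.
#' @return A data.frame of regions (3 rows per gene), sorted by `gene_id`
#'   then `kind`.
#' @export
build_region_set <- function(annotations, tss_table = NULL,
                             rules = region_rules(), genome) {
  if (nrow(annotations) == 0L) stop("empty annotation set")
  validate_annotations(annotations)
  tss_of <- function(gid) {
    if (is.null(tss_table)) return(NULL)
    i <- match(gid, tss_table$gene_id)
    if (is.na(i)) NULL else tss_table$tss_position[i]
  }
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    g <- annotations[i, ]
    out[[i]] <- rbind(
      define_utr5(g, tss_of(g$gene_id), rules, genome),
      region_row(g, "BODY", g$start, g$end, FALSE),
      define_utr3(g, rules, genome))
  }
  rs <- do.call(rbind, out)
  rs <- rs[order(rs$gene_id, rs$kind), , drop = FALSE]
  rownames(rs) <- NULL
  rs
}

#' Export a region set as BED6
#'
#' 0-based half-open records named `gene_id|kind`, score 0, strand column.
#'
#' @param regions Region data.frame from [build_region_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
regions_to_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$seq_id, start = regions$start,
                   end = regions$end,
                   name = paste(regions$gene_id, regions$kind, sep = "|"),
                   score = 0L, strand = regions$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
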