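# Readers/writers for the standard formats the pipeline touches, plus the
# internal coordinate model shared by all modules.
#
# Internal convention: 0-based half-open intervals [start, end) on every
# object.  Each reader performs its own conversion at the boundary
# (GFF3 is 1-based inclusive; bedGraph is already 0-based half-open;
# the TSS table convention is a flag, 1-based by default).

#' Construct a genome sequence object
#'
#' A minimal container for one (typically bacterial) replicon: the residue
#' string, its identifier and whether the molecule is circular.
#'
#' @param seq_id Sequence identifier (e.g. a RefSeq accession).
#' @param residues Character scalar over the alphabet `A,C,G,T,N`.
#' @param circular Logical; is the molecule circular?  Regions running off
#'   a linear contig are truncated; on a circular one they may wrap.
#' @return An object of class `genome_sequence` with fields `seq_id`,
#'   `length`, `residues` and `circular`.
#' @export
genome_sequence <- function(seq_id, residues, circular = FALSE) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (grepl("[^ACGTN]", residues))
    stop("genome residues outside alphabet {A,C,G,T,N}")
  structure(
    list(seq_id = seq_id, length = nchar(residues),
         residues = residues, circular = isTRUE(circular)),
    class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %s nt%s\n", x$seq_id,
              format(x$length, big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Only single-sequence genomes are supported (the pipeline is designed for
#' one bacterial chromosome); a multi-record file is an error.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, passed through to [genome_sequence()].
#' @return A `genome_sequence`.
#' @export
read_fasta <- function(path, circular = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected exactly one sequence in ", path, ", found ", length(ss))
  genome_sequence(seq_id = sub("\\s.*$", "", names(ss)[1L]),
                  residues = as.character(ss[[1L]]),
                  circular = circular)
}

#' Write a genome to a FASTA file
#' @param genome A `genome_sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$residues)
  names(ss) <- genome$seq_id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract a subsequence, strand-aware
#'
#' Coordinates are 0-based half-open on the forward strand; with
#' `strand = "-"` the reverse complement is returned, i.e. the sequence in
#' transcript orientation for a minus-strand feature.  On circular genomes
#' the window may wrap; on linear genomes it is clipped.
#'
#' @param genome A `genome_sequence`.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar.
#' @export
extract_sequence <- function(genome, start, end, strand = "+") {
  stopifnot(start < end)
  L <- genome$length
  if (start < 0L || end > L) {
    if (genome$circular) {
      idx <- (seq.int(start, end - 1L) %% L) + 1L
      s <- paste(strsplit(genome$residues, "", fixed = TRUE)[[1L]][idx],
                 collapse = "")
    } else {
      s <- substr(genome$residues, max(start, 0L) + 1L, min(end, L))
    }
  } else {
    s <- substr(genome$residues, start + 1L, end)
  }
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Read gene annotations from GFF3
#'
#' Keeps the feature types in `feature_types` (CDS and ncRNA by default,
#' mirroring the distinction between coding genes and small RNAs), converts
#' the 1-based inclusive GFF coordinates to the internal 0-based half-open
#' convention and takes the gene identifier from `id_attribute`.
#'
#' @param path Path to a GFF3 file.
#' @param genome A `genome_sequence` used for bounds validation.
#' @param feature_types Character vector of GFF `type` values to keep.
#' @param id_attribute Attribute key holding the gene identifier.
#' @return A data.frame with columns `gene_id`, `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, `feature_class`, `product`.
#' @export
read_gff <- function(path, genome, feature_types = c("CDS", "ncRNA"),
                     id_attribute = "locus_tag") {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      feature_class = character(), product = character()))
  mc <- S4Vectors::mcols(gr)
  if (!id_attribute %in% names(mc))
    stop("GFF3 attribute '", id_attribute, "' not present in ", path)
  ids <- as.character(mc[[id_attribute]])
  if (anyNA(ids) || any(ids == ""))
    stop("missing '", id_attribute, "' attribute on some features in ", path)
  ann <- data.frame(
    gene_id = ids,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_class = as.character(gr$type),
    product = if ("product" %in% names(mc)) as.character(mc$product) else NA_character_,
    stringsAsFactors = FALSE)
  validate_annotations(ann, genome)
  ann[order(ann$gene_id), , drop = FALSE]
}

validate_annotations <- function(ann, genome = NULL) {
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation set: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  if (any(ann$end <= ann$start))
    stop("annotation with end <= start: ",
         paste(ann$gene_id[ann$end <= ann$start], collapse = ", "))
  if (!all(ann$strand %in% c("+", "-")))
    stop("annotation strand must be '+' or '-'")
  if (!is.null(genome) && !genome$circular &&
      (any(ann$start < 0L) || any(ann$end > genome$length)))
    stop("annotation coordinates beyond genome length on a linear genome")
  invisible(ann)
}

#' Construct a per-base coverage track
#'
#' One track holds the 1-nt-bin coverage of a single read-orientation class
#' of one sequencing library, together with that library's total aligned
#' fragment count (the RPM denominator).
#'
#' @param seq_id Sequence identifier.
#' @param values Numeric vector, one value per genomic base, all `>= 0`.
#'   Values are not forced to integers: RPM-scaled tracks are fractional.
#' @param orientation_class `"PLUS_SET"` or `"MINUS_SET"` — which
#'   alignment-orientation class (SAM flag pair set) the track was built from.
#' @param library_total Positive number: total aligned fragments in the
#'   library the track came from.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(seq_id, values, orientation_class, library_total) {
  orientation_class <- match.arg(orientation_class, c("PLUS_SET", "MINUS_SET"))
  stopifnot(is.numeric(values), length(library_total) == 1L, library_total > 0)
  if (any(values < 0)) stop("coverage values must be >= 0")
  structure(
    list(seq_id = seq_id, values = as.numeric(values),
         orientation_class = orientation_class,
         library_total = as.numeric(library_total)),
    class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s [%s]: %s bases, library total %s, mean %.3g\n",
              x$seq_id, x$orientation_class,
              format(length(x$values), big.mark = ","),
              format(x$library_total, big.mark = ","), mean(x$values)))
  invisible(x)
}

#' Read a per-base coverage track from bedGraph
#'
#' bedGraph intervals are 0-based half-open, must not overlap, and must lie
#' within the genome; positions not covered by any record get value 0.
#'
#' @param path Path to a bedGraph file.
#' @param genome A `genome_sequence` fixing the track length.
#' @param orientation_class,library_total See [coverage_track()].
#' @return A `coverage_track` whose `values` has one entry per genome base.
#' @export
read_bedgraph <- function(path, genome, orientation_class, library_total) {
  vals <- numeric(genome$length)
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) > 0L) {
      start0 <- GenomicRanges::start(gr) - 1L  # rtracklayer re-bases to 1-based
      end0 <- GenomicRanges::end(gr)
      if (any(start0 < 0L) || any(end0 > genome$length))
        stop("bedGraph interval beyond genome length in ", path)
      o <- order(start0)
      if (any(start0[o][-1L] < end0[o][-length(o)]))
        stop("overlapping bedGraph intervals in ", path)
      score <- as.numeric(gr$score)
      widths <- end0[o] - start0[o]
      idx <- sequence(widths, from = start0[o] + 1L)
      vals[idx] <- rep(score[o], widths)
    }
  }
  coverage_track(genome$seq_id, vals, orientation_class, library_total)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into intervals; zero runs are omitted,
#' matching the sparse files the track was read from.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$values)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values != 0
  # plain 0-based half-open text; column order is fixed by the format
  writeLines(paste(track$seq_id, start[keep], end[keep],
                   format(r$values[keep], scientific = FALSE, trim = TRUE,
                          digits = 15),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a transcription start site table
#'
#' A TSV with header columns `gene_id`, `position`, `strand`, one row per
#' gene (multi-TSS resolution is left to the caller; duplicates are an
#' error).  Positions are converted to the internal 0-based convention
#' according to `one_based`.
#'
#' @param path Path to the TSV.
#' @param annotations Annotation data.frame used to check that each TSS lies
#'   upstream of its gene on the matching strand; `NULL` skips the check.
#' @param one_based Logical; is the `position` column 1-based (default)?
#' @return A data.frame with columns `gene_id`, `tss_position` (0-based),
#'   `strand`.
#' @export
read_tss_table <- function(path, annotations = NULL, one_based = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "position", "strand")
  if (!all(need %in% names(df)))
    stop("TSS table must have header columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in TSS table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  tss <- data.frame(gene_id = as.character(df$gene_id),
                    tss_position = as.integer(df$position) - as.integer(one_based),
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    m <- match(tss$gene_id, annotations$gene_id)
    known <- !is.na(m)
    if (any(tss$strand[known] != annotations$strand[m[known]]))
      stop("TSS strand disagrees with gene strand for: ",
           paste(tss$gene_id[known][tss$strand[known] !=
                                    annotations$strand[m[known]]], collapse = ", "))
    up_ok <- ifelse(annotations$strand[m[known]] == "+",
                    tss$tss_position[known] <= annotations$start[m[known]],
                    tss$tss_position[known] >= annotations$end[m[known]] - 1L)
    if (!all(up_ok))
      stop("TSS downstream of gene start for: ",
           paste(tss$gene_id[known][!up_ok], collapse = ", "))
  }
  tss
}

#' Write a data.frame as headered TSV
#'
#' The single table writer used for every tabular output; tab-separated,
#' header row, no quoting, no row names.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a headered TSV written by [write_table()]
#' @param path Input path.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
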