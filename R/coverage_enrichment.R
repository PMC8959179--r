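# Strand-aware region coverage, RPM normalisation, and the MAPS candidate
# caller: a region is called when its log2 RPM ratio (pull-down over
# control) reaches the threshold AND its pull-down coverage clears the
# lower-quantile floor computed over all regions of the MS library.

#' Classify a SAM FLAG into a read-orientation class
#'
#' Stranded paired-end libraries are split into two alignment-orientation
#' classes before coverage is computed: properly paired reads with flags
#' 99/147 form one class (`PLUS_SET`) and flags 83/163 the other
#' (`MINUS_SET`).  Every other flag is excluded.
#'
#' @param sam_flag Integer vector of SAM FLAG values.
#' @return Character vector over `{"PLUS_SET","MINUS_SET","EXCLUDED"}`.
#' @export
classify_pair_orientation <- function(sam_flag) {
  sam_flag <- as.integer(sam_flag)
  if (any(is.na(sam_flag)) || any(sam_flag < 0L))
    stop("SAM flags must be non-negative integers")
  out <- rep("EXCLUDED", length(sam_flag))
  out[sam_flag %in% c(99L, 147L)] <- "PLUS_SET"
  out[sam_flag %in% c(83L, 163L)] <- "MINUS_SET"
  out
}

#' Orientation protocol: which flag class is sense for each strand
#'
#' @param plus_strand Orientation class carrying transcripts of `+` strand
#'   genes (default `"PLUS_SET"`, the usual layout of the Illumina stranded
#'   paired-end protocol).
#' @return Named list mapping `"+"` and `"-"` to orientation classes.
#' @export
orientation_protocol <- function(plus_strand = c("PLUS_SET", "MINUS_SET")) {
  plus_strand <- match.arg(plus_strand)
  list(`+` = plus_strand,
       `-` = if (plus_strand == "PLUS_SET") "MINUS_SET" else "PLUS_SET")
}

#' A stranded library: one coverage track per orientation class
#'
#' @param plus,minus `coverage_track`s with orientation classes `PLUS_SET`
#'   and `MINUS_SET` respectively, from the same library (they must agree on
#'   `library_total`).
#' @return An object of class `stranded_library`.
#' @export
stranded_library <- function(plus, minus) {
  stopifnot(inherits(plus, "coverage_track"), inherits(minus, "coverage_track"),
            plus$orientation_class == "PLUS_SET",
            minus$orientation_class == "MINUS_SET",
            length(plus$values) == length(minus$values))
  if (plus$library_total != minus$library_total)
    stop("the two tracks of one library must share library_total")
  structure(list(PLUS_SET = plus, MINUS_SET = minus,
                 library_total = plus$library_total),
            class = "stranded_library")
}

#' Per-region coverage sums and RPM for a stranded library
#'
#' For each region, 1-nt coverage values are summed over `[start, end)`
#' from the track whose orientation class matches the region's strand under
#' the protocol mapping, then scaled to reads per million:
#' `rpm = raw_sum * 1e6 / library_total`.
#'
#' @param regions Region data.frame from [build_region_set()] (or any frame
#'   with `gene_id`, `kind`, `start`, `end`, `strand`).
#' @param library A [stranded_library()].
#' @param protocol An [orientation_protocol()].
#' @return `regions` with columns `raw_sum` and `rpm` appended.
#' @export
region_coverage <- function(regions, library, protocol = orientation_protocol()) {
  L <- length(library$PLUS_SET$values)
  if (any(regions$start < 0L) || any(regions$end > L))
    stop("region outside the coverage track")
  # cumulative sums give O(1) interval sums per region
  cs <- list(PLUS_SET = c(0, cumsum(library$PLUS_SET$values)),
             MINUS_SET = c(0, cumsum(library$MINUS_SET$values)))
  cls <- unlist(protocol[regions$strand], use.names = FALSE)
  raw <- numeric(nrow(regions))
  for (k in c("PLUS_SET", "MINUS_SET")) {
    i <- which(cls == k)
    raw[i] <- cs[[k]][regions$end[i] + 1L] - cs[[k]][regions$start[i] + 1L]
  }
  regions$raw_sum <- raw
  regions$rpm <- raw * 1e6 / library$library_total
  regions
}

#' MAPS caller configuration
#'
#' @param log2_threshold Minimum log2 RPM ratio for a candidate region
#'   (default 2, i.e. a 4-fold linear increase); the comparison is
#'   inclusive.
#' @param coverage_quantile Fraction of lowest-covered MS regions excluded
#'   by the floor (default 0.25: a candidate must exceed the lower 25% of
#'   regions in the pull-down).
#' @param pseudocount_rpm Pseudocount added (in RPM units) to both
#'   numerator and denominator of the ratio (default 1; set 0 for the raw
#'   ratio).
#' @param quantile_method Only `"nearest_rank"`: the floor is the observed
#'   value at rank `ceiling(q * n)`.
#' @param quantile_on Scale the floor is computed on: `"rpm"` (default) or
#'   `"raw"`.
#' @return An object of class `maps_caller_config`.
#' @export
maps_caller_config <- function(log2_threshold = 2, coverage_quantile = 0.25,
                               pseudocount_rpm = 1,
                               quantile_method = "nearest_rank",
                               quantile_on = c("rpm", "raw")) {
  quantile_method <- match.arg(quantile_method)
  quantile_on <- match.arg(quantile_on)
  stopifnot(log2_threshold > 0, coverage_quantile > 0, coverage_quantile < 1,
            pseudocount_rpm >= 0)
  structure(list(log2_threshold = log2_threshold,
                 coverage_quantile = coverage_quantile,
                 pseudocount_rpm = pseudocount_rpm,
                 quantile_method = quantile_method,
                 quantile_on = quantile_on),
            class = "maps_caller_config")
}

# Nearest-rank quantile: the smallest observed value with at least a
# fraction q of the data at or below it.
nearest_rank_quantile <- function(x, q) {
  sort(x)[max(1L, ceiling(q * length(x)))]
}

#' Call MAPS candidate target regions and genes
#'
#' The core decision rule of the pipeline.  For each region,
#' `log2_ratio = log2((ms_rpm + pc) / (control_rpm + pc))`; the region
#' passes the ratio filter when `log2_ratio >= log2_threshold` and passes
#' the floor when its MS coverage is strictly greater than the
#' `coverage_quantile` nearest-rank quantile of MS coverage over *all*
#' regions (zeros included).  A region is a candidate when it passes both;
#' a gene is a candidate when at least one of its regions is.
#'
#' @param ms,control Region-coverage data.frames from [region_coverage()]
#'   for the MS2 pull-down and the untagged control; they must describe the
#'   same region set in the same order.
#' @param config A [maps_caller_config()].
#' @return An object of class `maps_call` with components
#'   `calls` (per-region data.frame: `gene_id`, `kind`, `ms_rpm`,
#'   `control_rpm`, `log2_ratio`, `passed_ratio`, `passed_floor`,
#'   `is_candidate_region`), `candidate_genes` (character vector),
#'   `floor` (the quantile floor value) and `config`.
#' @export
maps_call <- function(ms, control, config = maps_caller_config()) {
  if (nrow(ms) != nrow(control) ||
      !identical(ms$gene_id, control$gene_id) ||
      !identical(ms$kind, control$kind))
    stop("MS and control region-coverage sets do not match")
  pc <- config$pseudocount_rpm
  lr <- log2((ms$rpm + pc) / (control$rpm + pc))
  floor_basis <- if (config$quantile_on == "rpm") ms$rpm else ms$raw_sum
  floor_val <- nearest_rank_quantile(floor_basis, config$coverage_quantile)
  passed_ratio <- lr >= config$log2_threshold
  passed_floor <- floor_basis > floor_val
  calls <- data.frame(gene_id = ms$gene_id, kind = ms$kind,
                      ms_rpm = ms$rpm, control_rpm = control$rpm,
                      log2_ratio = lr,
                      passed_ratio = passed_ratio,
                      passed_floor = passed_floor,
                      is_candidate_region = passed_ratio & passed_floor,
                      stringsAsFactors = FALSE)
  o <- order(calls$gene_id, calls$kind)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls,
                 candidate_genes =
                   sort(unique(calls$gene_id[calls$is_candidate_region])),
                 floor = floor_val, config = config),
            class = "maps_call")
}

#' @export
print.maps_call <- function(x, ...) {
  cat("MAPS candidate-target call\n")
  cat(sprintf("  regions scored     : %d\n", nrow(x$calls)))
  cat(sprintf("  log2 RPM threshold : %g (>= , i.e. %g-fold)\n",
              x$config$log2_threshold, 2^x$config$log2_threshold))
  cat(sprintf("  coverage floor     : > %g (%s, lower %g%% of MS regions)\n",
              x$floor, x$config$quantile_on,
              100 * x$config$coverage_quantile))
  cat(sprintf("  candidate regions  : %d\n", sum(x$calls$is_candidate_region)))
  cat(sprintf("  candidate genes    : %d\n", length(x$candidate_genes)))
  invisible(x)
}

#' @export
summary.maps_call <- function(object, ...) {
  calls <- object$calls
  by_kind <- table(factor(calls$kind, c("UTR5", "BODY", "UTR3")),
                   calls$is_candidate_region)
  s <- list(n_regions = nrow(calls),
            n_candidate_regions = sum(calls$is_candidate_region),
            n_candidate_genes = length(object$candidate_genes),
            candidate_regions_by_kind = by_kind,
            floor = object$floor,
            config = object$config)
  class(s) <- "summary.maps_call"
  s
}

#' @export
print.summary.maps_call <- function(x, ...) {
  cat(sprintf("MAPS call: %d/%d candidate regions, %d candidate genes\n",
              x$n_candidate_regions, x$n_regions, x$n_candidate_genes))
  cat("candidate regions by kind:\n")
  print(x$candidate_regions_by_kind)
  invisible(x)
}

#' @export
as.data.frame.maps_call <- function(x, ...) x$calls

#' MA-style plot of a MAPS call
#'
#' log2 RPM ratio against mean log10 RPM, candidate regions highlighted,
#' threshold and floor drawn.
#'
#' @param x A `maps_call`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.maps_call <- function(x, ...) {
  calls <- x$calls
  a <- log10((calls$ms_rpm + calls$control_rpm) / 2 + 1)
  graphics::plot(a, calls$log2_ratio,
                 col = ifelse(calls$is_candidate_region, "firebrick", "grey50"),
                 pch = 20, xlab = "log10 mean RPM + 1",
                 ylab = "log2 (MS / control) RPM", ...)
  graphics::abline(h = x$config$log2_threshold, lty = 2)
  invisible(x)
}

#' Gene-level candidacy table of a MAPS call
#'
#' @param x A `maps_call`.
#' @return data.frame with `gene_id`, `n_candidate_regions`, `is_candidate`.
#' @export
gene_candidacy <- function(x) {
  stopifnot(inherits(x, "maps_call"))
  agg <- stats::aggregate(is_candidate_region ~ gene_id, data = x$calls, FUN = sum)
  data.frame(gene_id = agg$gene_id,
             n_candidate_regions = agg$is_candidate_region,
             is_candidate = agg$is_candidate_region > 0L,
             stringsAsFactors = FALSE)
}

#' Build stranded coverage from paired-end alignments (BAM)
#'
#' Optional ingestion path when per-base bedGraphs are not available:
#' alignments are split by [classify_pair_orientation()] on their SAM flags
#' and per-base read coverage is accumulated per class.  The library total
#' is the number of fragments (read pairs) retained.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM file.
#' @param genome A `genome_sequence`.
#' @return A [stranded_library()].
#' @export
read_bam_library <- function(bam_path, genome) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM ingestion requires the Rsamtools and GenomicAlignments packages")
  ga <- GenomicAlignments::readGAlignments(
    bam_path, param = Rsamtools::ScanBamParam(what = "flag"))
  cls <- classify_pair_orientation(S4Vectors::mcols(ga)$flag)
  vals <- function(keep) {
    v <- numeric(genome$length)
    if (any(keep)) {
      cov <- GenomicRanges::coverage(GenomicRanges::granges(ga[keep]))[[1]]
      dec <- as.numeric(cov)
      v[seq_along(dec)] <- dec
      length(v) <- genome$length
      v[is.na(v)] <- 0
    }
    v
  }
  total <- sum(cls != "EXCLUDED") / 2   # two reads per fragment
  if (total <= 0) stop("no properly oriented pairs in ", bam_path)
  stranded_library(
    coverage_track(genome$seq_id, vals(cls == "PLUS_SET"), "PLUS_SET", total),
    coverage_track(genome$seq_id, vals(cls == "MINUS_SET"), "MINUS_SET", total))
}
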