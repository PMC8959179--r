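# Motif presence and enrichment in 5' UTRs (the seed-pairing GGGG/Loop-A
# analysis) and PWM scanning for transcription-factor boxes with
# closest-gene assignment and regulon set enrichment.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA/RNA string
#' @param x Character scalar; `U` is accepted and pairs as `A`.
#' @return Character scalar over `{A,C,G,T,N}`.
#' @export
revcomp <- function(x) {
  x <- chartr("uU", "tT", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Does a UTR sequence contain a motif?
#'
#' Presence is boolean — overlapping occurrences count once.  The sequence
#' must already be in transcript orientation (the extraction helpers
#' reverse-complement minus-strand genes).
#'
#' @param utr_sequence Character scalar (transcript orientation).
#' @param motif Motif string over `{A,C,G,T}` (default `"GGGG"`).
#' @return Logical scalar.
#' @export
utr_has_motif <- function(utr_sequence, motif = "GGGG") {
  stopifnot(nchar(motif) > 0)
  grepl(motif, toupper(utr_sequence), fixed = TRUE)
}

#' Count motif occurrences in a sequence
#'
#' Overlapping occurrences are counted (a run of six G contains three
#' GGGG), matching a sliding-window count.
#'
#' @inheritParams utr_has_motif
#' @return Integer count.
#' @export
count_motif <- function(utr_sequence, motif = "GGGG") {
  Biostrings::countPattern(motif, Biostrings::DNAString(toupper(utr_sequence)))
}

#' Derive the target-side motif from an sRNA loop
#'
#' Base-pairing means the motif to search in target UTRs is the reverse
#' complement of the exposed loop subsequence of the small RNA (a CCCC
#' loop targets GGGG in the mRNA).
#'
#' @param ncrna_sequence The sRNA sequence (DNA or RNA alphabet).
#' @param loop_interval Integer pair `c(start, end)`, 0-based half-open,
#'   within the sRNA.
#' @return The motif string (DNA alphabet).
#' @export
loop_complement_motif <- function(ncrna_sequence, loop_interval) {
  s <- loop_interval[1L]; e <- loop_interval[2L]
  if (s >= e) stop("empty loop interval")
  if (s < 0L || e > nchar(ncrna_sequence)) stop("loop interval out of bounds")
  revcomp(substr(ncrna_sequence, s + 1L, e))
}

#' Extract 5' UTR sequences in transcript orientation
#'
#' @param regions Region data.frame from [build_region_set()].
#' @param genome A `genome_sequence`.
#' @param gene_ids Genes to extract (default: all with a UTR5 region).
#' @param kind Region kind to extract (default `"UTR5"`).
#' @return Named character vector of sequences.
#' @export
utr_sequences <- function(regions, genome, gene_ids = NULL, kind = "UTR5") {
  r <- regions[regions$kind == kind, , drop = FALSE]
  if (!is.null(gene_ids)) r <- r[r$gene_id %in% gene_ids, , drop = FALSE]
  out <- vapply(seq_len(nrow(r)), function(i)
    extract_sequence(genome, r$start[i], r$end[i], r$strand[i]), character(1))
  names(out) <- r$gene_id
  out
}

#' Randomly sample background 5' UTR sequences
#'
#' Draws `n` genes (without replacement unless `replace = TRUE`) and
#' returns their UTR5 sequences in transcript orientation — the background
#' set against which candidate UTRs are compared for motif enrichment.
#'
#' @param regions Region data.frame.
#' @param genome A `genome_sequence`.
#' @param n Sample size.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param replace Sample with replacement?
#' @return Named character vector of `n` sequences.
#' @export
sample_background_utrs <- function(regions, genome, n, seed, replace = FALSE) {
  if (n <= 0) stop("n must be positive")
  pool <- unique(regions$gene_id[regions$kind == "UTR5"])
  if (!replace && n > length(pool))
    stop("n exceeds the number of genes; set replace = TRUE")
  picked <- local_seed(seed, sample(pool, n, replace = replace))
  utr_sequences(regions, genome, gene_ids = NULL)[picked]
}

# Run expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' One-sided upper-tail exact binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, the p-value of the one-sided
#' exact binomial test.  Computed by direct summation of the tail terms in
#' log space (log-sum-exp), which is stable for small tail masses.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return The tail probability; 1 when `k = 0`.
#' @export
binomial_upper_tail <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (k < 0 || n < 0 || k > n || p0 < 0 || p0 > 1)
    stop("require 0 <= k <= n and 0 <= p0 <= 1")
  if (k == 0) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  i <- k:n
  lt <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' One-sided exact binomial enrichment result
#'
#' @param k Set members with the property.
#' @param n Set size.
#' @param p0 Background probability of the property.
#' @param what Short description of the tested property.
#' @return Object of class `enrichment_result` with fields `k`, `n`, `p0`,
#'   `fraction` (= k/n) and `p_value`.
#' @export
enrichment_result <- function(k, n, p0, what = "") {
  stopifnot(k >= 0, n >= 1, k <= n, p0 >= 0, p0 <= 1)
  structure(list(k = as.integer(k), n = as.integer(n), p0 = p0,
                 fraction = k / n,
                 p_value = binomial_upper_tail(k, n, p0),
                 what = what),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("One-sided exact binomial enrichment%s\n",
              if (nzchar(x$what)) paste0(" (", x$what, ")") else ""))
  cat(sprintf("  k/n = %d/%d (%.1f%%), background p0 = %.4g\n",
              x$k, x$n, 100 * x$fraction, x$p0))
  cat(sprintf("  P(X >= k) = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(k = x$k, n = x$n, p0 = x$p0, fraction = x$fraction,
             p_value = x$p_value, test = "one-sided exact binomial",
             what = x$what, stringsAsFactors = FALSE)
}

#' Motif enrichment of foreground UTRs against a background set
#'
#' `k` foreground UTRs contain the motif out of `n`; the background
#' fraction containing it defines `p0`; the p-value is the one-sided
#' upper-tail exact binomial probability.
#'
#' @param foreground_utrs,background_utrs Character vectors of UTR
#'   sequences in transcript orientation (both non-empty).
#' @param motif Motif string (default `"GGGG"`).
#' @return An [enrichment_result()].
#' @export
motif_enrichment <- function(foreground_utrs, background_utrs, motif = "GGGG") {
  if (length(foreground_utrs) == 0L || length(background_utrs) == 0L)
    stop("foreground and background must be non-empty")
  k <- sum(vapply(foreground_utrs, utr_has_motif, logical(1), motif = motif))
  p0 <- mean(vapply(background_utrs, utr_has_motif, logical(1), motif = motif))
  enrichment_result(k, length(foreground_utrs), p0,
                    what = paste0("motif ", motif, " in 5' UTRs"))
}

#' Build a position weight matrix object
#'
#' @param mat Numeric matrix, one row per position, columns `A,C,G,T`.
#'   With `type = "counts"` the rows are base counts and are converted to
#'   log-odds against a uniform background with a pseudocount of 1 per
#'   cell; with `type = "scores"` they are used as-is.
#' @param type `"scores"` or `"counts"`.
#' @param threshold_fraction Fraction of the maximum score a window must
#'   reach to be reported (default 0.70).
#' @param threshold_scale `"absolute"` uses
#'   `threshold = threshold_fraction * max_score` on the matrix's own score
#'   scale; `"minmax"` rescales so the threshold is
#'   `min + f * (max - min)`, for matrices with negative (log-odds) scores.
#' @return Object of class `pwm` with `scores` (width x 4), `width`,
#'   `max_score`, `min_score`, `threshold_fraction`, `threshold_scale`.
#' @export
pwm <- function(mat, type = c("scores", "counts"), threshold_fraction = 0.70,
                threshold_scale = c("absolute", "minmax")) {
  type <- match.arg(type)
  threshold_scale <- match.arg(threshold_scale)
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(mat) <- BASES
  if (nrow(mat) < 1L) stop("PWM must have width >= 1")
  if (type == "counts") {
    if (any(mat < 0)) stop("counts must be non-negative")
    f <- (mat + 1) / rowSums(mat + 1)
    mat <- log2(f / 0.25)
  }
  structure(list(scores = mat, width = nrow(mat),
                 max_score = sum(apply(mat, 1, max)),
                 min_score = sum(apply(mat, 1, min)),
                 threshold_fraction = threshold_fraction,
                 threshold_scale = threshold_scale),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, score range [%.3g, %.3g], threshold %s\n",
              x$width, x$min_score, x$max_score,
              format(pwm_threshold(x), digits = 4)))
  invisible(x)
}

#' Score threshold of a PWM under its configured convention
#' @param p A [pwm()].
#' @return Numeric threshold on the matrix's score scale.
#' @export
pwm_threshold <- function(p) {
  if (p$threshold_scale == "absolute")
    p$threshold_fraction * p$max_score
  else
    p$min_score + p$threshold_fraction * (p$max_score - p$min_score)
}

#' Read a PWM from TSV
#'
#' Four columns `A,C,G,T` with a header row, one row per motif position.
#'
#' @param path Path to the TSV.
#' @inheritParams pwm
#' @return A [pwm()].
#' @export
read_pwm <- function(path, type = c("scores", "counts"),
                     threshold_fraction = 0.70,
                     threshold_scale = c("absolute", "minmax")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(BASES %in% names(df)))
    stop("PWM file must have header columns A, C, G, T")
  pwm(as.matrix(df[, BASES]), type = type,
      threshold_fraction = threshold_fraction,
      threshold_scale = threshold_scale)
}

#' Write a PWM's score matrix to TSV
#' @param p A [pwm()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwm <- function(p, path) {
  utils::write.table(as.data.frame(p$scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Score every window of one strand; returns numeric vector of window
# scores at forward leftmost positions 0..L-w (NA where the window holds N).
score_windows <- function(code, scores) {
  w <- nrow(scores)
  L <- length(code)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) s <- s + scores[j, ][code[j:(j + n - 1L)]]
  s
}

#' Scan a genome with a PWM on both strands
#'
#' Every window is scored as the sum of per-position base scores; windows
#' scoring at least the configured threshold are reported.  Windows
#' containing `N` never match.  Minus-strand matches are reported at the
#' leftmost forward-strand base of the window.
#'
#' @param genome A `genome_sequence`.
#' @param p A [pwm()].
#' @return data.frame of sites: `seq_id`, `position` (0-based leftmost
#'   forward base), `strand`, `score`, sorted by position then strand.
#' @export
scan_pwm <- function(genome, p) {
  if (genome$length < p$width)
    return(data.frame(seq_id = character(), position = integer(),
                      strand = character(), score = numeric()))
  thr <- pwm_threshold(p)
  code_of <- function(s) {
    v <- match(strsplit(s, "", fixed = TRUE)[[1L]], BASES)
    v  # N -> NA, poisoning any window that includes it
  }
  fwd_code <- code_of(genome$residues)
  rev_code <- code_of(revcomp(genome$residues))
  fwd <- score_windows(fwd_code, p$scores)
  rev <- score_windows(rev_code, p$scores)
  L <- genome$length; w <- p$width
  hit_f <- which(!is.na(fwd) & fwd >= thr)
  hit_r <- which(!is.na(rev) & rev >= thr)
  out <- rbind(
    data.frame(seq_id = rep(genome$seq_id, length(hit_f)),
               position = as.integer(hit_f - 1L),
               strand = rep("+", length(hit_f)),
               score = fwd[hit_f], stringsAsFactors = FALSE),
    # window at p (0-based) on the reverse complement covers forward
    # bases [L - p - w, L - p)
    data.frame(seq_id = rep(genome$seq_id, length(hit_r)),
               position = as.integer(L - (hit_r - 1L) - w),
               strand = rep("-", length(hit_r)),
               score = rev[hit_r], stringsAsFactors = FALSE))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign PWM sites to the closest gene within its promoter window
#'
#' A gene's promoter window is the `upstream_window` nt immediately
#' upstream of its start codon (strand-aware, ATG excluded).  A site
#' belongs to a gene's window when its reported position falls inside it;
#' among genes whose windows contain the site it is assigned to the one
#' whose ATG is nearest (distance from the site base closest to the ATG),
#' ties broken by lexicographically smaller `gene_id`.
#'
#' @param sites Site data.frame from [scan_pwm()].
#' @param annotations Annotation data.frame.
#' @param site_width Width of each site in nt (the PWM width).
#' @param upstream_window Window size in nt (default 250).
#' @return List with `sites` (input plus `assigned_gene`) and `genes`
#'   (data.frame `gene_id`, `has_site`, `n_sites`).
#' @export
assign_sites_to_genes <- function(sites, annotations, site_width,
                                  upstream_window = 250L) {
  atg <- ifelse(annotations$strand == "+", annotations$start,
                annotations$end - 1L)   # genomic base of the A of ATG
  win_lo <- ifelse(annotations$strand == "+", annotations$start - upstream_window,
                   annotations$end)
  win_hi <- ifelse(annotations$strand == "+", annotations$start,
                   annotations$end + upstream_window)  # [win_lo, win_hi)
  assigned <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s0 <- sites$position[i]; s1 <- s0 + site_width  # site spans [s0, s1)
    inside <- win_lo <= s0 & s0 < win_hi &
      annotations$seq_id == sites$seq_id[i]
    if (!any(inside)) next
    cand <- which(inside)
    # distance from the site base nearest the ATG
    d <- pmax(0L, pmax(s0 - atg[cand], atg[cand] - (s1 - 1L)))
    best <- cand[order(d, annotations$gene_id[cand])][1L]
    assigned[i] <- annotations$gene_id[best]
  }
  sites$assigned_gene <- assigned
  tab <- table(assigned)
  genes <- data.frame(gene_id = annotations$gene_id,
                      n_sites = as.integer(tab[annotations$gene_id]),
                      stringsAsFactors = FALSE)
  genes$n_sites[is.na(genes$n_sites)] <- 0L
  genes$has_site <- genes$n_sites > 0L
  genes <- genes[order(genes$gene_id), c("gene_id", "has_site", "n_sites")]
  rownames(genes) <- NULL
  list(sites = sites, genes = genes)
}

#' Enrichment of PWM sites in a gene set
#'
#' Tests whether a gene set (e.g. the differentially expressed genes)
#' carries promoter sites more often than the genome-wide baseline:
#' `k` members with a site out of `n`, against `p0` = fraction of all
#' genes with a site, one-sided exact binomial.
#'
#' @param gene_set Character vector, a subset of `genes$gene_id`.
#' @param genes Per-gene site table from [assign_sites_to_genes()].
#' @param what Label for the result.
#' @return An [enrichment_result()].
#' @export
site_set_enrichment <- function(gene_set, genes, what = "TF sites in gene set") {
  if (length(gene_set) == 0L) stop("empty gene set")
  if (!all(gene_set %in% genes$gene_id))
    stop("gene_set contains unknown gene ids")
  has <- genes$has_site[match(gene_set, genes$gene_id)]
  enrichment_result(sum(has), length(gene_set), mean(genes$has_site), what)
}

#' Export PWM sites as BED6
#' @param sites Assigned or raw site data.frame.
#' @param site_width PWM width in nt.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
sites_to_bed <- function(sites, site_width, path) {
  nm <- if ("assigned_gene" %in% names(sites))
    ifelse(is.na(sites$assigned_gene), "unassigned", sites$assigned_gene)
  else "site"
  df <- data.frame(chrom = sites$seq_id, start = sites$position,
                   end = sites$position + site_width, name = nm,
                   score = sites$score, strand = sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
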