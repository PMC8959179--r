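# Independent reference implementations used as oracles.  They share no
# code with the package internals: plain loops and direct formulas.

# make a one-row annotation data.frame
gene_row <- function(gene_id, start, end, strand, seq_id = "chr",
                     feature_class = "CDS") {
  data.frame(gene_id = gene_id, seq_id = seq_id, start = start, end = end,
             strand = strand, feature_class = feature_class,
             product = NA_character_, stringsAsFactors = FALSE)
}

random_genome <- function(n, seed) {
  set.seed(seed)
  genome_sequence("chr", paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Exact binomial upper tail for small n and rational p0 = a/b: every term
# is an exact integer ratio (choose(n,i) * a^i * (b-a)^(n-i)) / b^n, all
# representable without rounding for the sizes used in tests.
exact_binom_tail_rational <- function(k, n, a, b) {
  if (k == 0) return(1)
  num <- 0
  for (i in k:n) num <- num + choose(n, i) * a^i * (b - a)^(n - i)
  num / b^n
}

# brute-force tail by direct summation of dbinom-style terms
direct_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# Brute-force PWM scan: enumerate every window on both strands with an
# explicit per-position loop.
brute_pwm_scan <- function(genome, p) {
  chars <- strsplit(genome$residues, "", fixed = TRUE)[[1L]]
  thr <- if (p$threshold_scale == "absolute")
    p$threshold_fraction * p$max_score
  else p$min_score + p$threshold_fraction * (p$max_score - p$min_score)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_at <- function(win) {
    s <- 0
    for (j in seq_along(win)) {
      if (win[j] == "N") return(NA_real_)
      s <- s + p$scores[j, win[j]]
    }
    s
  }
  out <- data.frame(position = integer(), strand = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  for (pos in seq_len(genome$length - p$width + 1L) - 1L) {
    win <- chars[(pos + 1L):(pos + p$width)]
    sf <- score_at(win)
    if (!is.na(sf) && sf >= thr)
      out <- rbind(out, data.frame(position = pos, strand = "+", score = sf))
    sr <- score_at(rev(unname(comp[win])))
    if (!is.na(sr) && sr >= thr)
      out <- rbind(out, data.frame(position = pos, strand = "-", score = sr))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent reference of the MAPS candidate rule: explicit loops, its
# own quantile and ratio arithmetic.
brute_maps_call <- function(ms, control, log2_threshold = 2,
                            coverage_quantile = 0.25, pseudocount = 1) {
  n <- nrow(ms)
  srt <- sort(ms$rpm)
  floor_val <- srt[max(1, ceiling(coverage_quantile * n))]
  res <- data.frame(gene_id = ms$gene_id, kind = ms$kind,
                    log2_ratio = NA_real_, is_candidate = NA)
  for (i in seq_len(n)) {
    lr <- log((ms$rpm[i] + pseudocount) / (control$rpm[i] + pseudocount), 2)
    res$log2_ratio[i] <- lr
    res$is_candidate[i] <- (lr >= log2_threshold) && (ms$rpm[i] > floor_val)
  }
  res
}

# small simulated dataset used by several pipeline-level tests
small_sim_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, genome_length = 80000L, n_genes = 40L,
                    ...)
}
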