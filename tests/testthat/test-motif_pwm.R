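# Motif presence/enrichment and PWM scanning with gene assignment.

test_that("motif presence is a substring test, overlapping hits count once", {
  expect_true(utr_has_motif("AAGGGGTT", "GGGG"))
  expect_false(utr_has_motif("AGGGT", "GGGG"))
  expect_true(utr_has_motif("GGGGGG", "GGGG"))
  expect_equal(count_motif("GGGGGG", "GGGG"), 3L)   # sliding-window count
  expect_equal(count_motif("AGGGT", "GGGG"), 0L)
})

test_that("the target-side motif is the reverse complement of the sRNA loop", {
  expect_equal(loop_complement_motif("AACCCCAA", c(2L, 6L)), "GGGG")
  expect_equal(loop_complement_motif("AUGC", c(0L, 4L)), "GCAT")  # RNA accepted
  expect_error(loop_complement_motif("ACGT", c(2L, 2L)), "empty")
  expect_error(loop_complement_motif("ACGT", c(1L, 9L)), "bounds")
})

test_that("background UTR sampling is seeded and bounded by the gene count", {
  sim <- simulate_genome(small_sim_config(seed = 31L))
  a <- sample_background_utrs(sim$regions, sim$genome, n = 10, seed = 99)
  b <- sample_background_utrs(sim$regions, sim$genome, n = 10, seed = 99)
  expect_identical(a, b)
  c <- sample_background_utrs(sim$regions, sim$genome, n = 10, seed = 100)
  expect_false(identical(names(a), names(c)))
  all_of_them <- sample_background_utrs(sim$regions, sim$genome,
                                        n = nrow(sim$annotations), seed = 1)
  expect_setequal(names(all_of_them), sim$annotations$gene_id)
  expect_error(sample_background_utrs(sim$regions, sim$genome,
                                      n = nrow(sim$annotations) + 1, seed = 1),
               "exceeds")
  expect_error(sample_background_utrs(sim$regions, sim$genome, n = 0, seed = 1))
})

test_that("binomial upper tail matches closed forms and independent oracles", {
  expect_equal(binomial_upper_tail(0, 17, 0.3), 1)
  expect_equal(binomial_upper_tail(3, 3, 0.5), 0.125)
  # exact rational enumeration at small n (p0 = 1/4)
  expect_equal(binomial_upper_tail(10, 20, 0.25),
               exact_binom_tail_rational(10, 20, 1, 4), tolerance = 1e-14)
  expect_equal(binomial_upper_tail(5, 12, 0.5),
               exact_binom_tail_rational(5, 12, 1, 2), tolerance = 1e-14)
  # the canonical test implementation, across a grid up to n = 200
  for (n in c(10, 50, 137, 200)) {
    for (p0 in c(0.05, 0.25, 0.5, 0.9)) {
      for (k in unique(c(1, floor(n / 3), n - 1, n))) {
        expect_equal(binomial_upper_tail(k, n, p0),
                     stats::binom.test(k, n, p0, alternative = "greater")$p.value,
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(binomial_upper_tail(5, 3, 0.5))
  expect_error(binomial_upper_tail(1, 3, 1.5))
})

test_that("motif enrichment wires k, n, p0 and the exact tail together", {
  fg <- c("AAGGGGTT", "GGGGAAAA", "CCCCAAAA")
  bg <- c(rep("GGGGAA", 2), rep("ACACAC", 18))
  enr <- motif_enrichment(fg, bg, "GGGG")
  expect_equal(enr$k, 2L)
  expect_equal(enr$n, 3L)
  expect_equal(enr$p0, 0.1)
  expect_equal(enr$p_value, binomial_upper_tail(2, 3, 0.1))
  # all-foreground, p0 = 0.1, n = 10 -> 0.1^10
  enr2 <- motif_enrichment(rep("GGGG", 10), bg, "GGGG")
  expect_equal(enr2$p_value, 0.1^10, tolerance = 1e-12)
  # k = 0 -> p = 1
  enr3 <- motif_enrichment(rep("ACAC", 4), bg, "GGGG")
  expect_equal(enr3$p_value, 1)
  expect_equal(enr3$fraction, 0)
  expect_error(motif_enrichment(character(0), bg), "non-empty")
})

hand_pwm <- function() {
  pwm(matrix(c(2, 0, 0, 0,
               0, 2, 0, 0), nrow = 2, byrow = TRUE), type = "scores",
      threshold_fraction = 0.70)
}

test_that("scan_pwm reproduces the hand-worked two-position example", {
  p <- hand_pwm()                    # consensus AC, max_score 4, threshold 2.8
  expect_equal(p$max_score, 4)
  fwd <- scan_pwm(genome_sequence("chr", "AACT"), p)
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$position, 1L)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$score, 4)
  rev <- scan_pwm(genome_sequence("chr", "AGTT"), p)  # revcomp holds AC
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$strand, "-")
  expect_equal(rev$position, 1L)
  none <- scan_pwm(genome_sequence("chr", "NNNNNN"), p)
  expect_equal(nrow(none), 0L)
})

test_that("scan_pwm equals the brute-force window oracle on random genomes and PWMs", {
  for (seed in 1:4) {
    set.seed(seed)
    g <- random_genome(sample(200:1500, 1), seed + 40)
    w <- sample(4:12, 1)
    mat <- matrix(round(runif(w * 4, -2, 3), 2), nrow = w)
    p <- pwm(mat, type = "scores", threshold_fraction = runif(1, 0.6, 0.9))
    got <- scan_pwm(g, p)
    ref <- brute_pwm_scan(g, p)
    expect_equal(got$position, ref$position)
    expect_equal(got$strand, ref$strand)
    expect_equal(got$score, ref$score, tolerance = 1e-12)
  }
})

test_that("scanning the reverse-complemented genome mirrors the site list", {
  g <- random_genome(4000, 51)
  p <- ctra_box_pwm(threshold_fraction = 0.45)
  fwd <- scan_pwm(g, p)
  expect_gt(nrow(fwd), 0)
  gm <- genome_sequence("chr", revcomp(g$residues))
  mir <- scan_pwm(gm, p)
  L <- g$length; w <- p$width
  flip <- data.frame(position = L - fwd$position - w,
                     strand = ifelse(fwd$strand == "+", "-", "+"),
                     score = fwd$score)
  flip <- flip[order(flip$position, flip$strand), ]
  expect_equal(mir$position, flip$position)
  expect_equal(mir$strand, flip$strand)
  expect_equal(mir$score, flip$score, tolerance = 1e-12)
})

test_that("raising the threshold fraction never adds sites", {
  g <- random_genome(2000, 52)
  base <- ctra_box_pwm(threshold_fraction = 0.5)
  n_prev <- Inf
  for (f in c(0.5, 0.6, 0.7, 0.8, 0.95)) {
    p <- ctra_box_pwm(threshold_fraction = f)
    n <- nrow(scan_pwm(g, p))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("count matrices become log-odds scores with a pseudocount", {
  counts <- matrix(c(10, 0, 0, 0), nrow = 1)
  p <- pwm(counts, type = "counts")
  expect_equal(unname(p$scores[1, "A"]), log2((11 / 14) / 0.25),
               tolerance = 1e-12)
  expect_error(pwm(matrix(-1, 1, 4), type = "counts"), "non-negative")
  expect_error(pwm(matrix(1, 2, 3)), "4 columns")
})

test_that("PWM TSV round-trips and the minmax threshold convention rescales", {
  p <- ctra_box_pwm()
  path <- tempfile(fileext = ".tsv")
  write_pwm(p, path)
  back <- read_pwm(path, type = "scores")
  expect_equal(unname(back$scores), unname(p$scores))
  mm <- read_pwm(path, type = "scores", threshold_scale = "minmax")
  expect_equal(pwm_threshold(mm),
               p$min_score + 0.7 * (p$max_score - p$min_score))
})

test_that("sites are assigned to the closest gene within the 250-nt upstream window", {
  ann <- rbind(gene_row("geneA", 1000, 2000, "+"),
               gene_row("geneZ", 5000, 6000, "+"))
  sites <- data.frame(seq_id = "chr", position = c(980L, 700L, 5100L),
                      strand = "+", score = 5, stringsAsFactors = FALSE)
  asg <- assign_sites_to_genes(sites, ann, site_width = 4L)
  expect_equal(asg$sites$assigned_gene[1], "geneA")   # 20 nt upstream
  expect_true(is.na(asg$sites$assigned_gene[2]))      # 300 nt: outside window
  expect_true(is.na(asg$sites$assigned_gene[3]))      # inside the gene body
  expect_equal(asg$genes$has_site, c(TRUE, FALSE))
  expect_equal(asg$genes$n_sites, c(1L, 0L))
})

test_that("equidistant sites break ties toward the lexicographically smaller gene id", {
  ann <- rbind(gene_row("geneB", 1000, 2000, "+"),
               gene_row("geneA", 440, 940, "-"))
  # width-2 site at 969: 30 nt from geneB's ATG (1000) and geneA's (939)
  sites <- data.frame(seq_id = "chr", position = 969L, strand = "+",
                      score = 5, stringsAsFactors = FALSE)
  asg <- assign_sites_to_genes(sites, ann, site_width = 2L)
  expect_equal(asg$sites$assigned_gene, "geneA")
})

test_that("site-set enrichment uses the genome-wide site fraction as p0", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50),
                      has_site = c(rep(TRUE, 10), rep(FALSE, 40)),
                      n_sites = c(rep(1L, 10), rep(0L, 40)),
                      stringsAsFactors = FALSE)
  enr <- site_set_enrichment(sprintf("g%02d", 1:10), genes)
  expect_equal(enr$p0, 0.2)
  expect_equal(enr$k, 10L)
  expect_equal(enr$p_value, 0.2^10, tolerance = 1e-12)
  # the full gene set is never significantly enriched against itself
  null <- site_set_enrichment(genes$gene_id, genes)
  expect_equal(null$fraction, null$p0)
  expect_gt(null$p_value, 0.05)
  expect_error(site_set_enrichment(character(0), genes), "empty")
  expect_error(site_set_enrichment("nope", genes), "unknown")
})
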