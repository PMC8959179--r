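# Strand-aware region coverage, RPM arithmetic and the candidate caller.

test_that("SAM flags split into the two orientation classes", {
  expect_equal(classify_pair_orientation(c(99, 147)), rep("PLUS_SET", 2))
  expect_equal(classify_pair_orientation(c(83, 163)), rep("MINUS_SET", 2))
  others <- c(0, 4, 16, 77, 141, 97, 145, 81, 161, 355, 1123)
  expect_equal(classify_pair_orientation(others),
               rep("EXCLUDED", length(others)))
  expect_error(classify_pair_orientation(-1), "non-negative")
})

make_library <- function(plus_vals, minus_vals, total) {
  stranded_library(coverage_track("chr", plus_vals, "PLUS_SET", total),
                   coverage_track("chr", minus_vals, "MINUS_SET", total))
}

test_that("region coverage sums 1-nt values in the expected orientation and scales to RPM", {
  vals <- numeric(20); vals[11:13] <- 5   # bases 10,11,12
  lib <- make_library(vals, numeric(20) + 7, 2e6)
  reg <- data.frame(gene_id = "g", kind = "BODY", seq_id = "chr",
                    start = 10L, end = 13L, strand = "+",
                    stringsAsFactors = FALSE)
  rc <- region_coverage(reg, lib)
  expect_equal(rc$raw_sum, 15)
  expect_equal(rc$rpm, 7.5)               # 15 * 1e6 / 2e6
  # minus-strand region reads only the MINUS-mapped track
  reg$strand <- "-"
  rc2 <- region_coverage(reg, lib)
  expect_equal(rc2$raw_sum, 21)           # 3 bases * 7
  # all-zero track
  lib0 <- make_library(numeric(20), numeric(20), 1e6)
  expect_equal(region_coverage(reg, lib0)$rpm, 0)
  # region beyond the track errors
  reg$end <- 50L
  expect_error(region_coverage(reg, lib), "outside")
})

test_that("a flipped orientation protocol swaps which track a strand reads", {
  lib <- make_library(rep(2, 10), rep(9, 10), 1e6)
  reg <- data.frame(gene_id = "g", kind = "BODY", seq_id = "chr",
                    start = 0L, end = 10L, strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(region_coverage(reg, lib)$raw_sum, 20)
  flipped <- orientation_protocol("MINUS_SET")
  expect_equal(region_coverage(reg, lib, flipped)$raw_sum, 90)
})

cov_frame <- function(ms_rpm, control_rpm = NULL) {
  n <- length(ms_rpm)
  base <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                     kind = "BODY", raw_sum = ms_rpm, rpm = ms_rpm,
                     stringsAsFactors = FALSE)
  if (is.null(control_rpm)) return(base)
  ctl <- base; ctl$rpm <- control_rpm; ctl$raw_sum <- control_rpm
  list(ms = base, control = ctl)
}

test_that("the ratio threshold is inclusive at log2 = 2 (a 4-fold RPM increase)", {
  p <- cov_frame(c(400, 390, 1000), c(100, 100, 100))
  mc <- maps_call(p$ms, p$control,
                  maps_caller_config(pseudocount_rpm = 0,
                                     coverage_quantile = 0.25))
  expect_equal(mc$calls$log2_ratio[1], 2)
  expect_true(mc$calls$passed_ratio[1])        # exactly 4-fold passes
  expect_false(mc$calls$passed_ratio[2])       # 3.9-fold does not
  expect_equal(mc$calls$log2_ratio[2], log2(3.9), tolerance = 1e-12)
})

test_that("the floor is the nearest-rank quantile and the comparison is strict", {
  p <- cov_frame(c(10, 20, 30, 40), c(1, 1, 1, 1))
  mc <- maps_call(p$ms, p$control, maps_caller_config(pseudocount_rpm = 0))
  expect_equal(mc$floor, 10)                   # nearest-rank 25th percentile
  calls <- mc$calls[order(mc$calls$ms_rpm), ]
  expect_false(calls$passed_floor[1])          # 10 is not > 10
  expect_true(all(calls$passed_floor[-1]))
})

test_that("the pseudocount keeps zero-control regions finite", {
  p <- cov_frame(c(30, 5, 8, 9), c(0, 5, 8, 9))
  mc <- maps_call(p$ms, p$control, maps_caller_config(pseudocount_rpm = 1))
  expect_equal(mc$calls$log2_ratio[mc$calls$gene_id == "g01"], log2(31),
               tolerance = 1e-12)
  expect_true(all(is.finite(mc$calls$log2_ratio)))
})

test_that("caller matches an independent reference on random small region sets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:20, 1)
    ms_rpm <- round(runif(n, 0, 500), 3)
    ctl_rpm <- round(runif(n, 0, 500), 3)
    p <- cov_frame(ms_rpm, ctl_rpm)
    mc <- maps_call(p$ms, p$control, maps_caller_config(pseudocount_rpm = 1))
    ref <- brute_maps_call(p$ms, p$control, pseudocount = 1)
    ref <- ref[order(ref$gene_id, ref$kind), ]
    expect_equal(mc$calls$log2_ratio, ref$log2_ratio, tolerance = 1e-14)
    expect_equal(mc$calls$is_candidate_region, ref$is_candidate)
  }
})

test_that("with pseudocount 0 the calls are invariant to library depth rescaling", {
  set.seed(7)
  vals_p <- rpois(300, 5); vals_m <- rpois(300, 5)
  reg <- data.frame(gene_id = sprintf("g%02d", 1:10), kind = "BODY",
                    seq_id = "chr", start = seq(0L, 270L, by = 30L),
                    end = seq(30L, 300L, by = 30L),
                    strand = rep(c("+", "-"), 5), stringsAsFactors = FALSE)
  ms1 <- region_coverage(reg, make_library(vals_p * 10, vals_m * 10, 1e5))
  ms2 <- region_coverage(reg, make_library(vals_p, vals_m, 1e4))
  ctl <- region_coverage(reg, make_library(rev(vals_p), rev(vals_m), 5e4))
  cfg <- maps_caller_config(pseudocount_rpm = 0)
  expect_equal(maps_call(ms1, ctl, cfg)$calls$is_candidate_region,
               maps_call(ms2, ctl, cfg)$calls$is_candidate_region)
  expect_equal(ms1$rpm, ms2$rpm)
})

test_that("raising a region's MS coverage never demotes it (floor frozen)", {
  p <- cov_frame(c(50, 80, 120, 200, 350), c(40, 40, 40, 40, 40))
  cfg <- maps_caller_config(pseudocount_rpm = 1)
  mc0 <- maps_call(p$ms, p$control, cfg)
  for (i in seq_len(5)) {
    ms2 <- p$ms
    ms2$rpm[i] <- ms2$rpm[i] * 2; ms2$raw_sum[i] <- ms2$rpm[i]
    mc1 <- maps_call(ms2, p$control, cfg)
    # frozen-floor comparison: the bumped region's flags against the old floor
    lr1 <- mc1$calls$log2_ratio[i]
    expect_gte(lr1, mc0$calls$log2_ratio[i])
    if (mc0$calls$is_candidate_region[i])
      expect_true(lr1 >= cfg$log2_threshold && ms2$rpm[i] > mc0$floor)
  }
})

test_that("gene candidacy is the OR of its region decisions", {
  ms <- data.frame(gene_id = rep(c("a", "b"), each = 3),
                   kind = rep(c("UTR5", "BODY", "UTR3"), 2),
                   raw_sum = c(500, 30, 30, 30, 30, 30),
                   rpm = c(500, 30, 30, 30, 30, 30), stringsAsFactors = FALSE)
  ctl <- ms; ctl$rpm <- rep(30, 6); ctl$raw_sum <- ctl$rpm
  mc <- maps_call(ms, ctl, maps_caller_config(pseudocount_rpm = 0))
  expect_equal(mc$candidate_genes, "a")
  agg <- gene_candidacy(mc)
  expect_equal(agg$is_candidate, c(TRUE, FALSE))
  expect_equal(agg$n_candidate_regions, c(1L, 0L))
})

test_that("mismatched region sets are rejected", {
  p <- cov_frame(c(1, 2), c(1, 2))
  bad <- p$control[2:1, ]
  expect_error(maps_call(p$ms, bad), "do not match")
})

test_that("summary and print report candidate counts", {
  p <- cov_frame(c(400, 10, 20, 30), c(50, 10, 20, 30))
  mc <- maps_call(p$ms, p$control, maps_caller_config(pseudocount_rpm = 0))
  s <- summary(mc)
  expect_equal(s$n_regions, 4L)
  expect_equal(s$n_candidate_genes, length(mc$candidate_genes))
  expect_output(print(mc), "candidate genes")
})

test_that("BAM ingestion splits fragments by flag class into stranded tracks", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr\tLN:100",
    "r1\t99\tchr\t11\t60\t10M\t=\t31\t30\tACGTACGTAC\t*",
    "r1\t147\tchr\t31\t60\t10M\t=\t11\t-30\tACGTACGTAC\t*",
    "r2\t163\tchr\t41\t60\t10M\t=\t51\t20\tACGTACGTAC\t*",
    "r2\t83\tchr\t51\t60\t10M\t=\t41\t-20\tACGTACGTAC\t*"),
    sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  genome <- random_genome(100, 21)
  lib <- read_bam_library(bam, genome)
  expect_equal(lib$library_total, 2)          # two proper pairs
  # flag-99/147 pair covers bases 10..19 and 30..39 (0-based)
  expect_equal(sum(lib$PLUS_SET$values), 20)
  expect_equal(lib$PLUS_SET$values[11:20], rep(1, 10))
  expect_equal(lib$PLUS_SET$values[21:30], rep(0, 10))
  # flag-83/163 pair covers bases 40..59
  expect_equal(sum(lib$MINUS_SET$values), 20)
  expect_equal(lib$MINUS_SET$values[41:60], rep(1, 20))
})
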