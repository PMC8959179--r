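# Seeded synthetic-data generator: genome + annotation + TSS table,
# stranded coverage libraries with planted pull-down enrichment, DE tables
# and side tables with known ground truth.  Every generator derives its
# own sub-stream from the master seed, so regenerating one artifact never
# perturbs another.

# deterministic sub-stream seeds, kept inside 32-bit integer range
sub_seed <- function(seed, k) as.integer((as.numeric(seed) + 104729 * k) %% 2147483647L)

#' A demonstration transcription-factor box PWM
#'
#' A palindromic TTAA-N7-TTAA box (the dyad layout of the CtrA full
#' binding site): +2 for the consensus base and -2 otherwise at the eight
#' informative positions, 0 everywhere in the 7-nt spacer.
#'
#' @param threshold_fraction Passed to [pwm()] (default 0.70).
#' @return A [pwm()] of width 15 with `max_score` 16.
#' @export
ctra_box_pwm <- function(threshold_fraction = 0.70) {
  cons <- strsplit("TTAANNNNNNNTTAA", "")[[1]]
  m <- matrix(0, nrow = 15, ncol = 4, dimnames = list(NULL, BASES))
  for (i in seq_along(cons)) {
    if (cons[i] != "N") {
      m[i, ] <- -2
      m[i, cons[i]] <- 2
    }
  }
  pwm(m, type = "scores", threshold_fraction = threshold_fraction)
}

#' Consensus sequence of a PWM
#' @param p A [pwm()].
#' @return Character scalar (ties resolved to the first of A,C,G,T).
#' @export
pwm_consensus <- function(p) {
  paste(BASES[apply(p$scores, 1, which.max)], collapse = "")
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: a small bacterial genome of
#' non-overlapping stranded genes, per-base Poisson fragment counts around
#' a baseline mean with stranded bleed-through, pull-down enrichment
#' planted in chosen regions of the MS library only, a controlled fraction
#' of motif-bearing 5' UTRs, PWM consensus sites planted upstream of
#' chosen genes, and a DE table with known true positives.
#'
#' @param seed Master seed; all artifacts derive deterministic sub-streams
#'   from it.
#' @param genome_length Genome size in nt (default 200000).
#' @param n_genes Number of genes (default 150).
#' @param gene_length_range Uniform sampling range for gene lengths, nt
#'   (default `c(300, 1500)`).
#' @param min_intergenic_gap Minimum gap between genes, nt (default 300;
#'   must exceed the 3' UTR downstream span so planted regions of adjacent
#'   genes cannot collide).
#' @param tss_fraction Fraction of genes given an experimental TSS
#'   (default 0.6).
#' @param tss_distance_range Uniform range of TSS-to-start distances, nt
#'   (default `c(20, 250)`, so both the TSS rule and the short-UTR
#'   fallback are exercised).
#' @param baseline_mean Expected per-base fragment count on the sense
#'   strand of gene regions (default 20).
#' @param antisense_fraction Antisense/intergenic background as a fraction
#'   of `baseline_mean` (default 0.05, mimicking stranded-library
#'   bleed-through).
#' @param planted_targets Either a data.frame with columns `gene_id`,
#'   `kind`, `fold`, or a list `list(n =, kind =, fold =)` asking for `n`
#'   random genes; `NULL` plants nothing.
#' @param planted_motif `NULL`, or a list
#'   `list(motif =, foreground_n =, fg_fraction =, bg_fraction =)`:
#'   `foreground_n` genes form the foreground set; motif presence in each
#'   gene's 5' UTR is then *controlled* — planted into exactly
#'   `round(fraction * n)` UTRs of each group and scrubbed from the rest.
#' @param planted_pwm_sites `NULL`, or a data.frame with columns `gene_id`
#'   and `offset` (nt between the site's gene-proximal edge and the ATG);
#'   the PWM consensus is written into the genome there.  Offsets beyond
#'   `(min_intergenic_gap - pwm width) / 2` can put the site closer to a
#'   neighbouring gene's ATG, in which case closest-gene assignment will
#'   (correctly) pick the neighbour.
#' @param pwm The [pwm()] used for planting and scanning (default
#'   [ctra_box_pwm()]).
#' @param de_truth List `n_up`, `n_down`, `lfc_range`, `fdr` describing
#'   the DE ground truth (defaults 10 up, 5 down, |lfc| in 0.48..2.9,
#'   selection threshold 0.01).
#' @param side_prevalence Named list of prevalences for the binary side
#'   tables (defaults: essential 0.15, cell_cycle 0.2, methylation 0.1).
#' @param rules [region_rules()] used when regions are needed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 200000L,
                              n_genes = 150L,
                              gene_length_range = c(300L, 1500L),
                              min_intergenic_gap = 300L,
                              tss_fraction = 0.6,
                              tss_distance_range = c(20L, 250L),
                              baseline_mean = 20,
                              antisense_fraction = 0.05,
                              planted_targets = NULL,
                              planted_motif = NULL,
                              planted_pwm_sites = NULL,
                              pwm = ctra_box_pwm(),
                              de_truth = list(n_up = 10L, n_down = 5L,
                                              lfc_range = c(0.48, 2.9),
                                              fdr = 0.01),
                              side_prevalence = list(essential = 0.15,
                                                     cell_cycle = 0.2,
                                                     methylation = 0.1),
                              rules = region_rules()) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              min_intergenic_gap = as.integer(min_intergenic_gap),
              tss_fraction = tss_fraction,
              tss_distance_range = as.integer(tss_distance_range),
              baseline_mean = baseline_mean,
              antisense_fraction = antisense_fraction,
              planted_targets = planted_targets,
              planted_motif = planted_motif,
              planted_pwm_sites = planted_pwm_sites,
              pwm = pwm, de_truth = de_truth,
              side_prevalence = side_prevalence, rules = rules)
  if (cfg$min_intergenic_gap <= rules$utr3_downstream)
    stop("min_intergenic_gap must exceed the 3' UTR downstream span")
  if (cfg$tss_fraction < 0 || cfg$tss_fraction > 1)
    stop("tss_fraction must be in [0, 1]")
  structure(cfg, class = "simulation_config")
}

#' Simulate a genome, annotation, TSS table and ground-truth skeleton
#'
#' Genes are packed left to right with random gaps of at least
#' `min_intergenic_gap`, strands drawn by fair coin, residues i.i.d.
#' uniform over A,C,G,T except where motif and PWM plantings overwrite
#' them.  Byte-identical output for a given configuration.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genome` (a `genome_sequence`), `annotations`,
#'   `tss_table`, `regions` (the [build_region_set()] of the annotation)
#'   and `truth` (list: `target_regions`, `motif_genes`,
#'   `motif_foreground`, `pwm_sites`, `true_up`, `true_down`).
#' @export
simulate_genome <- function(cfg) {
  local_seed(sub_seed(cfg$seed, 1L), {
    n <- cfg$n_genes
    lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                   n, replace = TRUE)
    slack <- cfg$genome_length - sum(lens) - (n + 1L) * cfg$min_intergenic_gap
    if (slack < 0)
      stop("infeasible packing: n_genes * (gene length + gap) exceeds genome_length")
    extra <- as.vector(stats::rmultinom(1, slack, rep(1, n + 1L)))
    gaps <- cfg$min_intergenic_gap + extra
    starts <- cumsum(gaps)[1:n] + c(0L, cumsum(lens))[1:n]
    ends <- starts + lens
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("gene%04d", seq_len(n))
    feature <- ifelse(stats::runif(n) < 0.1, "ncRNA", "CDS")
    ann <- data.frame(gene_id = ids, seq_id = "synthchr",
                      start = as.integer(starts), end = as.integer(ends),
                      strand = strands, feature_class = feature,
                      product = NA_character_, stringsAsFactors = FALSE)

    residues <- paste(sample(BASES, cfg$genome_length, replace = TRUE),
                      collapse = "")

    # TSS for a random subset of genes
    n_tss <- round(cfg$tss_fraction * n)
    tss_genes <- sort(sample(ids, n_tss))
    ti <- match(tss_genes, ann$gene_id)
    d <- sample(seq(cfg$tss_distance_range[1], cfg$tss_distance_range[2]),
                n_tss, replace = TRUE)
    tss_pos <- ifelse(ann$strand[ti] == "+", ann$start[ti] - d,
                      ann$end[ti] - 1L + d)
    tss <- data.frame(gene_id = tss_genes, tss_position = as.integer(tss_pos),
                      strand = ann$strand[ti], stringsAsFactors = FALSE)

    # resolve planted targets
    targets <- cfg$planted_targets
    if (is.list(targets) && !is.data.frame(targets) && !is.null(targets$n)) {
      targets <- data.frame(gene_id = sort(sample(ids, targets$n)),
                            kind = targets$kind, fold = targets$fold,
                            stringsAsFactors = FALSE)
    }
    if (!is.null(targets) && nrow(targets) > 0 &&
        !all(targets$gene_id %in% ids))
      stop("planted target gene_id not in the annotation")

    # DE truth
    de_pool <- sample(ids)
    true_up <- sort(de_pool[seq_len(cfg$de_truth$n_up)])
    true_down <- sort(de_pool[cfg$de_truth$n_up + seq_len(cfg$de_truth$n_down)])

    genome <- genome_sequence("synthchr", residues)
    regions <- build_region_set(ann, tss, cfg$rules, genome)

    # controlled motif presence in 5' UTRs
    motif_fg <- character(0); motif_genes <- character(0)
    if (!is.null(cfg$planted_motif)) {
      pm <- cfg$planted_motif
      motif_fg <- sort(sample(ids, pm$foreground_n))
      bg_pool <- setdiff(ids, motif_fg)
      pos_fg <- sample(motif_fg, round(pm$fg_fraction * length(motif_fg)))
      pos_bg <- sample(bg_pool, round(pm$bg_fraction * length(bg_pool)))
      motif_genes <- sort(c(pos_fg, pos_bg))
      genome <- control_motif_presence(genome, regions, pm$motif,
                                       present = ids %in% motif_genes,
                                       ids = ids)
    }

    # planted PWM consensus sites upstream of chosen genes
    pwm_sites <- NULL
    if (!is.null(cfg$planted_pwm_sites) && nrow(cfg$planted_pwm_sites) > 0) {
      pwm_sites <- plant_pwm_sites(genome, ann, cfg$planted_pwm_sites, cfg$pwm)
      genome <- pwm_sites$genome
      pwm_sites <- pwm_sites$sites
    }

    list(genome = genome, annotations = ann, tss_table = tss,
         regions = regions,
         truth = list(target_regions = targets, motif_genes = motif_genes,
                      motif_foreground = motif_fg, pwm_sites = pwm_sites,
                      true_up = true_up, true_down = true_down))
  })
}

# overwrite the genome substring of a region with `seq` given in
# transcript orientation
write_region_seq <- function(genome, start, end, strand, seq) {
  if (strand == "-") seq <- revcomp(seq)
  res <- genome$residues
  substr(res, start + 1L, end) <- seq
  genome$residues <- res
  genome
}

# enforce motif presence/absence in each gene's 5' UTR (transcript
# orientation); presence by insertion at a random offset, absence by
# mutating occurrences until none remain
control_motif_presence <- function(genome, regions, motif, present, ids) {
  ml <- nchar(motif)
  u <- regions[regions$kind == "UTR5", , drop = FALSE]
  u <- u[match(ids, u$gene_id), , drop = FALSE]
  # UTR5 windows of adjacent genes can overlap on opposite strands, so
  # fixing one UTR may (rarely) disturb another: iterate to a fixed point.
  for (pass in 1:8) {
    changed <- FALSE
    for (i in seq_along(ids)) {
      s <- extract_sequence(genome, u$start[i], u$end[i], u$strand[i])
      if (present[i]) {
        if (!grepl(motif, s, fixed = TRUE)) {
          off <- sample.int(nchar(s) - ml + 1L, 1L) - 1L
          substr(s, off + 1L, off + ml) <- motif
          changed <- TRUE
        } else next
      } else {
        if (!grepl(motif, s, fixed = TRUE)) next
        guard <- 0L
        while (grepl(motif, s, fixed = TRUE)) {
          occ <- gregexpr(motif, s, fixed = TRUE)[[1L]]
          for (o in occ)
            substr(s, o, o + ml - 1L) <-
              paste(sample(BASES, ml, replace = TRUE), collapse = "")
          guard <- guard + 1L
          if (guard > 100L) stop("failed to scrub motif from a UTR")
        }
        changed <- TRUE
      }
      genome <- write_region_seq(genome, u$start[i], u$end[i], u$strand[i], s)
    }
    if (!changed) return(genome)
  }
  stop("motif presence control did not converge")
}

# write the PWM consensus `offset` nt upstream of each listed gene's ATG
# (strand-aware); returns the modified genome and the site table
plant_pwm_sites <- function(genome, ann, plan, p) {
  cons <- pwm_consensus(p)
  w <- p$width
  out <- data.frame(gene_id = character(), position = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(plan))) {
    g <- ann[ann$gene_id == plan$gene_id[i], ]
    if (nrow(g) != 1L) stop("planted PWM site gene not found: ", plan$gene_id[i])
    off <- plan$offset[i]
    if (g$strand == "+") {
      s0 <- g$start - off - w
      genome <- write_region_seq(genome, s0, s0 + w, "+", cons)
    } else {
      s0 <- g$end + off
      genome <- write_region_seq(genome, s0, s0 + w, "-", cons)
    }
    out <- rbind(out, data.frame(gene_id = g$gene_id, position = as.integer(s0),
                                 strand = g$strand, stringsAsFactors = FALSE))
  }
  list(genome = genome, sites = out)
}

#' Simulate one stranded sequencing library
#'
#' Per-base counts are independent Poisson draws: mean `baseline_mean` on
#' the sense track of every gene region, `baseline_mean *
#' antisense_fraction` on antisense and intergenic bases, and (for the MS
#' role only) `baseline_mean * fold` inside planted target regions.  The
#' library total is the sum of all counts on both tracks.
#'
#' @param cfg A [simulation_config()].
#' @param sim Output of [simulate_genome()].
#' @param role `"MS"` (pull-down, receives the planted enrichment) or
#'   `"control"`.
#' @param seed Optional override of the role-specific sub-stream seed
#'   (used to draw replicate libraries).
#' @return A [stranded_library()].
#' @export
simulate_library <- function(cfg, sim, role = c("MS", "control"), seed = NULL) {
  role <- match.arg(role)
  if (is.null(seed))
    seed <- sub_seed(cfg$seed, if (role == "MS") 11L else 12L)
  L <- sim$genome$length
  bg <- cfg$baseline_mean * cfg$antisense_fraction
  mean_plus <- rep(bg, L)
  mean_minus <- rep(bg, L)
  r <- sim$regions
  for (i in seq_len(nrow(r))) {
    idx <- (r$start[i] + 1L):r$end[i]
    if (r$strand[i] == "+") mean_plus[idx] <- cfg$baseline_mean
    else mean_minus[idx] <- cfg$baseline_mean
  }
  if (role == "MS" && !is.null(sim$truth$target_regions)) {
    tg <- sim$truth$target_regions
    for (i in seq_len(nrow(tg))) {
      rr <- r[r$gene_id == tg$gene_id[i] & r$kind == tg$kind[i], ]
      idx <- (rr$start + 1L):rr$end
      if (rr$strand == "+") mean_plus[idx] <- cfg$baseline_mean * tg$fold[i]
      else mean_minus[idx] <- cfg$baseline_mean * tg$fold[i]
    }
  }
  local_seed(seed, {
    vp <- stats::rpois(L, mean_plus)
    vm <- stats::rpois(L, mean_minus)
    total <- sum(vp) + sum(vm)
    stranded_library(
      coverage_track(sim$genome$seq_id, vp, "PLUS_SET", total),
      coverage_track(sim$genome$seq_id, vm, "MINUS_SET", total))
  })
}

#' Simulate a differential-expression results table
#'
#' True up-regulated genes draw `log2fc` uniformly in the configured
#' positive range and `p_adj` below the selection threshold; true
#' down-regulated genes are symmetric; null genes get `log2fc` near zero
#' and `p_adj` uniform on (0.05, 1].
#'
#' @param cfg A [simulation_config()].
#' @param sim Output of [simulate_genome()].
#' @return data.frame with columns `gene_id`, `log2fc`, `p_adj`.
#' @export
simulate_de_table <- function(cfg, sim) {
  local_seed(sub_seed(cfg$seed, 21L), {
    ids <- sim$annotations$gene_id
    lfc <- stats::rnorm(length(ids), 0, 0.1)
    p <- stats::runif(length(ids), 0.05, 1)
    lr <- cfg$de_truth$lfc_range
    up <- ids %in% sim$truth$true_up
    dn <- ids %in% sim$truth$true_down
    lfc[up] <- stats::runif(sum(up), lr[1], lr[2])
    lfc[dn] <- -stats::runif(sum(dn), lr[1], lr[2])
    p[up | dn] <- stats::runif(sum(up | dn), 0, 0.9 * cfg$de_truth$fdr)
    data.frame(gene_id = ids, log2fc = lfc, p_adj = p,
               stringsAsFactors = FALSE)
  })
}

#' Simulate the literature-style side tables
#'
#' Random boolean tables at the configured prevalences, plus a COG
#' category column drawn uniformly over the common single-letter classes.
#'
#' @param cfg A [simulation_config()].
#' @param sim Output of [simulate_genome()].
#' @return Named list of data.frames `essential`, `cell_cycle`,
#'   `methylation`, `cog`, each with `gene_id` and `value`.
#' @export
simulate_side_tables <- function(cfg, sim) {
  local_seed(sub_seed(cfg$seed, 31L), {
    ids <- sim$annotations$gene_id
    flag_table <- function(prev)
      data.frame(gene_id = ids,
                 value = stats::runif(length(ids)) < prev,
                 stringsAsFactors = FALSE)
    list(essential = flag_table(cfg$side_prevalence$essential),
         cell_cycle = flag_table(cfg$side_prevalence$cell_cycle),
         methylation = flag_table(cfg$side_prevalence$methylation),
         cog = data.frame(gene_id = ids,
                          value = sample(c("C", "E", "G", "J", "K", "L",
                                           "M", "O", "P", "T"),
                                         length(ids), replace = TRUE),
                          stringsAsFactors = FALSE))
  })
}

#' Write a complete simulated dataset to disk
#'
#' Emits the exact formats the pipeline consumes: FASTA, GFF3, TSS TSV,
#' four bedGraphs plus a library-totals JSON, DE TSV, side-table TSVs, the
#' PWM TSV and a ground-truth JSON.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   `sim` object.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(cfg)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "annotation.gff3"),
    tss = file.path(dir, "tss.tsv"),
    de = file.path(dir, "de_table.tsv"),
    pwm = file.path(dir, "pwm.tsv"),
    totals = file.path(dir, "library_totals.json"),
    truth = file.path(dir, "ground_truth.json"))
  write_fasta(sim$genome, paths$fasta)
  write_gff(sim$annotations, paths$gff)
  write_table(data.frame(gene_id = sim$tss_table$gene_id,
                         position = sim$tss_table$tss_position + 1L,  # 1-based on disk
                         strand = sim$tss_table$strand), paths$tss)
  de <- simulate_de_table(cfg, sim)
  write_table(de, paths$de)
  write_pwm(cfg$pwm, paths$pwm)
  side <- simulate_side_tables(cfg, sim)
  for (nm in names(side)) {
    paths[[paste0("side_", nm)]] <- file.path(dir, paste0("side_", nm, ".tsv"))
    write_table(side[[nm]], paths[[paste0("side_", nm)]])
  }
  totals <- list()
  for (role in c("MS", "control")) {
    lib <- simulate_library(cfg, sim, role)
    for (cls in c("PLUS_SET", "MINUS_SET")) {
      key <- paste0(tolower(role), "_", tolower(sub("_SET", "", cls)))
      paths[[key]] <- file.path(dir, paste0(key, ".bedgraph"))
      write_bedgraph(lib[[cls]], paths[[key]])
    }
    totals[[role]] <- lib$library_total
  }
  jsonlite::write_json(totals, paths$totals, auto_unbox = TRUE)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(c(paths, list(sim = sim)))
}

#' Write gene annotations as GFF3
#'
#' Inverse of [read_gff()]: internal 0-based half-open coordinates go back
#' to 1-based inclusive; the gene identifier is written to `locus_tag`.
#'
#' @param annotations Annotation data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$seq_id,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end),
    strand = annotations$strand)
  S4Vectors::mcols(gr)$type <- annotations$feature_class
  S4Vectors::mcols(gr)$phase <- ifelse(annotations$feature_class == "CDS",
                                       0L, NA_integer_)
  S4Vectors::mcols(gr)$locus_tag <- annotations$gene_id
  S4Vectors::mcols(gr)$ID <- annotations$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
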