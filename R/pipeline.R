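# Pipeline orchestration: a YAML/JSON configuration carrying every
# tunable constant, staged execution (simulate / regions / call / motif /
# pwm / integrate / all), and a JSON run manifest with a config hash and
# output checksums.  Data files never mix with logs: messages go to
# stderr via message()/warning().

#' Default pipeline configuration
#'
#' All defaults equal the method's published parameterisation: 100-nt UTR5
#' fallback, 250-nt UTR3 window (50 into the gene + 200 downstream), log2
#' RPM threshold 2 with the 25% coverage floor, GGGG motif, PWM threshold
#' 0.70 of the maximum score with a 250-nt upstream site window, FDR 0.01
#' with no fold-change filter, and the 200/50 ChIP promoter window.
#'
#' @param seed Seed for every stochastic step (background UTR sampling,
#'   simulation).
#' @return A nested named list, serialisable to YAML or JSON.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    paths = list(genome = NULL, gff = NULL, tss = NULL,
                 ms_plus = NULL, ms_minus = NULL,
                 control_plus = NULL, control_minus = NULL,
                 de_table = NULL, chip = NULL, pwm = NULL,
                 side_essential = NULL, side_cell_cycle = NULL,
                 side_methylation = NULL, side_cog = NULL),
    library_totals = list(MS = NULL, control = NULL),
    region_rules = list(utr5_default_len = 100L, utr5_min_len = 100L,
                        utr3_into_gene = 50L, utr3_downstream = 200L),
    caller = list(log2_threshold = 2, coverage_quantile = 0.25,
                  pseudocount_rpm = 1, quantile_on = "rpm"),
    protocol = list(plus_strand = "PLUS_SET"),
    motif = list(motif = "GGGG", background_n = NULL),
    pwm = list(type = "scores", threshold_fraction = 0.70,
               threshold_scale = "absolute", upstream_window = 250L),
    deg = list(fdr_threshold = 0.01, lfc_threshold = 0),
    chip = list(upstream = 200L, into_gene = 50L),
    tss_one_based = TRUE)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension); values present in the file override the
#' defaults, unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(default_pipeline_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", k)
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else
      base[[k]] <- user[[k]]
  }
  base
}

#' Write a configuration list to YAML or JSON
#' @param config Configuration list.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(config, path)
  else
    jsonlite::write_json(config, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  unname(tools::md5sum(tmp))
}

require_paths <- function(config, keys) {
  for (k in keys) {
    p <- config$paths[[k]]
    if (is.null(p)) stop("config is missing required path: paths$", k)
    if (!file.exists(p)) stop("input file not found: ", p, " (paths$", k, ")")
  }
  invisible(TRUE)
}

load_pipeline_inputs <- function(config) {
  require_paths(config, c("genome", "gff"))
  genome <- read_fasta(config$paths$genome)
  ann <- read_gff(config$paths$gff, genome)
  tss <- NULL
  if (!is.null(config$paths$tss)) {
    require_paths(config, "tss")
    tss <- read_tss_table(config$paths$tss, ann,
                          one_based = isTRUE(config$tss_one_based))
  }
  rr <- do.call(region_rules, config$region_rules)
  regions <- build_region_set(ann, tss, rr, genome)
  list(genome = genome, annotations = ann, tss = tss, rules = rr,
       regions = regions)
}

load_library_pair <- function(config, role, genome) {
  keys <- paste0(tolower(role), c("_plus", "_minus"))
  require_paths(config, keys)
  total <- config$library_totals[[role]]
  if (is.null(total))
    stop("config is missing library_totals$", role)
  stranded_library(
    read_bedgraph(config$paths[[keys[1]]], genome, "PLUS_SET", total),
    read_bedgraph(config$paths[[keys[2]]], genome, "MINUS_SET", total))
}

#' Run the pipeline
#'
#' Stages: `"simulate"` writes a synthetic dataset into `out_dir` and
#' points the configuration paths at it; `"regions"` builds and exports
#' the region model; `"call"` computes region coverage and MAPS candidate
#' calls; `"motif"` tests motif enrichment of candidate 5' UTRs against a
#' seeded random background; `"pwm"` scans the genome and assigns sites to
#' genes; `"integrate"` selects DEGs and writes the fused per-gene matrix;
#' `"all"` runs everything in order.  A JSON manifest (config hash, seed,
#' package version, per-file md5 checksums) is written last, so repeated
#' runs are verifiably identical.
#'
#' @param config Configuration list ([default_pipeline_config()]), or the
#'   path of a YAML/JSON file.
#' @param stage One of `simulate`, `regions`, `call`, `motif`, `pwm`,
#'   `integrate`, `all`.
#' @param out_dir Output directory.
#' @param sim_config Optional [simulation_config()] for the simulate
#'   stage (default uses the pipeline seed).
#' @return Invisibly, a list of result objects per executed stage.
#' @export
run_pipeline <- function(config, stage = "all", out_dir,
                         sim_config = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  stage <- match.arg(stage, c("simulate", "regions", "call", "motif",
                              "pwm", "integrate", "all"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "regions", "call", "motif", "pwm", "integrate")
  else stage
  results <- list()
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    write_table(obj, p)
    outputs <<- c(outputs, p)
    p
  }

  if ("simulate" %in% stages) {
    sc <- if (is.null(sim_config)) {
      simulation_config(seed = config$seed,
                        planted_targets = list(n = 10L, kind = "UTR5", fold = 8),
                        planted_motif = list(motif = config$motif$motif,
                                             foreground_n = 40L,
                                             fg_fraction = 0.6,
                                             bg_fraction = 0.1))
    } else sim_config
    message("simulate: writing synthetic dataset to ", out_dir)
    ds <- simulate_dataset(sc, out_dir)
    config$paths$genome <- ds$fasta
    config$paths$gff <- ds$gff
    config$paths$tss <- ds$tss
    config$paths$de_table <- ds$de
    config$paths$pwm <- ds$pwm
    config$paths$ms_plus <- ds$ms_plus
    config$paths$ms_minus <- ds$ms_minus
    config$paths$control_plus <- ds$control_plus
    config$paths$control_minus <- ds$control_minus
    for (nm in c("essential", "cell_cycle", "methylation", "cog"))
      config$paths[[paste0("side_", nm)]] <- ds[[paste0("side_", nm)]]
    totals <- jsonlite::read_json(ds$totals, simplifyVector = TRUE)
    config$library_totals$MS <- totals$MS
    config$library_totals$control <- totals$control
    outputs <- c(outputs, unlist(ds[vapply(ds, is.character, logical(1))]))
    results$simulate <- ds$sim
  }

  inputs <- NULL
  need_inputs <- any(c("regions", "call", "motif", "pwm", "integrate") %in% stages)
  if (need_inputs) inputs <- load_pipeline_inputs(config)

  if ("regions" %in% stages) {
    message("regions: ", nrow(inputs$regions), " regions for ",
            nrow(inputs$annotations), " genes")
    emit(inputs$regions, "regions.tsv")
    p <- file.path(out_dir, "regions.bed")
    regions_to_bed(inputs$regions, p)
    outputs <- c(outputs, p)
    results$regions <- inputs$regions
  }

  call_obj <- NULL
  if (any(c("call", "motif", "integrate") %in% stages)) {
    protocol <- orientation_protocol(config$protocol$plus_strand)
    ms_lib <- load_library_pair(config, "MS", inputs$genome)
    ctl_lib <- load_library_pair(config, "control", inputs$genome)
    ms_cov <- region_coverage(inputs$regions, ms_lib, protocol)
    ctl_cov <- region_coverage(inputs$regions, ctl_lib, protocol)
    cc <- config$caller
    call_obj <- maps_call(ms_cov, ctl_cov,
                          maps_caller_config(log2_threshold = cc$log2_threshold,
                                             coverage_quantile = cc$coverage_quantile,
                                             pseudocount_rpm = cc$pseudocount_rpm,
                                             quantile_on = cc$quantile_on))
    if ("call" %in% stages) {
      message("call: ", length(call_obj$candidate_genes), " candidate genes")
      emit(call_obj$calls, "region_calls.tsv")
      emit(gene_candidacy(call_obj), "gene_candidacy.tsv")
      results$call <- call_obj
    }
  }

  if ("motif" %in% stages) {
    fg_ids <- call_obj$candidate_genes
    if (length(fg_ids) == 0L) {
      warning("motif: no candidate genes; skipping enrichment")
    } else {
      n_bg <- config$motif$background_n
      if (is.null(n_bg)) n_bg <- nrow(inputs$annotations)
      fg <- utr_sequences(inputs$regions, inputs$genome, gene_ids = fg_ids)
      bg <- sample_background_utrs(inputs$regions, inputs$genome,
                                   n = n_bg, seed = config$seed)
      enr <- motif_enrichment(fg, bg, motif = config$motif$motif)
      message(sprintf("motif: %d/%d candidate UTRs carry %s (p = %.3g)",
                      enr$k, enr$n, config$motif$motif, enr$p_value))
      emit(as.data.frame(enr), "motif_enrichment.tsv")
      results$motif <- enr
    }
  }

  pwm_genes <- NULL
  if (any(c("pwm", "integrate") %in% stages) && !is.null(config$paths$pwm)) {
    require_paths(config, "pwm")
    p <- read_pwm(config$paths$pwm, type = config$pwm$type,
                  threshold_fraction = config$pwm$threshold_fraction,
                  threshold_scale = config$pwm$threshold_scale)
    sites <- scan_pwm(inputs$genome, p)
    asg <- assign_sites_to_genes(sites, inputs$annotations, p$width,
                                 upstream_window = config$pwm$upstream_window)
    pwm_genes <- asg$genes
    if ("pwm" %in% stages) {
      message("pwm: ", nrow(sites), " sites, ",
              sum(asg$genes$has_site), " genes with a site")
      emit(asg$sites, "pwm_sites.tsv")
      emit(asg$genes, "pwm_gene_sites.tsv")
      bp <- file.path(out_dir, "pwm_sites.bed")
      sites_to_bed(asg$sites, p$width, bp)
      outputs <- c(outputs, bp)
      results$pwm <- asg
    }
  }

  if ("integrate" %in% stages) {
    require_paths(config, "de_table")
    de <- read_de_table(config$paths$de_table)
    degs <- select_degs(de, do.call(deg_selection_config, config$deg))
    s <- deg_summary(degs)
    message(sprintf("integrate: %d DEGs (%d up, %d down)",
                    s$total, s$up, s$down))
    chip_means <- NULL
    if (!is.null(config$paths$chip)) {
      require_paths(config, "chip")
      chip <- read_bedgraph(config$paths$chip, inputs$genome, "PLUS_SET", 1)
      cwc <- do.call(chip_window_config, config$chip)
      chip_means <- vapply(seq_len(nrow(inputs$annotations)), function(i)
        chip_window_mean(chip, inputs$annotations[i, ], cwc), numeric(1))
      names(chip_means) <- inputs$annotations$gene_id
    }
    side <- lapply(c(essential = "side_essential", cell_cycle = "side_cell_cycle",
                     methylation = "side_methylation", cog = "side_cog"),
                   function(k) if (is.null(config$paths[[k]])) NULL
                   else read_side_table(config$paths[[k]]))
    motif_counts <- vapply(
      utr_sequences(inputs$regions, inputs$genome), count_motif, integer(1),
      motif = config$motif$motif)
    mat <- build_matrix(inputs$annotations, degs,
                        maps_candidates = if (is.null(call_obj)) list()
                                          else list(call_obj$candidate_genes),
                        full_site = pwm_genes,
                        motif_counts = motif_counts, chip_means = chip_means,
                        essential = side$essential, cell_cycle = side$cell_cycle,
                        methylation = side$methylation, cog = side$cog)
    emit(degs, "degs.tsv")
    emit(as.data.frame(mat), "gene_annotation_matrix.tsv")
    emit(as.data.frame(matrix_deg_rows(mat)), "gene_annotation_matrix_degs.tsv")
    results$integrate <- mat
  }

  manifest <- list(
    package = "mapscall",
    version = as.character(utils::packageVersion("mapscall")),
    seed = config$seed,
    stage = stage,
    config_hash = config_hash(config),
    outputs = lapply(stats::setNames(nm = basename(outputs)),
                     function(b) unname(tools::md5sum(
                       outputs[basename(outputs) == b][1]))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
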