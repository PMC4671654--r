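# Pipeline orchestration: configuration, stage execution, provenance.

.default_config <- function() {
  list(
    seed = 1L,
    # the simulated test individual and the aCGH reference individual
    test_haplotypes = c("H2", "H2"),
    ref_haplotypes = c("H2", "H2"),
    sample_id = "sim01",
    n_clones = 300L,
    n_molecules = 12L,
    population_n = 50L,
    # simulation error model (see sim_params)
    paralog_divergence = 0.0025,
    fosmid_insert_mean = 40000, fosmid_insert_sd = 2500,
    rmap_cv = 0.05, rmap_p_miss = 0.10, rmap_false_rate = 1 / 500000,
    rmap_min_frag = 800,
    acgh_sigma = 0.10, acgh_identity = 1.0,
    readdepth_window = 500L, readdepth_sigma = 0.2,
    # module thresholds
    insert_min = 32000, insert_max = 48000, min_mapq = 20, min_support = 1L,
    align_sigma_rel = 0.05, align_c_cut = 3.0, align_delta = 3L,
    call_margin = 5.0,
    detect_k = 31L, detect_min_block = 10000L, detect_min_identity = 0.9,
    detect_max_gap = 2000L,
    motif_threshold = 0.85,
    cn_ref = 4L
  )
}

#' Build a pipeline configuration
#'
#' Starts from the package defaults and overrides the named fields; unknown
#' keys are rejected. A configuration round-trips unchanged through YAML.
#'
#' @param ... Named overrides of default fields.
#' @param file Optional YAML file of overrides (applied before `...`).
#' @return A named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- .default_config()
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s) from ", src, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file), file)
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over, "arguments")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Write a configuration to YAML
#' @param cfg A `PipelineConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.sim_params_from_config <- function(cfg) {
  sim_params(seed = cfg$seed,
             paralog_divergence = cfg$paralog_divergence,
             fosmid_insert_mean = cfg$fosmid_insert_mean,
             fosmid_insert_sd = cfg$fosmid_insert_sd,
             rmap_cv = cfg$rmap_cv, rmap_p_miss = cfg$rmap_p_miss,
             rmap_false_rate = cfg$rmap_false_rate,
             rmap_min_frag = cfg$rmap_min_frag,
             acgh_sigma = cfg$acgh_sigma, acgh_identity = cfg$acgh_identity,
             readdepth_window = cfg$readdepth_window,
             readdepth_sigma = cfg$readdepth_sigma)
}

.PIPELINE_STAGES <- c("simulate", "detect-lcr", "scan-motifs", "call-fosmid",
                      "call-rmap", "call-dosage", "genotype", "popstats")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' simulate -> detect-lcr / scan-motifs -> call-fosmid / call-rmap /
#' call-dosage -> genotype; popstats runs on the simulated population.
#' Every output file carries provenance comments (package version, seed,
#' configuration hash). Outputs are deterministic: the same configuration
#' and seed give byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of the stage names (default all).
#' @param outdir Output directory (created if needed).
#' @param artifacts Artifact bundle from a previous partial run, supplying
#'   upstream inputs when early stages are skipped.
#' @return Invisibly, the artifact bundle (named list) including `files`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = .PIPELINE_STAGES,
                         outdir = tempfile("nphp1sv_run"),
                         artifacts = list()) {
  stopifnot(inherits(config, "PipelineConfig"))
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  prov <- c(package = paste0("nphp1sv ",
                             as.character(utils::packageVersion("nphp1sv"))),
            seed = config$seed, config = .config_hash(config))
  need <- function(name, stage) {
    if (is.null(artifacts[[name]]))
      stop("missing upstream artifact '", name, "': run stage '", stage,
           "' first (or pass it via `artifacts`)")
    artifacts[[name]]
  }
  out_file <- function(name) file.path(outdir, name)
  files <- character(0)
  log_stage <- function(s) message("[nphp1sv] stage ", s)

  arch <- build_reference_architecture()
  p <- .sim_params_from_config(config)

  if ("simulate" %in% stages) {
    log_stage("simulate")
    test_g <- make_genotype(config$test_haplotypes, arch = arch)
    ref_g <- make_genotype(config$ref_haplotypes, arch = arch)
    seq_h1 <- synth_haplotype_sequence(arch, make_haplotype("H1", arch), p)
    artifacts$test_genotype <- test_g
    artifacts$ref_genotype <- ref_g
    artifacts$sequence_h1 <- seq_h1
    artifacts$esp <- simulate_fosmid_library(test_g, config$n_clones, p)
    cands <- candidate_rmaps(arch, p)
    artifacts$candidates <- cands
    artifacts$molecules <- lapply(seq_along(config$test_haplotypes),
      function(i) simulate_rmaps(cands[[config$test_haplotypes[i]]],
                                 config$n_molecules, p, seed_offset = i))
    artifacts$acgh <- simulate_acgh(test_g, ref_g, p = p)
    artifacts$readdepth <- simulate_readdepth(test_g, p)
    artifacts$population <- sample_population(default_population_freqs(),
                                              config$population_n, p)
    write_fasta(c(H1 = seq_h1), f <- out_file("haplotype_H1.fasta"))
    files <- c(files, f)
    write_pipeline_tsv(artifacts$esp, f <- out_file("esp.tsv"), prov)
    files <- c(files, f)
    write_rmaps_tsv(unlist(artifacts$molecules, recursive = FALSE),
                    f <- out_file("rmaps.tsv"), prov)
    files <- c(files, f)
    write_pipeline_tsv(artifacts$acgh$table, f <- out_file("acgh.tsv"), prov)
    files <- c(files, f)
    write_pipeline_tsv(artifacts$readdepth$table,
                       f <- out_file("readdepth.tsv"), prov)
    files <- c(files, f)
    write_pipeline_tsv(artifacts$population, f <- out_file("population.tsv"),
                       prov)
    files <- c(files, f)
  }

  if ("detect-lcr" %in% stages) {
    log_stage("detect-lcr")
    seq_h1 <- need("sequence_h1", "simulate")
    det <- detect_paralogs(seq_h1, k = config$detect_k,
                           min_block = config$detect_min_block,
                           min_identity = config$detect_min_identity,
                           max_gap = config$detect_max_gap)
    artifacts$paralogs <- det
    write_pipeline_tsv(det$pairs, f <- out_file("paralog_pairs.tsv"), prov)
    files <- c(files, f)
    bed <- data.frame(chrom = arch$chrom,
                      start = det$blocks$start, end = det$blocks$end,
                      name = paste0("family", det$blocks$family),
                      score = 0L, strand = ".")
    utils::write.table(bed, f <- out_file("paralog_blocks.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }

  if ("scan-motifs" %in% stages) {
    log_stage("scan-motifs")
    seq_h1 <- need("sequence_h1", "simulate")
    hits <- scan_prdm9(seq_h1, threshold = config$motif_threshold)
    artifacts$motifs <- hits
    write_pipeline_tsv(hits, f <- out_file("prdm9_hits.tsv"), prov)
    files <- c(files, f)
  }

  if ("call-fosmid" %in% stages) {
    log_stage("call-fosmid")
    esp <- need("esp", "simulate")
    calls <- classify_esp(esp, insert_min = config$insert_min,
                          insert_max = config$insert_max,
                          min_mapq = config$min_mapq, arch = arch)
    artifacts$esp_calls <- calls
    artifacts$fosmid_evidence <- aggregate_individual(calls,
                                                      config$min_support)
    write_pipeline_tsv(calls, f <- out_file("esp_calls.tsv"), prov)
    files <- c(files, f)
    write_discordant_bed(esp, calls, f <- out_file("esp_discordant.bed"))
    files <- c(files, f)
  }

  if ("call-rmap" %in% stages) {
    log_stage("call-rmap")
    mols <- need("molecules", "simulate")
    cands <- need("candidates", "simulate")
    consensus <- lapply(mols, consensus_rmap,
                        sigma_rel = config$align_sigma_rel,
                        c_cut = config$align_c_cut,
                        delta = config$align_delta)
    rmap_call <- call_haplotype_rmap(consensus, cands,
                                     sigma_rel = config$align_sigma_rel,
                                     c_cut = config$align_c_cut,
                                     delta = config$align_delta,
                                     margin = config$call_margin)
    artifacts$rmap_call <- rmap_call
    write_pipeline_tsv(rmap_call$calls, f <- out_file("rmap_calls.tsv"), prov)
    files <- c(files, f)
  }

  if ("call-dosage" %in% stages) {
    log_stage("call-dosage")
    acgh <- need("acgh", "simulate")
    s <- summarize_region(region_dosage(
      acgh$table[acgh$table$target == "45K", , drop = FALSE],
      kind = "log2ratio"))
    artifacts$cn_call <- estimate_cn_intra(s$mean_lr, cn_ref = config$cn_ref,
                                           dlrs = s$dlrs)
    df <- data.frame(sample_id = config$sample_id, region = "45K",
                     mean_lr = s$mean_lr, dlrs = s$dlrs,
                     cn = artifacts$cn_call$cn)
    write_pipeline_tsv(df, f <- out_file("cn_call.tsv"), prov)
    files <- c(files, f)
  }

  if ("genotype" %in% stages) {
    log_stage("genotype")
    rmap_call <- need("rmap_call", "call-rmap")
    cn_call <- need("cn_call", "call-dosage")
    fe <- artifacts$fosmid_evidence  # optional cross-check
    report <- integrate_evidence(rmap_alleles = rmap_call$allele_types,
                                 fosmid_evidence = fe, cn_call = cn_call,
                                 sample_id = config$sample_id, arch = arch)
    artifacts$report <- report
    df <- if (nrow(report$genotypes)) {
      data.frame(sample_id = report$sample_id,
                 allele_types = paste(report$allele_types, collapse = ","),
                 hap1 = report$genotypes$hap1, hap2 = report$genotypes$hap2,
                 total45 = report$total45, protection = report$protection,
                 flags = paste(names(report$flags), collapse = ","))
    } else {
      data.frame(sample_id = report$sample_id,
                 allele_types = paste(report$allele_types, collapse = ","),
                 hap1 = NA, hap2 = NA, total45 = report$total45,
                 protection = NA,
                 flags = paste(names(report$flags), collapse = ","))
    }
    write_pipeline_tsv(df, f <- out_file("genotype_report.tsv"), prov)
    files <- c(files, f)
    txt <- utils::capture.output(print(report))
    writeLines(txt, f <- out_file("genotype_report.txt"))
    files <- c(files, f)
  }

  if ("popstats" %in% stages) {
    log_stage("popstats")
    popn <- need("population", "simulate")
    dist <- cn_distribution(popn)
    kw <- kruskal_wallis(split(popn$count45, popn$population))
    artifacts$cn_dist <- dist
    artifacts$kw <- kw
    write_pipeline_tsv(dist, f <- out_file("cn_distribution.tsv"), prov)
    files <- c(files, f)
    stat <- data.frame(method = kw$method, statistic = kw$statistic,
                       df = kw$df, p_value = kw$p_value)
    write_pipeline_tsv(stat, f <- out_file("popstats.tsv"), prov)
    files <- c(files, f)
  }

  artifacts$files <- files
  invisible(artifacts)
}
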