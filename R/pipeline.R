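# Configured end-to-end pipeline: simulate -> qc -> enrich -> sites,
# under one master seed, with provenance records (parameters, seed,
# input checksums) for every stage. Data go to files; no timestamps are
# written, so a rerun under the same seed is byte-identical.

#' Integrated copies per genome from duplexed ddPCR concentrations
#'
#' `copies = 2 * target / reference`: the fractional abundance of the
#' target amplicon adjusted for the two copies of the autosomal
#' reference locus per diploid genome.
#'
#' @param target_concentration target amplicon concentration (>= 0).
#' @param reference_concentration reference amplicon concentration
#'   (> 0).
#' @return copies per genome (vectorized).
#' @export
copy_number <- function(target_concentration, reference_concentration) {
  if (any(target_concentration < 0))
    stop("'target_concentration' must be >= 0")
  if (any(reference_concentration <= 0))
    stop("'reference_concentration' must be > 0")
  2 * target_concentration / reference_concentration
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "pipeline_out",
    stages = c("simulate", "qc", "enrich", "sites"),
    simulate = list(length_aa = 300L, n_mutations = 50L, n_variants = 1000L,
                    mean_mutation_load = 4.4, read_error_rate = 0.002,
                    n_reads_naive = 20000L, n_reads_sorted = 20000L,
                    selection_stringency = 1, n_effect_mutations = 5L,
                    effect_size = 1, genome_length = 200000L,
                    n_transcripts = 10L, transcript_fraction = 0.3,
                    n_insertions = 100L, tsd_length = 8L,
                    reads_per_junction = 2L, read_length = 60L),
    qc = list(min_coverage = 0.95, min_identity = 0.85),
    enrich = list(pseudocount = 0.5),
    sites = list(merge_window = 5L, tsd_length = 8L, n_random = 5000L,
                 n_bootstrap = 100L, min_itr_match = 12L,
                 min_genomic_len = 20L))
}

merge_config <- function(user, defaults, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", " at ",
         if (nzchar(path)) path else "top level", ": ",
         paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "/"))
    else user[[k]]
  }
  defaults
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list), validates every key against the
#' schema and fills defaults. Unknown keys are rejected.
#'
#' @param config YAML path or list; `NULL` gives the defaults.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
          else if (is.character(config)) yaml::read_yaml(config)
          else config
  cfg <- merge_config(user, pipeline_defaults())
  cfg$stages <- match.arg(cfg$stages,
                          c("simulate", "qc", "enrich", "sites"),
                          several.ok = TRUE)
  structure(cfg, class = "pipeline_config")
}

need_file <- function(path, stage, what) {
  if (!file.exists(path))
    stop("dependency error: stage '", stage, "' requires ", what, " at ",
         path, " (run the producing stage first or point the config at it)")
  path
}

#' Run the configured pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> qc -> enrich; simulate -> sites), writing standard-format
#' outputs plus a provenance record per stage (parameters, seed, md5 of
#' consumed inputs) to `provenance.json`. All randomness derives from
#' the master seed, so two runs with the same config are byte-identical.
#'
#' @param config YAML path, list, or [pipeline_config()] result.
#' @return (invisibly) list of output paths per stage.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out, ...)
  prov <- list()
  outputs <- list()
  stage_prov <- function(stage, params, inputs, outs) {
    sums <- tools::md5sum(inputs)
    names(sums) <- basename(inputs)
    list(stage = stage, seed = cfg$seed, params = params,
         inputs = as.list(sums), outputs = outs)
  }

  if ("simulate" %in% cfg$stages) {
    sp <- cfg$simulate
    scfg <- sim_config(seed = cfg$seed,
                       read_error_rate = sp$read_error_rate,
                       mean_mutation_load = sp$mean_mutation_load,
                       n_variants = sp$n_variants,
                       n_reads_naive = sp$n_reads_naive,
                       n_reads_sorted = sp$n_reads_sorted,
                       selection_stringency = sp$selection_stringency,
                       tsd_length = sp$tsd_length)
    ref <- make_reference(sp$length_aa, seed = cfg$seed)
    design <- make_design(ref, sp$n_mutations, seed = cfg$seed)
    lib <- simulate_library(design, scfg, n_reads = 0L)
    eff_ids <- with_seed(derive_seed(cfg$seed, "effects"),
                         sample(design$mutation_id, sp$n_effect_mutations))
    effects <- setNames(rep(sp$effect_size, length(eff_ids)), eff_ids)
    srt <- simulate_sort(lib, effects, scfg)
    gen <- simulate_genome_and_insertions(
      scfg, genome_length = sp$genome_length,
      n_transcripts = sp$n_transcripts,
      transcript_fraction = sp$transcript_fraction,
      n_insertions = sp$n_insertions,
      reads_per_junction = sp$reads_per_junction,
      read_length = sp$read_length)
    write_fasta(setNames(ref$cds, "reference"), p("reference.fasta"))
    write_design_tsv(design, p("design.tsv"))
    write_fastq(srt$naive, p("naive.fastq"))
    write_fastq(srt$sorted, p("sorted.fastq"))
    write_fasta(gen$genome, p("genome.fasta"))
    write_annotation_gff3(gen$annotation, p("annotation.gff3"))
    write_fastq(gen$reads, p("junctions.fastq"))
    truth <- list(genotypes = lib$genotypes,
                  effects = as.list(effects),
                  insertion_sites = gen$sites)
    write_json(truth, p("ground_truth.json"))
    outs <- c("reference.fasta", "design.tsv", "naive.fastq",
              "sorted.fastq", "genome.fasta", "annotation.gff3",
              "junctions.fastq", "ground_truth.json")
    outputs$simulate <- p(outs)
    prov$simulate <- stage_prov("simulate", sp, character(0), outs)
  }

  if ("qc" %in% cfg$stages) {
    refp <- need_file(p("reference.fasta"), "qc", "the reference FASTA")
    desp <- need_file(p("design.tsv"), "qc", "the design TSV")
    ref <- as.character(Biostrings::readDNAStringSet(refp))[[1]]
    design <- load_design(desp, ref)
    for (pop in c("naive", "sorted")) {
      rp <- need_file(p(paste0(pop, ".fastq")), "qc",
                      paste0("the ", pop, " reads"))
      calls <- genotype_reads(read_reads(rp), design, ref,
                              cfg$qc$min_coverage, cfg$qc$min_identity)
      stats <- library_stats(calls)
      write_tsv(calls$per_read, p(paste0(pop, "_genotypes.tsv")))
      write_tsv(stats$variant_table, p(paste0(pop, "_variants.tsv")))
      write_tsv(stats$per_mutation, p(paste0(pop, "_counts.tsv")))
      write_json(list(total_reads = stats$total_reads,
                      passing_reads = stats$passing_reads,
                      n_unique_variants = stats$n_unique_variants,
                      mean_mutation_load = signif6(stats$mean_mutation_load)),
                 p(paste0(pop, "_stats.json")))
    }
    outs <- as.vector(outer(c("naive", "sorted"),
                            c("_genotypes.tsv", "_variants.tsv",
                              "_counts.tsv", "_stats.json"), paste0))
    outputs$qc <- p(outs)
    prov$qc <- stage_prov("qc", cfg$qc,
                          c(refp, desp, p("naive.fastq"), p("sorted.fastq")),
                          outs)
  }

  if ("enrich" %in% cfg$stages) {
    refp <- need_file(p("reference.fasta"), "enrich", "the reference FASTA")
    desp <- need_file(p("design.tsv"), "enrich", "the design TSV")
    ncp <- need_file(p("naive_counts.tsv"), "enrich",
                     "per-mutation naive counts (qc stage output)")
    scp <- need_file(p("sorted_counts.tsv"), "enrich",
                     "per-mutation sorted counts (qc stage output)")
    ref <- as.character(Biostrings::readDNAStringSet(refp))[[1]]
    design <- load_design(desp, ref)
    et <- enrichment_table(read_tsv(ncp), read_tsv(scp), design,
                           pseudocount = cfg$enrich$pseudocount)
    write_tsv(as.data.frame(et), p("enrichment.tsv"))
    top <- head(et[!et$undefined, ], 10)
    write_json(list(n_mutations = nrow(et),
                    n_undefined = sum(et$undefined),
                    top10 = top$label,
                    top10_wes = signif6(top$WES)),
               p("enrichment_summary.json"))
    outputs$enrich <- p(c("enrichment.tsv", "enrichment_summary.json"))
    prov$enrich <- stage_prov("enrich", cfg$enrich, c(ncp, scp),
                              c("enrichment.tsv", "enrichment_summary.json"))
  }

  if ("sites" %in% cfg$stages) {
    jp <- need_file(p("junctions.fastq"), "sites", "junction reads")
    gp <- need_file(p("genome.fasta"), "sites", "the genome FASTA")
    ap <- need_file(p("annotation.gff3"), "sites", "the GFF3 annotation")
    genome <- as.character(Biostrings::readDNAStringSet(gp))
    names(genome) <- sub("\\s.*$", "", names(genome))
    ann <- read_annotation(ap)
    probe <- sim_config()$itr_probe
    jx <- extract_junctions(read_reads(jp), probe,
                            cfg$sites$min_itr_match,
                            cfg$sites$min_genomic_len)
    loci <- map_fragments(jx, genome)
    sites <- cluster_sites(loci, genome, cfg$sites$merge_window,
                           cfg$sites$tsd_length)
    prof <- profile_summary(sites, ann, genome,
                            n_random = cfg$sites$n_random,
                            n_bootstrap = cfg$sites$n_bootstrap,
                            seed = cfg$seed)
    write_sites_bed(sites, p("sites.bed"))
    write_json(list(n_sites = prof$n_sites,
                    median_tss_distance = signif6(prof$median_tss_distance),
                    median_tss_se = signif6(prof$median_tss_se),
                    fractions = as.list(signif6(prof$fractions)),
                    baseline_fractions =
                      as.list(signif6(prof$baseline$fractions)),
                    fraction_ratio = as.list(signif6(prof$fraction_ratio))),
               p("profile.json"))
    outputs$sites <- p(c("sites.bed", "profile.json"))
    prov$sites <- stage_prov("sites", cfg$sites, c(jp, gp, ap),
                             c("sites.bed", "profile.json"))
  }

  write_json(prov, p("provenance.json"))
  invisible(outputs)
}
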