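# End-to-end orchestration: merge -> demux -> call -> code -> statistics.

default_params <- function() {
  list(min_overlap = 30L, max_mismatch_frac = 0.1, q_threshold = 30L,
       max_mismatch = 2L, identity = 0.99, max_gap = 2L, noise_frac = 0.01,
       min_reads = 10L, stutter_frac = 0.05,
       low_cov_individual_frac = 0.10, missing_locus_frac = 0.30,
       paralog_locus_frac = 0.05, n_perm = 10000L, seed = 1L)
}

#' Run the full genotyping pipeline
#'
#' Stages: paired-end merge (skipped when a pre-merged FASTQ is given),
#' demultiplexing, allele calling with QC filters, catalog annotation and
#' coding, size homoplasy, and the diversity/differentiation summary per
#' coding scheme. Every stage writes a TSV into `out_dir` and logs its
#' input/output counts; stages are also independently callable on the
#' previous stage's files.
#'
#' @param config list or YAML file path with entries `r1`/`r2` or `merged`
#'   (FASTQ paths), `loci`, `samples`, `pops` (TSV paths), `out_dir`, and an
#'   optional `params` list overriding [default_params()] entries.
#' @return list with `genotypes`, `catalog`, `coded`, `homoplasy`,
#'   `qc`, `summaries`, `demux_summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(default_params(), config$params %||% list())
  for (f in c("loci", "samples", "pops")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("missing input file for '", f, "': ",
           config[[f]] %||% "(unset)", call. = FALSE)
    }
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(params = params), file.path(out_dir, "params.yaml"))

  specs <- load_locus_table(config$loci)
  samples <- load_sample_sheet(config$samples)
  popmap <- load_population_map(config$pops)

  if (!is.null(config$merged)) {
    merged <- read_fastq(config$merged)
  } else {
    for (f in c("r1", "r2")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("missing input file for '", f, "'", call. = FALSE)
      }
    }
    f1 <- read_fastq(config$r1)
    f2 <- read_fastq(config$r2)
    pairs <- data.frame(read_id = f1$read_id, r1 = f1$seq, q1 = f1$qual,
                        r2 = f2$seq, q2 = f2$qual, stringsAsFactors = FALSE)
    mg <- merge_read_pairs(pairs, params$min_overlap,
                           params$max_mismatch_frac)
    merged <- data.frame(read_id = mg$merged$read_id, seq = mg$merged$seq,
                         qual = mg$merged$qual, stringsAsFactors = FALSE)
    writeLines(mg$unmerged_ids, file.path(out_dir, "unmerged_ids.txt"))
  }

  dm <- demultiplex_stream(merged, specs, samples, params$max_mismatch)
  write.table(dm$summary, file.path(out_dir, "demux_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- call_all_bins(dm$bins, samples, specs,
                         min_reads = params$min_reads,
                         identity = params$identity,
                         max_gap = params$max_gap,
                         noise_frac = params$noise_frac,
                         stutter_frac = params$stutter_frac)
  write.table(calls$contig_debug, file.path(out_dir, "contig_debug.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  locus_ids <- vapply(specs, `[[`, "", "locus_id")
  qc <- qc_filters(calls$calls, samples$individual_id, locus_ids,
                   params$low_cov_individual_frac,
                   params$missing_locus_frac, params$paralog_locus_frac)
  write.table(qc$exclusions, file.path(out_dir, "exclusions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  geno <- calls$genotypes
  geno <- geno[geno$locus_id %in% qc$keep_loci &
                 geno$individual_id %in% qc$keep_individuals, , drop = FALSE]
  catalog <- allele_catalog(geno$locus_id, geno$sequence)
  ckey <- paste(catalog$locus_id, catalog$sequence, sep = "\r")
  geno$allele_id <- catalog$allele_id[
    match(paste(geno$locus_id, geno$sequence, sep = "\r"), ckey)]
  write_genotype_table(geno, file.path(out_dir, "calls.tsv"))
  write_allele_catalog(catalog, file.path(out_dir, "alleles.fasta"))

  catalog <- annotate_catalog(catalog, specs)
  coded <- code_datasets(catalog, geno)
  for (scheme in names(coded)) {
    write.table(coded[[scheme]],
                file.path(out_dir, sprintf("dataset_%s.tsv", scheme)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  homoplasy <- homoplasy_table(catalog)
  write.table(homoplasy, file.path(out_dir, "homoplasy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summaries <- list(
    ssr_length = popgen_summary(coded$ssr_length, popmap, TRUE,
                                params$n_perm, params$seed),
    fragment_length = popgen_summary(coded$fragment_length, popmap, TRUE,
                                     params$n_perm, params$seed),
    sequence_identity = popgen_summary(coded$sequence_identity, popmap,
                                       FALSE, 0L, params$seed))
  for (scheme in names(summaries)) {
    write.table(summaries[[scheme]],
                file.path(out_dir, sprintf("stats_%s.tsv", scheme)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(genotypes = geno, catalog = catalog, coded = coded,
       homoplasy = homoplasy, qc = qc, summaries = summaries,
       demux_summary = dm$summary)
}
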