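# Shared fixture builders. Everything is generated in code; no binary data.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

snp_at <- function(seq, pos, to) {
  stopifnot(substr(seq, pos, pos) != to)
  substr(seq, pos, pos) <- to
  seq
}

# A hand-built locus: 30 bp flanks around (CAC) x 8, with fixed primers and
# one or two barcode sets.
make_locus <- function(locus_id = "locA", n_sets = 1L, motif = "CAC",
                       n_units = 8L, seed = 101L) {
  set.seed(seed)
  left <- rand_dna(30)
  right <- rand_dna(30)
  # keep the repeat run maximal at exactly the annotated interval
  u <- nchar(motif)
  if (substr(left, 30, 30) == substr(motif, u, u)) {
    substr(left, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                    substr(motif, u, u))[1]
  }
  if (substr(right, 1, 1) == substr(motif, 1, 1)) {
    substr(right, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                   substr(motif, 1, 1))[1]
  }
  ref <- paste0(left, strrep(motif, n_units), right)
  bcs <- setNames(
    vapply(seq_len(n_sets), function(i) rand_dna(10), character(1)),
    sprintf("set%d", seq_len(n_sets)))
  locus_spec(locus_id, "testsp", rand_dna(20), rand_dna(20), bcs, ref,
             matrix(c(30L, 30L + u * n_units), ncol = 2), motif)
}

# Tagged on-wire read for a locus/set/insert, in reference orientation.
make_read <- function(locus, set_id, insert) {
  tag <- locus$barcodes[[set_id]]
  paste0(tag, locus$forward_primer, insert,
         revcomp(locus$reverse_primer), revcomp(tag))
}

# Small deterministic simulated dataset reused by several test files.
small_sim <- function(seed = 7L, ...) {
  simulate_dataset(sim_config(seed = seed, n_loci = 3L,
                              n_individuals_per_pop = 5L,
                              mean_reads_per_allele = 30L,
                              seq_error_rate = 0,
                              recombinant_fraction = 0,
                              stutter_fraction = 0, ...))
}

# Run merge -> demux -> call on a simulated dataset, returning calls.
run_sim_pipeline <- function(sim) {
  pairs <- data.frame(read_id = sim$reads$read_id, r1 = sim$reads$r1,
                      q1 = sim$reads$q1, r2 = sim$reads$r2,
                      q2 = sim$reads$q2, stringsAsFactors = FALSE)
  mg <- suppressMessages(merge_read_pairs(pairs))
  idx <- match(mg$merged$read_id, sim$reads$read_id)
  merged <- data.frame(
    read_id = paste0(mg$merged$read_id, " pool=", sim$reads$pool_id[idx]),
    seq = mg$merged$seq, qual = mg$merged$qual, stringsAsFactors = FALSE)
  dm <- suppressMessages(
    demultiplex_stream(merged, sim$loci, sim$sample_sheet))
  calls <- call_all_bins(dm$bins, sim$sample_sheet, sim$loci)
  list(demux = dm, calls = calls)
}

geno_key <- function(d) {
  paste(d$individual_id, d$locus_id, d$sequence, d$dosage)
}
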