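#' Configuration for the amplicon-read simulator
#'
#' Defaults describe a typical plant SSR-seq experiment of the kind the
#' package targets: 20 trusted loci per species, 3-6 bp repeat units with a
#' repeat region of at least 21 bp on the reference allele, amplicons up to
#' 450 bp so that one merged MiSeq read pair spans the whole repeat, 10-nt
#' sample-set tags on both primers, and per-allele coverage around 50 reads.
#' Noise knobs mirror the artifacts seen in real amplicon libraries:
#' per-base sequencing error, single-breakpoint PCR recombinants between the
#' two parental alleles of an individual, and polymerase stutter of one
#' repeat unit.
#'
#' @param seed integer RNG seed; every random draw derives from it.
#' @param n_loci number of SSR loci.
#' @param n_populations,n_individuals_per_pop sampling design.
#' @param ploidy 2 or 4.
#' @param n_sets number of 10-nt barcode sets (non-combinatorial tagging).
#' @param motif_length_range repeat unit length bounds, within `[3, 6]`.
#' @param repeat_count_range repeat counts drawn for the reference allele
#'   (forced up so the reference repeat region is at least 21 bp).
#' @param n_alleles_per_locus distinct allele lineages segregating per locus.
#' @param flank_snp_rate per-lineage probability of carrying a flanking SNP.
#' @param flank_indel_rate per-lineage probability of a flanking indel.
#' @param indel_length_range flanking indel lengths in bp.
#' @param mean_reads_per_allele expected read count for a dosage-1 allele
#'   copy; scaled by dosage for polyploids.
#' @param coverage_dispersion negative-binomial `size`; smaller = more skewed
#'   per-allele coverage.
#' @param seq_error_rate per-base substitution error probability.
#' @param recombinant_fraction probability that a read is a single-breakpoint
#'   chimera of two alleles of the same individual.
#' @param cross_set_recombinant_fraction probability that a read is a chimera
#'   joining templates of individuals from two different barcode sets
#'   (detectable only through the tag check; requires `n_sets >= 2`).
#' @param stutter_fraction probability that a read gains or loses one repeat
#'   unit.
#' @param amplicon_length_range total amplicon length (primers included,
#'   tags excluded); at most 450 bp.
#' @param read_length paired-end read length.
#' @param differentiation_mode `"none"` (panmixia), `"smm_drift"` (repeat
#'   counts drift stepwise apart between populations) or `"iam_shuffle"`
#'   (populations differ in flanking-SNP allele identity while repeat sizes
#'   stay exchangeable).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 20L,
                       n_populations = 2L,
                       n_individuals_per_pop = 20L,
                       ploidy = 2L,
                       n_sets = 1L,
                       motif_length_range = c(3L, 6L),
                       repeat_count_range = c(7L, 14L),
                       n_alleles_per_locus = 4L,
                       flank_snp_rate = 0.5,
                       flank_indel_rate = 0.1,
                       indel_length_range = c(1L, 9L),
                       mean_reads_per_allele = 50L,
                       coverage_dispersion = 20,
                       seq_error_rate = 0.001,
                       recombinant_fraction = 0.02,
                       cross_set_recombinant_fraction = 0,
                       stutter_fraction = 0.01,
                       amplicon_length_range = c(250L, 400L),
                       read_length = 250L,
                       differentiation_mode = c("none", "smm_drift",
                                                "iam_shuffle")) {
  differentiation_mode <- match.arg(differentiation_mode)
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              n_populations = as.integer(n_populations),
              n_individuals_per_pop = as.integer(n_individuals_per_pop),
              ploidy = as.integer(ploidy), n_sets = as.integer(n_sets),
              motif_length_range = as.integer(motif_length_range),
              repeat_count_range = as.integer(repeat_count_range),
              n_alleles_per_locus = as.integer(n_alleles_per_locus),
              flank_snp_rate = flank_snp_rate,
              flank_indel_rate = flank_indel_rate,
              indel_length_range = as.integer(indel_length_range),
              mean_reads_per_allele = as.integer(mean_reads_per_allele),
              coverage_dispersion = coverage_dispersion,
              seq_error_rate = seq_error_rate,
              recombinant_fraction = recombinant_fraction,
              cross_set_recombinant_fraction = cross_set_recombinant_fraction,
              stutter_fraction = stutter_fraction,
              amplicon_length_range = as.integer(amplicon_length_range),
              read_length = as.integer(read_length),
              differentiation_mode = differentiation_mode)
  rates <- c(cfg$flank_snp_rate, cfg$flank_indel_rate, cfg$seq_error_rate,
             cfg$recombinant_fraction, cfg$stutter_fraction,
             cfg$cross_set_recombinant_fraction)
  stopifnot(all(rates >= 0 & rates <= 1),
            cfg$ploidy %in% c(2L, 4L),
            cfg$motif_length_range[1] >= 3L, cfg$motif_length_range[2] <= 6L,
            cfg$amplicon_length_range[2] <= 450L)
  if (cfg$cross_set_recombinant_fraction > 0 && cfg$n_sets < 2L) {
    stop("cross-set recombinants require n_sets >= 2", call. = FALSE)
  }
  # the repeat region must be able to reach 21 bp within the amplicon
  if (cfg$amplicon_length_range[1] < 40L + 60L + 21L) {
    stop("amplicons too short to host primers, flanks and a 21 bp repeat",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

QUAL_CLEAN <- 37L  # 'F'
QUAL_ERROR <- 20L  # '5'

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# A primitive repeat unit: not a power of a shorter string, not a homopolymer.
random_motif <- function(len) {
  repeat {
    m <- random_dna(len)
    ch <- strsplit(m, "")[[1]]
    periodic <- any(vapply(seq_len(len - 1), function(p) {
      len %% p == 0 && all(ch == ch[((seq_len(len) - 1) %% p) + 1])
    }, logical(1)))
    if (!periodic) return(m)
  }
}

# Random 20-mers with pairwise Hamming distance > 2 * max demux mismatches.
random_keyset <- function(n, len, min_dist = 6L) {
  keys <- character(0)
  while (length(keys) < n) {
    k <- random_dna(len)
    if (all(vapply(keys, function(o) {
      sum(strsplit(k, "")[[1]] != strsplit(o, "")[[1]]) >= min_dist
    }, logical(1)))) {
      keys <- c(keys, k)
    }
  }
  keys
}

# One allele lineage is kept as parts so its repeat region stays addressable.
allele_parts <- function(left, motif, n_units, right) {
  list(left = left, motif = motif, n_units = n_units, right = right)
}

parts_seq <- function(p) {
  paste0(p$left, strrep(p$motif, p$n_units), p$right)
}

mutate_flank_snp <- function(flank) {
  if (nchar(flank) < 3L) return(flank)
  pos <- sample(2L:(nchar(flank) - 1L), 1L)
  old <- substr(flank, pos, pos)
  substr(flank, pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
  flank
}

mutate_flank_indel <- function(flank, len_range) {
  len <- sample(len_range[1]:len_range[2], 1L)
  if (nchar(flank) < len + 4L) return(flank)
  if (runif(1) < 0.5) {  # deletion
    pos <- sample(2L:(nchar(flank) - len - 1L), 1L)
    paste0(substr(flank, 1L, pos - 1L), substr(flank, pos + len, nchar(flank)))
  } else {               # insertion
    pos <- sample(2L:(nchar(flank) - 1L), 1L)
    paste0(substr(flank, 1L, pos), random_dna(len),
           substr(flank, pos + 1L, nchar(flank)))
  }
}

# Flank edges must not extend the repeat run, so truth coordinates stay exact.
guard_flank_edges <- function(left, right, motif) {
  u <- nchar(motif)
  last_unit_char <- substr(motif, u, u)
  while (substr(left, nchar(left), nchar(left)) == last_unit_char) {
    substr(left, nchar(left), nchar(left)) <-
      sample(setdiff(DNA_BASES, last_unit_char), 1L)
  }
  first_unit_char <- substr(motif, 1L, 1L)
  while (substr(right, 1L, 1L) == first_unit_char) {
    substr(right, 1L, 1L) <- sample(setdiff(DNA_BASES, first_unit_char), 1L)
  }
  list(left = left, right = right)
}

simulate_locus_pool <- function(cfg, locus_idx, barcodes) {
  u <- sample(cfg$motif_length_range[1]:cfg$motif_length_range[2], 1L)
  motif <- random_motif(u)
  n0 <- max(sample(cfg$repeat_count_range[1]:cfg$repeat_count_range[2], 1L),
            ceiling(21 / u))
  amp_len <- sample(cfg$amplicon_length_range[1]:cfg$amplicon_length_range[2],
                    1L)
  insert_len <- amp_len - 40L
  flank_total <- insert_len - n0 * u
  if (flank_total < 60L) {
    insert_len <- n0 * u + 60L
    flank_total <- 60L
  }
  left_len <- sample(30L:(flank_total - 30L), 1L)
  left <- random_dna(left_len)
  right <- random_dna(flank_total - left_len)
  g <- guard_flank_edges(left, right, motif)
  ref <- allele_parts(g$left, motif, n0, g$right)

  # allele lineages: stepwise repeat-count changes plus flanking SNPs/indels;
  # under iam_shuffle each population receives private flank variants.
  n_pools <- if (cfg$differentiation_mode == "iam_shuffle")
    cfg$n_populations else 1L
  pools <- vector("list", n_pools)
  for (pp in seq_len(n_pools)) {
    alleles <- list(ref)
    while (length(alleles) < cfg$n_alleles_per_locus) {
      a <- ref
      if (cfg$differentiation_mode == "iam_shuffle") {
        # same size distribution everywhere; identity differs via flank SNPs
        a$n_units <- n0 + sample(c(-1L, 0L, 1L), 1L)
        a$left <- mutate_flank_snp(a$left)
        if (runif(1) < 0.5) a$right <- mutate_flank_snp(a$right)
      } else {
        a$n_units <- max(ceiling(21 / u) + 0L,
                         n0 + sample(c(-2L, -1L, 1L, 2L, 3L), 1L))
        if (runif(1) < cfg$flank_snp_rate) a$left <- mutate_flank_snp(a$left)
        if (runif(1) < cfg$flank_snp_rate) a$right <- mutate_flank_snp(a$right)
        if (runif(1) < cfg$flank_indel_rate) {
          a$right <- mutate_flank_indel(a$right, cfg$indel_length_range)
        }
      }
      eg <- guard_flank_edges(a$left, a$right, a$motif)
      a$left <- eg$left; a$right <- eg$right
      if (!parts_seq(a) %in% vapply(alleles, parts_seq, character(1))) {
        alleles <- c(alleles, list(a))
      }
    }
    pools[[pp]] <- alleles
  }

  if (cfg$differentiation_mode == "smm_drift") {
    # population-specific stepwise offsets create a strong size signal
    base <- pools[[1]]
    pools <- lapply(seq_len(cfg$n_populations), function(pp) {
      lapply(base, function(a) {
        a$n_units <- a$n_units + (pp - 1L) * 4L
        a
      })
    })
  } else if (cfg$differentiation_mode == "none") {
    pools <- rep(pools[1], cfg$n_populations)
  }

  list(locus_id = sprintf("sim%02d", locus_idx), motif = motif,
       ref = ref, pools = pools, barcodes = barcodes)
}

inject_errors <- function(seqs, rate) {
  qual <- strrep(int_to_phred(QUAL_CLEAN), nchar(seqs))
  has_err <- logical(length(seqs))
  if (rate > 0) {
    n_err <- rbinom(length(seqs), nchar(seqs), rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(nchar(seqs[i]), n_err[i])
      s <- seqs[i]; q <- qual[i]
      for (p in pos) {
        old <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(DNA_BASES, old), 1L)
        substr(q, p, p) <- int_to_phred(QUAL_ERROR)
      }
      seqs[i] <- s; qual[i] <- q
      has_err[i] <- TRUE
    }
  }
  list(seq = seqs, qual = qual, has_err = has_err)
}

#' Simulate a complete SSR amplicon sequencing dataset
#'
#' Generates loci, per-population allele pools, individual genotypes with
#' dosage, and tagged paired-end reads with the simulated noise structure
#' (sequencing errors, one-unit stutter, single-breakpoint PCR recombinants,
#' optionally cross-set recombinants). Reads have the on-wire structure
#' `tag(10) + forward_primer + insert + revcomp(reverse_primer) +
#' revcomp(tag)`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `reads_R1.fastq`,
#'   `reads_R2.fastq`, `merged.fastq`, `loci.tsv`, `samples.tsv`, `pops.tsv`,
#'   `truth_genotypes.tsv` and `read_labels.tsv`.
#' @return a list with elements `reads` (data.frame: `read_id, template,
#'   qual, r1, q1, r2, q2, pool_id`), `loci` (list of [locus_spec()]),
#'   `sample_sheet`, `pop_map`, and `truth` (list: `catalog`, `genotypes`,
#'   `read_labels`).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)

  # locus scaffolds: primers and per-set tags with safe pairwise distances
  n_keys <- cfg$n_loci * (2L + cfg$n_sets)
  keys <- random_keyset(n_keys, 20L)
  primers_f <- substr(keys[seq_len(cfg$n_loci)], 1, 20)
  primers_r <- substr(keys[cfg$n_loci + seq_len(cfg$n_loci)], 1, 20)
  tag_pool <- substr(keys[2L * cfg$n_loci + seq_len(cfg$n_loci * cfg$n_sets)],
                     1, 10)
  pools <- lapply(seq_len(cfg$n_loci), function(i) {
    bcs <- setNames(tag_pool[(i - 1L) * cfg$n_sets + seq_len(cfg$n_sets)],
                    sprintf("set%d", seq_len(cfg$n_sets)))
    simulate_locus_pool(cfg, i, bcs)
  })

  # individuals, sets, pools, populations
  n_ind <- cfg$n_populations * cfg$n_individuals_per_pop
  individual_id <- sprintf("ind%03d", seq_len(n_ind))
  population_id <- rep(sprintf("pop%d", seq_len(cfg$n_populations)),
                       each = cfg$n_individuals_per_pop)
  set_id <- sprintf("set%d", rep_len(seq_len(cfg$n_sets), n_ind))
  pool_id <- sprintf("pool%03d", seq_len(n_ind))
  sample_sheet <- data.frame(individual_id, set_id, pool_id, population_id,
                             ploidy = cfg$ploidy,
                             replicate_of = NA_character_,
                             stringsAsFactors = FALSE)
  pop_map <- sample_sheet[, c("individual_id", "population_id")]

  # genotypes: ploidy iid draws from the population's allele pool
  geno <- list(); read_rows <- list(); labels <- list()
  read_no <- 0L
  for (li in seq_along(pools)) {
    pl <- pools[[li]]
    fwd <- primers_f[li]; rev <- primers_r[li]
    rc_rev <- revcomp(rev)
    rc_tags <- setNames(revcomp(unname(pl$barcodes)), names(pl$barcodes))
    pool_seqs <- lapply(pl$pools, function(p) vapply(p, parts_seq, character(1)))
    for (ii in seq_len(n_ind)) {
      pop_i <- match(population_id[ii], sprintf("pop%d", seq_len(cfg$n_populations)))
      alleles <- pl$pools[[pop_i]]
      copies <- sample.int(length(alleles), cfg$ploidy, replace = TRUE)
      tab <- table(copies)
      a_idx <- as.integer(names(tab))
      dosage <- as.integer(tab)
      geno[[length(geno) + 1L]] <- data.frame(
        individual_id = individual_id[ii], locus_id = pl$locus_id,
        sequence = pool_seqs[[pop_i]][a_idx], dosage = dosage,
        stringsAsFactors = FALSE)

      tag <- pl$barcodes[[set_id[ii]]]
      rc_tag <- rc_tags[[set_id[ii]]]
      mk_template <- function(insert) {
        paste0(tag, fwd, insert, rc_rev, rc_tag)
      }
      counts <- pmax(
        rnbinom(length(a_idx), size = cfg$coverage_dispersion,
                mu = cfg$mean_reads_per_allele * dosage),
        ceiling(0.5 * cfg$mean_reads_per_allele * dosage))
      for (k in seq_along(a_idx)) {
        n_reads <- counts[k]
        if (n_reads == 0L) next
        src <- alleles[[a_idx[k]]]
        u <- runif(n_reads)
        p_rec <- cfg$recombinant_fraction
        p_cross <- cfg$cross_set_recombinant_fraction
        p_stut <- cfg$stutter_fraction
        kind <- rep("clean", n_reads)
        kind[u < p_rec & length(a_idx) > 1L] <- "recombinant"
        kind[u >= p_rec & u < p_rec + p_cross] <- "cross_recombinant"
        kind[u >= p_rec + p_cross & u < p_rec + p_cross + p_stut] <- "stutter"
        inserts <- character(n_reads)
        clean_seq <- parts_seq(src)
        inserts[kind == "clean"] <- clean_seq
        for (r in which(kind == "recombinant")) {
          other <- alleles[[resample(setdiff(a_idx, a_idx[k]))]]
          sa <- clean_seq; sb <- parts_seq(other)
          if (runif(1) < 0.5) { tmp <- sa; sa <- sb; sb <- tmp }
          bp <- sample.int(min(nchar(sa), nchar(sb)) - 1L, 1L)
          inserts[r] <- paste0(substr(sa, 1L, bp),
                               substr(sb, bp + 1L, nchar(sb)))
        }
        for (r in which(kind == "stutter")) {
          st <- src
          st$n_units <- max(1L, st$n_units + sample(c(-1L, 1L), 1L))
          inserts[r] <- parts_seq(st)
        }
        # cross-set recombinants: 3' half from an individual of another set
        cross_rows <- which(kind == "cross_recombinant")
        templates <- character(n_reads)
        templates[kind != "cross_recombinant"] <-
          mk_template(inserts[kind != "cross_recombinant"])
        for (r in cross_rows) {
          other_set <- resample(setdiff(names(pl$barcodes), set_id[ii]))
          t_a <- mk_template(clean_seq)
          t_b <- paste0(pl$barcodes[[other_set]], fwd, clean_seq,
                        rc_rev, rc_tags[[other_set]])
          bp <- sample(30L:(min(nchar(t_a), nchar(t_b)) - 30L), 1L)
          templates[r] <- paste0(substr(t_a, 1L, bp),
                                 substr(t_b, bp + 1L, nchar(t_b)))
        }
        err <- inject_errors(templates, cfg$seq_error_rate)
        lab <- ifelse(kind == "clean" & err$has_err, "error", kind)
        ids <- sprintf("r%07d", read_no + seq_len(n_reads))
        read_no <- read_no + n_reads
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          read_id = ids, template = err$seq, qual = err$qual,
          pool_id = pool_id[ii], stringsAsFactors = FALSE)
        labels[[length(labels) + 1L]] <- data.frame(
          read_id = ids, individual_id = individual_id[ii],
          locus_id = pl$locus_id, label = lab, stringsAsFactors = FALSE)
      }
    }
  }
  reads <- do.call(rbind, read_rows)
  read_labels <- do.call(rbind, labels)
  genotypes <- do.call(rbind, geno)

  # paired-end views of the tagged template
  rl <- cfg$read_length
  len <- nchar(reads$template)
  reads$r1 <- substr(reads$template, 1L, pmin(rl, len))
  reads$q1 <- substr(reads$qual, 1L, pmin(rl, len))
  reads$r2 <- revcomp(substr(reads$template, pmax(1L, len - rl + 1L), len))
  reads$q2 <- vapply(substr(reads$qual, pmax(1L, len - rl + 1L), len),
                     function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                     character(1), USE.NAMES = FALSE)

  loci <- lapply(pools, function(pl) {
    ref <- pl$ref
    s <- nchar(ref$left)
    locus_spec(pl$locus_id, "simsp", primers_f[match(pl$locus_id,
                 vapply(pools, `[[`, "", "locus_id"))],
               primers_r[match(pl$locus_id,
                 vapply(pools, `[[`, "", "locus_id"))],
               pl$barcodes, parts_seq(ref),
               matrix(c(s, s + nchar(ref$motif) * ref$n_units), ncol = 2),
               pl$motif)
  })

  catalog <- allele_catalog(genotypes$locus_id, genotypes$sequence)
  key <- paste(catalog$locus_id, catalog$sequence, sep = "\r")
  genotypes$allele_id <- catalog$allele_id[
    match(paste(genotypes$locus_id, genotypes$sequence, sep = "\r"), key)]

  out <- list(reads = reads, loci = loci, sample_sheet = sample_sheet,
              pop_map = pop_map,
              truth = list(catalog = catalog, genotypes = genotypes,
                           read_labels = read_labels))
  if (!is.null(out_dir)) write_sim_dataset(out, out_dir)
  out
}

write_fastq <- function(ids, seqs, quals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids)) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  }
  invisible(path)
}

#' Write a simulated dataset to disk
#' @param sim result of [simulate_dataset()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- paste0(sim$reads$read_id, " pool=", sim$reads$pool_id)
  write_fastq(ids, sim$reads$r1, sim$reads$q1,
              file.path(out_dir, "reads_R1.fastq"))
  write_fastq(ids, sim$reads$r2, sim$reads$q2,
              file.path(out_dir, "reads_R2.fastq"))
  write_fastq(ids, sim$reads$template, sim$reads$qual,
              file.path(out_dir, "merged.fastq"))
  write_locus_table(sim$loci, file.path(out_dir, "loci.tsv"))
  write.table(sim$sample_sheet, file.path(out_dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$pop_map, file.path(out_dir, "pops.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genotypes, file.path(out_dir, "truth_genotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$read_labels, file.path(out_dir, "read_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Size homoplasy of the simulated truth alleles
#'
#' Applies the same fragment-length-class computation as [size_homoplasy()]
#' to the ground-truth allele catalog, giving the reference table that a
#' correct end-to-end run must reproduce.
#'
#' @param truth `truth` element of [simulate_dataset()] output.
#' @return data.frame as from [homoplasy_table()].
#' @export
truth_homoplasy <- function(truth) {
  homoplasy_table(truth$catalog)
}

#' Simulate a coded genotype dataset directly (no reads)
#'
#' Draws allele copies at one locus for a stratified sample of individuals,
#' for calibrating the diversity and differentiation estimators without the
#' expense of read-level simulation. Each distinct allele carries a size (in
#' bp). Under `mode = "null_iam"` sizes are assigned to alleles at random,
#' so allele size carries no population signal beyond identity (the null of
#' the allele-size permutation test); allele frequencies may still differ
#' between populations when `fst_like > 0`. Under `mode = "smm"`,
#' population-specific stepwise shifts are added to the sizes.
#'
#' @param n_pops,n_ind_per_pop,ploidy sampling design.
#' @param n_alleles distinct alleles at the locus.
#' @param unit repeat unit length in bp (size step).
#' @param mode `"null_iam"` or `"smm"`.
#' @param fst_like Dirichlet-style concentration contrast between population
#'   allele frequencies (0 = identical frequencies).
#' @param shift stepwise units separating consecutive populations under
#'   `"smm"`.
#' @return data.frame `individual_id, population_id, locus, code, size,
#'   dosage` (one row per distinct allele per individual).
#' @export
simulate_coded_locus <- function(n_pops = 2L, n_ind_per_pop = 20L,
                                 ploidy = 2L, n_alleles = 6L, unit = 3L,
                                 mode = c("null_iam", "smm"),
                                 fst_like = 0.3, shift = 4L) {
  mode <- match.arg(mode)
  sizes <- if (mode == "smm") {
    # tight stepwise ladder so the between-population shift dominates
    300L + unit * sample(seq_len(n_alleles))
  } else {
    300L + unit * sample.int(3L * n_alleles, n_alleles)
  }
  base_freq <- rexp(n_alleles) + 0.2
  rows <- list()
  for (pp in seq_len(n_pops)) {
    freq <- base_freq * exp(fst_like * rnorm(n_alleles))
    freq <- freq / sum(freq)
    for (ii in seq_len(n_ind_per_pop)) {
      copies <- sample.int(n_alleles, ploidy, replace = TRUE, prob = freq)
      tab <- table(copies)
      code <- as.integer(names(tab))
      size <- sizes[code]
      if (mode == "smm") size <- size + (pp - 1L) * shift * unit
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("p%d_i%03d", pp, ii),
        population_id = sprintf("pop%d", pp),
        locus = "locA",
        code = if (mode == "smm") code + (pp - 1L) * 1000L else code,
        size = size, dosage = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
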