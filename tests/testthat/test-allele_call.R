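# Independent enumeration oracle for dosage: score every composition of the
# ploidy with dmultinom and return the best (ties to the most even).
oracle_dosage <- function(counts, ploidy) {
  k <- length(counts)
  grid <- expand.grid(rep(list(seq_len(ploidy)), k))
  grid <- grid[rowSums(grid) == ploidy, , drop = FALSE]
  ll <- apply(grid, 1L, function(d) {
    stats::dmultinom(counts, prob = d / ploidy, log = TRUE)
  })
  best <- which(ll == max(ll))
  if (length(best) > 1L) {
    v <- apply(grid[best, , drop = FALSE], 1L, var)
    v[is.na(v)] <- 0
    best <- best[v == min(v)]
  }
  if (length(best) > 1L) {
    ord <- do.call(order, c(lapply(grid[best, , drop = FALSE],
                                   function(col) -col),
                            list(method = "radix")))
    best <- best[ord[1]]
  }
  unname(as.integer(grid[best, ]))
}

test_that("read clustering groups haplotypes and absorbs sub-1% noise", {
  set.seed(61)
  a <- rand_dna(300)
  ct <- cluster_reads(rep(a, 100))
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$read_count, 100L)

  # single-SNP read at 1/101 of the allele's reads is absorbed
  a_err <- snp_at(a, 150, setdiff(c("A", "C", "G", "T"),
                                  substr(a, 150, 150))[1])
  ct2 <- cluster_reads(c(rep(a, 100), a_err))
  expect_equal(nrow(ct2), 1L)
  expect_equal(ct2$read_count, 101L)
  expect_equal(ct2$sequence, a)

  # two alleles three SNPs apart at 50/50 both stand
  b <- a
  for (p in c(50L, 150L, 250L)) {
    b <- snp_at(b, p, setdiff(c("A", "C", "G", "T"), substr(b, p, p))[1])
  }
  ct3 <- cluster_reads(c(rep(a, 50), rep(b, 50)))
  expect_equal(nrow(ct3), 2L)
  expect_equal(ct3$read_count, c(50L, 50L))

  expect_equal(nrow(cluster_reads(character(0))), 0L)
})

test_that("clustering matches a brute-force grouping oracle on small bins", {
  set.seed(62)
  for (rep_i in 1:10) {
    base <- rand_dna(200)
    k <- sample(2:3, 1)
    alleles <- base
    while (length(alleles) < k) {
      cand <- base
      for (p in sample(200, 4)) {
        cand <- snp_at(cand, p, sample(setdiff(c("A", "C", "G", "T"),
                                               substr(cand, p, p)), 1))
      }
      alleles <- unique(c(alleles, cand))
    }
    counts <- sample(120:200, k)  # one noise read stays below the 1% rule
    reads <- rep(alleles, counts)
    # one noise read per allele: single SNP, guaranteed < 1%
    for (j in seq_len(k)) {
      noisy <- snp_at(alleles[j], j,
                      sample(setdiff(c("A", "C", "G", "T"),
                                     substr(alleles[j], j, j)), 1))
      reads <- c(reads, noisy)
    }
    ct <- cluster_reads(sample(reads))
    expect_equal(nrow(ct), k)
    expect_setequal(ct$sequence, alleles)
    expect_equal(sum(ct$read_count), length(reads))
  }
})

test_that("exact single-breakpoint joins of two abundant contigs are chimeras", {
  set.seed(63)
  a <- rand_dna(300)
  b <- a
  for (p in c(40L, 260L)) {
    b <- snp_at(b, p, setdiff(c("A", "C", "G", "T"), substr(b, p, p))[1])
  }
  chi <- paste0(substr(a, 1, 150), substr(b, 151, 300))
  contigs <- data.frame(sequence = c(a, b, chi),
                        read_count = c(90L, 80L, 10L),
                        status = "candidate", stringsAsFactors = FALSE)
  out <- detect_chimeras(contigs)
  expect_equal(out$status, c("candidate", "candidate", "chimera"))

  # with only two contigs nothing can be flagged
  out2 <- detect_chimeras(contigs[1:2, ])
  expect_true(all(out2$status == "candidate"))

  # a contig above its would-be parents is never flagged
  contigs3 <- contigs
  contigs3$read_count <- c(90L, 80L, 95L)
  expect_true(all(detect_chimeras(contigs3)$status == "candidate"))
})

test_that("surviving recombinant contigs are flagged on no-error simulations", {
  sim <- simulate_dataset(sim_config(
    seed = 64, n_loci = 3L, n_individuals_per_pop = 8L,
    mean_reads_per_allele = 60L, seq_error_rate = 0,
    recombinant_fraction = 0.08, stutter_fraction = 0))
  res <- run_sim_pipeline(sim)
  dbg <- res$calls$contig_debug
  truth_seqs <- split(sim$truth$genotypes$sequence,
                      paste(sim$truth$genotypes$individual_id,
                            sim$truth$genotypes$locus_id, sep = "\r"))
  for (i in seq_len(nrow(dbg))) {
    cell_truth <- truth_seqs[[paste(dbg$individual_id[i], dbg$locus_id[i],
                                    sep = "\r")]]
    if (dbg$status[i] == "chimera") {
      expect_false(dbg$sequence[i] %in% cell_truth)
    }
    if (dbg$sequence[i] %in% cell_truth) {
      expect_true(dbg$status[i] %in% c("allele", "candidate"))
    }
  }
  expect_gt(sum(dbg$status == "chimera"), 0L)
})

test_that("genotype calls follow the coverage rules", {
  set.seed(65)
  a <- rand_dna(300)
  b <- snp_at(a, 100, setdiff(c("A", "C", "G", "T"), substr(a, 100, 100))[1])
  mk <- function(seqs, counts) {
    data.frame(sequence = seqs, read_count = counts, status = "candidate",
               stringsAsFactors = FALSE)
  }
  het <- call_genotype(mk(c(a, b), c(120L, 110L)), ploidy = 2L)
  expect_equal(het$dosages, c(1L, 1L))
  expect_setequal(het$alleles, c(a, b))

  hom <- call_genotype(mk(a, 200L), ploidy = 2L)
  expect_equal(hom$dosages, 2L)

  # second contig below the 10-read threshold: homozygote call
  weak <- call_genotype(mk(c(a, b), c(120L, 8L)), ploidy = 2L)
  expect_equal(weak$alleles, a)
  expect_equal(weak$dosages, 2L)

  none <- call_genotype(mk(c(a, b), c(6L, 4L)), ploidy = 2L)
  expect_true(all(c("missing", "low_coverage") %in% none$flags))

  # one-repeat-unit neighbour at 3% of the allele is stutter, at 8% an allele
  a_minus <- paste0(substr(a, 1, 297))
  st <- call_genotype(mk(c(a, a_minus), c(1000L, 30L)), ploidy = 2L,
                      unit_length = 3L)
  expect_equal(st$alleles, a)
  expect_equal(st$contigs$status[2], "stutter_suspect")
  st2 <- call_genotype(mk(c(a, a_minus), c(1000L, 80L)), ploidy = 2L,
                       unit_length = 3L)
  expect_setequal(st2$alleles, c(a, a_minus))

  # more qualifying contigs than the ploidy: paralog suspect, top kept
  c_ <- snp_at(a, 200, setdiff(c("A", "C", "G", "T"), substr(a, 200, 200))[1])
  par <- call_genotype(mk(c(a, b, c_), c(120L, 110L, 100L)), ploidy = 2L)
  expect_true("paralog_suspect" %in% par$flags)
  expect_length(par$alleles, 2L)
})

test_that("dosage estimation equals the exhaustive-composition oracle", {
  expect_equal(estimate_dosage(c(75L, 25L), 4L), c(3L, 1L))
  expect_equal(estimate_dosage(c(50L, 25L, 25L), 4L), c(2L, 1L, 1L))
  expect_equal(estimate_dosage(c(52L, 48L), 4L), c(2L, 2L))
  expect_equal(estimate_dosage(200L, 2L), 2L)
  set.seed(66)
  for (i in 1:60) {
    k <- sample(1:4, 1)
    counts <- as.integer(sample(5:200, k, replace = TRUE))
    expect_equal(estimate_dosage(counts, 4L), oracle_dosage(counts, 4L),
                 info = paste(counts, collapse = ","))
  }
})

test_that("QC filters drop loci and individuals at the documented thresholds", {
  inds <- sprintf("i%03d", 1:100)
  loci <- sprintf("L%02d", 1:20)
  calls <- expand.grid(individual_id = inds, locus_id = loci,
                       stringsAsFactors = FALSE)
  calls$n_alleles <- 2L
  calls$total_reads <- 100L
  calls$flags <- ""
  # L01 missing in 11 of 100 individuals (> 10%)
  calls$flags[calls$locus_id == "L01" &
                calls$individual_id %in% inds[1:11]] <- "missing"
  # i001 additionally missing in 7 of the 20 loci (35% > 30%)
  calls$flags[calls$individual_id == "i001" &
                calls$locus_id %in% loci[2:8]] <- "missing"
  qc <- qc_filters(calls, inds, loci)
  expect_false("L01" %in% qc$keep_loci)
  expect_false("i001" %in% qc$keep_individuals)
  expect_true(all(setdiff(loci, "L01") %in% qc$keep_loci))
  expect_true(all(setdiff(inds, "i001") %in% qc$keep_individuals))
  expect_setequal(qc$exclusions$id, c("i001", "L01"))

  # a clean dataset loses nothing
  calls$flags <- ""
  qc2 <- qc_filters(calls, inds, loci)
  expect_equal(qc2$keep_loci, loci)
  expect_equal(qc2$keep_individuals, inds)
  expect_equal(nrow(qc2$exclusions), 0L)
})
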