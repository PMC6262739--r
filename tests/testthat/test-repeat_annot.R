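# Brute-force tandem-repeat scan, independent of the rle-based
# implementation: extend a candidate unit from every start position.
oracle_ssrs <- function(seq, unit_range = c(3L, 6L), min_len = 21L) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  prim_period <- function(ch) {
    for (p in seq_len(length(ch) - 1L)) {
      if (all(ch[seq_len(length(ch) - p)] == ch[(p + 1L):length(ch)])) {
        return(p)
      }
    }
    length(ch)
  }
  hits <- list()
  for (u in unit_range[1]:unit_range[2]) {
    s <- 1L
    while (s + u <= n) {
      e <- s + u  # extend while x[e] continues the tandem
      while (e <= n && x[e] == x[e - u]) e <- e + 1L
      run_len <- e - s
      if (run_len >= min_len && run_len > u) {
        region <- x[s:(e - 1L)]
        if (prim_period(region) == u) {
          hits[[length(hits) + 1L]] <- data.frame(
            start = s - 1L, end = e - 1L,
            unit = ssrseq:::canonical_rotation(
              paste(region[1:u], collapse = "")),
            n_units = run_len %/% u, length = run_len,
            stringsAsFactors = FALSE)
        }
        s <- e  # jump past the maximal run
      } else {
        s <- s + 1L
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), n_units = integer(),
                      length = integer()))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

test_that("find_ssrs honours the length and unit-size boundaries", {
  set.seed(71)
  flank <- function() rand_dna(40)
  hit <- find_ssrs(paste0("TTGGTTGGAA", strrep("CAC", 7), "TTAAGGTTAA"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, 21L)
  expect_equal(hit$n_units, 7L)
  expect_equal(hit$unit, "ACC")  # canonical rotation of CAC

  expect_equal(nrow(find_ssrs(paste0("TTGGAA", strrep("CAC", 6), "TTGGAA"))),
               0L)  # 18 bp, below the 21 bp minimum
  expect_equal(nrow(find_ssrs(strrep("CA", 15))), 0L)  # dinucleotide
  expect_equal(nrow(find_ssrs(paste0("TAGGC", strrep("TTCTGA", 4), "AGGCT"))),
               1L)  # 24 bp hexanucleotide
})

test_that("find_ssrs agrees with the brute-force oracle on random strings", {
  set.seed(72)
  for (i in 1:15) {
    parts <- rand_dna(120)
    if (i %% 3 == 0) {
      parts <- paste0(parts, strrep("GAT", sample(6:12, 1)), rand_dna(80))
    }
    if (i %% 3 == 1) {
      parts <- paste0(parts, strrep("TTAAGC", sample(3:6, 1)), rand_dna(80),
                      strrep("CCG", 8), rand_dna(60))
    }
    got <- find_ssrs(parts)
    want <- oracle_ssrs(parts)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("annotation projects SSR regions through indels correctly", {
  loc <- make_locus("locA", seed = 73)           # flanks 30bp, (CAC) x 8
  ref <- loc$reference_seq

  ident <- annotate_allele(ref, loc)
  expect_equal(ident$ssr_lengths, 24L)
  expect_false(ident$paralog_suspect)

  left <- substr(ref, 1, 30); right <- substr(ref, 55, nchar(ref))
  plus_unit <- paste0(left, strrep("CAC", 9), right)
  expect_equal(annotate_allele(plus_unit, loc)$ssr_lengths, 27L)

  minus9 <- paste0(substr(left, 1, 21), strrep("CAC", 8), right)
  ann9 <- annotate_allele(minus9, loc)
  expect_equal(ann9$ssr_lengths, 24L)  # flank deletion leaves the SSR alone
  expect_equal(nchar(minus9), nchar(ref) - 9L)

  # an unrelated sequence is a paralog suspect, not annotated
  set.seed(74)
  far <- rand_dna(nchar(ref))
  expect_true(annotate_allele(far, loc)$paralog_suspect)
})

test_that("the three coding schemes key on the documented equivalences", {
  loc <- make_locus("locA", seed = 75)
  ref <- loc$reference_seq
  a2 <- snp_at(ref, 5, setdiff(c("A", "C", "G", "T"),
                               substr(ref, 5, 5))[1])  # same length, 1 SNP
  left <- substr(ref, 1, 30); right <- substr(ref, 55, nchar(ref))
  a3 <- paste0(left, strrep("CAC", 9), right)          # one more unit

  catalog <- allele_catalog(rep("locA", 3), c(ref, a2, a3))
  catalog <- annotate_catalog(catalog, list(loc))
  geno <- data.frame(
    individual_id = c("i1", "i1", "i2", "i2"), locus_id = "locA",
    allele_id = catalog$allele_id[match(c(ref, a2, ref, a3),
                                        catalog$sequence)],
    dosage = 1L, stringsAsFactors = FALSE)
  coded <- code_datasets(catalog, geno)

  # ref and a2: same fragment code, different sequence codes
  i1 <- coded$fragment_length[coded$fragment_length$individual_id == "i1", ]
  expect_equal(length(unique(i1$code)), 1L)
  i1s <- coded$sequence_identity[
    coded$sequence_identity$individual_id == "i1", ]
  expect_equal(length(unique(i1s$code)), 2L)
  # allele counts per scheme match hand enumeration
  expect_equal(length(unique(coded$sequence_identity$code)), 3L)
  expect_equal(length(unique(coded$fragment_length$code)), 2L)
  expect_equal(length(unique(coded$ssr_length$code)), 2L)
  # SSR-length sizes are the repeat-region lengths
  expect_setequal(unique(coded$ssr_length$size), c(24L, 27L))
})

test_that("a two-region locus splits into sub-loci in the SSR-length scheme only", {
  loc1 <- make_locus("locT", seed = 76)
  ref2 <- paste0(loc1$reference_seq, strrep("GAT", 8), "CCTTAACCGGTT")
  loc <- locus_spec("locT", "testsp", loc1$forward_primer,
                    loc1$reverse_primer, loc1$barcodes, ref2,
                    rbind(loc1$ssr_regions,
                          c(nchar(loc1$reference_seq),
                            nchar(loc1$reference_seq) + 24L)),
                    c(loc1$ssr_motifs, "GAT"))
  left <- substr(ref2, 1, 30)
  tail2 <- substr(ref2, 55, nchar(ref2))
  alt <- paste0(left, strrep("CAC", 9), tail2)
  catalog <- annotate_catalog(allele_catalog(rep("locT", 2),
                                             c(ref2, alt)), list(loc))
  geno <- data.frame(individual_id = "i1", locus_id = "locT",
                     allele_id = catalog$allele_id, dosage = 1L)
  coded <- code_datasets(catalog, geno)
  expect_setequal(unique(coded$ssr_length$locus), c("locT_a", "locT_b"))
  expect_equal(unique(coded$fragment_length$locus), "locT")
  expect_equal(unique(coded$sequence_identity$locus), "locT")
})

test_that("variable-site bookkeeping satisfies its identity on constructed loci", {
  loc <- make_locus("locA", seed = 77)
  ref <- loc$reference_seq
  left <- substr(ref, 1, 30); right <- substr(ref, 55, nchar(ref))
  other <- function(s, p) setdiff(c("A", "C", "G", "T"),
                                  substr(s, p, p))[1]

  # five flank SNPs across alleles + variable repeat count -> 6 sites
  a2 <- snp_at(snp_at(ref, 3, other(ref, 3)), 10, other(ref, 10))
  a3 <- paste0(snp_at(left, 20, other(left, 20)), strrep("CAC", 9),
               snp_at(snp_at(right, 5, other(right, 5)), 15,
                      other(right, 15)))
  vs <- count_variable_sites(c(ref, a2, a3), loc)
  expect_equal(vs$n_snps, 5L)
  expect_equal(vs$n_indels, 0L)
  expect_true(vs$ssr_count_variable)
  expect_equal(vs$n_variable_sites, 6L)
  expect_false(vs$mutated_motif)

  # identical alleles -> all-zero summary
  vs0 <- count_variable_sites(c(ref, ref), loc)
  expect_equal(vs0$n_variable_sites, 0L)

  # two SNPs + one 9 bp flank indel, constant repeats -> 3 sites
  b2 <- snp_at(snp_at(ref, 7, other(ref, 7)), 12, other(ref, 12))
  b3 <- paste0(left, strrep("CAC", 8),
               paste0(substr(right, 1, 10), substr(right, 20, 30)))
  vs2 <- count_variable_sites(c(ref, b2, b3), loc)
  expect_equal(vs2$n_snps, 2L)
  expect_equal(vs2$n_indels, 1L)
  expect_equal(vs2$indel_lengths[[1]], 9L)
  expect_false(vs2$ssr_count_variable)
  expect_equal(vs2$n_variable_sites, 3L)

  # a repeat interrupted by a substitution marks the motif as mutated
  m <- paste0(left, "CAC CAC CAC CAT CAC CAC CAC CAC", right)
  m <- gsub(" ", "", m)
  vsm <- count_variable_sites(c(ref, m), loc)
  expect_true(vsm$mutated_motif)
  expect_equal(vsm$n_variable_sites,
               vsm$n_snps + vsm$n_indels + as.integer(vsm$ssr_count_variable))
})

test_that("scheme allele counts are ordered sequence >= fragment >= SSR on simulations", {
  sim <- small_sim(seed = 78)
  catalog <- annotate_catalog(sim$truth$catalog, sim$loci)
  coded <- code_datasets(catalog, sim$truth$genotypes)
  n_codes <- function(ds) {
    tapply(ds$code, sub("_[ab]$", "", ds$locus),
           function(x) length(unique(x)))
  }
  ns <- n_codes(coded$sequence_identity)
  nf <- n_codes(coded$fragment_length)
  nl <- n_codes(coded$ssr_length)
  for (lc in names(ns)) {
    expect_gte(ns[[lc]], nf[[lc]])
    expect_gte(ns[[lc]], nl[[lc]])
  }
})

test_that("coding is invariant to allele input order", {
  sim <- small_sim(seed = 79)
  catalog <- annotate_catalog(sim$truth$catalog, sim$loci)
  coded1 <- code_datasets(catalog, sim$truth$genotypes)
  perm <- sample.int(nrow(sim$truth$genotypes))
  coded2 <- code_datasets(catalog, sim$truth$genotypes[perm, ])
  for (scheme in names(coded1)) {
    a <- coded1[[scheme]][order(coded1[[scheme]]$individual_id,
                                coded1[[scheme]]$locus,
                                coded1[[scheme]]$code), ]
    b <- coded2[[scheme]][order(coded2[[scheme]]$individual_id,
                                coded2[[scheme]]$locus,
                                coded2[[scheme]]$code), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})
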