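# Independent variance-component oracle working directly on copy-level
# indicator/size vectors (sums of squares route, no shared code with the
# package's per-allele accumulation).
oracle_components <- function(y, pop) {
  pops <- unique(pop)
  n_i <- vapply(pops, function(p) sum(pop == p), numeric(1))
  N <- sum(n_i); r <- length(pops)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  gm <- mean(y)
  means <- vapply(pops, function(p) mean(y[pop == p]), numeric(1))
  msa <- sum(n_i * (means - gm)^2) / (r - 1)
  msw <- sum((y - means[match(pop, pops)])^2) / (N - r)
  sa <- (msa - msw) / nc
  c(num = sa, den = sa + msw)
}

oracle_fst <- function(tab) {
  pops <- rep(rownames(tab), rowSums(tab))
  codes <- unlist(lapply(rownames(tab), function(p) {
    rep(colnames(tab), tab[p, ])
  }))
  comp <- vapply(unique(codes), function(a) {
    oracle_components(as.numeric(codes == a), pops)
  }, numeric(2))
  sum(comp["num", ]) / sum(comp["den", ])
}

test_that("gene diversity matches Nei's closed forms", {
  expect_equal(nei_He(c(2, 2)), 2 / 3 * (1 - 0.5) * 2, tolerance = 1e-12)
  expect_equal(nei_He(c(2, 2)), 4 / 3 * 0.5)
  expect_equal(nei_He(c(1, 1, 1, 1)), 1)
  expect_equal(nei_He(c(10)), 0)            # monomorphic
  expect_error(nei_He(c(1)), "undefined")
})

test_that("observed heterozygosity enumerates within-individual copy pairs", {
  dip <- data.frame(individual_id = rep(c("a", "b"), each = 1),
                    locus = "L", code = c(1L, 1L), dosage = 2L)
  expect_equal(observed_Ho(dip, "L"), 0)
  dip2 <- data.frame(individual_id = rep(c("a", "b"), each = 2), locus = "L",
                     code = c(1L, 2L, 1L, 3L), dosage = 1L)
  expect_equal(observed_Ho(dip2, "L"), 1)
  tet <- data.frame(individual_id = c("t", "t"), locus = "L",
                    code = c(1L, 2L), dosage = c(3L, 1L))
  expect_equal(observed_Ho(tet, "L"), 0.5)    # 3 differing of 6 pairs
  tet2 <- data.frame(individual_id = c("t", "t"), locus = "L",
                     code = c(1L, 2L), dosage = c(2L, 2L))
  expect_equal(observed_Ho(tet2, "L"), 4 / 6)
})

test_that("ANOVA FST reaches its boundary cases and matches the oracle", {
  fixed <- matrix(c(50L, 0L, 0L, 50L), 2, 2,
                  dimnames = list(c("p1", "p2"), c("1", "2")))
  expect_equal(anova_fst(fixed)$fst, 1)

  same <- matrix(c(120L, 80L, 120L, 80L), 2, 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("1", "2")))
  expect_lt(abs(anova_fst(same)$fst), 0.02)

  set.seed(91)
  for (i in 1:8) {
    k <- sample(2:5, 1)
    tab <- matrix(rpois(2 * k, 20) + 1L, 2, k,
                  dimnames = list(c("p1", "p2"), as.character(seq_len(k))))
    expect_equal(anova_fst(tab)$fst, oracle_fst(tab), tolerance = 1e-12)
  }
  expect_error(anova_fst(matrix(1:3, 1)), "2 populations")
})

test_that("ANOVA RST responds to size structure and matches the oracle", {
  expect_equal(anova_rst(c(rep(300, 20), rep(330, 20)),
                         rep(c("a", "b"), each = 20))$rst, 1)
  set.seed(92)
  sizes <- sample(c(300, 303, 306, 309), 400, replace = TRUE)
  shuffled <- anova_rst(sizes, rep(c("a", "b"), each = 200))
  expect_lt(abs(shuffled$rst), 0.02)
  for (i in 1:8) {
    y <- sample(seq(300, 330, by = 3), 60, replace = TRUE)
    pop <- sample(c("a", "b", "c"), 60, replace = TRUE)
    got <- anova_rst(y, pop)
    want <- oracle_components(y, pop)
    expect_equal(got$rst, unname(want["num"] / want["den"]),
                 tolerance = 1e-12)
  }
  expect_error(anova_rst(rep(300, 10), rep(c("a", "b"), 5)), "all sizes")
})

test_that("RST is size-affine invariant and He ignores labels", {
  set.seed(93)
  y <- sample(seq(300, 330, 3), 80, replace = TRUE)
  pop <- rep(c("a", "b"), each = 40)
  r0 <- anova_rst(y, pop)$rst
  expect_equal(anova_rst(y + 57, pop)$rst, r0, tolerance = 1e-12)
  expect_equal(anova_rst(y * 3, pop)$rst, r0, tolerance = 1e-12)
  counts <- c(7, 3, 5)
  expect_equal(nei_He(counts), nei_He(rev(counts)))
})

test_that("the allele-size permutation test is seeded, bounded and calibrated", {
  # two alleles: swapping the two sizes leaves RST unchanged, so every
  # permuted value equals the observed one and p must be exactly 1
  two <- data.frame(individual_id = sprintf("i%02d", 1:20),
                    population_id = rep(c("p1", "p2"), each = 10),
                    locus = "L", code = rep(c(1L, 2L), 10),
                    dosage = 2L, size = rep(c(300L, 312L), 10),
                    stringsAsFactors = FALSE)
  pm <- two[, c("individual_id", "population_id")]
  res <- rst_permutation_test(two, pm, "L", n_perm = 99L, seed = 1L)
  expect_equal(res$p_value, 1)

  d <- simulate_coded_locus(mode = "null_iam")
  pm2 <- d[, c("individual_id", "population_id")]
  expect_error(rst_permutation_test(d, pm2, "locA", n_perm = 200L), "seed")
  r2 <- rst_permutation_test(d, pm2, "locA", n_perm = 200L, seed = 5L)
  r3 <- rst_permutation_test(d, pm2, "locA", n_perm = 200L, seed = 5L)
  expect_identical(r2$permuted, r3$permuted)
  expect_gt(r2$p_value, 0)
  expect_lte(r2$p_value, 1)

  # strong stepwise signal is detected in most replicate simulations
  set.seed(94)
  hits <- replicate(20, {
    ds <- simulate_coded_locus(mode = "smm")
    rst_permutation_test(ds, ds[, c("individual_id", "population_id")],
                         "locA", n_perm = 500L,
                         seed = sample.int(1e6, 1))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.7)
})

test_that("multilocus statistics combine variance components", {
  set.seed(95)
  tab1 <- matrix(c(30L, 10L, 10L, 30L), 2, 2,
                 dimnames = list(c("p1", "p2"), c("1", "2")))
  f1 <- anova_fst(tab1)
  expect_equal(multilocus_ratio(list(f1)), f1$fst)
  expect_equal(multilocus_ratio(list(f1, f1)), f1$fst)
  tab2 <- matrix(c(5L, 35L, 25L, 15L), 2, 2,
                 dimnames = list(c("p1", "p2"), c("1", "2")))
  f2 <- anova_fst(tab2)
  combined <- multilocus_ratio(list(f1, f2))
  expect_equal(combined, (f1$num + f2$num) / (f1$den + f2$den))
  expect_true(combined >= min(f1$fst, f2$fst) &&
                combined <= max(f1$fst, f2$fst))
})

test_that("the per-scheme summary has the expected shape and bounds", {
  set.seed(96)
  d <- simulate_coded_locus(mode = "null_iam", n_alleles = 5L)
  pm <- d[, c("individual_id", "population_id")]
  s <- popgen_summary(d, pm, size_based = TRUE, n_perm = 100L, seed = 2L)
  expect_equal(s$locus, c("all", "locA"))
  expect_true(all(s$He >= 0 & s$He <= 1))
  expect_true(all(s$Ho >= 0 & s$Ho <= 1))
  expect_equal(s$NA_[1], 5L)
  expect_false(is.na(s$p_RST[2]))
  s2 <- popgen_summary(d, pm, size_based = FALSE)
  expect_true(all(is.na(s2$RST)))
})
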