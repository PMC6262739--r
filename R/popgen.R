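# Diversity and differentiation statistics on coded datasets.
#
# FST and RST come from a two-level ANOVA over allele copies (among / within
# populations). FST decomposes allele-indicator variance per allele and sums
# components (Weir & Cockerham family, copy level, no within-individual
# term); RST applies the same decomposition to allele sizes in bp
# (Slatkin-type). Multilocus values combine variance components, not
# per-locus ratios.

#' Per-population allele copy counts at one locus
#'
#' @param coded data.frame `individual_id, locus, code, dosage` (one scheme
#'   of [code_datasets()]), restricted or not to one locus.
#' @param popmap data.frame `individual_id, population_id`.
#' @param locus locus (sub-locus) name to tabulate.
#' @return integer matrix population x allele code; attribute `NA_total`
#'   gives the overall number of distinct alleles.
#' @export
allele_counts <- function(coded, popmap, locus) {
  sub <- coded[coded$locus == locus, , drop = FALSE]
  if (!nrow(sub)) stop("locus not present in dataset: ", locus, call. = FALSE)
  pop <- popmap$population_id[match(sub$individual_id, popmap$individual_id)]
  if (anyNA(pop)) {
    stop("individual(s) missing from population map", call. = FALSE)
  }
  tab <- tapply(sub$dosage, list(pop, sub$code), sum, default = 0L)
  tab <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  empty <- rowSums(tab) == 0L
  if (any(empty)) {
    warning("population(s) without copies excluded: ",
            paste(rownames(tab)[empty], collapse = ", "), call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  attr(tab, "NA_total") <- sum(colSums(tab) > 0L)
  tab
}

#' Nei's gene diversity corrected for sample size
#'
#' `He = n (1 - sum(p_i^2)) / (n - 1)` where `n` is the number of allele
#' copies and `p_i` the allele frequencies.
#'
#' @param counts allele copy counts (one population, or pooled).
#' @return He in `[0, 1]`.
#' @export
nei_He <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) stop("He undefined for fewer than 2 copies", call. = FALSE)
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Observed heterozygosity
#'
#' Diploids: the fraction of individuals whose two allele copies differ.
#' Tetraploids: the mean over individuals of the fraction of the six
#' within-individual copy pairs that differ (so dosage 3:1 scores 0.5).
#' Both reduce to `1 - sum(d_i (d_i - 1)) / (P (P - 1))` per individual
#' with dosages `d_i` and ploidy `P`.
#'
#' @param coded data.frame `individual_id, locus, code, dosage`.
#' @param locus locus name.
#' @return Ho in `[0, 1]`.
#' @export
observed_Ho <- function(coded, locus) {
  sub <- coded[coded$locus == locus, , drop = FALSE]
  if (!nrow(sub)) stop("no non-missing individuals", call. = FALSE)
  per_ind <- vapply(split(sub$dosage, sub$individual_id), function(d) {
    P <- sum(d)
    1 - sum(d * (d - 1)) / (P * (P - 1))
  }, numeric(1))
  mean(per_ind)
}

# Shared ANOVA scaffolding: per-population sizes and the n_c coefficient.
anova_frame <- function(n_i) {
  r <- length(n_i)
  N <- sum(n_i)
  list(r = r, N = N, nc = (N - sum(n_i^2) / N) / (r - 1))
}

#' ANOVA-based FST from a population-by-allele count table
#'
#' Allele-indicator variance is decomposed among/within populations for
#' each allele and the components summed:
#' `FST = sum(sigma2_a) / sum(sigma2_a + sigma2_w)`.
#'
#' @param tab matrix population x allele copy counts (>= 2 populations).
#' @return list `fst, num, den` (components for multilocus combination).
#' @export
anova_fst <- function(tab) {
  n_i <- rowSums(tab)
  if (length(n_i) < 2L) stop("FST needs >= 2 populations", call. = FALSE)
  fr <- anova_frame(n_i)
  num <- 0; den <- 0
  for (k in seq_len(ncol(tab))) {
    p_ik <- tab[, k] / n_i
    pbar <- sum(tab[, k]) / fr$N
    msa <- sum(n_i * (p_ik - pbar)^2) / (fr$r - 1)
    msw <- sum(n_i * p_ik * (1 - p_ik)) / (fr$N - fr$r)
    sa <- (msa - msw) / fr$nc
    num <- num + sa
    den <- den + sa + msw
  }
  list(fst = num / den, num = num, den = den)
}

#' ANOVA-based RST from allele sizes
#'
#' The same among/within decomposition applied to allele sizes (bp), giving
#' a Slatkin-type RST sensitive to stepwise mutation.
#'
#' @param sizes numeric vector of allele sizes, one per copy.
#' @param pop population label per copy.
#' @return list `rst, num, den`.
#' @export
anova_rst <- function(sizes, pop) {
  pop <- as.character(pop)
  if (length(unique(sizes)) < 2L) {
    stop("RST undefined: all sizes equal", call. = FALSE)
  }
  n_i <- tapply(sizes, pop, length)
  if (length(n_i) < 2L) stop("RST needs >= 2 populations", call. = FALSE)
  fr <- anova_frame(as.numeric(n_i))
  ybar_i <- tapply(sizes, pop, mean)
  ybar <- mean(sizes)
  ssa <- sum(n_i * (ybar_i - ybar)^2)
  ssw <- sum((sizes - ybar_i[pop])^2)
  msa <- ssa / (fr$r - 1)
  msw <- ssw / (fr$N - fr$r)
  sa <- (msa - msw) / fr$nc
  list(rst = sa / (sa + msw), num = sa, den = sa + msw)
}

#' Permutation test of RST against the stepwise-mutation null
#'
#' Permutes the size labels among the distinct alleles of the locus (not
#' among copies, so allele frequency structure is preserved), recomputing
#' RST each time. The one-sided p-value is
#' `(1 + #permuted >= observed) / (1 + n_perm)`; under the null that
#' stepwise mutations do not contribute to differentiation, observed RST is
#' exchangeable with the permuted values.
#'
#' @param coded data.frame `individual_id, locus, code, size, dosage` for
#'   one size-based scheme.
#' @param popmap data.frame `individual_id, population_id`.
#' @param locus locus (sub-locus) name.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list `observed_rst, permuted, permuted_mean, p_value, n_perm,
#'   seed`.
#' @export
rst_permutation_test <- function(coded, popmap, locus, n_perm = 10000L,
                                 seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  sub <- coded[coded$locus == locus, , drop = FALSE]
  pop <- popmap$population_id[match(sub$individual_id,
                                    popmap$individual_id)]
  codes <- sort(unique(sub$code))
  if (length(codes) < 2L) {
    stop("permutation test undefined for < 2 distinct alleles",
         call. = FALSE)
  }
  size_of <- vapply(codes, function(cc) sub$size[match(cc, sub$code)],
                    numeric(1))
  copy_allele <- rep(match(sub$code, codes), sub$dosage)
  copy_pop <- rep(pop, sub$dosage)

  # precompute the ANOVA frame once; only sizes change under permutation
  n_i <- tapply(copy_pop, copy_pop, length)
  fr <- anova_frame(as.numeric(n_i))
  pops <- names(n_i)
  pop_idx <- match(copy_pop, pops)
  rst_of <- function(allele_sizes) {
    y <- allele_sizes[copy_allele]
    ybar_i <- vapply(seq_along(pops), function(i) mean(y[pop_idx == i]),
                     numeric(1))
    ssa <- sum(n_i * (ybar_i - mean(y))^2)
    ssw <- sum((y - ybar_i[pop_idx])^2)
    msa <- ssa / (fr$r - 1)
    msw <- ssw / (fr$N - fr$r)
    sa <- (msa - msw) / fr$nc
    sa / (sa + msw)
  }
  observed <- rst_of(size_of)
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(i) {
    rst_of(size_of[sample.int(length(size_of))])
  }, numeric(1))
  list(observed_rst = observed, permuted = permuted,
       permuted_mean = mean(permuted),
       p_value = (1 + sum(permuted >= observed)) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

#' Combine per-locus variance components into multilocus statistics
#'
#' Multilocus FST/RST are ratios of summed numerator and denominator
#' components across loci; NA is summed; He and Ho are averaged over loci.
#'
#' @param components list of per-locus lists with `num` and `den` (from
#'   [anova_fst()] or [anova_rst()]).
#' @return the combined ratio.
#' @export
multilocus_ratio <- function(components) {
  num <- sum(vapply(components, `[[`, numeric(1), "num"))
  den <- sum(vapply(components, `[[`, numeric(1), "den"))
  num / den
}

#' Full diversity/differentiation summary for one coded dataset
#'
#' Per locus and multilocus ("all") rows: number of alleles NA, Nei's He on
#' the pooled sample, observed heterozygosity Ho, ANOVA FST, and for
#' size-based schemes RST with its allele-size permutation p-value.
#'
#' @param coded one scheme from [code_datasets()].
#' @param popmap data.frame `individual_id, population_id`.
#' @param size_based whether the scheme's codes carry sizes (RST defined).
#' @param n_perm,seed permutation settings; `n_perm = 0` skips the test.
#' @return data.frame, one row per locus plus an `all` row.
#' @export
popgen_summary <- function(coded, popmap, size_based = TRUE,
                           n_perm = 10000L, seed = 1L) {
  loci <- sort(unique(coded$locus))
  fst_comp <- list(); rst_comp <- list()
  rows <- list()
  for (lc in loci) {
    tab <- allele_counts(coded, popmap, lc)
    na_tot <- attr(tab, "NA_total")
    he <- nei_He(colSums(tab))
    ho <- observed_Ho(coded, lc)
    fst <- tryCatch(anova_fst(tab), error = function(e) NULL)
    if (!is.null(fst) && is.finite(fst$fst)) fst_comp[[lc]] <- fst
    rst <- NULL; p_rst <- NA_real_
    if (size_based) {
      sub <- coded[coded$locus == lc, , drop = FALSE]
      pop <- popmap$population_id[match(sub$individual_id,
                                        popmap$individual_id)]
      sizes <- rep(sub$size, sub$dosage)
      pops <- rep(pop, sub$dosage)
      rst <- tryCatch(anova_rst(sizes, pops), error = function(e) NULL)
      if (!is.null(rst) && is.finite(rst$rst)) {
        rst_comp[[lc]] <- rst
        if (n_perm > 0L) {
          p_rst <- rst_permutation_test(coded, popmap, lc, n_perm,
                                        seed)$p_value
        }
      }
    }
    rows[[lc]] <- data.frame(
      locus = lc, NA_ = na_tot, He = he, Ho = ho,
      FST = if (is.null(fst)) NA_real_ else fst$fst,
      RST = if (is.null(rst)) NA_real_ else rst$rst,
      p_RST = p_rst, stringsAsFactors = FALSE)
  }
  per_locus <- do.call(rbind, rows)
  all_row <- data.frame(
    locus = "all", NA_ = sum(per_locus$NA_),
    He = mean(per_locus$He), Ho = mean(per_locus$Ho),
    FST = if (length(fst_comp)) multilocus_ratio(fst_comp) else NA_real_,
    RST = if (length(rst_comp)) multilocus_ratio(rst_comp) else NA_real_,
    p_RST = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(all_row, per_locus)
  rownames(out) <- NULL
  out
}
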