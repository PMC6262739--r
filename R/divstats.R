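# Descriptive statistics: size homoplasy, rare alleles, replicate error.

#' Size homoplasy of one locus
#'
#' Alleles are grouped into fragment-length classes; a class is homoplasious
#' when it contains at least two distinct sequences (alleles identical in
#' state by size but not by sequence). The percentage is
#' `100 * n_homoplasious / n_size_classes`. Computed on the catalog of
#' observed alleles (presence, not frequency): adding a further sequence
#' variant to an already-homoplasious class does not change the value.
#'
#' @param fragment_lengths integer vector, one per distinct allele.
#' @param sequences character vector parallel to `fragment_lengths`.
#' @return list `n_size_classes, n_homoplasious, percent`.
#' @export
size_homoplasy <- function(fragment_lengths, sequences) {
  stopifnot(length(fragment_lengths) == length(sequences),
            length(sequences) >= 1L)
  df <- unique(data.frame(len = fragment_lengths, seq = sequences,
                          stringsAsFactors = FALSE))
  n_per_class <- tapply(df$seq, df$len, function(s) length(unique(s)))
  n_classes <- length(n_per_class)
  n_hom <- sum(n_per_class >= 2L)
  list(n_size_classes = n_classes, n_homoplasious = n_hom,
       percent = 100 * n_hom / n_classes)
}

#' Per-locus homoplasy table for an allele catalog
#'
#' @param catalog data.frame with `locus_id, sequence, fragment_length`.
#' @return data.frame `locus_id, n_size_classes, n_homoplasious, percent`.
#' @export
homoplasy_table <- function(catalog) {
  rows <- lapply(split(catalog, catalog$locus_id), function(sub) {
    h <- size_homoplasy(sub$fragment_length, sub$sequence)
    data.frame(locus_id = sub$locus_id[1],
               n_size_classes = h$n_size_classes,
               n_homoplasious = h$n_homoplasious, percent = h$percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$locus_id), , drop = FALSE]
}

#' Pooled homoplasy over loci
#'
#' The mean over all loci is the ratio of summed counts, not the mean of
#' per-locus percentages: `100 * sum(n_homoplasious) / sum(n_size_classes)`.
#'
#' @param n_size_classes,n_homoplasious integer vectors, one entry per
#'   locus.
#' @return pooled percentage.
#' @export
pooled_homoplasy <- function(n_size_classes, n_homoplasious) {
  stopifnot(length(n_size_classes) >= 1L,
            all(n_homoplasious <= n_size_classes),
            all(n_homoplasious >= 0L))
  total <- sum(n_size_classes)
  if (total == 0L) stop("no fragment size classes", call. = FALSE)
  100 * sum(n_homoplasious) / total
}

#' Count rare alleles in a coded dataset
#'
#' A rare allele occurs exactly once in the dataset, counting allele copies
#' after dosage expansion (a homozygous diploid contributes two copies, so
#' its allele is not rare). Set `by = "carrier"` to count alleles observed
#' in exactly one individual instead.
#'
#' @param coded data.frame `individual_id, locus, code, dosage` (one scheme
#'   from [code_datasets()]).
#' @param by `"copy"` (default) or `"carrier"`.
#' @return data.frame `locus, n_alleles, n_rare`.
#' @export
rare_alleles <- function(coded, by = c("copy", "carrier")) {
  by <- match.arg(by)
  rows <- lapply(split(coded, coded$locus), function(sub) {
    occ <- if (by == "copy") {
      tapply(sub$dosage, sub$code, sum)
    } else {
      tapply(sub$individual_id, sub$code,
             function(x) length(unique(x)))
    }
    data.frame(locus = sub$locus[1], n_alleles = length(occ),
               n_rare = sum(occ == 1L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$locus), , drop = FALSE]
}

#' Replicate genotyping error rate
#'
#' For every (individual, replicate, locus) with both calls present, the
#' comparison is discordant when the two allele multisets (sequences with
#' dosage) differ. The rate is `100 * discordant / comparisons`.
#' Comparisons with either call missing are excluded.
#'
#' @param genotypes long data.frame `individual_id, locus_id, sequence,
#'   dosage` covering originals and replicates.
#' @param replicate_links data.frame `individual_id, replicate_of` (e.g.
#'   the non-`NA` rows of a sample sheet).
#' @return list with `rate` (percent), `n_comparisons`, `n_discordant` and
#'   a per-comparison `report`.
#' @export
replicate_error_rate <- function(genotypes, replicate_links) {
  links <- replicate_links[!is.na(replicate_links$replicate_of), , drop = FALSE]
  if (!nrow(links)) stop("no replicate pairs", call. = FALSE)
  geno_key <- function(ind, locus) {
    sub <- genotypes[genotypes$individual_id == ind &
                       genotypes$locus_id == locus, , drop = FALSE]
    if (!nrow(sub)) return(NA_character_)
    sub <- sub[order(sub$sequence), , drop = FALSE]
    paste(sub$sequence, sub$dosage, sep = ":", collapse = "|")
  }
  loci <- unique(genotypes$locus_id)
  report <- list()
  for (i in seq_len(nrow(links))) {
    for (locus in loci) {
      a <- geno_key(links$replicate_of[i], locus)
      b <- geno_key(links$individual_id[i], locus)
      if (is.na(a) || is.na(b)) next
      report[[length(report) + 1L]] <- data.frame(
        individual_id = links$replicate_of[i],
        replicate_id = links$individual_id[i], locus_id = locus,
        discordant = !identical(a, b), stringsAsFactors = FALSE)
    }
  }
  if (!length(report)) stop("no comparable replicate calls", call. = FALSE)
  report <- do.call(rbind, report)
  list(rate = 100 * mean(report$discordant),
       n_comparisons = nrow(report), n_discordant = sum(report$discordant),
       report = report)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  cor(x, y, method = "pearson")
}

#' Paired Student's t test
#'
#' Two-sided test on paired differences, used to compare He or Ho between
#' two coding schemes across loci.
#'
#' @param a,b paired numeric vectors.
#' @return list `t, df, p`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (var(d) == 0 && any(d != 0)) {
    stop("zero variance of differences", call. = FALSE)
  }
  if (all(d == 0)) {
    return(list(t = 0, df = length(d) - 1L, p = 1))
  }
  res <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
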