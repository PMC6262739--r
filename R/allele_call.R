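# Per individual-by-locus allele calling.
#
# Because a merged read spans the whole amplicon, assembly reduces to exact
# haplotype counting plus absorption of low-abundance neighbours: a unique
# sequence joins an existing contig when it lies within the 99%-identity /
# max-gap-2 distance of the representative AND it is rare relative to the
# contig (< 1% of that allele's reads), which is the signature of a
# sequencing error rather than a second allele.

edit_info <- function(a, b) {
  d <- adist(a, b, counts = TRUE)
  tr <- attr(d, "trafos")[1, 1]
  runs <- regmatches(tr, gregexpr("[ID]+", tr))[[1]]
  list(dist = as.integer(d[1, 1]),
       max_gap_run = if (length(runs)) max(nchar(runs)) else 0L)
}

#' Collapse a read bin into candidate allele contigs
#'
#' Identical sequences are grouped and unique sequences are visited in order
#' of decreasing abundance (ties broken lexicographically). Each sequence is
#' absorbed into the highest-abundance existing contig whose representative
#' is within `ceil((1 - identity) * L)` edits (no single gap run longer than
#' `max_gap`) provided it contributes less than `noise_frac` of that
#' contig's reads; otherwise it founds a new contig. The representative is
#' the most frequent member sequence.
#'
#' @param sequences character vector of full-length inserts
#'   (primer-to-primer).
#' @param identity overlap identity cutoff (default 0.99).
#' @param max_gap longest allowed single gap run in an absorbing alignment.
#' @param noise_frac abundance fraction below which a neighbour is treated
#'   as sequencing noise (default 1%).
#' @param read_ids optional ids parallel to `sequences`.
#' @return data.frame with columns `sequence` (representative),
#'   `read_count`, `status` (`"candidate"`), and list-columns `members`
#'   (unique member sequences) and `member_read_ids`.
#' @export
cluster_reads <- function(sequences, identity = 0.99, max_gap = 2L,
                          noise_frac = 0.01, read_ids = NULL) {
  empty <- data.frame(sequence = character(), read_count = integer(),
                      status = character(), stringsAsFactors = FALSE)
  empty$members <- list(); empty$member_read_ids <- list()
  if (!length(sequences)) return(empty)
  if (is.null(read_ids)) read_ids <- sprintf("seq%06d", seq_along(sequences))

  tab <- table(sequences)
  useq <- names(tab)
  ucount <- as.integer(tab)
  ord <- order_desc_then_lex(ucount, useq)
  useq <- useq[ord]; ucount <- ucount[ord]
  ids_by_seq <- split(read_ids, sequences)

  reps <- character(0); counts <- integer(0)
  members <- list(); member_ids <- list()
  for (i in seq_along(useq)) {
    s <- useq[i]; cnt <- ucount[i]
    absorbed <- FALSE
    if (length(reps)) {
      for (j in order(-counts)) {
        if (cnt >= noise_frac * (counts[j] + cnt)) next
        lim <- ceiling((1 - identity) * max(nchar(s), nchar(reps[j])))
        ei <- edit_info(s, reps[j])
        if (ei$dist <= lim && ei$max_gap_run <= max_gap) {
          counts[j] <- counts[j] + cnt
          members[[j]] <- c(members[[j]], s)
          member_ids[[j]] <- c(member_ids[[j]], ids_by_seq[[s]])
          absorbed <- TRUE
          break
        }
      }
    }
    if (!absorbed) {
      reps <- c(reps, s); counts <- c(counts, cnt)
      members <- c(members, list(s))
      member_ids <- c(member_ids, list(ids_by_seq[[s]]))
    }
  }
  ord <- order_desc_then_lex(counts, reps)
  out <- data.frame(sequence = reps[ord], read_count = counts[ord],
                    status = "candidate", stringsAsFactors = FALSE)
  out$members <- members[ord]
  out$member_read_ids <- member_ids[ord]
  out
}

#' Flag PCR-chimera contigs
#'
#' A contig is a chimera when its sequence is the exact single-breakpoint
#' join of two higher-coverage contigs (`a[1:i] + b[(i+1):len]`, either
#' order) and its read count is below both parents'. Such contigs arise
#' from template switching between the abundant true alleles during PCR.
#'
#' @param contigs data.frame from [cluster_reads()], sorted by read count
#'   descending.
#' @return the contigs with `status` set to `"chimera"` where detected.
#' @export
detect_chimeras <- function(contigs) {
  n <- nrow(contigs)
  if (n < 3L) return(contigs)
  seqs <- contigs$sequence
  counts <- contigs$read_count
  lcp <- function(x, y) {
    k <- 0L; m <- min(nchar(x), nchar(y))
    while (k < m && substr(x, k + 1L, k + 1L) == substr(y, k + 1L, k + 1L)) {
      k <- k + 1L
    }
    k
  }
  lcs <- function(x, y) {
    k <- 0L; m <- min(nchar(x), nchar(y))
    while (k < m && substr(x, nchar(x) - k, nchar(x) - k) ==
           substr(y, nchar(y) - k, nchar(y) - k)) {
      k <- k + 1L
    }
    k
  }
  for (ci in seq_len(n)) {
    higher <- which(counts > counts[ci])
    if (length(higher) < 2L) next
    found <- FALSE
    for (ai in higher) {
      for (bi in setdiff(higher, ai)) {
        # c = a[1:i] + b[(i+1):.] requires len(c) == len(b)
        if (nchar(seqs[ci]) != nchar(seqs[bi])) next
        pre <- lcp(seqs[ci], seqs[ai])
        suf <- lcs(seqs[ci], seqs[bi])
        lo <- max(1L, nchar(seqs[ci]) - suf)
        if (pre >= lo && pre >= 1L && lo <= nchar(seqs[ci]) - 1L) {
          contigs$status[ci] <- "chimera"
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  contigs
}

# All orderings of positive integers of length k summing to n.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- list()
  for (first in seq_len(n - k + 1L)) {
    rest <- compositions(n - first, k - 1L)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

#' Estimate allele dosage from read-depth ratios
#'
#' Returns the composition of `ploidy` into one positive integer per allele
#' maximizing the multinomial likelihood of the observed read counts with
#' cell probabilities `dosage / ploidy`. Ties go to the most even
#' composition. In a tetraploid this distinguishes the 3:1, 2:1:1, 2:2 and
#' 1:1:1:1 patterns visible in contig coverage graphs.
#'
#' @param allele_counts read counts, one per called allele.
#' @param ploidy 2 or 4.
#' @return integer dosage vector aligned with `allele_counts`.
#' @export
estimate_dosage <- function(allele_counts, ploidy) {
  k <- length(allele_counts)
  stopifnot(k >= 1L, k <= ploidy)
  comps <- compositions(ploidy, k)
  ll <- as.numeric(log(comps / ploidy) %*% allele_counts)
  best <- which(ll == max(ll))
  if (length(best) > 1L) {
    evenness <- apply(comps[best, , drop = FALSE], 1L, var)
    evenness[is.na(evenness)] <- 0
    best <- best[evenness == min(evenness)]
  }
  if (length(best) > 1L) {
    # exact ties (equal counts): give the surplus to the earlier allele
    ord <- do.call(order, c(lapply(seq_len(k), function(j) -comps[best, j]),
                            list(method = "radix")))
    best <- best[ord[1]]
  }
  as.integer(comps[best, ])
}

#' Call a genotype from denoised contigs
#'
#' Accepts up to `ploidy` non-chimera contigs with at least `min_reads`
#' reads, in decreasing coverage. Contigs whose length differs from an
#' already-accepted allele by exactly one repeat unit and whose coverage is
#' below `stutter_frac` of it are set aside as stutter suspects. If more
#' than `ploidy` contigs qualify the call is flagged `paralog_suspect` and
#' the top `ploidy` kept; if none qualify the call is `missing`. Dosages
#' come from [estimate_dosage()].
#'
#' @param contigs data.frame from [detect_chimeras()].
#' @param ploidy individual's ploidy (2 or 4).
#' @param min_reads minimum reads per accepted allele (default 10).
#' @param stutter_frac coverage fraction below which a one-unit neighbour is
#'   treated as polymerase stutter (default 5%).
#' @param unit_length repeat unit length in bp used for the stutter test;
#'   `NA` disables it.
#' @return list with `alleles` (sequences), `dosages`, `read_counts`,
#'   `total_reads`, `flags` (subset of `low_coverage, paralog_suspect,
#'   missing`), and the annotated `contigs`.
#' @export
call_genotype <- function(contigs, ploidy, min_reads = 10L,
                          stutter_frac = 0.05, unit_length = NA_integer_) {
  flags <- character(0)
  total <- sum(contigs$read_count)
  cand <- which(contigs$status == "candidate")
  accepted <- integer(0)
  for (ci in cand) {
    if (contigs$read_count[ci] < min_reads) {
      contigs$status[ci] <- "noise"
      next
    }
    is_stutter <- FALSE
    if (!is.na(unit_length) && length(accepted)) {
      for (ai in accepted) {
        dlen <- abs(nchar(contigs$sequence[ci]) - nchar(contigs$sequence[ai]))
        if (dlen == unit_length &&
            contigs$read_count[ci] < stutter_frac * contigs$read_count[ai]) {
          is_stutter <- TRUE
          break
        }
      }
    }
    if (is_stutter) {
      contigs$status[ci] <- "stutter_suspect"
    } else if (length(accepted) < ploidy) {
      accepted <- c(accepted, ci)
      contigs$status[ci] <- "allele"
    } else {
      flags <- union(flags, "paralog_suspect")
      contigs$status[ci] <- "noise"
    }
  }
  if (!length(accepted)) {
    # every contig fell below min_reads (or was an artifact): the cell has
    # no allele supported by >= min_reads reads
    flags <- union(flags, c("missing", "low_coverage"))
    return(list(alleles = character(0), dosages = integer(0),
                read_counts = integer(0), total_reads = total,
                flags = flags, contigs = contigs))
  }
  counts <- contigs$read_count[accepted]
  list(alleles = contigs$sequence[accepted],
       dosages = estimate_dosage(counts, ploidy),
       read_counts = counts, total_reads = total,
       flags = flags, contigs = contigs)
}

#' Call genotypes for every demultiplexed bin
#'
#' Driver over [cluster_reads()], [detect_chimeras()] and [call_genotype()].
#'
#' @param bins named list from [demultiplex_stream()] (`individual\rlocus`).
#' @param sample_sheet data.frame from [load_sample_sheet()].
#' @param loci list of [locus_spec()] (for repeat unit lengths).
#' @param min_reads,identity,max_gap,noise_frac,stutter_frac see the
#'   stage functions.
#' @return list with `genotypes` (long data.frame `individual_id, locus_id,
#'   sequence, dosage, read_count`), `calls` (per-cell summary incl. flags)
#'   and `contig_debug` (per-contig counts and statuses).
#' @export
call_all_bins <- function(bins, sample_sheet, loci, min_reads = 10L,
                          identity = 0.99, max_gap = 2L, noise_frac = 0.01,
                          stutter_frac = 0.05) {
  ploidy_of <- setNames(sample_sheet$ploidy, sample_sheet$individual_id)
  unit_of <- setNames(
    vapply(loci, function(s) {
      if (length(s$ssr_motifs)) nchar(s$ssr_motifs[1]) else NA_integer_
    }, integer(1)),
    vapply(loci, `[[`, "", "locus_id"))
  geno <- list(); calls <- list(); debug <- list()
  for (key in names(bins)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ind <- parts[1]; locus <- parts[2]
    bin <- bins[[key]]
    contigs <- cluster_reads(bin$insert, identity, max_gap, noise_frac,
                             bin$read_id)
    contigs <- detect_chimeras(contigs)
    call <- call_genotype(contigs, ploidy_of[[ind]], min_reads,
                          stutter_frac, unit_of[[locus]])
    if (length(call$alleles)) {
      geno[[length(geno) + 1L]] <- data.frame(
        individual_id = ind, locus_id = locus, sequence = call$alleles,
        dosage = call$dosages, read_count = call$read_counts,
        stringsAsFactors = FALSE)
    }
    calls[[length(calls) + 1L]] <- data.frame(
      individual_id = ind, locus_id = locus,
      n_alleles = length(call$alleles), total_reads = call$total_reads,
      flags = paste(call$flags, collapse = ","), stringsAsFactors = FALSE)
    debug[[length(debug) + 1L]] <- data.frame(
      individual_id = ind, locus_id = locus,
      sequence = call$contigs$sequence, read_count = call$contigs$read_count,
      status = call$contigs$status, stringsAsFactors = FALSE)
  }
  list(genotypes = do.call(rbind, geno),
       calls = do.call(rbind, calls),
       contig_debug = do.call(rbind, debug))
}

#' Apply the dataset-level quality filters
#'
#' Drops loci in which more than `low_cov_individual_frac` of individuals
#' are low-coverage or missing, then loci whose fraction of
#' paralog-suspect individuals exceeds `paralog_locus_frac`, then
#' individuals missing more than `missing_locus_frac` of the remaining
#' loci. Every exclusion is reported with its reason.
#'
#' @param calls per-cell summary from [call_all_bins()] (`calls` element);
#'   cells absent from `calls` count as missing.
#' @param individuals,loci character vectors of all expected ids.
#' @param low_cov_individual_frac locus-level threshold (default 0.10).
#' @param missing_locus_frac individual-level threshold (default 0.30).
#' @param paralog_locus_frac locus-level paralog reporting threshold.
#' @return list with `keep_loci`, `keep_individuals`, `exclusions`
#'   (data.frame `type, id, reason`).
#' @export
qc_filters <- function(calls, individuals, loci,
                       low_cov_individual_frac = 0.10,
                       missing_locus_frac = 0.30,
                       paralog_locus_frac = 0.05) {
  grid <- expand.grid(individual_id = individuals, locus_id = loci,
                      stringsAsFactors = FALSE)
  key <- paste(grid$individual_id, grid$locus_id, sep = "\r")
  ckey <- paste(calls$individual_id, calls$locus_id, sep = "\r")
  flags <- setNames(calls$flags, ckey)[key]
  flags[is.na(flags)] <- "missing"
  grid$bad <- grepl("missing|low_coverage", flags)
  grid$paralog <- grepl("paralog_suspect", flags)

  excl <- list()
  bad_frac <- tapply(grid$bad, grid$locus_id, mean)
  drop1 <- names(bad_frac)[bad_frac > low_cov_individual_frac]
  for (lc in drop1) {
    excl[[length(excl) + 1L]] <- data.frame(
      type = "locus", id = lc,
      reason = sprintf("low coverage/missing in %.0f%% of individuals",
                       100 * bad_frac[[lc]]), stringsAsFactors = FALSE)
  }
  par_frac <- tapply(grid$paralog, grid$locus_id, mean)
  drop2 <- setdiff(names(par_frac)[par_frac > paralog_locus_frac], drop1)
  for (lc in drop2) {
    excl[[length(excl) + 1L]] <- data.frame(
      type = "locus", id = lc,
      reason = sprintf("paralog suspect in %.0f%% of individuals",
                       100 * par_frac[[lc]]), stringsAsFactors = FALSE)
  }
  keep_loci <- setdiff(loci, c(drop1, drop2))

  sub <- grid[grid$locus_id %in% keep_loci, , drop = FALSE]
  miss_frac <- tapply(sub$bad, sub$individual_id, mean)
  drop_ind <- names(miss_frac)[miss_frac > missing_locus_frac]
  for (ind in drop_ind) {
    excl[[length(excl) + 1L]] <- data.frame(
      type = "individual", id = ind,
      reason = sprintf("missing in %.0f%% of retained loci",
                       100 * miss_frac[[ind]]), stringsAsFactors = FALSE)
  }
  list(keep_loci = keep_loci,
       keep_individuals = setdiff(individuals, drop_ind),
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(type = character(), id = character(),
                    reason = character()))
}
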