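# Demultiplexing by 10-nt tag + first 10 primer bases on both read ends.
#
# Non-combinatorial tagging (same tag on both primers of a pair) means the
# two ends of a genuine read must agree on (locus, set). Ends that match
# different keys expose inter-set PCR recombinants ("cross_tag").

# Candidate 20-mer keys for both orientations of every (locus, set) pair.
build_demux_keys <- function(specs) {
  rows <- lapply(specs, function(s) {
    sets <- names(s$barcodes)
    pf10 <- substr(s$forward_primer, 1, 10)
    pr10 <- substr(s$reverse_primer, 1, 10)
    data.frame(
      locus_id = s$locus_id,
      set_id = rep(sets, 2L),
      orientation = rep(c("forward", "reverse-complemented"), each = length(sets)),
      key5 = c(paste0(s$barcodes, pf10), paste0(s$barcodes, pr10)),
      key3 = c(revcomp(paste0(s$barcodes, pr10)),
               revcomp(paste0(s$barcodes, pf10))),
      trim5 = c(rep(10L + nchar(s$forward_primer), length(sets)),
                rep(10L + nchar(s$reverse_primer), length(sets))),
      trim3 = c(rep(10L + nchar(s$reverse_primer), length(sets)),
                rep(10L + nchar(s$forward_primer), length(sets))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign reads to (locus, sample set) by their terminal 20-mers
#'
#' The first 20 bases of a read are Hamming-matched against every
#' tag + primer-prefix key in both orientations; the best candidate within
#' `max_mismatch` wins (ties give `unassigned`, counted as ambiguous). The
#' last 20 bases are then matched against the reverse-complemented partner
#' keys: agreement on (locus, set) yields `assigned`, disagreement
#' `cross_tag`.
#'
#' @param seqs character vector of merged read sequences.
#' @param specs list of [locus_spec()] objects.
#' @param max_mismatch maximum Hamming mismatches per 20-mer window.
#' @return data.frame with columns `locus_id, set_id, orientation,
#'   mismatches_5p, mismatches_3p, verdict, trim5, trim3` (one row per read).
#' @export
assign_reads <- function(seqs, specs, max_mismatch = 2L) {
  keys <- build_demux_keys(specs)
  n <- length(seqs)
  out <- data.frame(locus_id = NA_character_, set_id = NA_character_,
                    orientation = NA_character_, mismatches_5p = NA_integer_,
                    mismatches_3p = NA_integer_, verdict = "unassigned",
                    trim5 = NA_integer_, trim3 = NA_integer_,
                    stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  if (n == 0L) return(out)
  long <- nchar(seqs) >= 40L
  if (!any(long)) return(out)

  pre <- substr(seqs[long], 1L, 20L)
  suf <- substr(seqs[long], nchar(seqs[long]) - 19L, nchar(seqs[long]))
  mm5 <- vapply(keys$key5, function(k) hamming_to(pre, k),
                numeric(sum(long)))
  mm3 <- vapply(keys$key3, function(k) hamming_to(suf, k),
                numeric(sum(long)))
  if (sum(long) == 1L) { mm5 <- rbind(mm5); mm3 <- rbind(mm3) }

  best5 <- apply(mm5, 1L, min)
  idx5 <- apply(mm5, 1L, which.min)
  tie5 <- rowSums(mm5 == best5) > 1L
  best3 <- apply(mm3, 1L, min)
  idx3 <- apply(mm3, 1L, which.min)
  tie3 <- rowSums(mm3 == best3) > 1L

  verdict <- rep("unassigned", sum(long))
  verdict[best5 <= max_mismatch & tie5] <- "ambiguous"
  ok5 <- best5 <= max_mismatch & !tie5
  ok3 <- best3 <= max_mismatch & !tie3
  same <- ok5 & ok3 &
    keys$locus_id[idx5] == keys$locus_id[idx3] &
    keys$set_id[idx5] == keys$set_id[idx3] &
    keys$orientation[idx5] == keys$orientation[idx3]
  cross <- ok5 & ok3 & !same
  verdict[same] <- "assigned"
  verdict[cross] <- "cross_tag"

  sub <- out[long, , drop = FALSE]
  keep <- ok5
  sub$locus_id[keep] <- keys$locus_id[idx5[keep]]
  sub$set_id[keep] <- keys$set_id[idx5[keep]]
  sub$orientation[keep] <- keys$orientation[idx5[keep]]
  sub$mismatches_5p[keep] <- best5[keep]
  sub$mismatches_3p[ok3] <- best3[ok3]
  sub$trim5[keep] <- keys$trim5[idx5[keep]]
  sub$trim3[keep] <- keys$trim3[idx5[keep]]
  sub$verdict <- verdict
  out[long, ] <- sub
  out
}

#' Assign one read (scalar convenience wrapper)
#' @inheritParams assign_reads
#' @param seq a single merged read sequence.
#' @return one-row data.frame as from [assign_reads()].
#' @export
assign_read <- function(seq, specs, max_mismatch = 2L) {
  assign_reads(seq, specs, max_mismatch)
}

#' Demultiplex merged reads into individual-by-locus bins
#'
#' Reads are assigned with [assign_reads()], reverse-complemented into the
#' reference orientation where needed, and trimmed of tag and full primer on
#' both ends, leaving the primer-to-primer insert. The (set, pool) pair of a
#' read resolves the individual via the sample sheet; the pool is taken from
#' a `pool=<id>` token in the read id unless `pool_ids` is given.
#'
#' @param reads data.frame with columns `read_id, seq` (e.g. from
#'   [read_fastq()] or `merge_read_pairs()$merged`).
#' @param specs list of [locus_spec()] objects.
#' @param sample_sheet data.frame from [load_sample_sheet()].
#' @param max_mismatch maximum Hamming mismatches per 20-mer window.
#' @param pool_ids optional character vector overriding pool parsing.
#' @return list with `bins` (named list `individual\rlocus` of data.frames
#'   `read_id, insert`), `summary` (per-locus verdict counts), and
#'   `assignments`.
#' @export
demultiplex_stream <- function(reads, specs, sample_sheet,
                               max_mismatch = 2L, pool_ids = NULL) {
  if (is.null(pool_ids)) {
    m <- regmatches(reads$read_id, regexpr("pool=\\S+", reads$read_id))
    if (length(m) != nrow(reads)) {
      stop("reads lack a pool=<id> token; supply pool_ids", call. = FALSE)
    }
    pool_ids <- sub("^pool=", "", m)
  }
  asg <- assign_reads(reads$seq, specs, max_mismatch)
  asg$read_id <- sub(" .*$", "", reads$read_id)
  asg$pool_id <- pool_ids

  ind_lookup <- setNames(sample_sheet$individual_id,
                         paste(sample_sheet$set_id, sample_sheet$pool_id,
                               sep = "\r"))
  ok <- asg$verdict == "assigned"
  seqs <- reads$seq
  rc_rows <- ok & asg$orientation == "reverse-complemented"
  seqs[rc_rows] <- revcomp(seqs[rc_rows])
  insert <- rep(NA_character_, nrow(asg))
  insert[ok] <- substr(seqs[ok], asg$trim5[ok] + 1L,
                       nchar(seqs[ok]) - asg$trim3[ok])
  individual <- rep(NA_character_, nrow(asg))
  individual[ok] <- ind_lookup[paste(asg$set_id[ok], asg$pool_id[ok],
                                     sep = "\r")]
  # an assigned read whose (set, pool) names no individual is unassignable
  orphan <- ok & is.na(individual)
  asg$verdict[orphan] <- "unassigned"
  ok <- ok & !orphan

  bins <- split(
    data.frame(read_id = asg$read_id[ok], insert = insert[ok],
               stringsAsFactors = FALSE),
    paste(individual[ok], asg$locus_id[ok], sep = "\r"))

  if (nrow(asg)) {
    locus_of <- ifelse(is.na(asg$locus_id), "(none)", asg$locus_id)
    summary <- as.data.frame(table(locus_id = locus_of,
                                   verdict = asg$verdict),
                             stringsAsFactors = FALSE)
    names(summary)[3] <- "n_reads"
    summary <- summary[summary$n_reads > 0L | summary$verdict == "assigned", ]
  } else {
    summary <- data.frame(locus_id = character(), verdict = character(),
                          n_reads = integer(), stringsAsFactors = FALSE)
  }
  message(sprintf(
    "demultiplex_stream: %d reads -> %d assigned, %d unassigned, %d cross_tag, %d ambiguous",
    nrow(asg), sum(asg$verdict == "assigned"),
    sum(asg$verdict == "unassigned"), sum(asg$verdict == "cross_tag"),
    sum(asg$verdict == "ambiguous")))
  list(bins = bins, summary = summary, assignments = asg)
}
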