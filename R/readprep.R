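# Paired-end merging and quality trimming.
#
# Merging uses a deterministic best-ungapped-overlap rule: the mate pair is
# merged when some overlap of at least `min_overlap` bases has a mismatch
# fraction of at most `max_mismatch_frac`; disagreeing bases are resolved to
# the higher-quality call and the merged quality is the elementwise maximum.

#' Merge one read pair by best ungapped overlap
#'
#' @param r1,r2 lists with elements `seq` and `qual` (phred+33), or character
#'   scalars (qualities then default to Q37).
#' @param min_overlap smallest acceptable overlap in bp.
#' @param max_mismatch_frac largest acceptable mismatch fraction within the
#'   overlap.
#' @return a list with `merged` (logical), and when merged, `seq` and `qual`
#'   of the consensus; `overlap` gives the chosen overlap length.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 30L, max_mismatch_frac = 0.1) {
  if (is.character(r1)) r1 <- list(seq = r1, qual = strrep("F", nchar(r1)))
  if (is.character(r2)) r2 <- list(seq = r2, qual = strrep("F", nchar(r2)))
  if (!nzchar(r1$seq) || !nzchar(r2$seq)) {
    return(list(merged = FALSE, reason = "empty"))
  }
  s1 <- r1$seq
  s2 <- revcomp(r2$seq)
  q2 <- paste(rev(strsplit(r2$qual, "")[[1]]), collapse = "")
  n1 <- nchar(s1); n2 <- nchar(s2)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  p1 <- phred_to_int(r1$qual); p2 <- phred_to_int(q2)

  best <- NULL
  max_o <- min(n1, n2)
  if (max_o < min_overlap) {
    return(list(merged = FALSE, reason = "no_overlap"))
  }
  for (o in max_o:min_overlap) {
    i1 <- (n1 - o + 1L):n1
    i2 <- 1L:o
    mm <- sum(c1[i1] != c2[i2])
    if (mm / o <= max_mismatch_frac) {
      if (is.null(best) || mm / o < best$frac) {
        best <- list(o = o, mm = mm, frac = mm / o)
        if (mm == 0L) break
      }
    }
  }
  if (is.null(best)) {
    return(list(merged = FALSE, reason = "no_overlap"))
  }
  o <- best$o
  i1 <- (n1 - o + 1L):n1
  i2 <- 1L:o
  ov_base <- ifelse(p1[i1] >= p2[i2], c1[i1], c2[i2])
  ov_qual <- pmax(p1[i1], p2[i2])
  seq <- paste0(substr(s1, 1L, n1 - o), paste(ov_base, collapse = ""),
                substr(s2, o + 1L, n2))
  qual <- int_to_phred(c(p1[seq_len(n1 - o)], ov_qual,
                         if (o < n2) p2[(o + 1L):n2] else integer(0)))
  list(merged = TRUE, seq = seq, qual = qual, overlap = o,
       mismatches = best$mm)
}

#' Quality-trim read ends
#'
#' Removes leading and trailing bases whose quality is below `q_threshold`;
#' never lengthens a read. Interior low-quality bases are kept.
#'
#' @param record list with `seq` and `qual` (phred+33).
#' @param q_threshold minimum terminal base quality.
#' @return trimmed record (possibly empty).
#' @export
quality_trim <- function(record, q_threshold = 30L) {
  q <- phred_to_int(record$qual)
  keep <- which(q >= q_threshold)
  if (!length(keep)) {
    return(list(seq = "", qual = ""))
  }
  list(seq = substr(record$seq, keep[1], keep[length(keep)]),
       qual = substr(record$qual, keep[1], keep[length(keep)]))
}

#' Merge all pairs of a simulated or real read set
#'
#' Vectorised driver around [merge_pairs()]: identical (sequence, quality)
#' pairs are merged once and the result reused, which makes deep amplicon
#' data cheap to process. Unmerged pairs are reported by id.
#'
#' @param reads data.frame with columns `read_id, r1, q1, r2, q2`.
#' @param min_overlap,max_mismatch_frac see [merge_pairs()].
#' @return list with `merged` (data.frame `read_id, seq, qual`) and
#'   `unmerged_ids`.
#' @export
merge_read_pairs <- function(reads, min_overlap = 30L,
                             max_mismatch_frac = 0.1) {
  key <- paste(reads$r1, reads$q1, reads$r2, reads$q2, sep = "\r")
  uniq <- !duplicated(key)
  res <- lapply(which(uniq), function(i) {
    merge_pairs(list(seq = reads$r1[i], qual = reads$q1[i]),
                list(seq = reads$r2[i], qual = reads$q2[i]),
                min_overlap, max_mismatch_frac)
  })
  names(res) <- key[uniq]
  res <- res[key]
  ok <- vapply(res, `[[`, logical(1), "merged")
  message(sprintf("merge_read_pairs: %d/%d pairs merged (%.1f%%)",
                  sum(ok), length(ok), 100 * mean(ok)))
  list(
    merged = data.frame(
      read_id = reads$read_id[ok],
      seq = vapply(res[ok], `[[`, character(1), "seq"),
      qual = vapply(res[ok], `[[`, character(1), "qual"),
      stringsAsFactors = FALSE, row.names = NULL),
    unmerged_ids = reads$read_id[!ok]
  )
}

#' Read a FASTQ file into a plain data.frame
#' @param path FASTQ path (phred+33).
#' @return data.frame `read_id, seq, qual` (id = full header line).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
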