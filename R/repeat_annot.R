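# SSR detection and allele annotation against the locus reference.

# Smallest (weak) period of a string: p such that s[i] == s[i+p] for all i.
primitive_period <- function(chars) {
  n <- length(chars)
  for (p in seq_len(n - 1L)) {
    if (all(chars[seq_len(n - p)] == chars[(p + 1L):n])) return(p)
  }
  n
}

#' Find perfect tandem repeats
#'
#' Scans for maximal perfect tandem runs with unit length in `unit_range`
#' and total run length of at least `min_len` bp. A run is reported at its
#' primitive period only (so a trinucleotide array is never double-reported
#' as a hexanucleotide one, and dinucleotide arrays are not reported at
#' all); the unit is given as its lexicographically smallest rotation.
#'
#' @param sequence uppercase DNA string.
#' @param unit_range repeat unit lengths considered (default 3-6).
#' @param min_len minimum run length in bp (default 21).
#' @return data.frame `start, end` (0-based half-open), `unit` (canonical
#'   rotation), `n_units` (complete units), `length`.
#' @export
find_ssrs <- function(sequence, unit_range = c(3L, 6L), min_len = 21L) {
  x <- strsplit(toupper(sequence), "")[[1]]
  n <- length(x)
  hits <- list()
  for (u in unit_range[1]:unit_range[2]) {
    if (n < u + 1L) next
    eq <- x[seq_len(n - u)] == x[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths + u >= min_len)) {
      s0 <- starts[k]               # 1-based start of region
      region_len <- r$lengths[k] + u
      region <- x[s0:(s0 + region_len - 1L)]
      if (primitive_period(region) != u) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = s0 - 1L, end = s0 - 1L + region_len,
        unit = canonical_rotation(paste(region[seq_len(u)], collapse = "")),
        n_units = region_len %/% u, length = region_len,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      n_units = integer(), length = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

is_motif_repeat <- function(ins, motif) {
  u <- nchar(motif)
  if (nchar(ins) == 0L || nchar(ins) %% u != 0L) return(FALSE)
  rots <- vapply(seq_len(u) - 1L, function(k) {
    paste0(substr(motif, k + 1L, u), substr(motif, 1L, k))
  }, character(1))
  any(vapply(rots, function(rt) {
    ins == strrep(rt, nchar(ins) %/% u)
  }, logical(1)))
}

# Global affine-gap alignment of an allele to the locus reference, returned
# as a per-reference-position projection.
project_to_reference <- function(allele_seq, reference_seq,
                                 match = 1, mismatch = -2,
                                 gap_opening = 10, gap_extension = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(allele_seq), Biostrings::DNAString(reference_seq),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n_ref <- nchar(reference_seq)
  base_at <- rep("-", n_ref)          # allele base at each ref position
  ins_pos <- integer(0); ins_seq <- character(0)
  r <- 0L                             # ref bases consumed (0-based next idx)
  i <- 1L
  ncol <- length(pc)
  while (i <= ncol) {
    if (sc[i] != "-") {
      base_at[r + 1L] <- pc[i]
      r <- r + 1L
      i <- i + 1L
    } else {
      j <- i
      while (j <= ncol && sc[j] == "-") j <- j + 1L
      ins_pos <- c(ins_pos, r)
      ins_seq <- c(ins_seq, paste(pc[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  identity <- sum(pc == sc) / ncol
  list(base_at = base_at,
       insertions = data.frame(ref_pos = ins_pos, seq = ins_seq,
                               stringsAsFactors = FALSE),
       identity = identity)
}

#' Annotate an allele against its locus reference
#'
#' Globally aligns the allele to `locus$reference_seq` (affine gaps: open
#' 10, extend 1; match 1, mismatch -2) and projects the reference SSR
#' regions through the alignment. The repeat-region length of the allele is
#' the number of allele bases falling inside the projected interval;
#' insertions at a region boundary are attributed to the region only when
#' they are whole repeats of the motif (a repeat expansion), so flanking
#' indels never inflate the SSR length.
#'
#' @param allele_seq allele sequence (tag- and primer-trimmed).
#' @param locus a [locus_spec()].
#' @param min_identity below this alignment identity the allele is flagged
#'   as a paralog suspect and not annotated (default 0.70).
#' @return list with `ssr_lengths` (bp, one per region; `NA` when flagged),
#'   `identity`, `paralog_suspect`, and the `projection`.
#' @export
annotate_allele <- function(allele_seq, locus, min_identity = 0.70) {
  proj <- project_to_reference(allele_seq, locus$reference_seq)
  if (proj$identity < min_identity) {
    return(list(ssr_lengths = rep(NA_integer_, nrow(locus$ssr_regions)),
                identity = proj$identity, paralog_suspect = TRUE,
                projection = proj))
  }
  ssr_lengths <- integer(nrow(locus$ssr_regions))
  for (k in seq_len(nrow(locus$ssr_regions))) {
    s0 <- locus$ssr_regions[k, 1]; e0 <- locus$ssr_regions[k, 2]
    motif <- locus$ssr_motifs[k]
    inside <- sum(proj$base_at[(s0 + 1L):e0] != "-")
    ins <- proj$insertions
    for (m in seq_len(nrow(ins))) {
      r <- ins$ref_pos[m]
      if (r > s0 && r < e0) {
        inside <- inside + nchar(ins$seq[m])
      } else if ((r == s0 || r == e0) && is_motif_repeat(ins$seq[m], motif)) {
        inside <- inside + nchar(ins$seq[m])
      }
    }
    ssr_lengths[k] <- inside
  }
  list(ssr_lengths = ssr_lengths, identity = proj$identity,
       paralog_suspect = FALSE, projection = proj)
}

#' Annotate a whole allele catalog
#'
#' @param catalog data.frame from [allele_catalog()].
#' @param loci list of [locus_spec()] objects.
#' @return the catalog with list-column `ssr_lengths` and logical
#'   `paralog_suspect`.
#' @export
annotate_catalog <- function(catalog, loci) {
  locus_of <- setNames(loci, vapply(loci, `[[`, "", "locus_id"))
  ann <- lapply(seq_len(nrow(catalog)), function(i) {
    annotate_allele(catalog$sequence[i], locus_of[[catalog$locus_id[i]]])
  })
  catalog$ssr_lengths <- lapply(ann, `[[`, "ssr_lengths")
  catalog$paralog_suspect <- vapply(ann, `[[`, logical(1), "paralog_suspect")
  catalog
}

#' Code genotypes under the three allele-coding schemes
#'
#' Produces the SSR-length, fragment-length and sequence-identity datasets.
#' Codes are dense integers per (sub-)locus: alleles share a code iff their
#' coding key (total repeat-region length / fragment length / exact
#' sequence) is equal. A locus with several SSR regions is split into
#' sub-loci (`<locus>_a`, `<locus>_b`, ...) in the SSR-length scheme only.
#'
#' @param catalog annotated catalog from [annotate_catalog()].
#' @param genotypes long data.frame `individual_id, locus_id, allele_id,
#'   dosage`.
#' @return named list of three data.frames (`ssr_length, fragment_length,
#'   sequence_identity`), each `individual_id, locus, code, size, dosage`
#'   (`size` is the coding key in bp for the length-based schemes, `NA` for
#'   sequence identity).
#' @export
code_datasets <- function(catalog, genotypes) {
  key <- paste(catalog$locus_id, catalog$allele_id, sep = "\r")
  idx <- match(paste(genotypes$locus_id, genotypes$allele_id, sep = "\r"), key)
  if (anyNA(idx)) {
    stop("genotype refers to allele absent from catalog", call. = FALSE)
  }
  dense_code <- function(values) match(values, sort(unique(values)))

  base <- data.frame(individual_id = genotypes$individual_id,
                     locus = genotypes$locus_id,
                     dosage = genotypes$dosage, stringsAsFactors = FALSE)

  # sequence identity: key = exact sequence
  seq_ds <- base
  seq_ds$size <- NA_integer_
  seq_ds$code <- unsplit(lapply(split(catalog$sequence[idx],
                                      genotypes$locus_id), dense_code),
                         genotypes$locus_id)

  # fragment length: key = total sequence length
  frag_ds <- base
  frag_ds$size <- catalog$fragment_length[idx]
  frag_ds$code <- unsplit(lapply(split(frag_ds$size, genotypes$locus_id),
                                 dense_code), genotypes$locus_id)

  # SSR length: one sub-locus per repeat region
  n_regions <- vapply(catalog$ssr_lengths, length, integer(1))
  rows <- list()
  if (!"paralog_suspect" %in% names(catalog)) catalog$paralog_suspect <- FALSE
  dropped <- FALSE
  for (g in seq_len(nrow(genotypes))) {
    ci <- idx[g]
    if (catalog$paralog_suspect[ci] || anyNA(catalog$ssr_lengths[[ci]])) {
      dropped <- TRUE
      next
    }
    nr <- n_regions[ci]
    sub <- if (nr > 1L) {
      paste0(genotypes$locus_id[g], "_", letters[seq_len(nr)])
    } else {
      genotypes$locus_id[g]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = genotypes$individual_id[g], locus = sub,
      dosage = genotypes$dosage[g], size = catalog$ssr_lengths[[ci]],
      stringsAsFactors = FALSE)
  }
  if (dropped) {
    warning("unannotated allele(s) excluded from the SSR-length dataset",
            call. = FALSE)
  }
  ssr_ds <- do.call(rbind, rows)
  if (is.null(ssr_ds)) {
    ssr_ds <- data.frame(individual_id = character(), locus = character(),
                         dosage = integer(), size = integer())
  }
  ssr_ds$code <- unsplit(lapply(split(ssr_ds$size, ssr_ds$locus), dense_code),
                         ssr_ds$locus)

  cols <- c("individual_id", "locus", "code", "size", "dosage")
  list(ssr_length = ssr_ds[, cols],
       fragment_length = frag_ds[, cols],
       sequence_identity = seq_ds[, cols])
}

#' Tally variable sites among the alleles of one locus
#'
#' Builds a reference-projected pseudo-alignment of the alleles and counts,
#' across alleles: substitution columns (`n_snps`), distinct indel events
#' (`n_indels`, with lengths) excluding whole-unit gaps inside the SSR
#' region (those are stepwise repeat-count changes, booked once via
#' `ssr_count_variable`), and whether any allele's repeat region deviates
#' from a pure tandem of the motif (`mutated_motif`). The bookkeeping
#' identity `n_variable_sites = n_snps + n_indels + [ssr_count_variable]`
#' holds by construction.
#'
#' @param allele_seqs character vector of allele sequences of one locus.
#' @param locus a [locus_spec()].
#' @return one-row data.frame `locus_id, n_variable_sites, n_snps,
#'   n_indels, ssr_count_variable, mutated_motif` plus list-column
#'   `indel_lengths`.
#' @export
count_variable_sites <- function(allele_seqs, locus) {
  zero <- data.frame(locus_id = locus$locus_id, n_variable_sites = 0L,
                     n_snps = 0L, n_indels = 0L, ssr_count_variable = FALSE,
                     mutated_motif = FALSE, stringsAsFactors = FALSE)
  zero$indel_lengths <- list(integer(0))
  allele_seqs <- unique(allele_seqs)
  if (length(allele_seqs) < 2L) {
    if (length(allele_seqs) == 1L) {
      ann <- annotate_allele(allele_seqs, locus)
      zero$mutated_motif <- region_mutated(ann, locus)
    }
    return(zero)
  }
  anns <- lapply(allele_seqs, annotate_allele, locus = locus)
  ok <- !vapply(anns, `[[`, logical(1), "paralog_suspect")
  anns <- anns[ok]
  if (length(anns) < 2L) return(zero)

  n_ref <- nchar(locus$reference_seq)
  in_ssr <- rep(FALSE, n_ref)
  for (k in seq_len(nrow(locus$ssr_regions))) {
    in_ssr[(locus$ssr_regions[k, 1] + 1L):locus$ssr_regions[k, 2]] <- TRUE
  }

  # SNP columns: reference positions with >= 2 distinct non-gap allele bases
  base_mat <- vapply(anns, function(a) a$projection$base_at,
                     character(n_ref))
  n_snps <- sum(apply(base_mat, 1L, function(col) {
    length(unique(col[col != "-"])) >= 2L
  }))

  # deletion events: maximal gap runs keyed by (start, length); keep those
  # not shared by every allele and not a whole-unit SSR contraction
  del_events <- unique(do.call(rbind, lapply(anns, function(a) {
    r <- rle(a$projection$base_at == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(start = starts[keep], len = r$lengths[keep])
  })))
  ins_events <- unique(do.call(rbind, lapply(anns, function(a) {
    a$projection$insertions
  })))

  region_of <- function(pos) {
    for (k in seq_len(nrow(locus$ssr_regions))) {
      if (pos > locus$ssr_regions[k, 1] && pos <= locus$ssr_regions[k, 2]) {
        return(k)
      }
    }
    NA_integer_
  }
  indel_lengths <- integer(0)
  if (!is.null(del_events) && nrow(del_events)) {
    for (m in seq_len(nrow(del_events))) {
      span <- del_events$start[m]:(del_events$start[m] + del_events$len[m] - 1L)
      if (all(in_ssr[span])) {
        k <- region_of(span[1])
        if (!is.na(k) &&
            del_events$len[m] %% nchar(locus$ssr_motifs[k]) == 0L) {
          next  # stepwise repeat contraction
        }
      }
      indel_lengths <- c(indel_lengths, del_events$len[m])
    }
  }
  if (!is.null(ins_events) && nrow(ins_events)) {
    for (m in seq_len(nrow(ins_events))) {
      r <- ins_events$ref_pos[m]
      k <- NA_integer_
      for (kk in seq_len(nrow(locus$ssr_regions))) {
        if (r >= locus$ssr_regions[kk, 1] && r <= locus$ssr_regions[kk, 2]) {
          k <- kk; break
        }
      }
      if (!is.na(k) && is_motif_repeat(ins_events$seq[m],
                                       locus$ssr_motifs[k])) {
        next    # stepwise repeat expansion
      }
      indel_lengths <- c(indel_lengths, nchar(ins_events$seq[m]))
    }
  }

  ssr_len_mat <- vapply(anns, `[[`, numeric(nrow(locus$ssr_regions)) + 0,
                        "ssr_lengths")
  if (is.null(dim(ssr_len_mat))) ssr_len_mat <- rbind(ssr_len_mat)
  ssr_var <- any(apply(ssr_len_mat, 1L, function(v) length(unique(v)) > 1L))

  mutated <- any(vapply(anns, region_mutated, logical(1), locus = locus))

  out <- data.frame(
    locus_id = locus$locus_id,
    n_variable_sites = n_snps + length(indel_lengths) + as.integer(ssr_var),
    n_snps = n_snps, n_indels = length(indel_lengths),
    ssr_count_variable = ssr_var, mutated_motif = mutated,
    stringsAsFactors = FALSE)
  out$indel_lengths <- list(sort(indel_lengths))
  out
}

# Does any projected repeat region of this allele deviate from a pure
# (possibly truncated) tandem of the locus motif?
region_mutated <- function(ann, locus) {
  if (isTRUE(ann$paralog_suspect)) return(FALSE)
  for (k in seq_len(nrow(locus$ssr_regions))) {
    s0 <- locus$ssr_regions[k, 1]; e0 <- locus$ssr_regions[k, 2]
    u <- nchar(locus$ssr_motifs[k])
    ins <- ann$projection$insertions
    inner <- ins$ref_pos > s0 & ins$ref_pos < e0
    if (any(inner & !vapply(ins$seq, is_motif_repeat, logical(1),
                            motif = locus$ssr_motifs[k]))) {
      return(TRUE)  # non-unit insertion interrupts the array
    }
    bases <- ann$projection$base_at[(s0 + 1L):e0]
    region_seq <- paste(bases[bases != "-"], collapse = "")
    if (!nzchar(region_seq)) next
    # accept any rotation of the motif, truncated at the region end
    rots <- vapply(seq_len(u) - 1L, function(off) {
      paste0(substr(locus$ssr_motifs[k], off + 1L, u),
             substr(locus$ssr_motifs[k], 1L, off))
    }, character(1))
    tandem <- any(vapply(rots, function(rt) {
      region_seq == substr(strrep(rt, ceiling(nchar(region_seq) / u)),
                           1L, nchar(region_seq))
    }, logical(1)))
    if (!tandem) return(TRUE)
  }
  FALSE
}
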