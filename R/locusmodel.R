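#' Construct a locus specification
#'
#' A `locus_spec` describes one amplicon SSR locus: the primer pair, the
#' per-sample-set 10-nt tags appended to both primers, the reference amplicon
#' sequence (tag- and primer-free insert), and the annotated SSR region(s) on
#' that reference. Coordinates are 0-based, half-open on `reference_seq`.
#'
#' @param locus_id,species_id identifiers.
#' @param forward_primer,reverse_primer primer sequences (reference strand /
#'   its reverse complement, as ordered for synthesis).
#' @param barcodes named character vector, `set_id -> 10-nt tag`.
#' @param reference_seq reference insert sequence (no tags, no primers).
#' @param ssr_regions integer matrix with columns `start`, `end` (0-based,
#'   half-open), one row per repeat region; sorted, non-overlapping.
#' @param ssr_motifs character vector of repeat units (3-6 bp), one per region.
#' @return an object of class `locus_spec`.
#' @export
locus_spec <- function(locus_id, species_id, forward_primer, reverse_primer,
                       barcodes, reference_seq, ssr_regions, ssr_motifs) {
  ssr_regions <- matrix(as.integer(ssr_regions), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  stopifnot(is.character(barcodes), length(barcodes) >= 1,
            !is.null(names(barcodes)))
  if (any(nchar(barcodes) != 10L)) {
    stop("barcodes must be exactly 10 nt: locus ", locus_id, call. = FALSE)
  }
  n <- nchar(reference_seq)
  if (nrow(ssr_regions) != length(ssr_motifs)) {
    stop("one motif per SSR region required: locus ", locus_id, call. = FALSE)
  }
  if (nrow(ssr_regions) > 0) {
    if (any(ssr_regions[, 1] < 0L) || any(ssr_regions[, 2] > n) ||
        any(ssr_regions[, 2] <= ssr_regions[, 1])) {
      stop("SSR region outside reference: locus ", locus_id, call. = FALSE)
    }
    if (is.unsorted(ssr_regions[, 1], strictly = TRUE) ||
        any(ssr_regions[-1, 1] < ssr_regions[-nrow(ssr_regions), 2])) {
      stop("SSR regions must be sorted and non-overlapping: locus ", locus_id,
           call. = FALSE)
    }
    if (any(nchar(ssr_motifs) < 3L | nchar(ssr_motifs) > 6L)) {
      stop("SSR motif length must be in [3,6]: locus ", locus_id,
           call. = FALSE)
    }
  }
  structure(list(
    locus_id = locus_id, species_id = species_id,
    forward_primer = toupper(forward_primer),
    reverse_primer = toupper(reverse_primer),
    barcodes = barcodes, reference_seq = toupper(reference_seq),
    ssr_regions = ssr_regions, ssr_motifs = toupper(ssr_motifs)
  ), class = "locus_spec")
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %s (%s): %d bp reference, %d SSR region(s), %d set(s)\n",
              x$locus_id, x$species_id, nchar(x$reference_seq),
              nrow(x$ssr_regions), length(x$barcodes)))
  invisible(x)
}

LOCUS_TABLE_COLS <- c("locus_id", "species_id", "set_id", "barcode",
                      "forward_primer", "reverse_primer", "reference_seq",
                      "ssr_start", "ssr_end", "ssr_motif")

#' Read a locus table
#'
#' The table is tab-delimited with `#` comments and one row per
#' (locus, set, SSR region) combination; rows of a locus must agree on
#' primers and reference sequence, and each (locus, set) pair must map to a
#' single barcode.
#'
#' @param path TSV file with columns `locus_id, species_id, set_id, barcode,
#'   forward_primer, reverse_primer, reference_seq, ssr_start, ssr_end,
#'   ssr_motif`.
#' @return list of [locus_spec()] objects, one per locus.
#' @export
load_locus_table <- function(path) {
  df <- read.delim(path, comment.char = "#", colClasses = "character")
  missing <- setdiff(LOCUS_TABLE_COLS, names(df))
  if (length(missing)) {
    stop("locus table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$ssr_start <- as.integer(df$ssr_start)
  df$ssr_end <- as.integer(df$ssr_end)
  for (i in seq_len(nrow(df))) {
    if (nchar(df$barcode[i]) != 10L) {
      stop_row(i, "barcode '%s' is not 10 nt", df$barcode[i])
    }
    if (is.na(df$ssr_start[i]) || is.na(df$ssr_end[i]) ||
        df$ssr_end[i] <= df$ssr_start[i]) {
      stop_row(i, "malformed SSR interval")
    }
  }
  specs <- lapply(split(seq_len(nrow(df)), df$locus_id), function(idx) {
    sub <- df[idx, , drop = FALSE]
    if (length(unique(sub$forward_primer)) != 1 ||
        length(unique(sub$reverse_primer)) != 1 ||
        length(unique(sub$reference_seq)) != 1) {
      stop("inconsistent primer/reference rows for locus ", sub$locus_id[1],
           call. = FALSE)
    }
    bc <- unique(sub[, c("set_id", "barcode")])
    if (anyDuplicated(bc$set_id)) {
      stop_row(idx[which(duplicated(sub$set_id) &
                           !duplicated(sub[, c("set_id", "barcode")]))][1] %||%
                 idx[1],
               "duplicate (locus_id, set_id) with conflicting barcode: %s/%s",
               sub$locus_id[1], bc$set_id[anyDuplicated(bc$set_id)])
    }
    reg <- unique(sub[, c("ssr_start", "ssr_end", "ssr_motif")])
    reg <- reg[order(reg$ssr_start), , drop = FALSE]
    locus_spec(sub$locus_id[1], sub$species_id[1], sub$forward_primer[1],
               sub$reverse_primer[1], setNames(bc$barcode, bc$set_id),
               sub$reference_seq[1],
               cbind(reg$ssr_start, reg$ssr_end), reg$ssr_motif)
  })
  specs <- specs[order(names(specs))]
  message(sprintf("load_locus_table: %d rows -> %d loci", nrow(df),
                  length(specs)))
  unname(specs)
}

#' Write a locus table
#'
#' Inverse of [load_locus_table()]: `load_locus_table(write_locus_table(x))`
#' reproduces `x`.
#'
#' @param specs list of [locus_spec()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(specs, path) {
  rows <- do.call(rbind, lapply(specs, function(s) {
    grid <- expand.grid(set = names(s$barcodes),
                        region = seq_len(nrow(s$ssr_regions)),
                        stringsAsFactors = FALSE)
    data.frame(
      locus_id = s$locus_id, species_id = s$species_id,
      set_id = grid$set, barcode = unname(s$barcodes[grid$set]),
      forward_primer = s$forward_primer, reverse_primer = s$reverse_primer,
      reference_seq = s$reference_seq,
      ssr_start = s$ssr_regions[grid$region, 1],
      ssr_end = s$ssr_regions[grid$region, 2],
      ssr_motif = s$ssr_motifs[grid$region],
      stringsAsFactors = FALSE
    )
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `individual_id, set_id, pool_id,
#'   population_id, ploidy` and optional `replicate_of`.
#' @return data.frame; `replicate_of` is `NA` for primary samples.
#' @export
load_sample_sheet <- function(path) {
  df <- read.delim(path, comment.char = "#", colClasses = "character")
  need <- c("individual_id", "set_id", "pool_id", "population_id", "ploidy")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$ploidy <- as.integer(df$ploidy)
  if (!all(df$ploidy %in% c(2L, 4L))) {
    stop("ploidy must be 2 or 4", call. = FALSE)
  }
  if (!"replicate_of" %in% names(df)) df$replicate_of <- NA_character_
  df$replicate_of[!nzchar(df$replicate_of) | is.na(df$replicate_of)] <-
    NA_character_
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual_id in sample sheet", call. = FALSE)
  }
  df
}

#' Read a population map
#' @param path TSV with columns `individual_id, population_id`.
#' @return data.frame.
#' @export
load_population_map <- function(path) {
  df <- read.delim(path, comment.char = "#", colClasses = "character")
  stopifnot(all(c("individual_id", "population_id") %in% names(df)))
  df
}

#' Build an allele catalog from sequences
#'
#' Distinct sequences within a locus are sorted lexicographically and numbered
#' from 1 (`a1`, `a2`, ...), so catalogs are reproducible across runs
#' regardless of input order. Identical sequences always map to the same
#' allele id.
#'
#' @param locus_id character vector (recycled against `sequence`).
#' @param sequence character vector of tag- and primer-trimmed allele
#'   sequences.
#' @return data.frame with columns `locus_id, allele_id, sequence,
#'   fragment_length` (one row per distinct locus x sequence), sorted by
#'   locus then allele id.
#' @export
allele_catalog <- function(locus_id, sequence) {
  if (!length(sequence)) {
    return(data.frame(locus_id = character(), allele_id = character(),
                      sequence = character(), fragment_length = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(data.frame(locus_id = locus_id, sequence = toupper(sequence),
                          stringsAsFactors = FALSE))
  df <- df[order(df$locus_id, df$sequence, method = "radix"), , drop = FALSE]
  df$allele_id <- unlist(lapply(split(df$sequence, df$locus_id)[unique(df$locus_id)],
                                function(s) paste0("a", seq_along(s))),
                         use.names = FALSE)
  df$fragment_length <- nchar(df$sequence)
  rownames(df) <- NULL
  df[, c("locus_id", "allele_id", "sequence", "fragment_length")]
}

#' Write an allele catalog to FASTA
#'
#' One record per allele with header `locus_id|allele_id|len=<fragment_length>`.
#'
#' @param catalog data.frame as returned by [allele_catalog()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_catalog <- function(catalog, path) {
  headers <- sprintf("%s|%s|len=%d", catalog$locus_id, catalog$allele_id,
                     catalog$fragment_length)
  if (anyDuplicated(headers)) {
    stop("duplicate allele header: ", headers[anyDuplicated(headers)],
         call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an allele catalog from FASTA
#' @param path FASTA written by [write_allele_catalog()].
#' @return data.frame with `locus_id, allele_id, sequence, fragment_length`.
#' @export
read_allele_catalog <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    return(data.frame(locus_id = character(), allele_id = character(),
                      sequence = character(), fragment_length = integer()))
  }
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(
    locus_id = vapply(parts, `[`, "", 1),
    allele_id = vapply(parts, `[`, "", 2),
    sequence = as.character(seqs),
    fragment_length = nchar(as.character(seqs)),
    stringsAsFactors = FALSE
  )
}

#' Write a genotype table
#'
#' Long format: one row per called allele with columns
#' `individual_id, locus_id, allele_id, dosage, read_count`.
#'
#' @param genotypes data.frame in long format.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  need <- c("individual_id", "locus_id", "allele_id", "dosage", "read_count")
  stopifnot(all(need %in% names(genotypes)))
  write.table(genotypes[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a genotype table
#'
#' When `sample_sheet` is supplied, the dosages of every called
#' individual-by-locus cell must sum to that individual's ploidy.
#'
#' @param path TSV written by [write_genotype_table()].
#' @param sample_sheet optional data.frame from [load_sample_sheet()].
#' @return data.frame in long format.
#' @export
load_genotype_table <- function(path, sample_sheet = NULL) {
  df <- read.delim(path, comment.char = "#", colClasses = "character")
  df$dosage <- as.integer(df$dosage)
  df$read_count <- as.integer(df$read_count)
  if (!is.null(sample_sheet)) {
    ploidy <- setNames(sample_sheet$ploidy, sample_sheet$individual_id)
    sums <- tapply(df$dosage, paste(df$individual_id, df$locus_id, sep = "\r"),
                   sum)
    ind <- vapply(strsplit(names(sums), "\r", fixed = TRUE), `[`, "", 1)
    bad <- which(sums != ploidy[ind])
    if (length(bad)) {
      stop(sprintf("dosage sum %d != ploidy %d for %s",
                   sums[bad[1]], ploidy[ind[bad[1]]],
                   gsub("\r", " x ", names(sums)[bad[1]])), call. = FALSE)
    }
  }
  message(sprintf("load_genotype_table: %d rows", nrow(df)))
  df
}

#' Export a coded diploid dataset in Genepop format
#'
#' Intended for cross-checking diversity statistics with external
#' population-genetics software. Allele codes are written as 3-digit
#' integers; only diploid datasets can be represented.
#'
#' @param coded data.frame with columns `individual_id, locus, code, dosage`
#'   (one scheme of [code_datasets()]).
#' @param popmap data.frame `individual_id, population_id`.
#' @param path output path.
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(coded, popmap, path, title = "ssrseq export") {
  loci <- sort(unique(coded$locus))
  cells <- split(coded, paste(coded$individual_id, coded$locus, sep = "\r"))
  geno_str <- vapply(cells, function(cell) {
    copies <- rep(cell$code, cell$dosage)
    if (length(copies) != 2) {
      stop("write_genepop requires diploid calls", call. = FALSE)
    }
    sprintf("%03d%03d", copies[1], copies[2])
  }, character(1))
  lines <- c(title, loci)
  for (pop in unique(popmap$population_id)) {
    lines <- c(lines, "Pop")
    for (ind in popmap$individual_id[popmap$population_id == pop]) {
      gs <- vapply(loci, function(lc) {
        geno_str[paste(ind, lc, sep = "\r")] %||% "000000"
      }, character(1))
      gs[is.na(gs)] <- "000000"
      lines <- c(lines, paste0(ind, " ,  ", paste(gs, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
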