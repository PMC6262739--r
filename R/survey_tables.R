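# Bundled per-locus summary tables from a published three-species SSR
# amplicon-sequencing survey (Donatia fascicularis, Mulguraea tridens,
# Oreobolus obtusangulus). They serve as fixed reference inputs for the
# package's homoplasy, rare-allele and variable-site arithmetic.

survey_file <- function(name) {
  system.file("extdata", name, package = "ssrseq", mustWork = TRUE)
}

#' Published per-locus fragment-size-class counts
#' @return data.frame `species, locus, n_size_classes, n_homoplasious`.
#' @export
survey_homoplasy_classes <- function() {
  read.delim(survey_file("survey_homoplasy_classes.tsv"), comment.char = "#")
}

#' Published per-locus variation summaries
#' @return data.frame with motif, repeat counts, fragment lengths and
#'   variable-site tallies per locus.
#' @export
survey_locus_variation <- function() {
  df <- read.delim(survey_file("survey_locus_variation.tsv"),
                   comment.char = "#",
                   colClasses = c(indel_lengths = "character"))
  df$indel_lengths[is.na(df$indel_lengths)] <- ""
  # repeat count varies when the listing holds more than one value
  df$repeat_count_variable <- grepl("[,-]", df$repeat_counts)
  df
}

#' Published per-locus allele counts under the three coding schemes
#' @return data.frame `species, locus, na_ssr, na_frag, na_seq, rare_ssr,
#'   rare_frag, rare_seq` (NA where a sub-locus has no entry in a scheme).
#' @export
survey_allele_counts <- function() {
  read.delim(survey_file("survey_allele_counts.tsv"), comment.char = "#")
}
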