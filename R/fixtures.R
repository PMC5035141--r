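#' Packaged fold-change table for the 32 candidate transcriptional regulators
#'
#' Individual-treatment log2 induction fold changes (Six1, Eya1, Six1+Eya1
#' injection groups) for the 32 transcription factors and co-factors selected
#' for characterisation in the published Six1/Eya1 direct-target screen of
#' Xenopus pre-placodal explants. \code{NA} marks entries printed as absent
#' (below the reporting floor). Feeding this table to
#' \code{\link{well_supported_list}} with the default threshold reproduces the
#' published selection: 30 passing regulators, with Ngn1 and Sox3 the only
#' sub-threshold rows.
#'
#' @return data.frame with columns \code{gene_id}, \code{accession},
#'   \code{fc_six1}, \code{fc_eya1}, \code{fc_six1_eya1}.
#' @export
tf_candidate_fold_changes <- function() {
  path <- system.file("extdata", "tf_candidates_log2fc.tsv",
                      package = "ppescreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged Venn region counts reported for the screen
#'
#' Per-direction counts of differentially expressed genes in each of the
#' seven Venn regions over the three treatment groups (S = Six1 alone,
#' E = Eya1 alone, C = combined), as reported for the real screen data. The
#' up-direction marginals are 365/508/836 and the down-direction marginals
#' 292/218/490.
#'
#' @param direction \code{"up"} or \code{"down"}.
#' @return named integer vector over the 7 regions.
#' @export
reported_venn_counts <- function(direction = c("up", "down")) {
  direction <- match.arg(direction)
  path <- system.file("extdata", "venn_region_counts.tsv",
                      package = "ppescreen", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$direction == direction, ]
  stats::setNames(as.integer(tab$count), tab$region)[VENN_REGIONS]
}

#' Packaged list of previously established Six1 targets
#'
#' Gene identifiers of Six1 targets established in earlier studies, used to
#' gauge screen quality via \code{\link{known_target_recovery}}.
#'
#' @return data.frame with columns \code{gene_id} and \code{source}.
#' @export
known_six1_targets <- function() {
  path <- system.file("extdata", "known_six1_targets.tsv",
                      package = "ppescreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
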