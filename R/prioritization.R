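#' Build the well-supported candidate list
#'
#' A gene is well supported when its log2 induction fold change meets the
#' threshold in at least two of the three individual treatment groups
#' (missing entries fail the threshold) and, when a control column is
#' supplied and \code{require_control} is set, every passing group's fold
#' change exceeds the un-injected control fold change by at least
#' \code{control_delta_min_log2}.
#'
#' @param fc_table data.frame with columns \code{gene_id}, \code{fc_six1},
#'   \code{fc_eya1}, \code{fc_six1_eya1} and optionally \code{fc_control};
#'   \code{NA} marks an absent fold-change entry.
#' @param fc_min_log2 per-group log2 fold-change threshold (default 1,
#'   boundary inclusive).
#' @param require_control apply the control-difference clause (needs an
#'   \code{fc_control} column).
#' @param control_delta_min_log2 minimum log2 difference to the control fold
#'   change (default 1).
#' @return data.frame with the fold-change columns plus
#'   \code{n_groups_passing} (0-3) and \code{well_supported}.
#' @export
well_supported_list <- function(fc_table, fc_min_log2 = 1,
                                require_control = FALSE,
                                control_delta_min_log2 = 1) {
  group_cols <- c("fc_six1", "fc_eya1", "fc_six1_eya1")
  missing_cols <- setdiff(c("gene_id", group_cols), names(fc_table))
  if (length(missing_cols))
    stop("fc_table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  fc <- as.matrix(fc_table[, group_cols])
  pass <- !is.na(fc) & fc >= fc_min_log2
  n_pass <- rowSums(pass)
  ws <- n_pass >= 2
  if (require_control) {
    if (!"fc_control" %in% names(fc_table))
      stop("require_control = TRUE needs an 'fc_control' column")
    delta <- fc - fc_table$fc_control
    ctrl_ok <- vapply(seq_len(nrow(fc)), function(i) {
      idx <- which(pass[i, ])
      length(idx) > 0 && all(delta[i, idx] >= control_delta_min_log2)
    }, logical(1))
    ws <- ws & ctrl_ok
  }
  out <- fc_table
  out$n_groups_passing <- as.integer(n_pass)
  out$well_supported <- ws
  out
}

#' Select candidate transcription factors, with manual rescues
#'
#' Restricts a well-supported candidate table to an explicit transcription
#' factor / co-factor list (curatorial input, never inferred), and re-includes
#' named rescue genes regardless of their threshold status. A rescue gene that
#' already passes on its own appears once with \code{rescue = FALSE}.
#'
#' @param records output of \code{\link{well_supported_list}}.
#' @param tf_annotation character vector of gene ids annotated as
#'   transcription factors or co-factors.
#' @param rescue character vector of gene ids to include regardless of
#'   status; every rescue gene must be present in \code{records}.
#' @return subset of \code{records} with added \code{is_tf} and \code{rescue}
#'   columns.
#' @export
select_candidates <- function(records, tf_annotation, rescue = character()) {
  absent <- setdiff(rescue, records$gene_id)
  if (length(absent))
    stop("rescue gene(s) absent from the candidate table: ",
         paste(absent, collapse = ", "))
  records$is_tf <- records$gene_id %in% tf_annotation
  by_threshold <- records$well_supported & records$is_tf
  keep <- by_threshold | records$gene_id %in% rescue
  out <- records[keep, , drop = FALSE]
  out$rescue <- out$gene_id %in% rescue & !(out$well_supported & out$is_tf)
  rownames(out) <- NULL
  out
}

#' Recovery report for externally established targets
#'
#' For each known target, reports whether it is present in the screened
#' transcriptome, its per-group fold changes where present, and (when DE sets
#' are supplied) the treatment groups in which it was called differentially
#' expressed. Presence is reported with fold changes rather than thresholded:
#' recovery of an established target is informative even below the screen's
#' own DE cutoff.
#'
#' @param fc_table data.frame with \code{gene_id} and per-group fold-change
#'   columns (\code{fc_six1}, \code{fc_eya1}, \code{fc_six1_eya1}).
#' @param known_targets character vector of gene ids, or data.frame with
#'   columns \code{gene_id} and \code{source}.
#' @param de_sets optional named list of DE gene-id vectors per group.
#' @return data.frame per known target with \code{in_transcriptome}, the fold
#'   changes, and \code{de_in} (comma-separated group names, \code{""} if
#'   none); the \code{summary} attribute holds the counts.
#' @export
known_target_recovery <- function(fc_table, known_targets, de_sets = NULL) {
  if (!is.data.frame(known_targets)) {
    ids <- as.character(known_targets)
    known_targets <- data.frame(gene_id = ids,
                                source = rep(NA_character_, length(ids)),
                                stringsAsFactors = FALSE)
  }
  if (!nrow(known_targets)) {
    out <- data.frame(gene_id = character(), source = character(),
                      in_transcriptome = logical(), fc_six1 = numeric(),
                      fc_eya1 = numeric(), fc_six1_eya1 = numeric(),
                      de_in = character(), stringsAsFactors = FALSE)
    attr(out, "summary") <- c(n_known = 0L, n_in_transcriptome = 0L,
                              n_de = 0L)
    return(out)
  }
  idx <- match(known_targets$gene_id, fc_table$gene_id)
  present <- !is.na(idx)
  grab <- function(col) {
    if (col %in% names(fc_table)) fc_table[[col]][idx] else NA_real_
  }
  de_in <- vapply(known_targets$gene_id, function(g) {
    if (is.null(de_sets)) return(NA_character_)
    hit <- names(de_sets)[vapply(de_sets, function(s) g %in% s, logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
  out <- data.frame(gene_id = known_targets$gene_id,
                    source = known_targets$source,
                    in_transcriptome = present,
                    fc_six1 = grab("fc_six1"),
                    fc_eya1 = grab("fc_eya1"),
                    fc_six1_eya1 = grab("fc_six1_eya1"),
                    de_in = unname(de_in),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    n_known = nrow(out),
    n_in_transcriptome = sum(present),
    n_de = if (is.null(de_sets)) NA_integer_ else sum(nzchar(de_in), na.rm = TRUE))
  out
}
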