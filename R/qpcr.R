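#' Read a qPCR Ct table
#'
#' Tab-separated with columns \code{gene_id}, \code{condition}
#' (\code{chx} or \code{chx_dex}), \code{biological_replicate},
#' \code{ct_target}, \code{ct_reference}.
#'
#' @param path path to the TSV.
#' @return validated data.frame.
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "condition", "biological_replicate", "ct_target",
              "ct_reference")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("qPCR table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Relative quantification of induction from qPCR Ct values
#'
#' Standard delta-delta-Ct against a reference gene (Smn2 in the screen's
#' assay design). Per gene and biological replicate, technical replicates are
#' first mean-collapsed on Ct, then
#' \code{delta_Ct = Ct(target) - Ct(reference)} within each condition,
#' \code{ddCt = delta_Ct(chx_dex) - delta_Ct(chx)},
#' \code{RQ = efficiency^(-ddCt)} and \code{log2FC = -ddCt * log2(efficiency)}.
#' RQ and log2 fold change are each averaged arithmetically across biological
#' replicates, with standard deviations.
#'
#' @param measurements data.frame as returned by
#'   \code{\link{read_qpcr_table}}; every (gene, biological replicate) must
#'   have both conditions.
#' @param efficiency assumed amplification efficiency (default 2, i.e. exact
#'   doubling per cycle).
#' @return list with \code{per_replicate} (per gene and replicate: delta-Cts,
#'   \code{delta_delta_ct}, \code{rq}, \code{log2fc}) and \code{summary}
#'   (per gene: \code{n_replicates}, \code{mean_rq}, \code{sd_rq},
#'   \code{mean_log2fc}, \code{sd_log2fc}).
#' @export
relative_quantification <- function(measurements, efficiency = 2) {
  if (efficiency <= 1) stop("amplification efficiency must be > 1")
  m <- measurements
  bad <- !m$condition %in% TREATMENT_TOKENS
  if (any(bad))
    stop("unknown qPCR condition '", m$condition[which(bad)[1]],
         "' (expected chx or chx_dex)")
  cts <- c(m$ct_target, m$ct_reference)
  if (anyNA(cts) || any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be positive and finite")
  # collapse technical replicates
  agg <- stats::aggregate(
    cbind(ct_target, ct_reference) ~ gene_id + condition + biological_replicate,
    data = m, FUN = mean)
  agg$delta_ct <- agg$ct_target - agg$ct_reference
  wide <- merge(
    agg[agg$condition == "chx",
        c("gene_id", "biological_replicate", "delta_ct")],
    agg[agg$condition == "chx_dex",
        c("gene_id", "biological_replicate", "delta_ct")],
    by = c("gene_id", "biological_replicate"), all = TRUE,
    suffixes = c("_chx", "_chx_dex"))
  incomplete <- is.na(wide$delta_ct_chx) | is.na(wide$delta_ct_chx_dex)
  if (any(incomplete)) {
    i <- which(incomplete)[1]
    stop("gene '", wide$gene_id[i], "' biological replicate ",
         wide$biological_replicate[i], " is missing one condition")
  }
  wide$delta_delta_ct <- wide$delta_ct_chx_dex - wide$delta_ct_chx
  wide$rq <- efficiency^(-wide$delta_delta_ct)
  wide$log2fc <- -wide$delta_delta_ct * log2(efficiency)
  wide <- wide[order(wide$gene_id, wide$biological_replicate), , drop = FALSE]
  rownames(wide) <- NULL
  summ <- do.call(rbind, lapply(split(wide, wide$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], n_replicates = nrow(d),
               mean_rq = mean(d$rq), sd_rq = stats::sd(d$rq),
               mean_log2fc = mean(d$log2fc), sd_log2fc = stats::sd(d$log2fc),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_replicate = wide, summary = summ)
}
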