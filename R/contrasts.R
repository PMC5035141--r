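#' Per-group induction contrast (CHX+DEX vs CHX)
#'
#' For one injection group, averages FPKM over replicates within each
#' treatment and reports the log2 fold change of the DEX-induced condition
#' over the CHX-only baseline, with a pseudocount:
#' \code{log2((mean_dex + pseudocount) / (mean_chx + pseudocount))}.
#'
#' @param x an \code{expr_matrix}.
#' @param injection injection-group token present in \code{x}.
#' @param pseudocount added to both mean FPKMs before the ratio (default 1,
#'   matching the log2(FPKM+1) display scale used throughout the screen).
#' @return data.frame of class \code{contrast_result} with columns
#'   \code{gene_id}, \code{injection}, \code{mean_fpkm_chx},
#'   \code{mean_fpkm_dex}, \code{log2fc}, \code{n_chx}, \code{n_dex}.
#' @export
compute_contrast <- function(x, injection, pseudocount = 1) {
  chx <- samples_for(x, injection, "chx")
  dex <- samples_for(x, injection, "chx_dex")
  if (!length(chx))
    stop("no 'chx' samples for injection group '", injection, "'")
  if (!length(dex))
    stop("no 'chx_dex' samples for injection group '", injection, "'")
  mean_chx <- rowMeans(x$values[, chx, drop = FALSE])
  mean_dex <- rowMeans(x$values[, dex, drop = FALSE])
  out <- data.frame(gene_id = rownames(x$values),
                    injection = injection,
                    mean_fpkm_chx = mean_chx,
                    mean_fpkm_dex = mean_dex,
                    log2fc = log2((mean_dex + pseudocount) /
                                  (mean_chx + pseudocount)),
                    n_chx = length(chx), n_dex = length(dex),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Differential-expression filter criteria
#'
#' The screen's three-criterion cascade: (1) an expression floor on the
#' induced condition, (2) a minimum induction fold change, (3) an un-injected
#' control comparison excluding DEX artifacts. Two control rules are
#' available: \code{"delta"} requires the experimental fold change to exceed
#' the control fold change by \code{control_delta_min_log2} (two-fold by
#' default, stated symmetrically for both directions), while
#' \code{"absolute"} simply caps the control fold change at
#' \code{control_abs_max_log2}.
#'
#' @param fc_min_log2 minimum |log2 fold change| (default 1, i.e. two-fold).
#' @param fpkm_min minimum mean FPKM in the CHX+DEX condition (default 1).
#' @param control_rule \code{"delta"} (default) or \code{"absolute"}.
#' @param control_delta_min_log2 minimum log2 difference between experimental
#'   and control fold change under the delta rule (default 1).
#' @param control_abs_max_log2 maximum control |log2 fold change| under the
#'   absolute rule (default 0.5).
#' @return list of class \code{de_filter_criteria}.
#' @export
de_filter_criteria <- function(fc_min_log2 = 1, fpkm_min = 1,
                               control_rule = c("delta", "absolute"),
                               control_delta_min_log2 = 1,
                               control_abs_max_log2 = 0.5) {
  control_rule <- match.arg(control_rule)
  if (fc_min_log2 < 0 || fpkm_min < 0 || control_delta_min_log2 < 0 ||
      control_abs_max_log2 < 0)
    stop("all thresholds must be >= 0")
  structure(list(fc_min_log2 = fc_min_log2, fpkm_min = fpkm_min,
                 control_rule = control_rule,
                 control_delta_min_log2 = control_delta_min_log2,
                 control_abs_max_log2 = control_abs_max_log2),
            class = "de_filter_criteria")
}

#' Apply the three-criterion DE filter cascade
#'
#' A gene passes the up-direction filter when its induced-condition mean FPKM
#' meets the floor, its induction log2 fold change meets the threshold, and
#' the un-injected control rule holds (delta rule: experimental minus control
#' fold change at least \code{control_delta_min_log2}; absolute rule: control
#' fold change below \code{control_abs_max_log2}). The down direction is the
#' mirror image on the fold-change clauses; the expression floor stays on the
#' CHX+DEX condition in both directions, as the cascade is defined.
#'
#' @param experimental \code{contrast_result} for an injected group.
#' @param control \code{contrast_result} for the un-injected group, covering
#'   the same genes.
#' @param criteria a \code{\link{de_filter_criteria}}.
#' @param direction \code{"up"} or \code{"down"}.
#' @return character vector of passing gene ids.
#' @export
apply_de_filters <- function(experimental, control,
                             criteria = de_filter_criteria(),
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!setequal(experimental$gene_id, control$gene_id)) {
    odd <- c(setdiff(experimental$gene_id, control$gene_id),
             setdiff(control$gene_id, experimental$gene_id))
    stop("experimental and control contrasts cover different genes (e.g. ",
         odd[1], ")")
  }
  ctrl <- control$log2fc[match(experimental$gene_id, control$gene_id)]
  lfc <- experimental$log2fc
  floor_ok <- experimental$mean_fpkm_dex >= criteria$fpkm_min
  if (direction == "up") {
    fc_ok <- lfc >= criteria$fc_min_log2
    ctrl_ok <- if (criteria$control_rule == "delta")
      lfc - ctrl >= criteria$control_delta_min_log2
    else ctrl < criteria$control_abs_max_log2
  } else {
    fc_ok <- lfc <= -criteria$fc_min_log2
    ctrl_ok <- if (criteria$control_rule == "delta")
      ctrl - lfc >= criteria$control_delta_min_log2
    else ctrl > -criteria$control_abs_max_log2
  }
  experimental$gene_id[floor_ok & fc_ok & ctrl_ok]
}

#' Per-group screen table
#'
#' Convenience wrapper combining a group's contrast, the control contrast and
#' both filter directions into one table (the per-group analogue of the
#' screen's supplementary DE tables).
#'
#' @inheritParams apply_de_filters
#' @return data.frame with \code{gene_id}, means, \code{log2fc},
#'   \code{control_log2fc}, \code{pass_up}, \code{pass_down}.
#' @export
screen_table <- function(experimental, control,
                         criteria = de_filter_criteria()) {
  up <- apply_de_filters(experimental, control, criteria, "up")
  down <- apply_de_filters(experimental, control, criteria, "down")
  data.frame(gene_id = experimental$gene_id,
             injection = experimental$injection,
             mean_fpkm_chx = experimental$mean_fpkm_chx,
             mean_fpkm_dex = experimental$mean_fpkm_dex,
             log2fc = experimental$log2fc,
             control_log2fc =
               control$log2fc[match(experimental$gene_id, control$gene_id)],
             pass_up = experimental$gene_id %in% up,
             pass_down = experimental$gene_id %in% down,
             row.names = NULL, stringsAsFactors = FALSE)
}
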