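MERGED_SCHEMES <- list(
  six1_m      = c("six1", "six1_eya1"),
  eya1_m      = c("eya1", "six1_eya1"),
  six1_eya1_m = c("six1", "eya1", "six1_eya1")
)

#' Merged-replicate pooling scheme
#'
#' The merged re-analysis treats replicates from several injection groups as
#' equivalent to gain statistical power: \code{six1_m} pools every group
#' overexpressing Six1 (Six1 alone and Six1+Eya1; 4 replicates per
#' treatment at the default design), \code{eya1_m} the Eya1-containing
#' groups, and \code{six1_eya1_m} all three injected groups (6 replicates).
#' The un-injected control group is never pooled.
#'
#' @param name one of \code{"six1_m"}, \code{"eya1_m"}, \code{"six1_eya1_m"}.
#' @return list of class \code{merged_scheme} with \code{name} and
#'   \code{member_groups}.
#' @export
merged_scheme <- function(name = c("six1_m", "eya1_m", "six1_eya1_m")) {
  name <- match.arg(name)
  structure(list(name = name, member_groups = MERGED_SCHEMES[[name]]),
            class = "merged_scheme")
}

#' Pool replicates across injection groups
#'
#' Subsets an expression matrix to a scheme's member groups and relabels the
#' samples into two pooled conditions (CHX vs CHX+DEX) under the scheme's
#' name, renumbering replicates consecutively in member-group order.
#'
#' @param x an \code{expr_matrix} containing all member groups.
#' @param scheme a \code{\link{merged_scheme}} (or its name).
#' @return an \code{expr_matrix} whose injection token is the scheme name.
#' @export
merge_replicates <- function(x, scheme) {
  if (is.character(scheme)) scheme <- merged_scheme(scheme)
  keep_rows <- list()
  for (grp in scheme$member_groups) {
    rows <- x$samples[x$samples$injection == grp, , drop = FALSE]
    if (!nrow(rows))
      stop("injection group '", grp, "' required by scheme '", scheme$name,
           "' is missing from the matrix")
    keep_rows[[grp]] <- rows[order(rows$treatment, rows$replicate), ,
                             drop = FALSE]
  }
  pooled <- do.call(rbind, keep_rows)
  pooled$injection <- scheme$name
  for (trt in TREATMENT_TOKENS) {
    sel <- pooled$treatment == trt
    pooled$replicate[sel] <- seq_len(sum(sel))
  }
  vals <- x$values[, pooled$sample_id, drop = FALSE]
  pooled$sample_id <- paste(scheme$name, pooled$treatment,
                            paste0("r", pooled$replicate), sep = "_")
  colnames(vals) <- pooled$sample_id
  rownames(pooled) <- NULL
  expression_matrix(vals, pooled, strict_tokens = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \code{q_i = min over ranks j >= rank(i) of p_(j) * m / j}, capped at 1,
#' returned in input order. Delegates to \code{stats::p.adjust} after
#' validating the input range.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Welch test of induction on a merged matrix
#'
#' Per gene, an unequal-variance two-sample t test on log2(FPKM+1) replicate
#' values, CHX+DEX vs CHX, with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value; q-values by Benjamini-Hochberg. A gene is called
#' significant when \code{q < alpha} and it additionally passes the
#' fold-change filter cascade for the pooled contrast (criterion 3, the
#' control comparison, is applied when an un-injected control contrast is
#' supplied). Degenerate genes with zero variance in both conditions get
#' \code{p = 1} when the means are equal, and the minimum representable
#' positive p-value (flagged \code{degenerate}) when they differ.
#'
#' @param x a merged \code{expr_matrix} from \code{\link{merge_replicates}}
#'   with at least 2 replicates per pooled condition.
#' @param control optional \code{contrast_result} for the un-injected group
#'   covering the same genes; enables the control filter criterion.
#' @param criteria a \code{\link{de_filter_criteria}}.
#' @param alpha significance level on the q-value (default 0.05).
#' @param pseudocount pseudocount for the pooled fold change (default 1).
#' @return data.frame of class \code{merged_result}: \code{gene_id},
#'   \code{log2fc}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{q_value}, \code{degenerate}, \code{pass_filters},
#'   \code{significant}.
#' @export
test_merged <- function(x, control = NULL, criteria = de_filter_criteria(),
                        alpha = 0.05, pseudocount = 1) {
  scheme_token <- unique(x$samples$injection)
  if (length(scheme_token) != 1)
    stop("'x' must be a merged matrix with a single pooled injection token")
  chx <- samples_for(x, scheme_token, "chx")
  dex <- samples_for(x, scheme_token, "chx_dex")
  if (length(chx) < 2 || length(dex) < 2)
    stop("need >= 2 replicates per pooled condition (got ", length(chx),
         " chx, ", length(dex), " chx_dex)")
  y1 <- log2(x$values[, chx, drop = FALSE] + 1)
  y2 <- log2(x$values[, dex, drop = FALSE] + 1)
  n1 <- ncol(y1); n2 <- ncol(y2)
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  v1 <- rowSums((y1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((y2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  degenerate <- se2 == 0
  equal_means <- degenerate & (m1 == m2)
  p[equal_means] <- 1
  stat[equal_means] <- 0
  p[degenerate & !equal_means] <- .Machine$double.xmin
  stat[degenerate & !equal_means] <- sign(m2 - m1)[degenerate & !equal_means] * Inf
  q <- benjamini_hochberg(p)

  pooled <- compute_contrast(x, scheme_token, pseudocount)
  if (!is.null(control)) {
    pass <- pooled$gene_id %in% union(
      apply_de_filters(pooled, control, criteria, "up"),
      apply_de_filters(pooled, control, criteria, "down"))
  } else {
    floor_ok <- pooled$mean_fpkm_dex >= criteria$fpkm_min
    pass <- floor_ok & abs(pooled$log2fc) >= criteria$fc_min_log2
  }
  out <- data.frame(gene_id = pooled$gene_id,
                    log2fc = pooled$log2fc,
                    statistic = unname(stat), df = unname(df),
                    p_value = unname(p), q_value = q,
                    degenerate = unname(degenerate & !equal_means),
                    pass_filters = pass,
                    significant = q < alpha & pass,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme_token
  attr(out, "alpha") <- alpha
  class(out) <- c("merged_result", "data.frame")
  out
}
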