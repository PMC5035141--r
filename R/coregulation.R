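#' Venn region and regulatory class labels
#'
#' \code{VENN_REGIONS} names the seven disjoint regions over the three
#' treatment-group DE sets (S = Six1 alone, E = Eya1 alone, C = combined);
#' \code{REG_CLASSES} the five regulatory classes assigned by
#' \code{\link{classify_coregulation}}.
#'
#' @format character vectors.
#' @export
VENN_REGIONS <- c("S_only", "E_only", "C_only", "SE_only", "SC_only",
                  "EC_only", "SEC")

#' @rdname VENN_REGIONS
#' @export
REG_CLASSES <- c("coregulated_all_three", "coregulated_combined_only",
                 "six1_independent", "eya1_independent", "ambiguous_pair_only")

#' Partition DE gene sets across the three treatment groups
#'
#' Splits the union of the Six1-alone (S), Eya1-alone (E) and combined (C)
#' differential-expression sets into the seven disjoint Venn regions. Region
#' counts satisfy the marginal identity, e.g.
#' \code{|S| = S_only + SE_only + SC_only + SEC}.
#'
#' @param six1,eya1,combined character vectors of DE gene ids for the three
#'   treatment groups.
#' @param direction optional direction label ("up"/"down") carried on the
#'   result.
#' @return object of class \code{venn_partition}: list with \code{direction}
#'   and \code{regions} (named list of 7 disjoint gene-id vectors).
#' @export
partition_de_sets <- function(six1, eya1, combined, direction = NA_character_) {
  s <- unique(as.character(six1))
  e <- unique(as.character(eya1))
  co <- unique(as.character(combined))
  all_genes <- union(union(s, e), co)
  ms <- all_genes %in% s
  me <- all_genes %in% e
  mc <- all_genes %in% co
  regions <- list(
    S_only  = all_genes[ms & !me & !mc],
    E_only  = all_genes[!ms & me & !mc],
    C_only  = all_genes[!ms & !me & mc],
    SE_only = all_genes[ms & me & !mc],
    SC_only = all_genes[ms & !me & mc],
    EC_only = all_genes[!ms & me & mc],
    SEC     = all_genes[ms & me & mc]
  )
  structure(list(direction = direction, regions = regions),
            class = "venn_partition")
}

#' Region counts of a Venn partition
#'
#' @param partition a \code{venn_partition}.
#' @return named integer vector over the 7 regions.
#' @export
venn_counts <- function(partition) {
  vapply(partition$regions, length, integer(1))
}

#' Realise a Venn partition from region counts
#'
#' Builds a partition over synthetic gene ids whose region counts equal the
#' given vector; used to replay region counts reported for real data through
#' the classifier.
#'
#' @param counts named numeric vector over (a subset of) the 7 regions.
#' @param direction direction label carried on the result.
#' @param prefix prefix for the generated gene ids.
#' @return a \code{venn_partition}.
#' @export
venn_partition_from_counts <- function(counts, direction = NA_character_,
                                       prefix = "g") {
  unknown <- setdiff(names(counts), VENN_REGIONS)
  if (length(unknown))
    stop("unknown Venn region: ", paste(unknown, collapse = ", "))
  full <- stats::setNames(integer(length(VENN_REGIONS)), VENN_REGIONS)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("region counts must be >= 0")
  regions <- lapply(VENN_REGIONS, function(r) {
    if (full[[r]] == 0) character() else
      sprintf("%s_%s_%04d", prefix, r, seq_len(full[[r]]))
  })
  names(regions) <- VENN_REGIONS
  structure(list(direction = direction, regions = regions),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition", if (!is.na(x$direction)) paste0("(", x$direction, ")"),
      "\n")
  print(venn_counts(x))
  invisible(x)
}

#' Classify co-regulation from a Venn partition
#'
#' Assigns each gene one regulatory class: genes DE in all three groups are
#' \code{coregulated_all_three}; genes DE only after combined injection are
#' \code{coregulated_combined_only}; genes DE in the Six1 group but never in
#' the Eya1 group are \code{six1_independent} (and vice versa for
#' \code{eya1_independent}); genes DE in both single-factor groups but not the
#' combined group form the separate \code{ambiguous_pair_only} class, which is
#' not counted in the co-regulated aggregate.
#'
#' @param partition a \code{venn_partition}.
#' @return data.frame with \code{gene_id}, \code{direction},
#'   \code{reg_class}; the \code{coregulated} attribute holds the co-regulated
#'   aggregate (all-three plus combined-only gene ids).
#' @export
classify_coregulation <- function(partition) {
  r <- partition$regions
  class_of <- c(
    stats::setNames(rep("coregulated_all_three", length(r$SEC)), r$SEC),
    stats::setNames(rep("coregulated_combined_only", length(r$C_only)), r$C_only),
    stats::setNames(rep("six1_independent", length(r$S_only) + length(r$SC_only)),
                    c(r$S_only, r$SC_only)),
    stats::setNames(rep("eya1_independent", length(r$E_only) + length(r$EC_only)),
                    c(r$E_only, r$EC_only)),
    stats::setNames(rep("ambiguous_pair_only", length(r$SE_only)), r$SE_only)
  )
  out <- data.frame(gene_id = if (is.null(names(class_of))) character()
                              else names(class_of),
                    direction = rep(partition$direction,
                                    length.out = length(class_of)),
                    reg_class = unname(class_of),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "coregulated") <- c(r$SEC, r$C_only)
  out
}

#' Count genes per regulatory class
#'
#' @param calls output of \code{\link{classify_coregulation}}.
#' @return named integer vector over the five classes plus the
#'   \code{coregulated} aggregate.
#' @export
coregulation_counts <- function(calls) {
  n <- vapply(REG_CLASSES, function(cl) sum(calls$reg_class == cl), integer(1))
  c(n, coregulated = unname(n["coregulated_all_three"] +
                              n["coregulated_combined_only"]))
}

#' Direction balance of co-regulated genes
#'
#' Reports the fraction of the co-regulated aggregate that is up-regulated,
#' overall and restricted to genes supported by all three treatment groups.
#' Percentages are rounded to one decimal. A zero denominator yields an
#' explicit undefined marker rather than a number.
#'
#' @param up_calls,down_calls classification tables for the two directions.
#' @return list with \code{counts} (per-direction class counts) and the two
#'   fraction entries, each a list \code{(percent, defined)}.
#' @export
coregulation_summary <- function(up_calls, down_calls) {
  cu <- coregulation_counts(up_calls)
  cd <- coregulation_counts(down_calls)
  frac <- function(up, down) {
    if (up + down == 0)
      list(percent = NA_real_, defined = FALSE)
    else
      list(percent = round(100 * up / (up + down), 1), defined = TRUE)
  }
  list(counts = rbind(up = cu, down = cd),
       pct_up_coregulated = frac(cu[["coregulated"]], cd[["coregulated"]]),
       pct_up_all_three = frac(cu[["coregulated_all_three"]],
                               cd[["coregulated_all_three"]]))
}

#' Overlap of top-ranked fractions of two orderings
#'
#' Tests whether the top fraction (by descending fold change) of one ranking
#' is enriched for the top fraction of another over the same gene universe,
#' with a 2x2 Fisher exact test. The top-set size is
#' \code{ceiling(fraction * universe)}; fold-change ties are broken
#' lexicographically by gene id.
#'
#' @param ranked_a,ranked_b data.frames with columns \code{gene_id} and
#'   \code{log2fc} over the same gene universe (or character vectors already
#'   ordered by decreasing rank).
#' @param fraction top fraction, strictly between 0 and 1 (default 0.1).
#' @param alternative sidedness passed to the Fisher test
#'   (default \code{"two.sided"}).
#' @return list with the 2x2 \code{table}, \code{overlap}, \code{top_n},
#'   \code{odds_ratio} (sample odds ratio; \code{Inf} when a zero cell forces
#'   it) and \code{p_value}.
#' @export
top_fraction_overlap_test <- function(ranked_a, ranked_b, fraction = 0.1,
                                      alternative = "two.sided") {
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be strictly between 0 and 1")
  top_set <- function(r) {
    if (is.data.frame(r)) {
      ord <- order(-r$log2fc, r$gene_id)
      ids <- r$gene_id[ord]
    } else ids <- as.character(r)
    ids
  }
  a <- top_set(ranked_a)
  b <- top_set(ranked_b)
  if (!setequal(a, b))
    stop("the two rankings cover different gene universes")
  n <- length(a)
  k <- ceiling(fraction * n)
  top_a <- a[seq_len(k)]
  top_b <- b[seq_len(k)]
  overlap <- length(intersect(top_a, top_b))
  tab <- matrix(c(overlap, k - overlap,
                  k - overlap, n - 2 * k + overlap), 2, 2,
                dimnames = list(a = c("top", "rest"), b = c("top", "rest")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(table = tab, overlap = overlap, top_n = k,
       odds_ratio = or, p_value = ft$p.value)
}
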