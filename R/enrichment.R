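.check_enrichment_sets <- function(query, term, background) {
  if (!length(background)) stop("background gene set is empty")
  if (anyDuplicated(background)) background <- unique(background)
  if (length(setdiff(query, background)))
    stop("query genes outside the background set")
  if (length(setdiff(term, background)))
    stop("term genes outside the background set")
  list(query = unique(query), term = unique(term), background = background)
}

#' Fisher (upper-tail hypergeometric) enrichment p-value
#'
#' Probability of observing an overlap at least as large as the one between a
#' query set and a term's gene set, given the background universe and fixed
#' margins: \code{P(X >= k)} under the hypergeometric distribution.
#'
#' @param query character vector of query gene ids (subset of background).
#' @param term character vector of the term's gene ids (subset of background).
#' @param background character vector: the gene universe.
#' @return the upper-tail p-value in (0, 1].
#' @export
fisher_enrichment <- function(query, term, background) {
  s <- .check_enrichment_sets(query, term, background)
  k <- length(intersect(s$query, s$term))
  stats::phyper(k - 1, length(s$term),
                length(s$background) - length(s$term),
                length(s$query), lower.tail = FALSE)
}

#' EASE enrichment score (conservative modified Fisher p-value)
#'
#' Identical to \code{\link{fisher_enrichment}} except that one gene is
#' removed from the observed overlap (\code{max(k - 1, 0)}) while the margins
#' are kept fixed, which penalises terms supported by very few genes. Always
#' at least as large as the Fisher p-value.
#'
#' @inheritParams fisher_enrichment
#' @return the EASE p-value in (0, 1].
#' @export
ease_score <- function(query, term, background) {
  s <- .check_enrichment_sets(query, term, background)
  k <- max(length(intersect(s$query, s$term)) - 1, 0)
  stats::phyper(k - 1, length(s$term),
                length(s$background) - length(s$term),
                length(s$query), lower.tail = FALSE)
}

#' Per-term enrichment table for a gene-set collection
#'
#' @param query character vector of query gene ids.
#' @param terms named list of gene-id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param background character vector: the gene universe. Term genes outside
#'   the background are dropped before testing.
#' @return data.frame with \code{term_id}, \code{k}, \code{n_query},
#'   \code{n_term}, \code{n_background}, \code{fisher_p}, \code{ease_p}.
#' @export
enrichment_table <- function(query, terms, background) {
  background <- unique(background)
  query <- intersect(unique(query), background)
  rows <- lapply(names(terms), function(id) {
    tg <- intersect(unique(terms[[id]]), background)
    data.frame(term_id = id,
               k = length(intersect(query, tg)),
               n_query = length(query), n_term = length(tg),
               n_background = length(background),
               fisher_p = fisher_enrichment(query, tg, background),
               ease_p = ease_score(query, tg, background),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(), k = integer(),
                      n_query = integer(), n_term = integer(),
                      n_background = integer(), fisher_p = numeric(),
                      ease_p = numeric(), stringsAsFactors = FALSE)
  out[order(out$ease_p, out$term_id), , drop = FALSE]
}

#' Cluster enrichment score
#'
#' Summarises a cluster of related annotation terms as \code{E}, minus log10
#' of the geometric mean of the member terms' EASE p-values, computed in log
#' space to avoid underflow. P-values are floored at 1e-300.
#'
#' @param member_ease_p numeric vector of EASE p-values in (0, 1].
#' @return the non-negative enrichment score E.
#' @export
cluster_enrichment_score <- function(member_ease_p) {
  if (!length(member_ease_p)) stop("empty cluster: no EASE p-values")
  if (anyNA(member_ease_p) || any(member_ease_p <= 0 | member_ease_p > 1))
    stop("EASE p-values must lie in (0, 1]")
  p <- pmax(member_ease_p, 1e-300)
  -mean(log10(p))
}

#' Score user-defined term clusters
#'
#' @param enrichment output of \code{\link{enrichment_table}}.
#' @param clusters data.frame with columns \code{cluster_id} and
#'   \code{term_id} assigning terms to clusters.
#' @return data.frame with \code{cluster_id}, \code{n_terms},
#'   \code{enrichment_score}, ordered by decreasing score.
#' @export
score_clusters <- function(enrichment, clusters) {
  missing <- setdiff(clusters$term_id, enrichment$term_id)
  if (length(missing))
    stop("cluster term(s) absent from enrichment table: ",
         paste(missing, collapse = ", "))
  ids <- unique(clusters$cluster_id)
  rows <- lapply(ids, function(cl) {
    terms <- clusters$term_id[clusters$cluster_id == cl]
    p <- enrichment$ease_p[match(terms, enrichment$term_id)]
    data.frame(cluster_id = cl, n_terms = length(terms),
               enrichment_score = cluster_enrichment_score(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$enrichment_score, out$cluster_id), , drop = FALSE]
}

#' Functional-category composition of a gene set
#'
#' @param genes character vector of gene ids.
#' @param category_map named character vector (gene id -> category) or
#'   data.frame with columns \code{gene_id}, \code{category}. Genes without a
#'   category are reported as \code{"unclassified"}.
#' @return data.frame with \code{category}, \code{n}, \code{percent}
#'   (percentages sum to 100 within rounding), ordered by decreasing n.
#' @export
category_composition <- function(genes, category_map) {
  genes <- unique(as.character(genes))
  if (!length(genes))
    return(data.frame(category = character(), n = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  if (is.data.frame(category_map))
    category_map <- stats::setNames(as.character(category_map$category),
                                    category_map$gene_id)
  cat_of <- category_map[genes]
  cat_of[is.na(cat_of)] <- "unclassified"
  tab <- table(cat_of)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    percent = round(100 * as.integer(tab) / length(genes), 1),
                    stringsAsFactors = FALSE)
  out[order(-out$n, out$category), , drop = FALSE]
}
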