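# Controlled vocabulary for the factorial design. Injection tokens beyond
# these four appear only on merged (pooled) matrices created in-memory by
# merge_replicates(); sample sheets read from disk must use this set.
INJECTION_TOKENS <- c("six1", "eya1", "six1_eya1", "uninjected")
TREATMENT_TOKENS <- c("chx", "chx_dex")

#' Construct a validated expression matrix
#'
#' Bundles a gene-by-sample FPKM matrix with a design-aware sample sheet.
#' This is the substrate every stage of the screen operates on.
#'
#' @param values numeric matrix of non-negative FPKM values; rownames are
#'   gene identifiers, colnames are sample identifiers.
#' @param samples data.frame with columns \code{sample_id}, \code{injection},
#'   \code{treatment} and \code{replicate}, one row per matrix column.
#' @param strict_tokens if \code{TRUE}, require injection tokens to be one of
#'   \code{six1}, \code{eya1}, \code{six1_eya1}, \code{uninjected}. Merged
#'   matrices relax this to allow pooled-scheme labels.
#'
#' @return an object of class \code{expr_matrix}: a list with elements
#'   \code{values} and \code{samples}.
#' @export
expression_matrix <- function(values, samples, strict_tokens = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("'values' must have unique gene identifiers as rownames")
  if (anyNA(values) || any(values < 0))
    stop("FPKM values must be non-negative and non-missing")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  needed <- c("sample_id", "injection", "treatment", "replicate")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet has ", nrow(samples), " rows but matrix has ",
         ncol(values), " columns")
  if (is.null(colnames(values)))
    colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("matrix column names do not match sample sheet sample_id order")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  samples$replicate <- as.integer(samples$replicate)
  if (anyNA(samples$replicate) || any(samples$replicate < 1))
    stop("replicate must be a positive integer")
  bad_trt <- !samples$treatment %in% TREATMENT_TOKENS
  if (any(bad_trt))
    stop("unknown treatment token '", samples$treatment[which(bad_trt)[1]],
         "' in sample sheet row ", which(bad_trt)[1],
         " (expected one of: ", paste(TREATMENT_TOKENS, collapse = ", "), ")")
  if (strict_tokens) {
    bad_inj <- !samples$injection %in% INJECTION_TOKENS
    if (any(bad_inj))
      stop("unknown injection token '", samples$injection[which(bad_inj)[1]],
           "' in sample sheet row ", which(bad_inj)[1],
           " (expected one of: ", paste(INJECTION_TOKENS, collapse = ", "), ")")
  }
  key <- paste(samples$injection, samples$treatment, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicate (injection, treatment, replicate) triple in sample sheet: ",
         key[anyDuplicated(key)])
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("Injection groups:", paste(unique(x$samples$injection), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample identifiers for a design cell
#'
#' @param x an \code{expr_matrix}.
#' @param injection injection-group token.
#' @param treatment treatment token (\code{chx} or \code{chx_dex}).
#' @return character vector of sample ids (possibly empty).
#' @export
samples_for <- function(x, injection, treatment) {
  keep <- x$samples$injection == injection & x$samples$treatment == treatment
  x$samples$sample_id[keep]
}

subset_genes <- function(x, gene_ids) {
  expression_matrix(x$values[gene_ids, , drop = FALSE], x$samples,
                    strict_tokens = FALSE)
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is tab-separated with a \code{gene_id} first column and one
#' column per sample; the sample sheet is tab-separated with columns
#' \code{sample_id}, \code{injection}, \code{treatment}, \code{replicate}.
#' Sample metadata is joined by \code{sample_id}; every matrix column must be
#' described in the sheet.
#'
#' @param matrix_path path to the FPKM table.
#' @param sample_sheet_path path to the sample sheet.
#' @return an \code{expr_matrix}.
#' @export
read_expression_table <- function(matrix_path, sample_sheet_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab))
    stop("expression table must have a 'gene_id' column: ", matrix_path)
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", matrix_path)
  rownames(vals) <- tab$gene_id
  missing <- setdiff(colnames(vals), sheet$sample_id)
  if (length(missing))
    stop("sample(s) in matrix missing from sample sheet: ",
         paste(missing, collapse = ", "))
  sheet <- sheet[match(colnames(vals), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  expression_matrix(vals, sheet)
}

#' Write an expression matrix and its sample sheet
#'
#' @param x an \code{expr_matrix}.
#' @param matrix_path output path for the FPKM table.
#' @param sample_sheet_path output path for the sample sheet.
#' @return invisibly, the paths written.
#' @export
write_expression_table <- function(x, matrix_path, sample_sheet_path) {
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Read a 12-column BLAST tabular best-hit file
#'
#' Consumes the standard tabular dialect (query, subject, identity, length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore), drops
#' hits above the e-value cutoff and retains a single best hit per transcript:
#' highest bitscore, ties broken by lowest e-value and then lexicographic
#' subject id.
#'
#' @param path path to the tabular file (no comment lines).
#' @param e_value_cutoff maximum e-value retained (default \code{1e-5}).
#' @return data.frame with columns \code{transcript_id}, \code{annotation_id},
#'   \code{gene_symbol} (\code{NA} unless supplied downstream), \code{e_value}
#'   and \code{bitscore}; zero rows for an empty file.
#' @export
read_blast_tabular <- function(path, e_value_cutoff = 1e-5) {
  if (e_value_cutoff < 0) stop("e_value_cutoff must be >= 0")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(transcript_id = character(), annotation_id = character(),
                      gene_symbol = character(), e_value = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("malformed BLAST tabular row at line ", which(nf != 12L)[1],
         " of ", path, ": expected 12 tab-separated fields, found ",
         nf[which(nf != 12L)[1]])
  m <- do.call(rbind, fields)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  bad <- which(is.na(evalue) | is.na(bitscore))
  if (length(bad))
    stop("malformed BLAST tabular row at line ", bad[1], " of ", path,
         ": non-numeric evalue/bitscore")
  if (any(evalue < 0))
    stop("malformed BLAST tabular row at line ", which(evalue < 0)[1],
         " of ", path, ": negative e-value")
  hits <- data.frame(transcript_id = m[, 1], annotation_id = m[, 2],
                     gene_symbol = NA_character_, e_value = evalue,
                     bitscore = bitscore, stringsAsFactors = FALSE)
  hits <- hits[hits$e_value <= e_value_cutoff, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  ord <- order(hits$transcript_id, -hits$bitscore, hits$e_value,
               hits$annotation_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$transcript_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Condense duplicate annotations into uniquely annotated gene models
#'
#' Re-keys an expression matrix from transcript models to annotation ids.
#' Transcripts without a retained hit are dropped (their count is reported in
#' the \code{n_unannotated} attribute). When several transcript models share
#' an annotation, either the model with the highest mean FPKM across all
#' samples is kept (\code{method = "max"}, ties broken by lexicographic
#' transcript id) or FPKM values are summed (\code{method = "sum"}).
#'
#' @param x an \code{expr_matrix} keyed by transcript id.
#' @param hits best-hit table from \code{\link{read_blast_tabular}} (at most
#'   one hit per transcript).
#' @param method \code{"max"} (default) or \code{"sum"}.
#' @return an \code{expr_matrix} keyed by annotation id, with attributes
#'   \code{n_unannotated} (dropped transcript count) and
#'   \code{transcript_map} (named vector annotation -> kept transcript,
#'   \code{method = "max"} only).
#' @export
condense_annotations <- function(x, hits, method = c("max", "sum")) {
  method <- match.arg(method)
  if (anyDuplicated(hits$transcript_id))
    stop("'hits' must contain at most one hit per transcript; ",
         "run read_blast_tabular() first")
  idx <- match(rownames(x$values), hits$transcript_id)
  annotated <- !is.na(idx)
  n_unannotated <- sum(!annotated)
  vals <- x$values[annotated, , drop = FALSE]
  ann <- hits$annotation_id[idx[annotated]]
  if (method == "sum") {
    out <- rowsum(vals, group = ann, reorder = TRUE)
    res <- expression_matrix(out, x$samples, strict_tokens = FALSE)
    attr(res, "n_unannotated") <- n_unannotated
    return(res)
  }
  means <- rowMeans(vals)
  ord <- order(ann, -means, rownames(vals))
  keep <- ord[!duplicated(ann[ord])]
  keep <- keep[order(ann[keep])]
  out <- vals[keep, , drop = FALSE]
  tmap <- rownames(out)
  rownames(out) <- ann[keep]
  names(tmap) <- ann[keep]
  res <- expression_matrix(out, x$samples, strict_tokens = FALSE)
  attr(res, "n_unannotated") <- n_unannotated
  attr(res, "transcript_map") <- tmap
  res
}

#' Remove genes expressed at low levels
#'
#' Retains genes whose mean FPKM across all samples is at least
#' \code{fpkm_min} (boundary inclusive); row order is preserved. This is the
#' transcriptome-level expression floor applied before any contrast.
#'
#' @param x an \code{expr_matrix}.
#' @param fpkm_min minimum mean FPKM (default 1).
#' @return the filtered \code{expr_matrix}.
#' @export
filter_low_expression <- function(x, fpkm_min = 1) {
  if (fpkm_min < 0) stop("fpkm_min must be >= 0")
  keep <- rowMeans(x$values) >= fpkm_min
  expression_matrix(x$values[keep, , drop = FALSE], x$samples,
                    strict_tokens = FALSE)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: term id, description, then member gene ids.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (term -> gene ids), with a
#'   \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1], " in ", path,
         ": need term, description and at least one gene")
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- vapply(fields, `[[`, "", 1L)
  attr(terms, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, "", 2L), names(terms))
  terms
}
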