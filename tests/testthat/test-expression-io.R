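test_that("expression tables round-trip through TSV with metadata intact", {
  x <- toy_design_matrix(list(
    geneA = function(inj, trt) 10,
    geneB = function(inj, trt) if (trt == "chx_dex") 20 else 5
  ))
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(x, mp, sp)
  y <- read_expression_table(mp, sp)
  expect_equal(y$values, x$values)
  expect_equal(y$samples, x$samples)
})

test_that("malformed inputs are rejected with informative errors", {
  x <- toy_design_matrix(list(geneA = function(inj, trt) 1))
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(x, mp, sp)

  sheet <- read.delim(sp, stringsAsFactors = FALSE)
  sheet$treatment[1] <- "DEX"
  write.table(sheet, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(mp, sp), "unknown treatment token 'DEX'")

  write.table(sheet[-1, -which(names(sheet) == "treatment")], sp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(mp, sp), "missing")

  neg <- x
  neg$values[1, 1] <- -1
  expect_error(expression_matrix(neg$values, neg$samples), "non-negative")
  dup <- x$samples
  dup$replicate <- 1L
  expect_error(expression_matrix(x$values[, c(1, 1), drop = FALSE],
                                 dup[c(1, 1), ]),
               "duplicate")
})

test_that("BLAST tabular parsing keeps one best hit per transcript", {
  path <- withr::local_tempfile(fileext = ".tsv")
  row <- function(q, s, ev, bs)
    paste(q, s, 98.5, 500, 2, 0, 1, 500, 1, 500, ev, bs, sep = "\t")
  writeLines(c(
    row("t1", "accA", "1e-10", 200),  # kept: passes cutoff
    row("t1", "accB", "1e-3", 500),   # dropped: fails e-value cutoff
    row("t2", "accC", "1e-20", 200),  # dropped: lower bitscore than accD
    row("t2", "accD", "1e-18", 210),
    row("t3", "accF", "1e-9", 150),   # tie on bitscore: lower e-value wins
    row("t3", "accE", "1e-11", 150)
  ), path)
  hits <- read_blast_tabular(path)
  expect_equal(hits$annotation_id[hits$transcript_id == "t1"], "accA")
  expect_equal(hits$annotation_id[hits$transcript_id == "t2"], "accD")
  expect_equal(hits$annotation_id[hits$transcript_id == "t3"], "accE")
  expect_equal(nrow(hits), 3L)

  # idempotence: best-hit of best-hits is itself
  rt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(vapply(seq_len(nrow(hits)), function(i)
    row(hits$transcript_id[i], hits$annotation_id[i],
        format(hits$e_value[i]), hits$bitscore[i]), character(1)), rt)
  again <- read_blast_tabular(rt)
  expect_equal(again[order(again$transcript_id), c("transcript_id", "annotation_id")],
               hits[order(hits$transcript_id), c("transcript_id", "annotation_id")])

  writeLines(character(), path)
  expect_equal(nrow(read_blast_tabular(path)), 0L)

  writeLines(c(row("t1", "accA", "1e-10", 200), "t2\taccB\tbroken"), path)
  expect_error(read_blast_tabular(path), "line 2")
})

test_that("condensing duplicate annotations keeps the highest-expressed model", {
  x <- toy_design_matrix(list(
    tA = function(inj, trt) 5,   # shares geneX with tB, lower mean
    tB = function(inj, trt) 9,
    tC = function(inj, trt) 2    # unannotated, dropped
  ))
  hits <- data.frame(transcript_id = c("tA", "tB"),
                     annotation_id = c("geneX", "geneX"),
                     gene_symbol = NA, e_value = 1e-10, bitscore = 100,
                     stringsAsFactors = FALSE)
  out <- condense_annotations(x, hits)
  expect_equal(rownames(out$values), "geneX")
  expect_true(all(out$values["geneX", ] == 9))
  expect_equal(attr(out, "n_unannotated"), 1L)
  expect_equal(unname(attr(out, "transcript_map")["geneX"]), "tB")

  sum_out <- condense_annotations(x, hits, method = "sum")
  expect_true(all(sum_out$values["geneX", ] == 14))

  # uniquely annotated input is an identity on row count
  uhits <- data.frame(transcript_id = c("tA", "tB", "tC"),
                      annotation_id = c("g1", "g2", "g3"),
                      gene_symbol = NA, e_value = 1e-10, bitscore = 100,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(condense_annotations(x, uhits)$values), 3L)

  expect_error(condense_annotations(x, rbind(hits, hits[1, ])),
               "at most one hit")
})

test_that("low-expression floor is an inclusive mean-FPKM threshold", {
  x <- toy_design_matrix(list(
    low = function(inj, trt) 0.5,
    boundary = function(inj, trt) 1.0,
    high = function(inj, trt) 30
  ))
  f <- filter_low_expression(x, 1)
  expect_setequal(rownames(f$values), c("boundary", "high"))
  expect_equal(rownames(filter_low_expression(x, 0)$values),
               rownames(x$values))
  expect_error(filter_low_expression(x, -1), ">= 0")

  # sequential filtering composes as the max of the thresholds
  set.seed(41)
  vals <- matrix(rexp(40 * 16, rate = 0.3), 40, 16)
  rownames(vals) <- sprintf("g%02d", 1:40)
  colnames(vals) <- x$samples$sample_id
  big <- expression_matrix(vals, x$samples)
  for (ab in list(c(0.5, 2), c(2, 0.5), c(1, 1))) {
    seq2 <- filter_low_expression(filter_low_expression(big, ab[1]), ab[2])
    expect_equal(seq2$values,
                 filter_low_expression(big, max(ab))$values)
  }
})

test_that("GMT gene-set files parse into named gene lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term1\tfirst term\tg1\tg2\tg3",
               "term2\tsecond term\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("term1", "term2"))
  expect_equal(sets$term2, c("g2", "g4"))
  expect_equal(unname(attr(sets, "descriptions")["term1"]), "first term")
  writeLines("term\tonly-description", path)
  expect_error(read_gmt(path), "line 1")
})
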