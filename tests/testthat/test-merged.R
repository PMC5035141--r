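test_that("pooling schemes collect the right replicates", {
  x <- toy_design_matrix(list(g = function(inj, trt) 10), n_replicates = 2)
  m4 <- merge_replicates(x, "six1_m")
  expect_equal(length(samples_for(m4, "six1_m", "chx")), 4L)
  expect_equal(length(samples_for(m4, "six1_m", "chx_dex")), 4L)
  m6 <- merge_replicates(x, "six1_eya1_m")
  expect_equal(length(samples_for(m6, "six1_eya1_m", "chx")), 6L)
  expect_equal(length(samples_for(m6, "six1_eya1_m", "chx_dex")), 6L)
  expect_false("uninjected" %in%
                 unlist(lapply(c("six1_m", "eya1_m", "six1_eya1_m"),
                               function(s) merged_scheme(s)$member_groups)))

  partial <- x
  keep <- partial$samples$injection != "eya1"
  partial <- expression_matrix(partial$values[, keep, drop = FALSE],
                               partial$samples[keep, ])
  expect_error(merge_replicates(partial, "eya1_m"), "'eya1'.*missing")
})

test_that("Welch statistic matches the textbook formula and stats::t.test", {
  # log2(FPKM+1) replicate values (1,2) vs (3,4)
  vals <- matrix(c(2^1 - 1, 2^2 - 1, 2^3 - 1, 2^4 - 1), nrow = 1)
  rownames(vals) <- "g1"
  samples <- data.frame(
    sample_id = c("m_chx_r1", "m_chx_r2", "m_chx_dex_r1", "m_chx_dex_r2"),
    injection = "m", treatment = c("chx", "chx", "chx_dex", "chx_dex"),
    replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  colnames(vals) <- samples$sample_id
  x <- expression_matrix(vals, samples, strict_tokens = FALSE)
  res <- test_merged(x)
  expect_equal(res$statistic, 2 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(res$df, 2, tolerance = 1e-12)
  tt <- t.test(c(3, 4), c(1, 2))
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)

  # identical values in both conditions: p = 1, not significant
  flat <- expression_matrix(matrix(7, 1, 4, dimnames = list("g1", samples$sample_id)),
                            samples, strict_tokens = FALSE)
  rf <- test_merged(flat)
  expect_equal(rf$p_value, 1)
  expect_false(rf$significant)
  expect_false(rf$degenerate)

  # zero variance, unequal means: minimal representable p, flagged
  deg_vals <- matrix(c(1, 1, 30, 30), 1, 4,
                     dimnames = list("g1", samples$sample_id))
  rd <- test_merged(expression_matrix(deg_vals, samples,
                                      strict_tokens = FALSE))
  expect_equal(rd$p_value, .Machine$double.xmin)
  expect_true(rd$degenerate)

  # permuting replicates within a condition changes nothing
  perm <- x
  perm$values <- perm$values[, c(2, 1, 4, 3), drop = FALSE]
  perm$samples$sample_id <- colnames(perm$values)
  rp <- test_merged(expression_matrix(
    perm$values, data.frame(sample_id = colnames(perm$values),
                            injection = "m",
                            treatment = c("chx", "chx", "chx_dex", "chx_dex"),
                            replicate = c(1, 2, 1, 2)),
    strict_tokens = FALSE))
  expect_equal(rp[, c("statistic", "p_value", "q_value")],
               res[, c("statistic", "p_value", "q_value")])

  # fewer than two replicates per condition is an error
  x1 <- expression_matrix(vals[, c(1, 3, 4), drop = FALSE],
                          samples[c(1, 3, 4), ], strict_tokens = FALSE)
  expect_error(test_merged(x1), ">= 2 replicates")
})

test_that("Benjamini-Hochberg q-values follow the step-up formula", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, stepup_bh(p), tolerance = 1e-12)
    # order invariance
    perm <- sample(seq_along(p))
    expect_equal(benjamini_hochberg(p[perm]), q[perm], tolerance = 1e-12)
    # monotone nondecreasing in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("significance requires both the q-value and the filter cascade", {
  # one strongly induced gene, one DEX artifact induced also in the control
  x <- toy_design_matrix(list(
    target = function(inj, trt)
      if (trt == "chx_dex" && inj != "uninjected") 63 else 7,
    artifact = function(inj, trt) if (trt == "chx_dex") 63 else 7,
    flat = function(inj, trt) 7
  ), n_replicates = 3)
  # add replicate jitter so variances are nonzero
  set.seed(5)
  x$values <- x$values * matrix(2^rnorm(length(x$values), 0, 0.05),
                                nrow(x$values))
  merged <- merge_replicates(x, "six1_eya1_m")
  control <- compute_contrast(x, "uninjected")
  res <- test_merged(merged, control)
  expect_true(res$significant[res$gene_id == "target"])
  # the artifact has an overwhelming p-value but fails the control criterion
  expect_lt(res$q_value[res$gene_id == "artifact"], 0.05)
  expect_false(res$significant[res$gene_id == "artifact"])
  expect_false(res$significant[res$gene_id == "flat"])
})
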