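test_that("Venn partition enumerates the seven regions correctly", {
  p <- partition_de_sets(c("a", "b", "c"), c("b", "c", "d"), c("c", "d", "e"))
  expect_equal(p$regions$S_only, "a")
  expect_length(p$regions$E_only, 0L)
  expect_equal(p$regions$C_only, "e")
  expect_equal(p$regions$SE_only, "b")
  expect_length(p$regions$SC_only, 0L)
  expect_equal(p$regions$EC_only, "d")
  expect_equal(p$regions$SEC, "c")

  empty <- partition_de_sets(character(), character(), character())
  expect_true(all(venn_counts(empty) == 0))
})

test_that("regions are disjoint and satisfy the marginal identity", {
  set.seed(19)
  universe <- sprintf("g%03d", 1:120)
  for (i in 1:20) {
    s <- sample(universe, sample(0:60, 1))
    e <- sample(universe, sample(0:60, 1))
    co <- sample(universe, sample(0:60, 1))
    p <- partition_de_sets(s, e, co)
    all_regions <- unlist(p$regions)
    expect_equal(anyDuplicated(all_regions), 0L)
    expect_setequal(all_regions, union(union(s, e), co))
    n <- venn_counts(p)
    expect_equal(unname(n["S_only"] + n["SE_only"] + n["SC_only"] + n["SEC"]),
                 length(unique(s)))
    expect_equal(unname(n["E_only"] + n["SE_only"] + n["EC_only"] + n["SEC"]),
                 length(unique(e)))
    expect_equal(unname(n["C_only"] + n["SC_only"] + n["EC_only"] + n["SEC"]),
                 length(unique(co)))
    # class counts always sum to the union cardinality
    calls <- classify_coregulation(p)
    expect_equal(sum(coregulation_counts(calls)[REG_CLASSES]),
                 length(all_regions))
  }
})

test_that("classification assigns each membership pattern its class", {
  calls <- classify_coregulation(partition_de_sets(
    c("s_only", "sc", "sec", "se"),
    c("e_only", "ec", "sec", "se"),
    c("c_only", "sc", "ec", "sec")))
  cls <- setNames(calls$reg_class, calls$gene_id)
  expect_equal(unname(cls["s_only"]), "six1_independent")
  expect_equal(unname(cls["sc"]), "six1_independent")
  expect_equal(unname(cls["e_only"]), "eya1_independent")
  expect_equal(unname(cls["ec"]), "eya1_independent")
  expect_equal(unname(cls["c_only"]), "coregulated_combined_only")
  expect_equal(unname(cls["sec"]), "coregulated_all_three")
  expect_equal(unname(cls["se"]), "ambiguous_pair_only")
})

test_that("direction-balance summary reports fractions or undefined markers", {
  up <- classify_coregulation(venn_partition_from_counts(
    c(C_only = 3, SEC = 2), "up"))
  down <- classify_coregulation(venn_partition_from_counts(
    c(C_only = 1, SEC = 1), "down"))
  s <- coregulation_summary(up, down)
  expect_equal(s$pct_up_coregulated$percent, round(100 * 5 / 7, 1))
  expect_equal(s$pct_up_all_three$percent, round(100 * 2 / 3, 1))

  none <- classify_coregulation(venn_partition_from_counts(
    c(S_only = 2), "up"))
  s0 <- coregulation_summary(none, none)
  expect_false(s0$pct_up_coregulated$defined)
  expect_true(is.na(s0$pct_up_coregulated$percent))
})

test_that("top-fraction overlap test matches hypergeometric enumeration", {
  # identical rankings: maximal overlap, minimal attainable p
  genes <- sprintf("g%03d", 1:100)
  fc <- seq(10, 0.1, length.out = 100)
  rk <- data.frame(gene_id = genes, log2fc = fc, stringsAsFactors = FALSE)
  res <- top_fraction_overlap_test(rk, rk, 0.1)
  expect_equal(res$overlap, 10L)
  expect_equal(res$odds_ratio, Inf)
  min_tab <- matrix(c(10, 0, 0, 90), 2, 2)
  expect_equal(res$p_value, enum_fisher_two_sided(min_tab))

  # universe 20, top sets of 2: zero and full overlap against the oracle
  g20 <- sprintf("h%02d", 1:20)
  a <- data.frame(gene_id = g20, log2fc = 20:1, stringsAsFactors = FALSE)
  b <- a
  b$log2fc <- c(1, 2, 20:3)  # displaces a's top genes to the bottom
  res0 <- top_fraction_overlap_test(a, b, 0.1)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p_value,
               enum_fisher_two_sided(matrix(c(0, 2, 2, 16), 2, 2)))
  res2 <- top_fraction_overlap_test(a, a, 0.1)
  expect_equal(res2$overlap, 2L)
  # the full-overlap table's point mass is 1/C(20,2)
  expect_equal(dhyper(2, 2, 18, 2), 1 / choose(20, 2))
  expect_equal(res2$p_value,
               enum_fisher_two_sided(matrix(c(2, 0, 0, 18), 2, 2)))

  # randomized equivalence for universes <= 50
  set.seed(61)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    u <- sprintf("u%03d", seq_len(n))
    ra <- data.frame(gene_id = u, log2fc = rnorm(n), stringsAsFactors = FALSE)
    rb <- data.frame(gene_id = u, log2fc = rnorm(n), stringsAsFactors = FALSE)
    res <- top_fraction_overlap_test(ra, rb, 0.2)
    k <- res$top_n
    tab <- matrix(c(res$overlap, k - res$overlap,
                    k - res$overlap, n - 2 * k + res$overlap), 2, 2)
    expect_equal(res$p_value, enum_fisher_two_sided(tab), tolerance = 1e-10)
  }

  # fold-change ties resolve lexicographically by gene id
  tie <- data.frame(gene_id = c("z9", "a1", "m5", "b2"),
                    log2fc = c(5, 5, 1, 1), stringsAsFactors = FALSE)
  res_tie <- top_fraction_overlap_test(tie, tie, 0.25)
  expect_equal(res_tie$overlap, 1L)

  expect_error(top_fraction_overlap_test(
    a, data.frame(gene_id = paste0(g20, "x"), log2fc = 1:20), 0.1),
    "different gene universes")
  expect_error(top_fraction_overlap_test(a, a, 0), "strictly between")
})
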