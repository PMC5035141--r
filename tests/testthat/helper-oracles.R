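# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enrichment p-values are obtained by explicit
# enumeration with choose(), BH by the step-up formula written out, and
# expected filter outcomes by evaluating the generative equations directly.

# Upper-tail hypergeometric P(overlap >= k) by explicit summation.
enum_upper_tail <- function(k, n_query, n_term, n_background) {
  kmax <- min(n_query, n_term)
  if (k > kmax) return(0)
  ks <- k:kmax
  probs <- choose(n_term, ks) * choose(n_background - n_term, n_query - ks) /
    choose(n_background, n_query)
  sum(probs)
}

# Two-sided Fisher p for a 2x2 table by enumerating all tables with the same
# margins and summing point probabilities not exceeding the observed one
# (with the customary relative tolerance, matching the standard convention).
enum_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, numeric(1))
  obs <- choose(c1, tab[1, 1]) * choose(n - c1, r1 - tab[1, 1]) / choose(n, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up formula written out directly.
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Expected noise-free DE-filter outcome computed from the truth table by
# evaluating the generative equations: which genes must pass the cascade for
# a given injection group and direction.
truth_filter_oracle <- function(truth, injection, direction,
                                criteria = de_filter_criteria(),
                                pseudocount = 1) {
  eff <- truth[[paste0("effect_", injection)]]
  eff_ctrl <- truth$effect_uninjected
  b <- truth$baseline_log2
  fpkm <- function(x) pmax(2^x - 1, 0)
  lfc <- log2((fpkm(b + eff) + pseudocount) / (fpkm(b) + pseudocount))
  lfc_ctrl <- log2((fpkm(b + eff_ctrl) + pseudocount) /
                   (fpkm(b) + pseudocount))
  floor_ok <- fpkm(b + eff) >= criteria$fpkm_min
  if (direction == "up") {
    ok <- floor_ok & lfc >= criteria$fc_min_log2 &
      (if (criteria$control_rule == "delta")
         lfc - lfc_ctrl >= criteria$control_delta_min_log2
       else lfc_ctrl < criteria$control_abs_max_log2)
  } else {
    ok <- floor_ok & lfc <= -criteria$fc_min_log2 &
      (if (criteria$control_rule == "delta")
         lfc_ctrl - lfc >= criteria$control_delta_min_log2
       else lfc_ctrl > -criteria$control_abs_max_log2)
  }
  truth$gene_id[ok]
}

# Small hand-built expression matrix over the full design, one replicate pair
# per cell, with per-gene FPKM supplied as a gene x condition function.
toy_design_matrix <- function(fpkm_rows, n_replicates = 2) {
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         treatment = c("chx", "chx_dex"),
                         injection = c("six1", "eya1", "six1_eya1",
                                       "uninjected"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("injection", "treatment", "replicate")]
  samples$sample_id <- paste(samples$injection, samples$treatment,
                             paste0("r", samples$replicate), sep = "_")
  samples <- samples[, c("sample_id", "injection", "treatment", "replicate")]
  vals <- t(vapply(fpkm_rows, function(f) {
    vapply(seq_len(nrow(samples)), function(j)
      f(samples$injection[j], samples$treatment[j]), numeric(1))
  }, numeric(nrow(samples))))
  rownames(vals) <- names(fpkm_rows)
  colnames(vals) <- samples$sample_id
  expression_matrix(vals, samples)
}
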