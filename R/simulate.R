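#' Planted gene classes of the synthetic screen
#'
#' Direction-crossed class labels used by the generator and its truth tables;
#' \code{"null"} carries no effect. Co-regulated classes differ in response
#' threshold: high-threshold genes respond in every injected group,
#' low-threshold genes only after combined Six1+Eya1 injection. DEX-artifact
#' classes respond in all groups including un-injected explants.
#'
#' @format character vector of length 11.
#' @export
GENE_CLASSES <- c(
  "null",
  "coreg_low_threshold_up", "coreg_low_threshold_down",
  "coreg_high_threshold_up", "coreg_high_threshold_down",
  "six1_only_up", "six1_only_down",
  "eya1_only_up", "eya1_only_down",
  "dex_artifact_up", "dex_artifact_down"
)

# Which injection groups carry a class's induction effect in their DEX
# samples. High-threshold co-regulated genes respond in every injected group
# (overexpressing either partner raises complex levels somewhere in the
# ectoderm); low-threshold genes respond only when both factors are supplied;
# DEX artifacts respond everywhere, including un-injected explants.
.class_groups <- list(
  null                      = character(),
  coreg_low_threshold_up    = "six1_eya1",
  coreg_low_threshold_down  = "six1_eya1",
  coreg_high_threshold_up   = c("six1", "eya1", "six1_eya1"),
  coreg_high_threshold_down = c("six1", "eya1", "six1_eya1"),
  six1_only_up              = c("six1", "six1_eya1"),
  six1_only_down            = c("six1", "six1_eya1"),
  eya1_only_up              = c("eya1", "six1_eya1"),
  eya1_only_down            = c("eya1", "six1_eya1"),
  dex_artifact_up           = INJECTION_TOKENS,
  dex_artifact_down         = INJECTION_TOKENS
)

.default_proportions <- c(
  null                      = 0.84,
  coreg_low_threshold_up    = 0.03,
  coreg_high_threshold_up   = 0.03,
  six1_only_up              = 0.02,
  eya1_only_up              = 0.02,
  dex_artifact_up           = 0.01,
  coreg_low_threshold_down  = 0.015,
  coreg_high_threshold_down = 0.01,
  six1_only_down            = 0.01,
  eya1_only_down            = 0.01,
  dex_artifact_down         = 0.005
)

.default_effect_means <- c(
  null                      = 0,
  coreg_low_threshold_up    = 3,  coreg_low_threshold_down  = -3,
  coreg_high_threshold_up   = 3,  coreg_high_threshold_down = -3,
  six1_only_up              = 3,  six1_only_down            = -3,
  eya1_only_up              = 3,  eya1_only_down            = -3,
  dex_artifact_up           = 3,  dex_artifact_down         = -3
)

#' Configuration for the synthetic screen generator
#'
#' Describes a simulated run of the inducible-target screen: four injection
#' groups (Six1, Eya1, Six1+Eya1, un-injected) each split into CHX and
#' CHX+DEX treatments with \code{n_replicates} biological replicates.
#' Baseline expression is Gaussian on the log2(FPKM+1) scale and planted
#' induction effects are additive on that scale, applied only to the DEX
#' samples of the groups a gene's class responds in, so that the noise-free
#' pseudocount-1 contrast of an affected group recovers the planted effect
#' exactly.
#'
#' @param n_genes number of simulated genes (>= 1).
#' @param class_proportions named numeric vector over the gene classes
#'   (see \code{GENE_CLASSES}); must sum to 1 within 1e-9. Classes omitted
#'   from the vector get proportion 0.
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of baseline
#'   log2(FPKM+1).
#' @param effect_log2_mean,effect_log2_sd named numeric vectors of planted
#'   effect-size means/sds (log2 units) per class; down-regulated classes use
#'   negative means. Scalars are recycled across non-null classes.
#' @param replicate_noise_sd sd of i.i.d. Gaussian per-sample noise in log2
#'   units.
#' @param n_replicates biological replicates per design cell (default 2).
#' @param seed integer seed driving the single random stream.
#' @return a validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n_genes = 2000,
                              class_proportions = .default_proportions,
                              baseline_log2_mean = 5,
                              baseline_log2_sd = 2,
                              effect_log2_mean = .default_effect_means,
                              effect_log2_sd = 0.5,
                              replicate_noise_sd = 0.2,
                              n_replicates = 2,
                              seed = 1L) {
  if (length(n_genes) != 1 || n_genes < 1 || n_genes != round(n_genes))
    stop("n_genes must be a positive integer")
  if (n_replicates < 1 || n_replicates != round(n_replicates))
    stop("n_replicates must be a positive integer")
  if (baseline_log2_sd < 0 || replicate_noise_sd < 0)
    stop("sd parameters must be >= 0")
  unknown <- setdiff(names(class_proportions), GENE_CLASSES)
  if (length(unknown))
    stop("unknown gene class in class_proportions: ",
         paste(unknown, collapse = ", "))
  props <- stats::setNames(numeric(length(GENE_CLASSES)), GENE_CLASSES)
  props[names(class_proportions)] <- class_proportions
  if (any(props < 0)) stop("class proportions must be >= 0")
  if (abs(sum(props) - 1) > 1e-9)
    stop("class proportions must sum to 1 (got ", sum(props), ")")
  expand <- function(x, default) {
    out <- stats::setNames(rep(default, length(GENE_CLASSES)), GENE_CLASSES)
    if (is.null(names(x))) {
      if (length(x) != 1) stop("per-class parameters must be named or scalar")
      out[] <- x
    } else {
      bad <- setdiff(names(x), GENE_CLASSES)
      if (length(bad)) stop("unknown gene class: ", paste(bad, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  emean <- expand(effect_log2_mean, 0)
  emean["null"] <- 0
  esd <- expand(effect_log2_sd, 0)
  if (any(esd < 0)) stop("sd parameters must be >= 0")
  esd["null"] <- 0
  structure(list(n_genes = as.integer(n_genes),
                 class_proportions = props,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 effect_log2_mean = emean,
                 effect_log2_sd = esd,
                 replicate_noise_sd = replicate_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic largest-remainder apportionment of n genes to classes.
.apportion <- function(n, props) {
  raw <- props * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- raw - counts
    extra <- order(-frac, names(props))[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Simulate a screen experiment with planted target structure
#'
#' Generates an FPKM expression matrix over the full factorial design together
#' with a truth table recording each gene's planted class and effect. The same
#' configuration and seed always yield bit-identical outputs.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list with elements \code{matrix} (an \code{expr_matrix}) and
#'   \code{truth} (data.frame: \code{gene_id}, \code{gene_class},
#'   \code{direction}, \code{effect}, \code{baseline_log2}, and expected
#'   per-group contrast columns \code{effect_six1}, \code{effect_eya1},
#'   \code{effect_six1_eya1}, \code{effect_uninjected}).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be built with simulation_config()")
  set.seed(config$seed)
  n <- config$n_genes
  counts <- .apportion(n, config$class_proportions)
  gene_class <- rep(names(counts), counts)
  gene_id <- sprintf("gene%05d", seq_len(n))

  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  effect <- stats::rnorm(n, config$effect_log2_mean[gene_class],
                         config$effect_log2_sd[gene_class])
  effect[gene_class == "null"] <- 0

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         treatment = TREATMENT_TOKENS,
                         injection = INJECTION_TOKENS,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("injection", "treatment", "replicate")]
  samples$sample_id <- paste(samples$injection, samples$treatment,
                             paste0("r", samples$replicate), sep = "_")
  samples <- samples[, c("sample_id", "injection", "treatment", "replicate")]

  # effect indicator: gene x sample (per-class lookup, then fan out)
  ind <- matrix(0, n, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    if (samples$treatment[j] != "chx_dex") next
    by_class <- vapply(GENE_CLASSES,
                       function(cl) samples$injection[j] %in% .class_groups[[cl]],
                       logical(1))
    ind[, j] <- as.numeric(by_class[gene_class])
  }
  noise <- matrix(stats::rnorm(n * nrow(samples), 0, config$replicate_noise_sd),
                  n, nrow(samples))
  log2v <- baseline + ind * effect + noise
  fpkm <- pmax(2^log2v - 1, 0)
  rownames(fpkm) <- gene_id
  colnames(fpkm) <- samples$sample_id

  truth <- data.frame(gene_id = gene_id, gene_class = gene_class,
                      direction = ifelse(gene_class == "null", "none",
                                         ifelse(grepl("_up$", gene_class),
                                                "up", "down")),
                      effect = effect, baseline_log2 = baseline,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, expected_log2fc(truth)[, -1, drop = FALSE])
  list(matrix = expression_matrix(fpkm, samples), truth = truth)
}

#' Expected noise-free contrast per gene and injection group
#'
#' Maps each truth-table row to the log2 induction fold change its class
#' plants in each injection group; null genes map to 0 everywhere.
#'
#' @param truth a truth table with columns \code{gene_id}, \code{gene_class}
#'   and \code{effect}.
#' @return data.frame with columns \code{gene_id}, \code{effect_six1},
#'   \code{effect_eya1}, \code{effect_six1_eya1}, \code{effect_uninjected}.
#' @export
expected_log2fc <- function(truth) {
  unknown <- setdiff(unique(truth$gene_class), GENE_CLASSES)
  if (length(unknown))
    stop("unknown gene class: ", paste(unknown, collapse = ", "))
  out <- data.frame(gene_id = truth$gene_id, stringsAsFactors = FALSE)
  for (grp in INJECTION_TOKENS) {
    by_class <- vapply(GENE_CLASSES,
                       function(cl) grp %in% .class_groups[[cl]], logical(1))
    out[[paste0("effect_", grp)]] <-
      ifelse(by_class[truth$gene_class], truth$effect, 0)
  }
  out
}

#' Write a truth table as TSV
#'
#' @param truth truth table from \code{\link{simulate_experiment}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
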