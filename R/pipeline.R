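# Polynomial rolling hash (mod 2^31-1) over the serialised configuration;
# enough to fingerprint a run in the manifest without external dependencies.
.config_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.default_config <- function() {
  list(
    seed = 1L,
    pseudocount = 1,
    transcriptome_floor = 1,
    e_value_cutoff = 1e-5,
    alpha = 0.05,
    top_fraction = 0.1,
    condense_method = "max",
    merged_schemes = names(MERGED_SCHEMES),
    filters = list(fc_min_log2 = 1, fpkm_min = 1, control_rule = "delta",
                   control_delta_min_log2 = 1, control_abs_max_log2 = 0.5)
  )
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with named sections. Exactly one of
#' \code{simulate:} (parameters forwarded to
#' \code{\link{simulation_config}}) or \code{input:} (paths \code{matrix} and
#' \code{sample_sheet}, plus optional \code{annotation_hits},
#' \code{gene_sets}, \code{clusters}, \code{tf_list}, \code{rescue_list},
#' \code{known_targets}, \code{qpcr}) must provide the expression matrix.
#' Unset thresholds default to the screen's values (fold-change threshold 1
#' log2 unit, FPKM floor 1, alpha 0.05, top fraction 0.1, e-value cutoff
#' 1e-5).
#'
#' @param path path to the YAML configuration (or an already-parsed list).
#' @return validated configuration list of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- .default_config()
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (nm == "filters") {
      for (f in names(defaults$filters))
        if (is.null(cfg$filters[[f]])) cfg$filters[[f]] <- defaults$filters[[f]]
    }
  }
  has_sim <- !is.null(cfg$simulate)
  has_input <- !is.null(cfg$input)
  if (has_sim == has_input)
    stop("configuration must provide exactly one of 'simulate' or 'input'")
  if (has_input) {
    for (p in c("matrix", "sample_sheet"))
      if (is.null(cfg$input[[p]]))
        stop("'input' section must name a '", p, "' file")
  }
  bad_scheme <- setdiff(cfg$merged_schemes, names(MERGED_SCHEMES))
  if (length(bad_scheme))
    stop("unknown merged scheme: ", paste(bad_scheme, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  basename(path)
}

#' Run the full target screen
#'
#' Executes, in order: data acquisition (simulation or file input), optional
#' annotation condensing, the transcriptome expression floor, per-group
#' induction contrasts with the three-criterion DE filter cascade in both
#' directions, Venn partitioning with co-regulation classification and
#' summary fractions (plus pairwise top-fraction overlap tests), merged
#' Welch re-analysis per requested scheme, optional gene-set enrichment,
#' candidate prioritisation, and optional qPCR cross-validation. Every
#' stage's table is written as TSV under \code{outdir} along with
#' \code{manifest.json}; identical configuration and seed give identical
#' outputs.
#'
#' @param config a \code{\link{read_pipeline_config}} result, a path to a
#'   YAML configuration, or a plain list.
#' @param outdir output directory (created if needed); overrides
#'   \code{config$outdir}.
#' @return the run manifest (list), invisibly.
#' @export
run_screen <- function(config, outdir = NULL) {
  if (!inherits(config, "pipeline_config"))
    config <- read_pipeline_config(config)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("an output directory is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  manifest <- list(package = "ppescreen",
                   version = as.character(utils::packageVersion("ppescreen")),
                   seed = config$seed,
                   config_hash = .config_hash(yaml::as.yaml(unclass(config))),
                   stages = list(), counts = list(), outputs = character())
  note <- function(stage, n_in, n_out, files = character()) {
    manifest$stages[[stage]] <<- list(n_in = n_in, n_out = n_out,
                                      outputs = files)
    manifest$outputs <<- c(manifest$outputs, files)
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  ## -- acquire ---------------------------------------------------------
  truth <- NULL
  tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      sim <- simulate_experiment(do.call(simulation_config, sim_args))
      mat <- sim$matrix
      truth <- sim$truth
      files <- c(.write_tsv(truth, file.path(outdir, "truth.tsv")))
      write_expression_table(mat, file.path(outdir, "expression.tsv"),
                             file.path(outdir, "sample_sheet.tsv"))
      files <- c(files, "expression.tsv", "sample_sheet.tsv")
      note("acquire", NA_integer_, nrow(mat$values), files)
    } else {
      mat <- read_expression_table(config$input$matrix,
                                   config$input$sample_sheet)
      note("acquire", NA_integer_, nrow(mat$values))
    }
  }, error = function(e) fail("acquire", e))

  ## -- annotation condensing (optional) --------------------------------
  if (!is.null(config$input$annotation_hits)) {
    tryCatch({
      hits <- read_blast_tabular(config$input$annotation_hits,
                                 config$e_value_cutoff)
      n_in <- nrow(mat$values)
      mat <- condense_annotations(mat, hits, method = config$condense_method)
      note("condense", n_in, nrow(mat$values))
    }, error = function(e) fail("condense", e))
  }

  ## -- expression floor ------------------------------------------------
  tryCatch({
    n_in <- nrow(mat$values)
    mat <- filter_low_expression(mat, config$transcriptome_floor)
    note("floor", n_in, nrow(mat$values))
  }, error = function(e) fail("floor", e))

  ## -- per-group contrasts and DE filters ------------------------------
  criteria <- do.call(de_filter_criteria, config$filters)
  groups <- setdiff(INJECTION_TOKENS, "uninjected")
  contrasts <- list()
  de_sets <- list(up = list(), down = list())
  tryCatch({
    control <- compute_contrast(mat, "uninjected", config$pseudocount)
    files <- character()
    for (grp in groups) {
      contrasts[[grp]] <- compute_contrast(mat, grp, config$pseudocount)
      de_sets$up[[grp]] <- apply_de_filters(contrasts[[grp]], control,
                                            criteria, "up")
      de_sets$down[[grp]] <- apply_de_filters(contrasts[[grp]], control,
                                              criteria, "down")
      files <- c(files, .write_tsv(
        screen_table(contrasts[[grp]], control, criteria),
        file.path(outdir, paste0("screen_", grp, ".tsv"))))
    }
    manifest$counts$de <- list(
      up = vapply(de_sets$up, length, integer(1)),
      down = vapply(de_sets$down, length, integer(1)))
    note("contrasts", nrow(mat$values), nrow(mat$values), files)
  }, error = function(e) fail("contrasts", e))

  ## -- co-regulation ----------------------------------------------------
  tryCatch({
    calls <- list()
    files <- character()
    for (dir in c("up", "down")) {
      part <- partition_de_sets(de_sets[[dir]]$six1, de_sets[[dir]]$eya1,
                                de_sets[[dir]]$six1_eya1, direction = dir)
      calls[[dir]] <- classify_coregulation(part)
      manifest$counts$venn[[dir]] <- as.list(venn_counts(part))
      manifest$counts$classes[[dir]] <-
        as.list(coregulation_counts(calls[[dir]]))
      files <- c(files, .write_tsv(calls[[dir]],
        file.path(outdir, paste0("coregulation_", dir, ".tsv"))))
    }
    summ <- coregulation_summary(calls$up, calls$down)
    manifest$counts$pct_up_coregulated <- summ$pct_up_coregulated
    manifest$counts$pct_up_all_three <- summ$pct_up_all_three
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    manifest$counts$top_fraction_tests <- lapply(pairs, function(pr) {
      res <- top_fraction_overlap_test(contrasts[[pr[1]]], contrasts[[pr[2]]],
                                       config$top_fraction)
      list(groups = pr, overlap = res$overlap, top_n = res$top_n,
           odds_ratio = res$odds_ratio, p_value = res$p_value)
    })
    note("coregulation",
         length(unique(unlist(de_sets))), nrow(calls$up) + nrow(calls$down),
         files)
  }, error = function(e) fail("coregulation", e))

  ## -- merged re-analysis ----------------------------------------------
  if (length(config$merged_schemes)) {
    tryCatch({
      files <- character()
      for (sc in config$merged_schemes) {
        merged <- merge_replicates(mat, sc)
        res <- test_merged(merged, control, criteria, config$alpha,
                           config$pseudocount)
        manifest$counts$merged_significant[[sc]] <- sum(res$significant)
        files <- c(files, .write_tsv(
          res, file.path(outdir, paste0("merged_", sc, ".tsv"))))
      }
      note("merged", nrow(mat$values), nrow(mat$values), files)
    }, error = function(e) fail("merged", e))
  }

  ## -- prioritisation ---------------------------------------------------
  tryCatch({
    fc_table <- data.frame(
      gene_id = contrasts$six1$gene_id,
      fc_six1 = contrasts$six1$log2fc,
      fc_eya1 = contrasts$eya1$log2fc[
        match(contrasts$six1$gene_id, contrasts$eya1$gene_id)],
      fc_six1_eya1 = contrasts$six1_eya1$log2fc[
        match(contrasts$six1$gene_id, contrasts$six1_eya1$gene_id)],
      fc_control = control$log2fc[
        match(contrasts$six1$gene_id, control$gene_id)],
      stringsAsFactors = FALSE)
    ws <- well_supported_list(fc_table, config$filters$fc_min_log2,
                              require_control = TRUE)
    manifest$counts$well_supported <- sum(ws$well_supported)
    files <- .write_tsv(ws, file.path(outdir, "well_supported.tsv"))
    if (!is.null(config$input$tf_list)) {
      tf <- readLines(config$input$tf_list)
      rescue <- if (is.null(config$input$rescue_list)) character()
                else readLines(config$input$rescue_list)
      cand <- select_candidates(ws, tf, rescue)
      manifest$counts$candidates <- nrow(cand)
      files <- c(files, .write_tsv(cand, file.path(outdir, "candidates.tsv")))
    }
    if (!is.null(config$input$known_targets)) {
      kt <- utils::read.delim(config$input$known_targets,
                              stringsAsFactors = FALSE)
      rec <- known_target_recovery(fc_table, kt, de_sets$up)
      manifest$counts$known_targets <- as.list(attr(rec, "summary"))
      files <- c(files, .write_tsv(rec, file.path(outdir,
                                                  "known_target_recovery.tsv")))
    }
    note("prioritization", nrow(fc_table), sum(ws$well_supported), files)
  }, error = function(e) fail("prioritization", e))

  ## -- enrichment (optional) --------------------------------------------
  if (!is.null(config$input$gene_sets)) {
    tryCatch({
      terms <- read_gmt(config$input$gene_sets)
      background <- rownames(mat$values)
      # query: the co-regulated aggregate over both directions
      query <- unique(c(attr(classify_coregulation(partition_de_sets(
        de_sets$up$six1, de_sets$up$eya1, de_sets$up$six1_eya1, "up")),
        "coregulated"),
        attr(classify_coregulation(partition_de_sets(
          de_sets$down$six1, de_sets$down$eya1, de_sets$down$six1_eya1,
          "down")), "coregulated")))
      enr <- enrichment_table(query, terms, background)
      files <- .write_tsv(enr, file.path(outdir, "enrichment.tsv"))
      if (!is.null(config$input$clusters)) {
        clust <- utils::read.delim(config$input$clusters,
                                   stringsAsFactors = FALSE)
        files <- c(files, .write_tsv(score_clusters(enr, clust),
                                     file.path(outdir, "clusters.tsv")))
      }
      note("enrichment", length(query), nrow(enr), files)
    }, error = function(e) fail("enrichment", e))
  }

  ## -- qPCR (optional) ---------------------------------------------------
  if (!is.null(config$input$qpcr)) {
    tryCatch({
      rq <- relative_quantification(read_qpcr_table(config$input$qpcr))
      files <- .write_tsv(rq$summary, file.path(outdir, "qpcr_summary.tsv"))
      note("qpcr", nrow(rq$per_replicate), nrow(rq$summary), files)
    }, error = function(e) fail("qpcr", e))
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Human-readable run report
#'
#' Renders a manifest into a textual summary: per-direction DE counts per
#' group, Venn region counts, co-regulation class counts and fractions,
#' merged significant counts and candidate counts. Sections whose stage did
#' not run are marked \code{not run}.
#'
#' @param manifest manifest list from \code{\link{run_screen}} (or a path to
#'   a written \code{manifest.json}).
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly.
#' @export
write_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  cnt <- manifest$counts
  fmt_set <- function(x) paste(names(x), unlist(x), sep = "=", collapse = "  ")
  lines <- c(
    paste0("ppescreen run report (seed ", manifest$seed, ", config ",
           manifest$config_hash, ")"),
    "")
  lines <- c(lines, "Differential expression (per treatment group):")
  if (is.null(cnt$de)) {
    lines <- c(lines, "  not run")
  } else {
    lines <- c(lines, paste0("  up:   ", fmt_set(cnt$de$up)),
               paste0("  down: ", fmt_set(cnt$de$down)))
  }
  lines <- c(lines, "", "Venn regions / co-regulation classes:")
  if (is.null(cnt$venn)) {
    lines <- c(lines, "  not run")
  } else {
    for (dir in names(cnt$venn)) {
      lines <- c(lines,
                 paste0("  ", dir, " regions: ", fmt_set(cnt$venn[[dir]])),
                 paste0("  ", dir, " classes: ", fmt_set(cnt$classes[[dir]])))
    }
    pc <- cnt$pct_up_coregulated
    pa <- cnt$pct_up_all_three
    lines <- c(lines,
      paste0("  co-regulated genes up-regulated: ",
             if (isTRUE(pc$defined)) paste0(pc$percent, "%") else "undefined"),
      paste0("  (all-three subset): ",
             if (isTRUE(pa$defined)) paste0(pa$percent, "%") else "undefined"))
  }
  lines <- c(lines, "", "Merged re-analysis (significant genes):")
  lines <- c(lines, if (is.null(cnt$merged_significant)) "  not run"
             else paste0("  ", fmt_set(cnt$merged_significant)))
  lines <- c(lines, "", "Prioritisation:")
  if (is.null(cnt$well_supported)) {
    lines <- c(lines, "  not run")
  } else {
    lines <- c(lines, paste0("  well-supported genes: ", cnt$well_supported))
    if (!is.null(cnt$candidates))
      lines <- c(lines, paste0("  selected candidates: ", cnt$candidates))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
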