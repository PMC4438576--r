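#' Pipeline configuration
#'
#' Gathers the input paths and every stage threshold of the end-to-end
#' analysis.  Thresholds default to the analysis conventions: signature
#' FDR 0.1 with linear fold 1.5 in every comparison, strict 66th-percentile
#' consistency for drug targets, top 30 percent most variant genes for
#' clustering, and enrichment FDR 0.005.
#'
#' @param expression path to the expression matrix (TSV or GCT).
#' @param samplesheet path to the sample sheet.
#' @param probeset_map optional path to a probeset-to-gene map; when given,
#'   the matrix is read at probeset level and collapsed.
#' @param drug_map optional path to a drug-target map.
#' @param gmt optional path to a gene-set collection.
#' @param out_dir output directory.
#' @param min_max_expr,min_variance pre-filter thresholds,
#'   see [filter_genes()].
#' @param signature_fdr_max,signature_fold_min,signature_direction
#'   consensus-signature thresholds, see [consensus_signature()].
#' @param fdr_scope `"global"` or `"per_comparison"`, see [diffexp_table()].
#' @param percentile_threshold consistency threshold, see [target_report()].
#' @param clustering_top_frac variance fraction, see [select_variant_genes()].
#' @param enrichment_fdr_max,enrichment_min_term_size,enrichment_method
#'   see [enrich()].
#' @param seed seed echoed into the manifest (the pipeline itself is
#'   deterministic).
#' @return config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, samplesheet, probeset_map = NULL,
                            drug_map = NULL, gmt = NULL,
                            out_dir = "targetsig_out",
                            min_max_expr = 6, min_variance = 0.01,
                            signature_fdr_max = 0.1,
                            signature_fold_min = 1.5,
                            signature_direction = "both",
                            fdr_scope = "global",
                            percentile_threshold = 66,
                            clustering_top_frac = 0.30,
                            enrichment_fdr_max = 0.005,
                            enrichment_min_term_size = 3L,
                            enrichment_method = "hypergeometric",
                            seed = 1L) {
  cfg <- as.list(environment())
  abort_if(signature_fdr_max < 0 || signature_fdr_max > 1,
           "signature_fdr_max must lie in [0, 1]")
  abort_if(signature_fold_min < 1, "signature_fold_min must be >= 1")
  abort_if(percentile_threshold < 0 || percentile_threshold > 100,
           "percentile_threshold must lie in [0, 100]")
  abort_if(clustering_top_frac <= 0 || clustering_top_frac > 1,
           "clustering_top_frac must lie in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.  `overrides` (e.g. parsed command-line flags) win over the file.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  abort_if(length(unknown) > 0L, "unknown config keys: ",
           paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the end-to-end analysis
#'
#' Stages: read inputs, collapse probesets (when a map is given), pre-filter,
#' pairwise moderated-t comparisons with pooled FDR, consensus signature,
#' drug-target percentile report, variance-selected Spearman/complete-linkage
#' sample clustering with Newick export, and gene-set over-representation of
#' the upregulated signature against the filtered-gene universe.  Every
#' stage's row counts are logged to console and to `run_log.txt`; outputs
#' carry no timestamps, so identical inputs and config give byte-identical
#' output files.  On failure the partially written outputs are removed.
#'
#' Outputs in `out_dir`: `comparison_table.tsv`, `signature.tsv`,
#' `signature_genes.txt`, `target_report.tsv`, `target_all_genes.tsv`,
#' `dendrogram.newick`, `enrichment.tsv`, `run_log.txt`, `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress console logging.
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  abort_if(!inherits(config, "pipeline_config"), "need a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  written <- character(0)
  emit <- function(path) written <<- c(written, path)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- c(expression = config$expression,
              samplesheet = config$samplesheet,
              probeset_map = config$probeset_map,
              drug_map = config$drug_map, gmt = config$gmt)

  mat <- stage("read_expression", {
    lvl <- if (is.null(config$probeset_map)) "gene" else "probeset"
    m <- read_expression(config$expression, level = lvl)
    say("read_expression: %d features x %d samples (level %s)",
        nrow(m), ncol(m), lvl)
    m
  })
  sheet <- stage("read_samplesheet", {
    s <- read_sample_sheet(config$samplesheet)
    validate_sample_sheet(s, mat)
    say("samplesheet: %d samples, %d groups, target '%s'",
        nrow(s), length(unique(s$group)), target_group(s))
    s
  })
  if (!is.null(config$probeset_map)) {
    mat <- stage("collapse_probesets", {
      map <- read_probeset_map(config$probeset_map)
      m <- suppressMessages(collapse_probesets(mat, map))
      say("collapse_probesets: %d genes retained, %d unmapped probesets dropped",
          nrow(m), attr(m, "n_dropped_unmapped"))
      m
    })
  }
  mat <- stage("filter_genes", {
    m <- filter_genes(mat, config$min_max_expr, config$min_variance)
    say("filter_genes: %d genes kept, %d removed (min_max_expr=%g, min_variance=%g)",
        nrow(m), attr(m, "n_removed"), config$min_max_expr,
        config$min_variance)
    m
  })

  tab <- stage("diffexp", {
    tb <- suppressMessages(diffexp_table(mat, sheet,
                                         fdr_scope = config$fdr_scope))
    say("diffexp: %d rows (%d genes x %d comparisons), fdr_scope=%s",
        nrow(tb), nrow(mat), nrow(tb) / nrow(mat), config$fdr_scope)
    path <- file.path(out, "comparison_table.tsv")
    write_tsv(format_num_cols(as.data.frame(tb)), path)
    emit(path)
    tb
  })
  sig <- stage("signature", {
    s <- consensus_signature(tab, config$signature_fdr_max,
                             config$signature_fold_min,
                             config$signature_direction)
    if (nrow(s) == 0L)
      warning("consensus signature is empty at the configured thresholds")
    say("signature: %d genes (%d up, %d down)", nrow(s),
        sum(s$direction == "up"), sum(s$direction == "down"))
    write_tsv(format_num_cols(s), file.path(out, "signature.tsv"))
    writeLines(s$gene, file.path(out, "signature_genes.txt"))
    emit(file.path(out, "signature.tsv"))
    emit(file.path(out, "signature_genes.txt"))
    s
  })
  rep <- stage("rank_targets", {
    dmap <- if (is.null(config$drug_map)) NULL
            else read_drug_map(config$drug_map)
    r <- suppressMessages(suppressWarnings(
      target_report(mat, sheet, dmap, config$percentile_threshold)))
    say("rank_targets: %d consistent candidates, %d with agents",
        sum(r$all_genes$n_above == sum(sheet$is_target)), nrow(r$report))
    write_tsv(format_num_cols(r$report), file.path(out, "target_report.tsv"))
    write_tsv(format_num_cols(r$all_genes),
              file.path(out, "target_all_genes.tsv"))
    emit(file.path(out, "target_report.tsv"))
    emit(file.path(out, "target_all_genes.tsv"))
    r
  })
  tree <- stage("clustering", {
    sel <- select_variant_genes(mat, config$clustering_top_frac)
    tr <- complete_linkage(spearman_distance(sel))
    say("clustering: %d variant genes, %d samples", nrow(sel), ncol(sel))
    writeLines(tree_to_newick(tr), file.path(out, "dendrogram.newick"))
    emit(file.path(out, "dendrogram.newick"))
    tr
  })
  enr <- stage("enrichment", {
    if (is.null(config$gmt)) {
      say("enrichment: skipped (no gene-set collection configured)")
      NULL
    } else {
      sets <- read_gmt(config$gmt)
      up <- sig$gene[sig$direction == "up"]
      e <- enrich(up, sets, rownames(mat), config$enrichment_fdr_max,
                  config$enrichment_min_term_size, config$enrichment_method)
      say("enrichment: %d terms tested, %d enriched (fdr <= %g)",
          nrow(e), sum(e$enriched), config$enrichment_fdr_max)
      write_tsv(format_num_cols(e), file.path(out, "enrichment.tsv"))
      emit(file.path(out, "enrichment.tsv"))
      e
    }
  })

  writeLines(log_lines, file.path(out, "run_log.txt"))
  manifest <- list(
    tool = "targetsig",
    version = as.character(utils::packageVersion("targetsig")),
    inputs = lapply(inputs[!vapply(inputs, is.null, TRUE)], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    config = Filter(Negate(is.null), unclass(config)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(matrix = mat, comparisons = tab, signature = sig,
                 targets = rep, tree = tree, enrichment = enr,
                 manifest = manifest))
}

#' Re-run an analysis from its manifest
#'
#' Reads `manifest.json`, verifies the recorded input checksums, and
#' re-runs [run_pipeline()] with the recorded configuration into
#' `out_dir`; given unchanged inputs the outputs are byte-identical to the
#' original run.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir output directory for the re-run.
#' @param quiet suppress console logging.
#' @return see [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir, quiet = FALSE) {
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  for (inp in man$inputs) {
    abort_if(!file.exists(inp$path), "manifest input missing: ", inp$path)
    abort_if(!identical(unname(tools::md5sum(inp$path)), inp$md5),
             "manifest input changed on disk: ", inp$path)
  }
  cfg <- man$config
  cfg$out_dir <- out_dir
  cfg$probeset_map <- cfg$probeset_map %||% NULL
  cfg$drug_map <- cfg$drug_map %||% NULL
  cfg$gmt <- cfg$gmt %||% NULL
  run_pipeline(do.call(pipeline_config, cfg), quiet = quiet)
}

# deterministic tab-delimited output: full-precision numerics, no quoting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num_cols <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- num_chr(df[[nm]])
  }
  df
}
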