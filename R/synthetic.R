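#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the study design the analysis assumes: one small
#' target tumor cohort (15 samples) among 14 reference groups of pediatric
#' and adult brain tumors, peripheral tumors, normal brain and pituitary
#' tissue totalling 195 samples; log2 intensities with per-gene baselines
#' `N(baseline_mean, baseline_sd^2)`; per-gene noise variances drawn from a
#' scaled-inverse-chi-square prior `d0 * s0_sq / chisq(d0)` (so the
#' moderated-t prior is exactly correct and hyperparameter recovery is
#' meaningful); a planted target-specific signature with log2 effects
#' uniform over linear folds 1.5-800; decoy genes up in exactly one
#' reference group; 1-3 probesets per gene with extra probesets strictly
#' dimmer by a fixed 1.0 log2 offset per rank; a planted druggable subset of
#' the signature in which a single dominant target carries the maximal fold
#' (mirroring the spread seen in real drug-target screens); and one planted
#' enriched gene set among random background sets.
#'
#' @param seed integer RNG seed; all stochastic draws pass through one
#'   stream seeded here.
#' @param n_genes number of genes.
#' @param target_group,n_target target cohort label and size.
#' @param reference_sizes named integer vector of reference group sizes.
#' @param baseline_mean,baseline_sd per-gene log2 baseline location prior.
#' @param d0,s0_sq variance-prior degrees of freedom and scale.
#' @param n_signature planted target-up genes.
#' @param effect_range log2 effect bounds for signature genes.
#' @param n_decoy genes elevated in exactly one reference group
#'   (round-robin over reference groups).
#' @param decoy_effect_range log2 effect bounds for decoys.
#' @param n_drug_targets planted druggable signature genes.
#' @param drug_effect_range log2 effect bounds for the non-dominant drug
#'   targets.
#' @param top_drug_fold linear fold of the dominant drug target.
#' @param probesets_per_gene integer vector of allowed probeset counts.
#' @param probeset_offset log2 attenuation per extra probeset rank.
#' @param n_unmapped probesets with no gene mapping (dropped at collapse).
#' @param n_background_sets,background_set_sizes,planted_set_size gene-set
#'   collection shape; the planted set is drawn from the signature.
#' @param zero_noise force all noise variances to zero (for exact-fold
#'   checks).
#' @return validated config list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 5000L,
                         target_group = "ACP",
                         n_target = 15L,
                         reference_sizes = c(ATRT = 20L, CPP = 5L, EPN = 46L,
                                             GBM = 12L, MED = 22L, MEN = 9L,
                                             PA = 15L, PNET = 13L, MPNST = 6L,
                                             RMS = 8L, N_B = 10L, N_CP = 6L,
                                             N_PIT = 9L, PIT_AD = 14L),
                         baseline_mean = 6.0, baseline_sd = 1.5,
                         d0 = 4, s0_sq = 0.05,
                         n_signature = 100L,
                         effect_range = log2(c(1.5, 800)),
                         n_decoy = 50L,
                         decoy_effect_range = log2(c(4, 64)),
                         n_drug_targets = 10L,
                         drug_effect_range = log2(c(1.5, 8)),
                         top_drug_fold = 800,
                         probesets_per_gene = 1:3,
                         probeset_offset = 1.0,
                         n_unmapped = 10L,
                         n_background_sets = 24L,
                         background_set_sizes = c(25L, 60L),
                         planted_set_size = 20L,
                         zero_noise = FALSE) {
  cfg <- as.list(environment())
  abort_if(n_target < 2L || any(reference_sizes < 2L),
           "all group sizes must be at least 2")
  abort_if(is.null(names(reference_sizes)),
           "reference_sizes must be named")
  abort_if(d0 <= 0 || s0_sq <= 0, "variance prior must be positive")
  abort_if(any(effect_range <= 0) || effect_range[1L] > effect_range[2L],
           "effect_range must be positive and ordered")
  abort_if(n_signature + n_decoy > n_genes,
           "planted genes exceed n_genes")
  abort_if(n_drug_targets > n_signature,
           "drug targets must be a subset of the signature")
  abort_if(planted_set_size > n_signature,
           "planted set cannot exceed the signature")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a seeded synthetic cohort with ground truth
#'
#' Emits a probeset-level expression matrix
#' `value(g, s) = baseline(g) - offset(probeset) + group_effect(g, group(s))
#' + noise`, with `noise ~ N(0, sigma_g^2)` and
#' `sigma_g^2 ~ d0 * s0_sq / chisq(d0)`, plus the sample sheet, probeset
#' map, drug-target map, gene-set collection and a truth record for
#' recovery tests.  Identical seeds give bit-identical cohorts; the
#' caller's RNG state is untouched.
#'
#' @param config a [synth_config()].
#' @return list of class `"synthetic_cohort"` with elements `expr`,
#'   `samples`, `probeset_map`, `drug_map`, `gene_sets`, `truth`, `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  abort_if(!inherits(config, "synth_config"), "need a synth_config")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  M <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(M))
  groups <- c(cfg$target_group, names(cfg$reference_sizes))
  sizes <- c(cfg$n_target, unname(cfg$reference_sizes))
  sample_ids <- unlist(lapply(seq_along(groups), function(i) {
    sprintf("%s_%02d", groups[[i]], seq_len(sizes[[i]]))
  }))
  group_of <- rep(groups, sizes)
  sheet <- data.frame(sample_id = sample_ids, group = group_of,
                      is_target = group_of == cfg$target_group,
                      stringsAsFactors = FALSE)

  baseline <- stats::rnorm(M, cfg$baseline_mean, cfg$baseline_sd)
  sigma2 <- if (cfg$zero_noise) rep(0, M)
            else cfg$d0 * cfg$s0_sq / stats::rchisq(M, df = cfg$d0)

  # planted target-specific signature, with a druggable subset whose
  # dominant member carries the maximal fold
  planted <- sample.int(M, cfg$n_signature + cfg$n_decoy)
  sig_idx <- planted[seq_len(cfg$n_signature)]
  decoy_idx <- planted[-seq_len(cfg$n_signature)]
  delta <- stats::runif(cfg$n_signature, cfg$effect_range[1L],
                        cfg$effect_range[2L])
  dt_pos <- if (cfg$n_drug_targets > 0L)
    sample.int(cfg$n_signature, cfg$n_drug_targets) else integer(0)
  if (cfg$n_drug_targets > 0L) {
    delta[dt_pos[1L]] <- log2(cfg$top_drug_fold)
    if (cfg$n_drug_targets > 1L)
      delta[dt_pos[-1L]] <- stats::runif(cfg$n_drug_targets - 1L,
                                         cfg$drug_effect_range[1L],
                                         cfg$drug_effect_range[2L])
  }
  decoy_group <- rep_len(names(cfg$reference_sizes), cfg$n_decoy)
  decoy_delta <- stats::runif(cfg$n_decoy, cfg$decoy_effect_range[1L],
                              cfg$decoy_effect_range[2L])

  # per-gene, per-group effects
  E <- matrix(0, M, length(groups), dimnames = list(genes, groups))
  if (cfg$n_signature > 0L)
    E[cbind(sig_idx, rep(1L, cfg$n_signature))] <- delta
  if (cfg$n_decoy > 0L)
    E[cbind(decoy_idx, match(decoy_group, groups))] <- decoy_delta

  # expand genes to probesets; extra probesets strictly dimmer
  n_ps <- sample(cfg$probesets_per_gene, M, replace = TRUE)
  pg <- rep.int(seq_len(M), n_ps)
  ps_rank <- sequence(n_ps)
  ps_ids <- sprintf("%s_ps%d", genes[pg], ps_rank)
  offset <- (ps_rank - 1) * cfg$probeset_offset

  mu <- baseline[pg] - offset + E[pg, match(group_of, groups), drop = FALSE]
  noise <- matrix(stats::rnorm(length(pg) * length(sample_ids)),
                  length(pg)) * sqrt(sigma2[pg])
  vals <- mu + noise
  dimnames(vals) <- list(ps_ids, sample_ids)

  ps_map <- stats::setNames(genes[pg], ps_ids)

  if (cfg$n_unmapped > 0L) {
    un_ids <- sprintf("UNMAPPED_ps%03d", seq_len(cfg$n_unmapped))
    un_base <- stats::rnorm(cfg$n_unmapped, cfg$baseline_mean, cfg$baseline_sd)
    un_s2 <- if (cfg$zero_noise) rep(0, cfg$n_unmapped)
             else cfg$d0 * cfg$s0_sq / stats::rchisq(cfg$n_unmapped, cfg$d0)
    un <- un_base + matrix(stats::rnorm(cfg$n_unmapped * length(sample_ids)),
                           cfg$n_unmapped) * sqrt(un_s2)
    dimnames(un) <- list(un_ids, sample_ids)
    vals <- rbind(vals, un)
  }
  expr <- expression_matrix(vals, level = "probeset")

  drug_genes <- genes[sig_idx[dt_pos]]
  drug_map <- if (cfg$n_drug_targets > 0L) {
    stats::setNames(lapply(seq_along(drug_genes), function(i) {
      sprintf("agent_%02d%s", i, c("", "b")[seq_len(1L + (i %% 2L))])
    }), drug_genes)
  } else list()

  set_sizes <- sample(seq(cfg$background_set_sizes[1L],
                          cfg$background_set_sizes[2L]),
                      cfg$n_background_sets, replace = TRUE)
  sets <- lapply(set_sizes, function(sz) sample(genes, sz))
  names(sets) <- sprintf("TERM%03d", seq_len(cfg$n_background_sets))
  planted_term <- NA_character_
  if (cfg$planted_set_size > 0L) {
    planted_term <- "TERM_PLANTED"
    sets[[planted_term]] <- sample(genes[sig_idx], cfg$planted_set_size)
  }
  collection <- gene_set_collection(
    sets, sprintf("synthetic gene set %s", names(sets)))

  truth <- list(
    signature = data.frame(gene = genes[sig_idx], delta = delta,
                           stringsAsFactors = FALSE),
    decoys = data.frame(gene = genes[decoy_idx], group = decoy_group,
                        delta = decoy_delta, stringsAsFactors = FALSE),
    drug_targets = drug_genes,
    strongest_target = if (length(drug_genes) > 0L) drug_genes[[1L]]
                       else NA_character_,
    enriched_term = planted_term,
    d0_true = cfg$d0,
    s0_sq_true = cfg$s0_sq,
    genes = genes,
    brightest_probeset = stats::setNames(sprintf("%s_ps1", genes), genes))

  structure(list(expr = expr, samples = sheet, probeset_map = ps_map,
                 drug_map = drug_map, gene_sets = collection,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Recall/precision of pipeline outputs against planted truth
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param signature_genes character vector of recovered signature genes.
#' @param report optional ranked drug-target report (the `report` element
#'   of a [target_report()]); when given, the rank of the strongest planted
#'   drug target is reported.
#' @return list with `recall`, `precision`, `n_found`, `n_planted`, and
#'   (when a report is given) `strongest_target_rank`.
#' @export
truth_recovery_report <- function(truth, signature_genes, report = NULL) {
  abort_if(!all(signature_genes %in% truth$genes),
           "signature genes not from this cohort")
  planted <- truth$signature$gene
  hit <- intersect(signature_genes, planted)
  out <- list(
    recall = if (length(planted) > 0L) length(hit) / length(planted) else NA,
    precision = if (length(signature_genes) > 0L)
      length(hit) / length(signature_genes) else NA,
    n_found = length(signature_genes),
    n_planted = length(planted))
  if (!is.null(report)) {
    abort_if(!all(report$gene %in% truth$genes),
             "report genes not from this cohort")
    pos <- match(truth$strongest_target, report$gene)
    out$strongest_target_rank <- if (is.na(pos)) NA_integer_
                                 else report$rank[[pos]]
  }
  out
}

#' Write a synthetic cohort to a directory of analysis inputs
#'
#' Emits `expression.tsv` (probeset level), `samples.tsv`,
#' `probeset_map.tsv`, `drug_targets.tsv`, `gene_sets.gmt` and
#' `truth.json`, i.e. exactly the formats the pipeline reads.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probeset_id = names(cohort$probeset_map),
               gene_symbol = unname(cohort$probeset_map)),
    file.path(dir, "probeset_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_drug_map(cohort$drug_map, file.path(dir, "drug_targets.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
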