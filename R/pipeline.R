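# Derive a deterministic sub-seed from the run seed and a set of labels.
derive_seed <- function(seed, ...) {
  h <- strtoi(substr(fnv1a(paste(..., sep = "|")), 1L, 7L), base = 16L)
  as.integer((as.numeric(seed) + h) %% (2^31 - 1))
}

#' Per-condition interaction scores after the applicability checkup
#'
#' Recomputes raw miRNA-pair scores on the sites surviving the mutation and
#' expression filters.  Under the default "global" normalization the
#' denominator stays the regulator's raw-score total over the full
#' high-confidence evidence table (condition-independent); under "condition"
#' the scores are renormalized within the surviving evidence.
#'
#' @param kept_sites All high-confidence sites (global evidence).
#' @param surv_sites Sites surviving [applicability_filter()] in the
#'   condition.
#' @param tf_sites TF binding-site table.
#' @param mode "global" or "condition".
#' @return An `interaction_scores` data.frame.
#' @keywords internal
condition_scores <- function(kept_sites, surv_sites, tf_sites,
                             mode = "global") {
  if (mode == "condition")
    return(score_regulators(surv_sites, tf_sites))
  global <- score_regulators(kept_sites, tf_sites)
  cond <- score_regulators(surv_sites, tf_sites)
  denom <- tapply(global$raw_rs, global$regulator_id, sum)
  cond$norm_rs <- cond$raw_rs / as.numeric(denom[cond$regulator_id])
  cond
}

#' Run the full identification pipeline on an input bundle
#'
#' Chains binding-site confidence filtering, regulatory scoring, condition
#' building (differential expression + applicability checkup + design
#' matrices), per-gene meta-Lasso regulator selection, the hierarchical
#' cancer-specific / pan-cancer consistency layer, k-miRNA module discovery
#' and a selection-stability spot check.  Deterministic given the config
#' seed; every output table carries the seed and a config digest in its
#' commented header.
#'
#' @param bundle A `synthetic_bundle` (or any list with the same fields:
#'   sites, mirna_singles, mrna_singles, tf_sites, mutations, gene_expr,
#'   mirna_expr, cnv, meth, sample_sheet, pathways).  A directory path is
#'   also accepted and read with [read_bundle()].
#' @param config A `run_config`.
#' @param outdir Optional output directory for the TSV bundle.
#' @param verbose Log stage-level counts (default TRUE).
#' @return list of class `pipeline_result`: site_tests, scores, de (per
#'   condition), selections, consistency, modules (a `module_report`),
#'   stability, analysed (conditions data.frame), config.
#' @export
run_pipeline <- function(bundle, config = run_config(), outdir = NULL,
                         verbose = TRUE) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  log <- function(...) if (verbose) message("[mirmeta] ", ...)
  seed <- config$seed

  site_cols <- setdiff(colnames(bundle$sites), "is_true")
  scored <- score_sites(bundle$sites[, site_cols, drop = FALSE],
                        bundle$mirna_singles, bundle$mrna_singles,
                        alpha = config$site_alpha)
  kept <- scored[scored$passed, , drop = FALSE]
  log("site filter: ", nrow(kept), "/", nrow(scored),
      " sites high-confidence (",
      length(unique(paste(kept$mirna_id, kept$mrna_id))), " interactions)")

  scores_global <- score_regulators(kept, bundle$tf_sites)
  log("scored ", nrow(scores_global), " regulator-gene interactions")

  ss <- bundle$sample_sheet
  conds <- list_conditions(ss)
  analysed <- conds[conds$n_tumor >= 2L & conds$n_normal >= 2L, ,
                    drop = FALSE]
  sel_list <- list()
  de_list <- list()
  designs <- list()
  tuned <- list()

  for (ci in seq_len(nrow(analysed))) {
    D <- analysed$condition[ci]
    cc <- analysed$cancer_type[ci]
    st <- analysed$stage[ci]
    tumor_ids <- ss$sample_id[ss$cancer_type == cc & ss$stage == st &
                                ss$status == "tumor"]
    normal_ids <- ss$sample_id[ss$cancer_type == cc &
                                 ss$status == "normal"]
    de_g <- detect_de(bundle$gene_expr, tumor_ids, normal_ids,
                      config$de_fold_change, config$de_alpha,
                      config$pseudocount)
    de_m <- detect_de(bundle$mirna_expr, tumor_ids, normal_ids,
                      config$de_fold_change, config$de_alpha,
                      config$pseudocount)
    de_list[[D]] <- list(genes = de_g, mirnas = de_m)
    mutated <- bundle$mutations$site_id[bundle$mutations$condition == D]
    surv <- applicability_filter(kept, bundle$gene_expr,
                                 bundle$mirna_expr, tumor_ids,
                                 config$expression_floor, mutated)
    cscores <- condition_scores(kept, surv, bundle$tf_sites,
                                config$rs_normalization)
    de_mirnas <- de_m$feature_id[de_m$de]
    eligible <- cscores[cscores$kind == "TF" |
                          cscores$regulator_id %in% de_mirnas, ,
                        drop = FALSE]
    # TF regulators need expression rows to build their P columns
    eligible <- eligible[eligible$kind == "miRNA" |
                           eligible$regulator_id %in%
                           rownames(bundle$gene_expr), , drop = FALSE]
    de_genes <- de_g$feature_id[de_g$de]
    genes <- sort(intersect(intersect(de_genes, eligible$gene_id),
                            intersect(rownames(bundle$cnv),
                                      rownames(bundle$meth))))
    log(D, ": ", length(de_genes), " DE genes, ", length(de_mirnas),
        " DE miRNAs, ", nrow(surv), "/", nrow(kept),
        " sites applicable, ", length(genes), " genes analysed")
    if (length(tumor_ids) < config$folds^config$rounds) {
      log(D, ": skipped (", length(tumor_ids),
          " tumor samples < ", config$folds^config$rounds,
          " needed for hierarchical sampling)")
      next
    }
    kind_map <- stats::setNames(eligible$kind, eligible$regulator_id)
    for (gj in genes) {
      cand <- eligible[eligible$gene_id == gj, , drop = FALSE]
      if (is.finite(config$candidate_cap) &&
          nrow(cand) > config$candidate_cap)
        cand <- cand[order(-cand$norm_rs), , drop = FALSE][
          seq_len(config$candidate_cap), , drop = FALSE]
      rs_row <- build_rs_row(gj, cand)
      des <- build_design(gj, D, rs_row, kind_map, bundle$gene_expr,
                          bundle$mirna_expr, bundle$cnv, bundle$meth,
                          tumor_ids, normal_ids, config$pseudocount)
      ml <- meta_lasso(des, w = config$w_grid,
                       lambda = config$lambda_grid,
                       folds = config$folds, rounds = config$rounds,
                       seed = derive_seed(seed, D, gj))
      if (nrow(ml$selection) > 0L) {
        sel <- ml$selection
        sel$kind <- unname(kind_map[sel$regulator_id])
        sel$cancer_type <- cc
        sel$stage <- st
        sel$w <- ml$tuning$w
        sel$lambda <- ml$tuning$lambda
        sel_list[[length(sel_list) + 1L]] <- sel
        if (length(designs) < config$stability_genes) {
          designs[[paste(D, gj)]] <- des
          # back to scaled units so the stability subsamples re-adapt
          tuned[[paste(D, gj)]] <-
            c(ml$tuning$w / ml$penalty_scale[["w"]],
              ml$tuning$lambda / ml$penalty_scale[["lambda"]])
        }
      }
    }
  }
  selections <- if (length(sel_list) > 0L) do.call(rbind, sel_list) else
    data.frame(condition = character(), gene_id = character(),
               regulator_id = character(), g_effect = numeric(),
               sign = numeric(), n_subsets_nonzero = integer(),
               kind = character(), cancer_type = character(),
               stage = character(), w = numeric(), lambda = numeric())
  rownames(selections) <- NULL
  log("selected ", nrow(selections), " regulator-gene-condition triples")

  consistency <- hierarchical_consistency(selections, analysed,
                                          config$stage_fraction,
                                          config$cancer_fraction)
  modules <- find_modules(selections, bundle$pathways,
                          conditions = analysed$condition,
                          k_min = config$k_min, k_max = config$k_max,
                          enrich_alpha = config$enrich_alpha,
                          involvement_alpha = config$involvement_alpha,
                          q_threshold = config$module_q,
                          cap = config$pathway_mirna_cap)
  log("modules: ", nrow(modules$candidates), " candidates, ",
      nrow(modules$modules), " reported")

  stab_rows <- list()
  for (nm in names(designs)) {
    des <- designs[[nm]]
    n <- length(des$sample_ids)
    lo <- config$folds^config$rounds
    sizes <- unique(round(seq(lo, n, length.out = 3L)))
    if (length(sizes) >= 2L)
      stab_rows[[nm]] <- cbind(
        condition = des$condition,
        stability_curve(des, sizes,
                        repetitions = config$stability_reps,
                        seed = derive_seed(seed, "stability", nm),
                        w = tuned[[nm]][1L], lambda = tuned[[nm]][2L],
                        folds = config$folds, rounds = config$rounds))
  }
  stability <- if (length(stab_rows) > 0L) do.call(rbind, stab_rows) else
    data.frame()
  rownames(stability) <- NULL

  result <- list(site_tests = scored, scores = scores_global, de = de_list,
                 selections = selections, consistency = consistency,
                 modules = modules, stability = stability,
                 analysed = analysed, config = config)
  class(result) <- "pipeline_result"
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' Write a pipeline result bundle as TSVs with provenance headers
#' @param result A `pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  wt <- function(df, f) write_tsv(df, file.path(outdir, f),
                                  seed = cfg$seed,
                                  config_digest = cfg$digest)
  wt(result$site_tests, "site_tests.tsv")
  wt(result$scores, "interaction_scores.tsv")
  de_g <- do.call(rbind, lapply(names(result$de), function(D)
    cbind(condition = D, result$de[[D]]$genes)))
  de_m <- do.call(rbind, lapply(names(result$de), function(D)
    cbind(condition = D, result$de[[D]]$mirnas)))
  wt(de_g, "de_genes.tsv")
  wt(de_m, "de_mirnas.tsv")
  wt(result$selections, "selections.tsv")
  wt(result$consistency$cancer_specific, "consistency_cancer.tsv")
  wt(result$consistency$common, "consistency_common.tsv")
  wt(result$modules$candidates, "module_candidates.tsv")
  wt(result$modules$modules, "modules.tsv")
  if (nrow(result$stability) > 0L) wt(result$stability, "stability.tsv")
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("mirmeta pipeline result\n")
  cat("  conditions analysed:", nrow(x$analysed), "\n")
  cat("  high-confidence sites:", sum(x$site_tests$passed), "/",
      nrow(x$site_tests), "\n")
  cat("  selections:", nrow(x$selections), "triples\n")
  cat("  modules reported:", nrow(x$modules$modules), "\n")
  invisible(x)
}
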