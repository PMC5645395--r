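#' Generate a ground-truth regulatory network
#'
#' Lays out the identifier universes, the (cancer, stage) condition grid, a
#' condition-specific true-regulator network and one planted k-miRNA module.
#' Outside the planted module the regulatory landscape is drawn independently
#' per condition, emulating stage-specific regulation; the module's miRNAs
#' target the module's genes in every one of its supporting conditions, and
#' those genes are later co-assigned to the module's pathways.  Every gene
#' also receives a per-condition differential-expression shift so tumor and
#' normal distributions separate.
#'
#' @param n_genes,n_mirnas,n_tfs Universe sizes (defaults 200, 60, 10).
#'   The miRNA universe is deliberately much larger than the number of
#'   regulator edges per condition: the recurrence null rate P_k divides the
#'   supported-candidate count by choose(K, k), and a true module's
#'   combinatorial halo (supported candidates overlapping it) inflates P_k
#'   unless K is large enough to dilute it, as it is in real CLASH data.
#' @param n_conditions Number of (cancer, stage) conditions (default 6;
#'   cancers carry up to 3 stages each).
#' @param regulators_per_gene True regulators drawn per regulated gene per
#'   condition (default 2; roughly 30\% TFs).
#' @param regulated_fraction Fraction of genes that carry regulator edges in
#'   any one condition (default 0.3).  Regulation is sparse and
#'   condition-specific: each condition regulates its own random gene
#'   subset, so each miRNA has only a handful of targets per condition and
#'   chance k-miRNA groups rarely share pathways, let alone recur — the
#'   regime the module recurrence test is designed for.
#' @param module_spec list(k, n_conditions, n_genes, n_pathways) of the
#'   planted module (defaults 4, 3, 12, 2).
#' @param seed Integer seed.
#' @return list of class `ground_truth`: ids, conditions (data.frame),
#'   edges (condition, gene_id, regulator_id, kind, effect), shifts
#'   (gene x condition matrix), module (mirnas, genes, pathways, conditions),
#'   seed.
#' @export
generate_truth <- function(n_genes = 200L, n_mirnas = 60L, n_tfs = 10L,
                           n_conditions = 6L, regulators_per_gene = 2L,
                           regulated_fraction = 0.3,
                           module_spec = list(k = 4L, n_conditions = 3L,
                                              n_genes = 12L,
                                              n_pathways = 2L),
                           seed = 1L) {
  stopifnot(regulated_fraction > 0, regulated_fraction <= 1)
  stopifnot(n_genes >= 1L, n_mirnas >= 1L, n_tfs >= 1L, n_conditions >= 1L)
  if (module_spec$k > n_mirnas)
    stop("infeasible module_spec: k exceeds the number of miRNAs")
  if (module_spec$n_conditions > n_conditions)
    stop("infeasible module_spec: more supporting conditions than conditions")
  if (module_spec$n_genes > n_genes)
    stop("infeasible module_spec: more module genes than genes")
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  mirnas <- sprintf("mir_%03d", seq_len(n_mirnas))
  tfs <- sprintf("tf_%02d", seq_len(n_tfs))
  n_cancers <- ceiling(n_conditions / 3)
  stages <- c("I", "II", "III")
  conds <- data.frame(
    cancer_type = paste0("cancer_", LETTERS[rep(seq_len(n_cancers),
                                                each = 3)][seq_len(n_conditions)]),
    stage = rep(stages, n_cancers)[seq_len(n_conditions)],
    stringsAsFactors = FALSE)
  conds$condition <- paste(conds$cancer_type, conds$stage, sep = ":")

  with_seed(seed, {
    regulator_pool <- c(mirnas, tfs)
    kind_of <- stats::setNames(c(rep("miRNA", n_mirnas), rep("TF", n_tfs)),
                               regulator_pool)
    edges <- list()
    n_reg <- max(1L, round(regulated_fraction * n_genes))
    for (D in conds$condition) {
      for (gj in sort(sample(genes, n_reg))) {
        # ~30% TFs among the true regulators of a gene
        k_tf <- stats::rbinom(1L, regulators_per_gene, 0.3)
        regs <- c(if (k_tf > 0L) sample(tfs, min(k_tf, n_tfs)),
                  sample(mirnas, regulators_per_gene - min(k_tf, n_tfs)))
        eff <- ifelse(kind_of[regs] == "miRNA",
                      -stats::runif(length(regs), 0.5, 1.5),
                      sample(c(-1, 1), length(regs), replace = TRUE) *
                        stats::runif(length(regs), 0.5, 1.5))
        edges[[length(edges) + 1L]] <- data.frame(
          condition = D, gene_id = gj, regulator_id = regs,
          kind = unname(kind_of[regs]), effect = unname(eff),
          stringsAsFactors = FALSE)
      }
    }
    mod_mirnas <- sort(sample(mirnas, module_spec$k))
    mod_genes <- sort(sample(genes, module_spec$n_genes))
    mod_conds <- sort(sample(conds$condition, module_spec$n_conditions))
    for (D in mod_conds) {
      grid <- expand.grid(gene_id = mod_genes, regulator_id = mod_mirnas,
                          stringsAsFactors = FALSE)
      edges[[length(edges) + 1L]] <- data.frame(
        condition = D, gene_id = grid$gene_id,
        regulator_id = grid$regulator_id, kind = "miRNA",
        effect = -stats::runif(nrow(grid), 0.5, 1.5),
        stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, edges)
    # deduplicate (module edge may coincide with a random edge)
    key <- paste(edges$condition, edges$gene_id, edges$regulator_id)
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
    shifts <- matrix(sample(c(-1, 1), n_genes * n_conditions,
                            replace = TRUE) *
                       stats::runif(n_genes * n_conditions, 1.2, 2),
                     nrow = n_genes,
                     dimnames = list(genes, conds$condition))
    out <- list(genes = genes, mirnas = mirnas, tfs = tfs,
                conditions = conds, edges = edges, shifts = shifts,
                module = list(mirnas = mod_mirnas, genes = mod_genes,
                              pathways = sprintf(
                                "pw_mod%d",
                                seq_len(module_spec$n_pathways)),
                              conditions = mod_conds),
                seed = seed)
    class(out) <- "ground_truth"
    out
  })
}

#' Generate CLASH-style binding evidence for a truth network
#'
#' True miRNA-gene pairs receive 1-3 binding sites with high-mean
#' negative-binomial chimeric counts; an equal number of decoy pairs receive
#' low-mean counts.  Minimum free energies are uniform on \[-31.2, -2.9\]
#' kcal/mol.  Unbound single reads are negative-binomial with mean scaling
#' with depth, deep enough that true pairs clear the Bonferroni confidence
#' filter while most decoys do not.  A small fraction of sites is flagged as
#' somatically mutated in one random condition.
#'
#' @param truth A `ground_truth`.
#' @param depth Mean chimeric count per true site (default 20).
#' @param seed Integer seed.
#' @return list: `sites` (binding-site table with is_true column),
#'   `mirna_singles`, `mrna_singles` (named counts), `mutations`
#'   (site_id, condition).
#' @export
generate_binding_evidence <- function(truth, depth = 20, seed = 1L) {
  stopifnot(depth > 0)
  me <- truth$edges[truth$edges$kind == "miRNA", , drop = FALSE]
  true_pairs <- unique(me[, c("regulator_id", "gene_id")])
  with_seed(seed, {
    n_true <- nrow(true_pairs)
    # decoys drawn from pairs not in the truth
    all_keys <- paste(true_pairs$regulator_id, true_pairs$gene_id)
    decoys <- data.frame(regulator_id = sample(truth$mirnas, 4L * n_true,
                                               replace = TRUE),
                         gene_id = sample(truth$genes, 4L * n_true,
                                          replace = TRUE),
                         stringsAsFactors = FALSE)
    decoys <- decoys[!paste(decoys$regulator_id, decoys$gene_id) %in%
                       all_keys, , drop = FALSE]
    decoys <- decoys[!duplicated(paste(decoys$regulator_id,
                                       decoys$gene_id)), , drop = FALSE]
    decoys <- utils::head(decoys, n_true)
    mk_sites <- function(pairs, is_true) {
      ns <- if (is_true) sample(1:3, nrow(pairs), replace = TRUE)
      else rep(1L, nrow(pairs))
      idx <- rep(seq_len(nrow(pairs)), ns)
      n_sites <- length(idx)
      cnt <- if (is_true)
        stats::rnbinom(n_sites, size = 2, mu = depth)
      else stats::rnbinom(n_sites, size = 0.5, mu = 0.5)
      data.frame(mirna_id = pairs$regulator_id[idx],
                 mrna_id = pairs$gene_id[idx],
                 site_id = NA_character_,
                 tx_id = pairs$gene_id[idx],
                 start = (st <- sample(0:2000, n_sites, replace = TRUE)),
                 end = st + 22L,
                 chimeric_count = cnt,
                 mfe = stats::runif(n_sites, -31.2, -2.9),
                 is_true = is_true, stringsAsFactors = FALSE)
    }
    sites <- rbind(mk_sites(true_pairs, TRUE), mk_sites(decoys, FALSE))
    sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
    mu_single <- 150 * depth
    mirna_singles <- stats::setNames(
      stats::rnbinom(length(truth$mirnas), size = 10, mu = mu_single),
      truth$mirnas)
    mrna_singles <- stats::setNames(
      stats::rnbinom(length(truth$genes), size = 10, mu = mu_single),
      truth$genes)
    n_mut <- max(1L, round(0.01 * nrow(sites)))
    mut_idx <- sample(seq_len(nrow(sites)), n_mut)
    mutations <- data.frame(
      site_id = sites$site_id[mut_idx],
      condition = sample(truth$conditions$condition, n_mut, replace = TRUE),
      stringsAsFactors = FALSE)
    list(sites = sites, mirna_singles = mirna_singles,
         mrna_singles = mrna_singles, mutations = mutations)
  })
}

#' Generate TF binding sites for a truth network
#'
#' True TF-gene edges receive 1-2 sites at TSS distances drawn exponentially
#' (mean 10 kb); half as many decoy TF-gene pairs receive one distant site.
#'
#' @param truth A `ground_truth`.
#' @param seed Integer seed.
#' @return data.frame: tf_id, gene_id, site_id, tss_distance.
#' @export
generate_tf_sites <- function(truth, seed = 1L) {
  te <- truth$edges[truth$edges$kind == "TF", , drop = FALSE]
  pairs <- unique(te[, c("regulator_id", "gene_id")])
  with_seed(seed, {
    keys <- paste(pairs$regulator_id, pairs$gene_id)
    dec <- data.frame(
      regulator_id = sample(truth$tfs, nrow(pairs), replace = TRUE),
      gene_id = sample(truth$genes, nrow(pairs), replace = TRUE),
      stringsAsFactors = FALSE)
    dec <- dec[!paste(dec$regulator_id, dec$gene_id) %in% keys, ,
               drop = FALSE]
    dec <- utils::head(dec[!duplicated(paste(dec$regulator_id,
                                             dec$gene_id)), , drop = FALSE],
                       ceiling(nrow(pairs) / 2))
    ns <- c(sample(1:2, nrow(pairs), replace = TRUE), rep(1L, nrow(dec)))
    all_pairs <- rbind(pairs, dec)
    idx <- rep(seq_len(nrow(all_pairs)), ns)
    data.frame(tf_id = all_pairs$regulator_id[idx],
               gene_id = all_pairs$gene_id[idx],
               site_id = sprintf("tfsite_%05d", seq_along(idx)),
               tss_distance = round(stats::rexp(length(idx), 1 / 10000)),
               stringsAsFactors = FALSE)
  })
}

#' Generate expression, CNV and methylation tables with a sample sheet
#'
#' Normal samples are log-normal around per-feature baselines.  Tumor
#' regulator (miRNA and TF) expression changes are normal around a
#' per-condition differential-expression mean; tumor gene changes follow the
#' generative linear model: the gene's DE shift, plus copy-number change
#' (coefficient +1) and methylation beta difference (coefficient -2), plus
#' the sum of its true regulators' effects times their expression changes,
#' plus Gaussian noise.  CNV changes are N(0, 0.3); methylation differences
#' N(0, 0.2) on the beta scale.
#'
#' @param truth A `ground_truth`.
#' @param samples_per_condition Tumor samples per condition (default 30,
#'   minimum 10).
#' @param n_normals Normal samples per cancer type (default 20).
#' @param noise_sd Residual sd of the gene model (default 0.3).
#' @param seed Integer seed.
#' @return list: gene_expr, mirna_expr, cnv, meth (matrices),
#'   sample_sheet (data.frame).
#' @export
generate_expression <- function(truth, samples_per_condition = 30L,
                                n_normals = 20L, noise_sd = 0.3,
                                seed = 1L) {
  stopifnot(samples_per_condition >= 10L, n_normals >= 2L, noise_sd >= 0)
  conds <- truth$conditions
  cancers <- unique(conds$cancer_type)
  gene_rows <- c(truth$genes, truth$tfs)  # TFs are genes in the gene table
  with_seed(seed, {
    tumor_ids <- unlist(lapply(conds$condition, function(D)
      sprintf("%s_T%02d", gsub(":", "_", D),
              seq_len(samples_per_condition))))
    tumor_cond <- rep(conds$condition, each = samples_per_condition)
    normal_ids <- unlist(lapply(cancers, function(cc)
      sprintf("%s_N%02d", cc, seq_len(n_normals))))
    normal_cancer <- rep(cancers, each = n_normals)
    all_ids <- c(tumor_ids, normal_ids)

    base_g <- stats::setNames(stats::rlnorm(length(gene_rows), log(100),
                                            0.7), gene_rows)
    base_m <- stats::setNames(stats::rlnorm(length(truth$mirnas), log(100),
                                            0.7), truth$mirnas)

    gene_expr <- matrix(0, length(gene_rows), length(all_ids),
                        dimnames = list(gene_rows, all_ids))
    mirna_expr <- matrix(0, length(truth$mirnas), length(all_ids),
                         dimnames = list(truth$mirnas, all_ids))
    cnv <- matrix(0, length(gene_rows), length(all_ids),
                  dimnames = list(gene_rows, all_ids))
    meth <- matrix(0, length(gene_rows), length(all_ids),
                   dimnames = list(gene_rows, all_ids))
    meth_base <- stats::setNames(stats::runif(length(gene_rows), 0.25,
                                              0.75), gene_rows)

    # normals
    for (sid in normal_ids) {
      gene_expr[, sid] <- base_g * stats::rlnorm(length(gene_rows), 0, 0.15)
      mirna_expr[, sid] <- base_m * stats::rlnorm(length(base_m), 0, 0.15)
      cnv[, sid] <- stats::rnorm(length(gene_rows), 0, 0.02)
      meth[, sid] <- pmin(pmax(meth_base +
                                 stats::rnorm(length(gene_rows), 0, 0.02),
                               0), 1)
    }
    ctrl_gene <- lapply(cancers, function(cc)
      rowMeans(gene_expr[, normal_ids[normal_cancer == cc], drop = FALSE]))
    names(ctrl_gene) <- cancers
    ctrl_mirna <- lapply(cancers, function(cc)
      rowMeans(mirna_expr[, normal_ids[normal_cancer == cc], drop = FALSE]))
    names(ctrl_mirna) <- cancers
    ctrl_cnv <- lapply(cancers, function(cc)
      rowMeans(cnv[, normal_ids[normal_cancer == cc], drop = FALSE]))
    names(ctrl_cnv) <- cancers
    ctrl_meth <- lapply(cancers, function(cc)
      rowMeans(meth[, normal_ids[normal_cancer == cc], drop = FALSE]))
    names(ctrl_meth) <- cancers

    for (ci in seq_len(nrow(conds))) {
      D <- conds$condition[ci]
      cc <- conds$cancer_type[ci]
      sids <- tumor_ids[tumor_cond == D]
      ns <- length(sids)
      eD <- truth$edges[truth$edges$condition == D, , drop = FALSE]

      # regulator expression changes: per-condition DE means, all regulators
      mu_m <- sample(c(-1, 1), length(truth$mirnas), replace = TRUE) *
        stats::runif(length(truth$mirnas), 1.2, 2.5)
      dm <- matrix(stats::rnorm(length(truth$mirnas) * ns, 0, 0.8),
                   ncol = ns) + mu_m
      rownames(dm) <- truth$mirnas
      mirna_expr[, sids] <- ctrl_mirna[[cc]] * 2^dm

      mu_t <- sample(c(-1, 1), length(truth$tfs), replace = TRUE) *
        stats::runif(length(truth$tfs), 1.2, 2.5)
      dt <- matrix(stats::rnorm(length(truth$tfs) * ns, 0, 0.8),
                   ncol = ns) + mu_t
      rownames(dt) <- truth$tfs
      gene_expr[truth$tfs, sids] <- ctrl_gene[[cc]][truth$tfs] * 2^dt

      dcnv <- matrix(stats::rnorm(length(gene_rows) * ns, 0, 0.3),
                     nrow = length(gene_rows),
                     dimnames = list(gene_rows, sids))
      cnv[, sids] <- ctrl_cnv[[cc]] + dcnv
      dmeth <- matrix(stats::rnorm(length(gene_rows) * ns, 0, 0.2),
                      nrow = length(gene_rows),
                      dimnames = list(gene_rows, sids))
      meth[, sids] <- pmin(pmax(ctrl_meth[[cc]] + dmeth, 0), 1)
      dmeth_eff <- meth[, sids, drop = FALSE] -
        ctrl_meth[[cc]]  # after clamping, the realized difference

      dreg <- rbind(dm, dt)  # regulator changes by id
      for (gj in truth$genes) {
        eg <- eD[eD$gene_id == gj, , drop = FALSE]
        reg_term <- if (nrow(eg) > 0L)
          as.numeric(eg$effect %*% dreg[eg$regulator_id, , drop = FALSE])
        else 0
        dg <- truth$shifts[gj, D] + 1.0 * dcnv[gj, ] -
          2.0 * dmeth_eff[gj, ] + reg_term +
          stats::rnorm(ns, 0, noise_sd)
        gene_expr[gj, sids] <- ctrl_gene[[cc]][gj] * 2^dg
      }
    }
    sample_sheet <- validate_sample_sheet(rbind(
      data.frame(sample_id = tumor_ids,
                 cancer_type = conds$cancer_type[match(tumor_cond,
                                                       conds$condition)],
                 stage = conds$stage[match(tumor_cond, conds$condition)],
                 status = "tumor", stringsAsFactors = FALSE),
      data.frame(sample_id = normal_ids, cancer_type = normal_cancer,
                 stage = "", status = "normal", stringsAsFactors = FALSE)))
    list(gene_expr = gene_expr, mirna_expr = mirna_expr, cnv = cnv,
         meth = meth, sample_sheet = sample_sheet)
  })
}

#' Generate a pathway collection with the planted module's pathways
#'
#' The planted module's target genes are co-assigned to each of the module's
#' pathways (padded with random genes); the remaining pathways are random
#' gene sets.
#'
#' @param truth A `ground_truth`.
#' @param n_pathways Total number of pathways (default 40).
#' @param size_range Pathway size range (default 8-15, minimum 5).
#' @param seed Integer seed.
#' @return Named list (pathway -> genes) of class `pathway_collection`.
#' @export
generate_pathways <- function(truth, n_pathways = 40L,
                              size_range = c(8L, 15L), seed = 1L) {
  stopifnot(n_pathways >= length(truth$module$pathways),
            size_range[1L] >= 5L)
  with_seed(seed, {
    pw <- list()
    for (nm in truth$module$pathways) {
      extra <- sample(setdiff(truth$genes, truth$module$genes),
                      max(0L, size_range[1L] - length(truth$module$genes)) +
                        3L)
      pw[[nm]] <- sort(unique(c(truth$module$genes, extra)))
    }
    n_rand <- n_pathways - length(pw)
    for (i in seq_len(n_rand)) {
      sz <- sample(seq(size_range[1L], size_range[2L]), 1L)
      pw[[sprintf("pw_%03d", i)]] <- sort(sample(truth$genes, sz))
    }
    class(pw) <- "pathway_collection"
    pw
  })
}

#' Generate a complete synthetic input bundle
#'
#' Chains the truth, binding-evidence, TF-site, expression and pathway
#' generators into the full set of inputs the pipeline consumes, optionally
#' writing them to disk in the layout [run_pipeline()] expects (plus
#' truth_edges.tsv / truth_module.tsv).
#'
#' @param n_genes,n_mirnas,n_tfs,n_conditions,regulators_per_gene,regulated_fraction,module_spec
#'   Passed to [generate_truth()].
#' @param depth Passed to [generate_binding_evidence()].
#' @param samples_per_condition,n_normals,noise_sd Passed to
#'   [generate_expression()].
#' @param n_pathways Passed to [generate_pathways()].
#' @param seed Master seed; per-generator seeds are derived from it.
#' @param dir Optional output directory.
#' @return list of class `synthetic_bundle` with all inputs plus `truth`.
#' @export
simulate_bundle <- function(n_genes = 200L, n_mirnas = 60L, n_tfs = 10L,
                            n_conditions = 6L, regulators_per_gene = 2L,
                            regulated_fraction = 0.3,
                            module_spec = list(k = 4L, n_conditions = 3L,
                                               n_genes = 12L,
                                               n_pathways = 2L),
                            depth = 20, samples_per_condition = 30L,
                            n_normals = 20L, noise_sd = 0.3,
                            n_pathways = 40L, seed = 1L, dir = NULL) {
  truth <- generate_truth(n_genes, n_mirnas, n_tfs, n_conditions,
                          regulators_per_gene, regulated_fraction,
                          module_spec, seed = seed)
  ev <- generate_binding_evidence(truth, depth = depth, seed = seed + 1L)
  tf_sites <- generate_tf_sites(truth, seed = seed + 2L)
  ex <- generate_expression(truth, samples_per_condition, n_normals,
                            noise_sd, seed = seed + 3L)
  pathways <- generate_pathways(truth, n_pathways, seed = seed + 4L)
  bundle <- c(list(truth = truth, sites = ev$sites,
                   mirna_singles = ev$mirna_singles,
                   mrna_singles = ev$mrna_singles,
                   mutations = ev$mutations, tf_sites = tf_sites,
                   pathways = pathways, seed = seed),
              ex)
  class(bundle) <- "synthetic_bundle"
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to disk
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$gene_expr, p("expression_genes.tsv"))
  write_expression(bundle$mirna_expr, p("expression_mirnas.tsv"))
  write_expression(bundle$cnv, p("cnv.tsv"))
  write_expression(bundle$meth, p("methylation.tsv"))
  utils::write.table(bundle$sample_sheet, p("sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$sites, p("binding_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(mirna_id = names(bundle$mirna_singles),
                                count = as.numeric(bundle$mirna_singles)),
                     p("mirna_singles.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(mrna_id = names(bundle$mrna_singles),
                                count = as.numeric(bundle$mrna_singles)),
                     p("mrna_singles.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$tf_sites, p("tf_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$mutations, p("mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$pathways, p("pathways.gmt"))
  utils::write.table(bundle$truth$edges, p("truth_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mod <- bundle$truth$module
  utils::write.table(
    data.frame(field = c("mirnas", "genes", "pathways", "conditions"),
               value = c(paste(mod$mirnas, collapse = ","),
                         paste(mod$genes, collapse = ","),
                         paste(mod$pathways, collapse = ","),
                         paste(mod$conditions, collapse = ","))),
    p("truth_module.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bundle directory back into memory
#' @param dir Directory written by [write_bundle()].
#' @return list shaped like the output of [simulate_bundle()] (without
#'   truth if the truth files are absent).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  ms <- read_tsv(p("mirna_singles.tsv"))
  rs <- read_tsv(p("mrna_singles.tsv"))
  bundle <- list(
    gene_expr = read_expression(p("expression_genes.tsv")),
    mirna_expr = read_expression(p("expression_mirnas.tsv")),
    cnv = read_expression(p("cnv.tsv"), nonnegative = FALSE),
    meth = read_expression(p("methylation.tsv")),
    sample_sheet = read_sample_sheet(p("sample_sheet.tsv")),
    sites = read_tsv(p("binding_sites.tsv")),
    mirna_singles = stats::setNames(ms$count, ms$mirna_id),
    mrna_singles = stats::setNames(rs$count, rs$mrna_id),
    tf_sites = read_tsv(p("tf_sites.tsv")),
    mutations = read_tsv(p("mutations.tsv")),
    pathways = read_gmt(p("pathways.gmt")))
  class(bundle) <- "synthetic_bundle"
  bundle
}

#' Precision, recall and F1 of selections against the truth
#'
#' Compares the selected (condition, gene, regulator) triples with the true
#' edges of the generator.
#'
#' @param selections data.frame with columns condition, gene_id,
#'   regulator_id.
#' @param truth A `ground_truth` (or its `edges` data.frame).
#' @param conditions Restrict to these conditions (default: all in truth).
#' @param genes Restrict to these genes (default: all; pass the analysed
#'   genes to score recovery conditional on analysis).
#' @return list with precision, recall, f1, tp, fp, fn.
#' @export
selection_f1 <- function(selections, truth, conditions = NULL,
                         genes = NULL) {
  edges <- if (inherits(truth, "ground_truth")) truth$edges else truth
  if (!is.null(conditions)) {
    edges <- edges[edges$condition %in% conditions, , drop = FALSE]
    selections <- selections[selections$condition %in% conditions, ,
                             drop = FALSE]
  }
  if (!is.null(genes)) {
    edges <- edges[edges$gene_id %in% genes, , drop = FALSE]
    selections <- selections[selections$gene_id %in% genes, , drop = FALSE]
  }
  tkey <- unique(paste(edges$condition, edges$gene_id, edges$regulator_id))
  skey <- unique(paste(selections$condition, selections$gene_id,
                       selections$regulator_id))
  tp <- length(intersect(skey, tkey))
  fp <- length(setdiff(skey, tkey))
  fn <- length(setdiff(tkey, skey))
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn)
}
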