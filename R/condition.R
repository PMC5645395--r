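#' Log2 expression change versus the control mean
#'
#' log2((value + c) / (control_mean + c)) with pseudocount c > 0 applied to
#' both terms, so zero-valued samples and controls stay finite.
#'
#' @param value Non-negative expression value(s).
#' @param control_mean Non-negative mean expression of the normal controls.
#' @param pseudocount Positive pseudocount, default 0.5.
#' @return Finite log2 fold change(s).
#' @export
log2_change <- function(value, control_mean, pseudocount = 0.5) {
  if (any(value < 0) || any(control_mean < 0))
    stop("expression values must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2((value + pseudocount) / (control_mean + pseudocount))
}

#' Matrix of expression changes for one condition
#'
#' For each feature, the per-tumor-sample log2 change against that feature's
#' mean over the condition's normal-control samples.
#'
#' @param expr Expression matrix (features x samples).
#' @param tumor_ids,normal_ids Sample id vectors (columns of `expr`).
#' @param pseudocount Pseudocount for [log2_change()].
#' @return Matrix (features x tumor samples) of log2 changes.
#' @export
expression_changes <- function(expr, tumor_ids, normal_ids,
                               pseudocount = 0.5) {
  miss <- setdiff(c(tumor_ids, normal_ids), colnames(expr))
  if (length(miss) > 0L)
    stop("sample id(s) absent from expression table: ",
         paste(miss, collapse = ", "))
  ctrl <- rowMeans(expr[, normal_ids, drop = FALSE])
  tum <- expr[, tumor_ids, drop = FALSE]
  log2((tum + pseudocount) / (ctrl + pseudocount))
}

#' Differential-expression test for one condition
#'
#' A feature is differentially expressed when its mean log2 change exceeds
#' log2(fc_threshold) in absolute value AND its Wilcoxon rank-sum tumor vs
#' normal p-value, Benjamini-Hochberg adjusted across all features of the
#' condition, is below alpha.
#'
#' @param expr Expression matrix (features x samples).
#' @param tumor_ids,normal_ids Sample id vectors.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param pseudocount Pseudocount for the log2 changes.
#' @return data.frame with feature_id, mean_delta, p_value, adjusted_p, de.
#' @export
detect_de <- function(expr, tumor_ids, normal_ids, fc_threshold = 2,
                      alpha = 0.05, pseudocount = 0.5) {
  if (length(tumor_ids) < 2L || length(normal_ids) < 2L) {
    warning("fewer than 2 samples in a group; no features tested")
    return(data.frame(feature_id = character(), mean_delta = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      de = logical()))
  }
  delta <- expression_changes(expr, tumor_ids, normal_ids, pseudocount)
  tum <- expr[, tumor_ids, drop = FALSE]
  nor <- expr[, normal_ids, drop = FALSE]
  pv <- vapply(seq_len(nrow(expr)), function(i) {
    x <- tum[i, ]; y <- nor[i, ]
    if (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L]) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }, numeric(1L))
  pv[is.na(pv)] <- 1
  adj <- stats::p.adjust(pv, method = "BH")
  md <- rowMeans(delta)
  data.frame(feature_id = rownames(expr), mean_delta = md, p_value = pv,
             adjusted_p = adj,
             de = abs(md) >= log2(fc_threshold) & adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Applicability checkup of interactions in one condition
#'
#' An interaction is carried into a condition only when both sides are
#' expressed there and its binding evidence is not mutated away: (i) the
#' median tumor expression of both the miRNA and the gene must exceed the
#' expression floor; (ii) sites whose site_id carries a somatic-mutation flag
#' in this condition are dropped and the pair's regulatory score is
#' recomputed from the surviving sites; a pair whose sites are all mutated is
#' removed.
#'
#' @param scored_sites High-confidence site table (from [score_sites()],
#'   passed sites).
#' @param gene_expr,mirna_expr Expression matrices.
#' @param tumor_ids Tumor sample ids of the condition.
#' @param expression_floor Minimum (exclusive) median tumor expression.
#' @param mutated_site_ids Character vector of site_ids flagged as mutated in
#'   this condition.
#' @return The surviving site rows (interaction scores must be recomputed on
#'   them with [score_regulators()]).
#' @export
applicability_filter <- function(scored_sites, gene_expr, mirna_expr,
                                 tumor_ids, expression_floor = 0,
                                 mutated_site_ids = character()) {
  if (nrow(scored_sites) == 0L) return(scored_sites)
  keep_mut <- !(scored_sites$site_id %in% mutated_site_ids)
  s <- scored_sites[keep_mut, , drop = FALSE]
  if (nrow(s) == 0L) return(s)
  med_g <- apply(gene_expr[, tumor_ids, drop = FALSE], 1L, stats::median)
  med_m <- apply(mirna_expr[, tumor_ids, drop = FALSE], 1L, stats::median)
  gi <- match(s$mrna_id, rownames(gene_expr))
  mi <- match(s$mirna_id, rownames(mirna_expr))
  if (anyNA(gi) || anyNA(mi))
    stop("interaction references a feature absent from the expression tables")
  keep <- med_g[gi] > expression_floor & med_m[mi] > expression_floor
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the design matrices of one gene in one condition
#'
#' Assembles the response Y (tumor-sample log2 expression changes of the
#' gene), the background X1 (per-sample copy-number log2 change and
#' methylation beta difference versus the control means), the regulator
#' expression-change matrix P, the regulatory-score row R and the regulatory
#' effect matrix X2 with X2\[s, p\] = P\[s, p\] * R\[p\].  Columns follow the
#' canonical regulator ordering (TFs first, then miRNAs, lexicographic).
#'
#' @param gene_id Gene identifier.
#' @param condition Condition label (informational).
#' @param rs_row Named normalized-score vector from [build_rs_row()].
#' @param regulator_kind Named character vector ("TF"/"miRNA") aligned with
#'   `rs_row` names.
#' @param gene_expr,mirna_expr,cnv,meth Feature x sample matrices; `meth`
#'   holds beta values in \[0, 1\].
#' @param tumor_ids,normal_ids Sample ids of the condition.
#' @param pseudocount Pseudocount for log2 changes.
#' @return list of class `gene_condition_design` with Y, X1, P, R, X2,
#'   regulator_ids, regulator_kind, gene_id, condition, sample_ids.
#' @export
build_design <- function(gene_id, condition, rs_row, regulator_kind,
                         gene_expr, mirna_expr, cnv, meth,
                         tumor_ids, normal_ids, pseudocount = 0.5) {
  if (length(rs_row) == 0L) stop("gene '", gene_id, "' has no candidates")
  n <- length(tumor_ids)
  if (n < 1L) stop("condition has no tumor samples")
  ord <- order(regulator_kind[names(rs_row)] != "TF", names(rs_row))
  rs_row <- rs_row[ord]
  regs <- names(rs_row)
  kinds <- regulator_kind[regs]

  ctrl_g <- mean(gene_expr[gene_id, normal_ids])
  Y <- matrix(log2_change(gene_expr[gene_id, tumor_ids], ctrl_g,
                          pseudocount), ncol = 1L,
              dimnames = list(tumor_ids, gene_id))

  cnv_ctrl <- mean(cnv[gene_id, normal_ids])
  meth_ctrl <- mean(meth[gene_id, normal_ids])
  X1 <- cbind(cnv_change = cnv[gene_id, tumor_ids] - cnv_ctrl,
              meth_change = meth[gene_id, tumor_ids] - meth_ctrl)
  rownames(X1) <- tumor_ids

  P <- matrix(0, nrow = n, ncol = length(regs),
              dimnames = list(tumor_ids, regs))
  for (p in seq_along(regs)) {
    src <- if (kinds[p] == "miRNA") mirna_expr else gene_expr
    if (!regs[p] %in% rownames(src))
      stop("regulator '", regs[p], "' absent from its expression table")
    ctrl <- mean(src[regs[p], normal_ids])
    P[, p] <- log2_change(src[regs[p], tumor_ids], ctrl, pseudocount)
  }
  R <- rs_row
  X2 <- sweep(P, 2L, R, "*")
  out <- list(gene_id = gene_id, condition = condition, Y = Y, X1 = X1,
              P = P, R = R, X2 = X2, regulator_ids = regs,
              regulator_kind = unname(kinds), sample_ids = tumor_ids)
  class(out) <- "gene_condition_design"
  out
}
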