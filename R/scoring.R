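#' Raw regulatory score of one miRNA-mRNA pair
#'
#' Aggregates binding affinity and binding probability over the K
#' high-confidence sites of the pair: mean over sites of |MFE_k| * P_ijk.
#'
#' @param mfe Numeric vector of site minimum free energies (kcal/mol, <= 0).
#' @param p_null Numeric vector of the sites' null binding probabilities.
#' @return Non-negative scalar raw score.
#' @export
mirna_raw_rs <- function(mfe, p_null) {
  if (length(mfe) == 0L) stop("no binding sites for this pair")
  if (length(mfe) != length(p_null)) stop("mfe and p_null lengths differ")
  mean(abs(mfe) * p_null)
}

#' Normalize one regulator's raw scores across its targets
#'
#' Divides each raw score by the regulator's total raw score, so that a
#' regulator's scores form a competition share over its targets and sum to 1.
#'
#' @param raw Named (by gene) numeric vector of raw scores, all >= 0.
#' @return Numeric vector of the same length summing to 1.
#' @export
normalize_rs <- function(raw) {
  if (length(raw) == 0L) stop("regulator has no targets")
  if (any(raw < 0)) stop("raw scores must be non-negative")
  tot <- sum(raw)
  if (tot <= 0) stop("regulator has no usable evidence (all raw scores zero)")
  raw / tot
}

#' TF binding-site score from TSS distance
#'
#' Regulatory potential decays exponentially with the distance d (bp) between
#' the binding site and the transcription start site:
#' exp(-(1/2 + 4 d / 1e5)), in (0, exp(-0.5)\].
#'
#' @param tss_distance Non-negative distance(s) in bp.
#' @return Site score(s).
#' @export
tf_site_rs <- function(tss_distance) {
  if (any(tss_distance < 0)) stop("tss_distance must be non-negative")
  exp(-(0.5 + 4 * tss_distance / 1e5))
}

#' Aggregate site scores of one TF-gene pair
#'
#' Probability-of-at-least-one-site aggregation: 1 - prod(1 - s_k), computed
#' in log space for stability.  Non-decreasing in the number of sites.
#'
#' @param site_scores Numeric vector of per-site scores in (0, 1).
#' @return Raw TF-gene score in (0, 1).
#' @export
tf_gene_rs <- function(site_scores) {
  if (length(site_scores) == 0L) stop("no binding sites for this pair")
  if (any(site_scores < 0 | site_scores >= 1))
    stop("site scores must be in [0, 1)")
  -expm1(sum(log1p(-site_scores)))
}

#' Score all miRNA-mRNA and TF-gene interactions
#'
#' Computes raw regulatory scores per pair (miRNA: Eq. of mean |MFE| x
#' binding probability over the pair's high-confidence sites; TF:
#' complement-product of TSS-distance decays) and normalizes each regulator's
#' scores to a competition share over its targets.
#'
#' @param scored_sites Site table from [score_sites()], already filtered to
#'   high-confidence sites (passed == TRUE rows are used).
#' @param tf_sites data.frame with columns tf_id, gene_id, site_id,
#'   tss_distance.
#' @return data.frame of class `interaction_scores` with columns
#'   regulator_id, kind ("miRNA"/"TF"), gene_id, raw_rs, norm_rs.
#' @export
score_regulators <- function(scored_sites, tf_sites = NULL) {
  out <- list()
  if (!is.null(scored_sites) && nrow(scored_sites) > 0L) {
    use <- if ("passed" %in% colnames(scored_sites))
      scored_sites[scored_sites$passed, , drop = FALSE] else scored_sites
    if (nrow(use) > 0L) {
      key <- paste(use$mirna_id, use$mrna_id, sep = "\r")
      sp <- split(seq_len(nrow(use)), key)
      raw <- vapply(sp, function(idx)
        mirna_raw_rs(use$mfe[idx], use$p_null[idx]), numeric(1L))
      ids <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
      mi <- data.frame(regulator_id = ids[, 1L], kind = "miRNA",
                       gene_id = ids[, 2L], raw_rs = as.numeric(raw),
                       stringsAsFactors = FALSE)
      out$mi <- mi
    }
  }
  if (!is.null(tf_sites) && nrow(tf_sites) > 0L) {
    if (any(tf_sites$tss_distance < 0))
      stop("tss_distance must be non-negative")
    key <- paste(tf_sites$tf_id, tf_sites$gene_id, sep = "\r")
    sp <- split(seq_len(nrow(tf_sites)), key)
    raw <- vapply(sp, function(idx)
      tf_gene_rs(tf_site_rs(tf_sites$tss_distance[idx])), numeric(1L))
    ids <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    tf <- data.frame(regulator_id = ids[, 1L], kind = "TF",
                     gene_id = ids[, 2L], raw_rs = as.numeric(raw),
                     stringsAsFactors = FALSE)
    out$tf <- tf
  }
  if (length(out) == 0L)
    return(structure(data.frame(regulator_id = character(),
                                kind = character(), gene_id = character(),
                                raw_rs = numeric(), norm_rs = numeric()),
                     class = c("interaction_scores", "data.frame")))
  scores <- do.call(rbind, out)
  scores$norm_rs <- NA_real_
  for (reg in unique(scores$regulator_id)) {
    idx <- which(scores$regulator_id == reg)
    scores$norm_rs[idx] <- normalize_rs(scores$raw_rs[idx])
  }
  scores <- scores[order(scores$kind, scores$regulator_id, scores$gene_id), ,
                   drop = FALSE]
  rownames(scores) <- NULL
  class(scores) <- c("interaction_scores", "data.frame")
  scores
}

#' Assemble the regulatory-score row of one gene
#'
#' Builds the dense 1 x (r1 + r2) score row aligned to the canonical
#' regulator ordering: TFs first, then miRNAs, lexicographic within kind.
#'
#' @param gene_id Gene identifier.
#' @param scores `interaction_scores` table restricted to this gene's
#'   candidate regulators.
#' @return Named numeric vector of normalized scores in canonical order.
#' @export
build_rs_row <- function(gene_id, scores) {
  sc <- scores[scores$gene_id == gene_id, , drop = FALSE]
  if (nrow(sc) == 0L)
    stop("gene '", gene_id, "' has no candidate regulators")
  if (anyDuplicated(sc$regulator_id))
    stop("duplicated regulator for gene '", gene_id, "'")
  if (anyNA(sc$norm_rs))
    stop("candidate regulator without a score for gene '", gene_id, "'")
  ord <- order(sc$kind != "TF", sc$regulator_id)  # TFs first, then miRNAs
  row <- sc$norm_rs[ord]
  names(row) <- sc$regulator_id[ord]
  row
}
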