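#' Link each miRNA to the pathways its selected targets belong to
#'
#' @param mirna_targets Named list: miRNA id -> character vector of its
#'   selected target genes in one condition.
#' @param pathways Named list: pathway -> gene set (see [read_gmt()]).
#' @return Named list: miRNA id -> character vector of linked pathway names
#'   (empty when no target falls in any pathway).
#' @export
link_mirnas_to_pathways <- function(mirna_targets, pathways) {
  lapply(mirna_targets, function(tg) {
    hit <- vapply(pathways, function(genes) any(tg %in% genes), logical(1L))
    names(pathways)[hit]
  })
}

#' Enumerate candidate k-miRNA modules sharing a pathway
#'
#' Candidates are all k-subsets of the miRNAs linked to some common pathway,
#' unioned over pathways and deduplicated.  To guard against combinatorial
#' explosion, pathways linked to more than `cap` miRNAs contribute only their
#' first `cap` miRNAs (lexicographic), with a warning.
#'
#' @param mirna_pathways Named list from [link_mirnas_to_pathways()].
#' @param k Module size (>= 1).
#' @param cap Per-pathway miRNA-count cap (default 30).
#' @return list of sorted character vectors (the k-sets), in lexicographic
#'   order of their joined ids.
#' @export
enumerate_candidates <- function(mirna_pathways, k, cap = 30L) {
  stopifnot(k >= 1L)
  by_pathway <- list()
  for (mi in names(mirna_pathways)) {
    for (pw in mirna_pathways[[mi]])
      by_pathway[[pw]] <- c(by_pathway[[pw]], mi)
  }
  seen <- new.env(parent = emptyenv())
  for (pw in names(by_pathway)) {
    mirnas <- sort(unique(by_pathway[[pw]]))
    if (length(mirnas) > cap) {
      warning("pathway '", pw, "' linked to ", length(mirnas),
              " miRNAs; capped at ", cap)
      mirnas <- mirnas[seq_len(cap)]
    }
    if (length(mirnas) < k) next
    sets <- utils::combn(mirnas, k, simplify = FALSE)
    for (s in sets) assign(paste(s, collapse = "+"), s, envir = seen)
  }
  keys <- sort(ls(seen))
  lapply(keys, function(kk) get(kk, envir = seen))
}

#' Hypergeometric pathway over-representation p-value
#'
#' Upper-tail probability P(X >= r_w) that at least r_w of the module's n
#' target genes fall in pathway w, drawing without replacement from the N_D
#' miRNA-regulated genes of the condition, of which round(p_w * N_D) belong
#' to the pathway.
#'
#' @param r_w Observed overlap (targets of the module in pathway w).
#' @param n_d Population size N_D (miRNA-regulated genes in the condition).
#' @param p_w Fraction of genes associated with pathway w, in (0, 1\].
#' @param n Number of target genes of the module.
#' @return p-value.
#' @export
pathway_enrichment <- function(r_w, n_d, p_w, n) {
  stopifnot(n_d >= n, n >= r_w, r_w >= 0, p_w > 0, p_w <= 1)
  succ <- round(p_w * n_d)
  if (succ < r_w)
    stop("inconsistent inputs: round(p_w * N_D) = ", succ, " < r_w = ", r_w)
  stats::phyper(r_w - 1, m = succ, n = n_d - succ, k = n,
                lower.tail = FALSE)
}

#' Binomial involvement test of a module in one condition
#'
#' Tests whether the number of significantly enriched pathways of a k-miRNA
#' module under a condition (w_MD) exceeds what random size-k groups achieve:
#' p = P(X >= w_MD), X ~ Binomial(|W|, P_WD).
#'
#' @param w_md Number of enriched pathways of the candidate in the condition.
#' @param n_pathways Total number of pathways |W|.
#' @param p_wd Null per-pathway enrichment probability (see details of
#'   [find_modules()]).
#' @return p-value.
#' @export
involvement_test <- function(w_md, n_pathways, p_wd) {
  if (p_wd > 1) stop("P_WD > 1: upstream counting violated its contract")
  if (p_wd < 0) stop("P_WD must be non-negative")
  stats::pbinom(w_md - 1, size = n_pathways, prob = p_wd,
                lower.tail = FALSE)
}

#' Binomial recurrence test of a module across conditions
#'
#' p = P(X >= d_M), X ~ Binomial(|D|, P_k), where d_M is the number of
#' conditions in which the module is pathway-associated.
#'
#' @param d_m Number of supporting conditions.
#' @param n_conditions Total number of conditions |D|.
#' @param p_k Null probability that a size-k group is pathway-associated in
#'   one condition.
#' @return p-value.
#' @export
recurrence_test <- function(d_m, n_conditions, p_k) {
  if (p_k > 1) stop("P_k > 1: upstream counting violated its contract")
  if (p_k < 0) stop("P_k must be non-negative")
  stats::pbinom(d_m - 1, size = n_conditions, prob = p_k,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' @param p Numeric vector of p-values.
#' @return Step-up q-values (monotone in the p ordering).
#' @export
fdr_control <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Discover k-miRNA regulatory modules from per-condition selections
#'
#' Implements the four-step module search: (i) per condition, link each
#' miRNA to the pathways of its selected targets and enumerate candidate
#' k-sets of miRNAs sharing a pathway; (ii) test hypergeometric enrichment of
#' each candidate's common pathways; (iii) binomial involvement test of the
#' enriched-pathway count w_MD against the null rate
#' P_WD = sum_w (enriched size-k groups)_wD / (|W| choose(K, k));
#' (iv) binomial recurrence test of the supporting-condition count d_M
#' against P_k = sum_D (pathway-associated size-k modules)_D /
#' (|D| choose(K, k)), with Benjamini-Hochberg control pooled over all
#' candidates of all k.  K is the number of miRNAs with at least one selected
#' target in at least one condition.
#'
#' @param selections data.frame with columns condition, gene_id,
#'   regulator_id, kind (only kind == "miRNA" rows are used).
#' @param pathways Named list (pathway -> genes), e.g. from [read_gmt()].
#' @param conditions Character vector of analysed conditions |D|; default
#'   the conditions present in `selections`.
#' @param k_min,k_max Module size range (defaults 1 and 5).
#' @param enrich_alpha Per-pathway enrichment cut used in the counting and in
#'   w_MD (default 0.05, unadjusted; FDR control happens at module level).
#' @param involvement_alpha Involvement significance per condition
#'   (default 0.05); a condition supports a module when its involvement
#'   p-value is below this.
#' @param q_threshold FDR level of the final report (default 0.05).
#' @param min_conditions Minimum supporting conditions to report (default 2).
#' @param cap Per-pathway miRNA cap for enumeration.
#' @return Object of class `module_report`: `candidates` (every tested
#'   candidate with k, d_M, p_recurrence, q, supporting conditions; q is NA
#'   for candidates supported in no condition, which never enter the FDR
#'   family), `modules` (the reported subset), `detail` (per reported module
#'   and supporting condition, enriched pathways with their target genes),
#'   and `params` (K, |W|, |D|, P_k per k).
#' @details The hypergeometric population of the enrichment test is the
#'   condition's N_D miRNA-regulated genes, and p_w is the fraction of those
#'   N_D genes belonging to pathway w, so round(p_w * N_D) is exactly the
#'   pathway's member count within the population and the test is
#'   self-consistent (overlaps can never exceed the success count).
#'   Benjamini-Hochberg control is applied to the recurrence p-values of the
#'   candidates that pass the involvement test in at least one condition;
#'   the tests are sequential, so candidates never supported anywhere are
#'   not part of the tested family.
#' @export
find_modules <- function(selections, pathways, conditions = NULL,
                         k_min = 1L, k_max = 5L,
                         enrich_alpha = 0.05, involvement_alpha = 0.05,
                         q_threshold = 0.05, min_conditions = 2L,
                         cap = 30L) {
  sel <- selections[selections$kind == "miRNA", , drop = FALSE]
  if (is.null(conditions)) conditions <- sort(unique(sel$condition))
  n_D <- length(conditions)
  W <- length(pathways)
  all_mirnas <- sort(unique(sel$regulator_id))
  K <- length(all_mirnas)
  empty <- data.frame(mirna_set = character(), k = integer(),
                      d_M = integer(), p_involvement_min = numeric(),
                      p_recurrence = numeric(), q = numeric(),
                      conditions = character(), stringsAsFactors = FALSE)
  out_params <- list(K = K, n_pathways = W, n_conditions = n_D,
                     enrich_alpha = enrich_alpha,
                     involvement_alpha = involvement_alpha)
  if (K == 0L || W == 0L || n_D == 0L) {
    res <- list(candidates = empty, modules = empty, detail = list(),
                params = out_params)
    class(res) <- "module_report"
    return(res)
  }

  # per-condition structures
  cond_data <- list()
  for (D in conditions) {
    sD <- sel[sel$condition == D, , drop = FALSE]
    tg <- split(sD$gene_id, sD$regulator_id)
    tg <- lapply(tg, unique)
    mp <- link_mirnas_to_pathways(tg, pathways)
    regulated <- unique(sD$gene_id)
    # pathway membership within the condition's regulated-gene population,
    # so the hypergeometric success count equals round(p_w * N_D) exactly
    m_w <- vapply(pathways, function(g)
      length(intersect(g, regulated)), numeric(1L))
    cond_data[[D]] <- list(targets = tg, mirna_pathways = mp,
                           N_D = length(regulated), m_w = m_w)
  }

  # evaluate every candidate in every condition where it is linkable
  cand <- new.env(parent = emptyenv())  # key -> list(set, k, per-cond rows)
  for (k in seq(k_min, k_max)) {
    for (D in conditions) {
      cd <- cond_data[[D]]
      sets <- enumerate_candidates(cd$mirna_pathways, k, cap = cap)
      for (s in sets) {
        key <- paste(s, collapse = "+")
        common <- Reduce(intersect, cd$mirna_pathways[s])
        if (length(common) == 0L) next
        targets <- unique(unlist(cd$targets[s], use.names = FALSE))
        n <- length(targets)
        enriched <- character(0)
        enr_detail <- list()
        for (pw in common) {
          overlap <- intersect(targets, pathways[[pw]])
          pe <- pathway_enrichment(length(overlap), cd$N_D,
                                   cd$m_w[[pw]] / cd$N_D, n)
          if (pe < enrich_alpha) {
            enriched <- c(enriched, pw)
            enr_detail[[pw]] <- list(p = pe, targets = sort(overlap))
          }
        }
        rec <- get0(key, envir = cand,
                    ifnotfound = list(set = s, k = k, conds = list()))
        rec$conds[[D]] <- list(w_MD = length(enriched),
                               enriched = enr_detail)
        assign(key, rec, envir = cand)
      }
    }
  }

  keys <- sort(ls(cand))
  if (length(keys) == 0L) {
    res <- list(candidates = empty, modules = empty, detail = list(),
                params = out_params)
    class(res) <- "module_report"
    return(res)
  }

  # Eq.-15 null rate per (condition, k): sum of enriched (group, pathway)
  # pairs over candidates of that size, scaled by |W| * choose(K, k)
  p_wd <- list()
  for (k in seq(k_min, k_max)) {
    p_wd[[as.character(k)]] <- stats::setNames(numeric(n_D), conditions)
    for (D in conditions) {
      tot <- 0
      for (key in keys) {
        rec <- get(key, envir = cand)
        if (rec$k == k && !is.null(rec$conds[[D]]))
          tot <- tot + rec$conds[[D]]$w_MD
      }
      p_wd[[as.character(k)]][D] <- min(1, tot / (W * choose(K, k)))
    }
  }

  # involvement test per candidate per condition; supported conditions
  supported_counts <- stats::setNames(
    lapply(seq(k_min, k_max), function(k)
      stats::setNames(numeric(n_D), conditions)),
    as.character(seq(k_min, k_max)))
  for (key in keys) {
    rec <- get(key, envir = cand)
    sup <- character(0)
    for (D in names(rec$conds)) {
      wmd <- rec$conds[[D]]$w_MD
      pin <- involvement_test(wmd, W, p_wd[[as.character(rec$k)]][D])
      rec$conds[[D]]$p_involvement <- pin
      if (wmd >= 1L && pin < involvement_alpha) {
        sup <- c(sup, D)
        kk <- as.character(rec$k)
        supported_counts[[kk]][D] <- supported_counts[[kk]][D] + 1
      }
    }
    rec$supported <- sort(sup)
    assign(key, rec, envir = cand)
  }

  # Eq.-17 null rate per k
  p_k <- vapply(as.character(seq(k_min, k_max)), function(kk) {
    k <- as.integer(kk)
    min(1, sum(supported_counts[[kk]]) / (n_D * choose(K, k)))
  }, numeric(1L))
  out_params$p_k <- p_k

  rows <- lapply(keys, function(key) {
    rec <- get(key, envir = cand)
    d_M <- length(rec$supported)
    prec <- recurrence_test(d_M, n_D, p_k[[as.character(rec$k)]])
    pinv <- vapply(rec$conds, function(cc) cc$p_involvement, numeric(1L))
    data.frame(mirna_set = key, k = rec$k, d_M = d_M,
               p_involvement_min = min(pinv),
               p_recurrence = prec,
               conditions = paste(rec$supported, collapse = ","),
               stringsAsFactors = FALSE)
  })
  candidates <- do.call(rbind, rows)
  # sequential testing: only involvement-passing candidates enter the FDR
  # family; the rest were never carried to the recurrence stage
  candidates$q <- NA_real_
  fam <- candidates$d_M >= 1L
  candidates$q[fam] <- fdr_control(candidates$p_recurrence[fam])
  candidates <- candidates[, c("mirna_set", "k", "d_M",
                               "p_involvement_min", "p_recurrence", "q",
                               "conditions")]

  modules <- candidates[candidates$q < q_threshold &
                          candidates$d_M >= min_conditions, , drop = FALSE]
  rownames(modules) <- NULL

  detail <- list()
  for (key in modules$mirna_set) {
    rec <- get(key, envir = cand)
    dd <- list()
    for (D in rec$supported) {
      enr <- rec$conds[[D]]$enriched
      if (length(enr) > 0L)
        dd[[D]] <- data.frame(
          pathway = names(enr),
          p_enrichment = vapply(enr, function(e) e$p, numeric(1L)),
          target_genes = vapply(enr, function(e)
            paste(e$targets, collapse = ","), character(1L)),
          row.names = NULL, stringsAsFactors = FALSE)
    }
    detail[[key]] <- dd
  }

  res <- list(candidates = candidates, modules = modules, detail = detail,
              params = out_params)
  class(res) <- "module_report"
  res
}

#' @export
print.module_report <- function(x, ...) {
  cat("miRNA regulatory module report\n")
  cat("  K =", x$params$K, "miRNAs, |W| =", x$params$n_pathways,
      "pathways, |D| =", x$params$n_conditions, "conditions\n")
  cat("  candidates tested:", nrow(x$candidates), "\n")
  cat("  modules reported: ", nrow(x$modules), "\n")
  if (nrow(x$modules) > 0L)
    print(x$modules[, c("mirna_set", "k", "d_M", "p_recurrence", "q")])
  invisible(x)
}

#' Filter a candidate table to the reported modules
#'
#' @param candidates Candidate data.frame (from [find_modules()]).
#' @param q_threshold FDR level (default 0.05).
#' @param min_conditions Minimum supporting conditions (default 2).
#' @return The reported subset.
#' @export
report_modules <- function(candidates, q_threshold = 0.05,
                           min_conditions = 2L) {
  out <- candidates[candidates$q < q_threshold &
                      candidates$d_M >= min_conditions, , drop = FALSE]
  rownames(out) <- NULL
  out
}
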