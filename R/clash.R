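#' Tally reads per miRNA, per mRNA, and globally
#'
#' For each miRNA the total count Sum_i is its chimeric reads across all its
#' sites plus its unbound single reads; likewise Sum_j for each mRNA.  C_all
#' is the grand total of chimeric reads over all binding sites.
#'
#' @param sites data.frame of binding-site evidence with columns mirna_id,
#'   mrna_id, site_id, chimeric_count, mfe (plus optional coordinates).
#' @param mirna_singles Named numeric vector (or 2-column data.frame
#'   mirna_id/count) of unbound miRNA single-read counts.
#' @param mrna_singles Named numeric vector (or 2-column data.frame
#'   mrna_id/count) of unbound mRNA single-read counts.
#' @return list of class `read_tally` with `sum_i` (named, per miRNA),
#'   `sum_j` (named, per mRNA) and `c_all`.
#' @export
tally_reads <- function(sites, mirna_singles, mrna_singles) {
  mirna_singles <- .as_named_counts(mirna_singles)
  mrna_singles <- .as_named_counts(mrna_singles)
  if (nrow(sites) == 0L) {
    out <- list(sum_i = numeric(), sum_j = numeric(), c_all = 0)
    class(out) <- "read_tally"
    return(out)
  }
  validate_sites(sites)
  unk_i <- setdiff(unique(sites$mirna_id), names(mirna_singles))
  if (length(unk_i) > 0L)
    stop("site references miRNA id(s) absent from single-read table: ",
         paste(unk_i, collapse = ", "))
  unk_j <- setdiff(unique(sites$mrna_id), names(mrna_singles))
  if (length(unk_j) > 0L)
    stop("site references mRNA id(s) absent from single-read table: ",
         paste(unk_j, collapse = ", "))
  chim_i <- tapply(sites$chimeric_count, sites$mirna_id, sum)
  chim_j <- tapply(sites$chimeric_count, sites$mrna_id, sum)
  sum_i <- mirna_singles[names(chim_i)] + as.numeric(chim_i)
  names(sum_i) <- names(chim_i)
  sum_j <- mrna_singles[names(chim_j)] + as.numeric(chim_j)
  names(sum_j) <- names(chim_j)
  out <- list(sum_i = sum_i, sum_j = sum_j,
              c_all = sum(sites$chimeric_count))
  class(out) <- "read_tally"
  out
}

.as_named_counts <- function(x) {
  if (is.data.frame(x)) {
    v <- x[[2L]]
    names(v) <- as.character(x[[1L]])
    x <- v
  }
  if (is.null(names(x)) && length(x) > 0L)
    stop("single-read counts must be named by id")
  if (any(x < 0)) stop("single-read counts must be non-negative")
  x
}

#' Validate a binding-site evidence table
#' @param sites data.frame; see [tally_reads()].
#' @return The table, invisibly, after checks.
#' @export
validate_sites <- function(sites) {
  need <- c("mirna_id", "mrna_id", "site_id", "chimeric_count", "mfe")
  miss <- setdiff(need, colnames(sites))
  if (length(miss) > 0L)
    stop("binding-site table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(sites$chimeric_count < 0))
    stop("chimeric_count must be non-negative")
  if (any(sites$mfe > 0))
    stop("mfe must be <= 0 (kcal/mol)")
  key <- paste(sites$mirna_id, sites$mrna_id, sites$site_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (mirna_id, mrna_id, site_id) in binding-site table")
  invisible(sites)
}

#' Null binding probability of a site
#'
#' Probability that miRNA i and mRNA j bind at site k by chance, estimated as
#' the product of the site's chimeric-read share of the miRNA's total reads
#' and of the mRNA's total reads: (C_ijk / Sum_i) * (C_ijk / Sum_j).
#'
#' @param c_ijk Chimeric read count at the site.
#' @param sum_i Total reads (chimeric + single) of the miRNA.
#' @param sum_j Total reads (chimeric + single) of the mRNA.
#' @return Probability in \[0, 1\] (vectorized).
#' @export
site_null_probability <- function(c_ijk, sum_i, sum_j) {
  if (any(sum_i <= 0) || any(sum_j <= 0))
    stop("sum_i and sum_j must be positive (malformed read tallies)")
  if (any(c_ijk < 0)) stop("chimeric count must be non-negative")
  if (any(c_ijk > pmin(sum_i, sum_j)))
    stop("chimeric count exceeds a total read count")
  (c_ijk / sum_i) * (c_ijk / sum_j)
}

#' Upper-tail binomial p-value for a site's chimeric count
#'
#' Under the null the site's chimeric count is Binomial(C_all, P_ijk); the
#' p-value is P(X >= C_ijk), evaluated with the survival function of the
#' binomial distribution (numerically stable for large C_all).
#'
#' @param c_ijk Observed chimeric count at the site.
#' @param c_all Total chimeric reads over all sites.
#' @param p_ijk Null binding probability (see [site_null_probability()]).
#' @return p-value in \[0, 1\] (vectorized).
#' @export
site_pvalue <- function(c_ijk, c_all, p_ijk) {
  if (any(c_ijk > c_all)) stop("c_ijk must not exceed c_all")
  if (any(c_ijk < 0)) stop("c_ijk must be non-negative")
  if (any(p_ijk < 0 | p_ijk > 1)) stop("p_ijk must be in [0, 1]")
  stats::pbinom(c_ijk - 1, size = c_all, prob = p_ijk, lower.tail = FALSE)
}

#' Score all binding sites and apply the Bonferroni confidence filter
#'
#' Computes the null probability and upper-tail binomial p-value for every
#' site, Bonferroni-adjusts over the whole family of tested sites, and flags
#' sites whose adjusted p-value is below `alpha` as high-confidence.
#'
#' @param sites Binding-site evidence table (see [tally_reads()]).
#' @param mirna_singles,mrna_singles Single-read counts (named vectors or
#'   2-column data.frames).
#' @param alpha Significance level for the Bonferroni-adjusted p-value.
#' @return The site table with added columns p_null, p_value, adjusted_p and
#'   passed, ordered by (mirna_id, mrna_id, site_id).
#' @export
score_sites <- function(sites, mirna_singles, mrna_singles, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  tal <- tally_reads(sites, mirna_singles, mrna_singles)
  if (nrow(sites) == 0L) {
    sites$p_null <- sites$p_value <- sites$adjusted_p <- numeric(0)
    sites$passed <- logical(0)
    return(sites)
  }
  si <- tal$sum_i[sites$mirna_id]
  sj <- tal$sum_j[sites$mrna_id]
  sites$p_null <- site_null_probability(sites$chimeric_count, si, sj)
  sites$p_value <- site_pvalue(sites$chimeric_count, tal$c_all, sites$p_null)
  n_sites <- nrow(sites)
  sites$adjusted_p <- pmin(1, sites$p_value * n_sites)
  sites$passed <- sites$p_value * n_sites < alpha
  ord <- order(sites$mirna_id, sites$mrna_id, sites$site_id)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Filter site tests to the high-confidence subset
#'
#' Keeps exactly the sites whose raw p-value times the family size is below
#' `alpha` (Bonferroni).  The result is invariant to input order.
#'
#' @param tests data.frame with a p_value column (one row per tested site).
#' @param alpha Family-wise significance level.
#' @return list with `kept` (the retained rows, in canonical site order),
#'   `n_total`, `n_kept` and `fraction_kept`.
#' @export
filter_sites <- function(tests, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  n <- nrow(tests)
  if (n < 1L) stop("no tested sites")
  keep <- tests$p_value * n < alpha
  kept <- tests[keep, , drop = FALSE]
  if (all(c("mirna_id", "mrna_id", "site_id") %in% colnames(kept))) {
    kept <- kept[order(kept$mirna_id, kept$mrna_id, kept$site_id), ,
                 drop = FALSE]
  }
  rownames(kept) <- NULL
  list(kept = kept, n_total = n, n_kept = nrow(kept),
       fraction_kept = nrow(kept) / n)
}

#' Collapse high-confidence sites to unique miRNA-mRNA interactions
#'
#' @param sites Site table (typically the `kept` element of [filter_sites()]).
#' @return data.frame with one row per (mirna_id, mrna_id) pair, with the
#'   site count and best (smallest) adjusted p-value, in lexicographic order.
#' @export
collapse_interactions <- function(sites) {
  if (nrow(sites) == 0L)
    return(data.frame(mirna_id = character(), mrna_id = character(),
                      n_sites = integer(), min_adjusted_p = numeric()))
  key <- paste(sites$mirna_id, sites$mrna_id, sep = "\r")
  sp <- split(seq_len(nrow(sites)), key)
  rows <- lapply(sp, function(idx) {
    data.frame(mirna_id = sites$mirna_id[idx[1L]],
               mrna_id = sites$mrna_id[idx[1L]],
               n_sites = length(idx),
               min_adjusted_p = if ("adjusted_p" %in% colnames(sites))
                 min(sites$adjusted_p[idx]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
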