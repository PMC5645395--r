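#' Jaccard similarity of two selected-regulator sets
#'
#' |A intersect B| / |A union B|; two empty sets are defined as identical
#' (similarity 1), which is logged as a message.
#'
#' @param a,b Character vectors (sets).
#' @return Similarity in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) {
    message("jaccard: both sets empty; similarity defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(u)
}

#' Selection-stability curve versus sample size
#'
#' For each sample size in `sizes`, draws `repetitions` random subsets of the
#' condition's samples, reruns the full regulator-selection procedure on each
#' subset, and averages the Jaccard similarity between the regulator set at
#' size n and the paired repetition at the previous size in the grid.  At
#' sizes below folds^rounds the hierarchical subsets are infeasible and the
#' selection falls back to a single pooled lasso (zeta fixed at 1) at the
#' same w penalty.
#'
#' @param design A `gene_condition_design` holding the condition's full data.
#' @param sizes Strictly increasing sample sizes (at least two values, each
#'   <= n).
#' @param repetitions Subsamples per size (default 100).
#' @param seed Integer seed.
#' @param w,lambda Scalar penalties in scaled units (multiples of the data
#'   scale; see [meta_lasso()]), so the same values stay meaningful as the
#'   subsample size shrinks.
#' @param folds,rounds Hierarchical sampling parameters.
#' @return data.frame of class `stability_curve`: gene_id, n, mean_J, sd_J,
#'   repetitions, seed (one row per size after the first).
#' @export
stability_curve <- function(design, sizes, repetitions = 100L, seed = 1L,
                            w = 0.2, lambda = 0.2, folds = 5L,
                            rounds = 2L) {
  n_total <- length(design$sample_ids)
  if (any(sizes > n_total))
    stop("requested size exceeds the condition's sample count (", n_total,
         ")")
  sizes <- sort(unique(as.integer(sizes)))
  empty <- data.frame(gene_id = character(), n = integer(),
                      mean_J = numeric(), sd_J = numeric(),
                      repetitions = integer(), seed = integer())
  if (length(sizes) < 2L) {
    warning("stability curve needs at least two sizes; returning empty")
    class(empty) <- c("stability_curve", "data.frame")
    return(empty)
  }
  stopifnot(repetitions >= 1L)
  Y <- as.numeric(design$Y)
  select_at <- function(idx, sub_seed) {
    yi <- Y[idx]
    x1 <- design$X1[idx, , drop = FALSE]
    x2 <- design$X2[idx, , drop = FALSE]
    if (length(idx) >= folds^rounds) {
      ml <- meta_lasso(yi, X2 = x2, X1 = x1, w = w, lambda = lambda,
                       folds = folds, rounds = rounds, seed = sub_seed)
      ml$selection$regulator_id
    } else {
      res <- fwl_residualize(yi, x1, x2)
      sdy <- stats::sd(res$Y - mean(res$Y))
      if (!is.finite(sdy) || sdy <= 0) sdy <- 1
      f <- fit_meta_lasso(list(list(y = res$Y, x = res$X2)),
                          w = w * sdy * sqrt(length(res$Y)),
                          lambda = 0, zeta_fixed = TRUE)
      select_regulators(f)$regulator_id
    }
  }
  sel <- with_seed(seed, {
    lapply(seq_along(sizes), function(si) {
      lapply(seq_len(repetitions), function(r) {
        idx <- sort(sample.int(n_total, sizes[si]))
        select_at(idx, sub_seed = sample.int(2^31 - 1L, 1L))
      })
    })
  })
  rows <- lapply(2:length(sizes), function(si) {
    js <- vapply(seq_len(repetitions), function(r)
      suppressMessages(jaccard(sel[[si]][[r]], sel[[si - 1L]][[r]])),
      numeric(1L))
    data.frame(gene_id = design$gene_id, n = sizes[si], mean_J = mean(js),
               sd_J = stats::sd(js), repetitions = repetitions,
               seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stability_curve", "data.frame")
  out
}
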