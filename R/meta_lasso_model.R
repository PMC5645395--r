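#' Fit a background-adjusted meta-Lasso to one gene in one condition
#'
#' The classic fitting entry point.  Given a gene's expression-change
#' response, its background covariates (copy-number and methylation change)
#' and its candidate-regulator effect matrix, the function (i) draws the
#' hierarchical fold-complement subsets of the condition's samples,
#' (ii) Frisch-Waugh-Lovell-residualizes the background out of each subset,
#' (iii) fits the meta-Lasso across the subsets at a penalty pair chosen by
#' aggregate BIC over the supplied grids (or fixed if scalars are given),
#' and (iv) reports the selected regulators (nonzero overall effects).
#'
#' @param x A `gene_condition_design` (see [build_design()]) or the response
#'   vector Y.
#' @param ... Further arguments to methods.
#' @return An object of class `meta_lasso` with components `fit`
#'   (the winning `meta_lasso_fit`), `selection`, `tuning`, `subsets`,
#'   `gene_id`, `condition`, `call`.
#' @seealso [fit_meta_lasso()], [select_tuning()], [select_regulators()]
#' @export
meta_lasso <- function(x, ...) UseMethod("meta_lasso")

#' @rdname meta_lasso
#' @param X2 Regulator-effect matrix (n x P) when `x` is the response vector.
#' @param X1 Background matrix (n x q) or NULL for intercept-only adjustment.
#' @param w,lambda Penalty grids (scalars fix the penalty; vectors are tuned
#'   by aggregate BIC).  With `penalty_units = "scaled"` (the default) they
#'   are dimensionless multiples of the data scale: w of sd(y) x sqrt(N
#'   pooled rows), lambda of sd(y) x sqrt(mean subset size); this keeps the
#'   same grid meaningful across sample sizes and noise levels.
#' @param penalty_units "scaled" (default) or "absolute".
#' @param folds,rounds Hierarchical sampling parameters (default 5, 2:
#'   25 subsets of ~64\% of samples).
#' @param seed Integer seed for the subset draw.
#' @param gene_id,condition Optional labels.
#' @export
meta_lasso.default <- function(x, X2, X1 = NULL,
                               w = c(0.1, 0.2, 0.4),
                               lambda = c(0.1, 0.2, 0.4),
                               penalty_units = c("scaled", "absolute"),
                               folds = 5L, rounds = 2L, seed = 1L,
                               gene_id = NULL, condition = NULL, ...) {
  penalty_units <- match.arg(penalty_units)
  Y <- as.numeric(x)
  X2 <- as.matrix(X2)
  n <- length(Y)
  part <- hierarchical_subsets(n, folds = folds, rounds = rounds,
                               seed = seed)
  datasets <- lapply(part$subsets, function(idx) {
    x1 <- if (is.null(X1)) matrix(nrow = length(idx), ncol = 0)
    else as.matrix(X1)[idx, , drop = FALSE]
    res <- fwl_residualize(Y[idx], x1, X2[idx, , drop = FALSE])
    list(y = res$Y, x = res$X2)
  })
  ys <- unlist(lapply(datasets, function(d) d$y - mean(d$y)))
  nm <- vapply(datasets, function(d) length(d$y), integer(1L))
  sdy <- stats::sd(ys)
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1
  penalty_scale <- c(w = sdy * sqrt(sum(nm)), lambda = sdy * sqrt(mean(nm)))
  if (penalty_units == "scaled") {
    w <- w * penalty_scale[["w"]]
    lambda <- lambda * penalty_scale[["lambda"]]
  }
  if (length(w) == 1L && length(lambda) == 1L) {
    fit <- fit_meta_lasso(datasets, w = w, lambda = lambda, ...)
    tuning <- list(w = w, lambda = lambda, bic = NULL)
  } else {
    tuning <- select_tuning(datasets, w_grid = w, lambda_grid = lambda, ...)
    fit <- tuning$fit
  }
  sel <- select_regulators(fit, gene_id = gene_id, condition = condition)
  out <- list(fit = fit, selection = sel,
              tuning = list(w = tuning$w, lambda = tuning$lambda,
                            bic = tuning$bic),
              penalty_scale = penalty_scale,
              subsets = part, gene_id = gene_id, condition = condition,
              call = match.call())
  class(out) <- "meta_lasso"
  out
}

#' @rdname meta_lasso
#' @export
meta_lasso.gene_condition_design <- function(x, ...) {
  obj <- meta_lasso.default(as.numeric(x$Y), X2 = x$X2, X1 = x$X1,
                            gene_id = x$gene_id, condition = x$condition,
                            ...)
  obj$call <- match.call()
  obj
}

#' @export
print.meta_lasso <- function(x, ...) {
  cat("Meta-Lasso regulator selection\n")
  if (!is.null(x$gene_id)) cat("  gene:     ", x$gene_id, "\n")
  if (!is.null(x$condition)) cat("  condition:", x$condition, "\n")
  cat("  subsets:  ", length(x$subsets$subsets), " (", x$subsets$folds,
      "-fold x ", x$subsets$rounds, " rounds, n = ", x$subsets$n, ")\n",
      sep = "")
  cat("  penalties: w =", x$tuning$w, ", lambda =", x$tuning$lambda, "\n")
  cat("  selected: ", nrow(x$selection), " regulator(s)",
      if (nrow(x$selection) > 0)
        paste0(": ", paste(x$selection$regulator_id, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.meta_lasso <- function(object, ...) {
  f <- object$fit
  out <- list(selection = object$selection,
              w = f$w, lambda = f$lambda,
              iterations = f$iterations, converged = f$converged,
              objective = utils::tail(f$objective, 1L),
              n_subsets = length(f$n),
              rss = f$rss, gene_id = object$gene_id,
              condition = object$condition)
  class(out) <- "summary.meta_lasso"
  out
}

#' @export
print.summary.meta_lasso <- function(x, ...) {
  cat("Meta-Lasso fit over", x$n_subsets, "subsets (w =", x$w,
      ", lambda =", x$lambda, ")\n")
  cat("converged:", x$converged, "after", x$iterations,
      "iterations; final objective", format(x$objective), "\n")
  cat("mean subset RSS:", format(mean(x$rss)), "\n\n")
  if (nrow(x$selection) == 0L) cat("No regulators selected.\n")
  else print(x$selection)
  invisible(x)
}

#' @export
coef.meta_lasso <- function(object, type = c("overall", "dataset"), ...) {
  type <- match.arg(type)
  if (type == "overall") object$fit$g else object$fit$beta
}

#' Predict gene expression change from regulator effects
#'
#' Uses the overall effects g on the standardized-predictor scale averaged
#' over the per-dataset coefficients: predictions are X2 \%*\% colMeans(beta)
#' plus the mean intercept, i.e. the consensus model across subsets.
#'
#' @param object A `meta_lasso` fit.
#' @param newdata Matrix of regulator effects (columns as in the fit).
#' @param ... Unused.
#' @return Numeric vector of predicted (background-unadjusted) changes.
#' @export
predict.meta_lasso <- function(object, newdata, ...) {
  b <- colMeans(object$fit$beta)
  as.numeric(as.matrix(newdata)[, names(b), drop = FALSE] %*% b +
               mean(object$fit$beta0))
}

#' @export
residuals.meta_lasso <- function(object, ...) {
  # per-subset RSS is the honest residual summary; pooled residuals would
  # double-count the overlapping samples
  object$fit$rss
}

#' Plot the overall regulator effects of a meta-Lasso fit
#' @param x A `meta_lasso` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.meta_lasso <- function(x, ...) {
  g <- x$fit$g
  graphics::barplot(g, las = 2, ylab = "overall effect g",
                    main = paste("Meta-Lasso effects",
                                 if (!is.null(x$gene_id)) x$gene_id else ""),
                    ...)
  invisible(x)
}
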