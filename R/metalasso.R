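#' Run an expression with a fixed, restored RNG state
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Frisch-Waugh-Lovell residualization of the background
#'
#' Projects the response and the regulator-effect matrix onto the orthogonal
#' complement of the background design: Y~ = M Y and X2~ = M X2 with
#' M = I - X1 (X1' X1)^- X1'.  The projection uses a rank-revealing QR
#' decomposition, so rank-deficient backgrounds are handled via the
#' pseudoinverse.  An intercept column is appended to X1 unless already
#' present.
#'
#' @param Y Numeric response vector or n x 1 matrix.
#' @param X1 Background matrix (n x q), without intercept.
#' @param X2 Regulator-effect matrix (n x P).
#' @param add_intercept Append an intercept column to X1 (default TRUE).
#' @return list with `Y` (residualized vector) and `X2` (residualized
#'   matrix).
#' @export
fwl_residualize <- function(Y, X1, X2, add_intercept = TRUE) {
  Y <- as.numeric(Y)
  n <- length(Y)
  X1 <- as.matrix(X1)
  if (add_intercept) X1 <- cbind(`(Intercept)` = 1, X1)
  if (n <= ncol(X1))
    stop("cannot residualize: n (", n, ") <= background columns (",
         ncol(X1), ")")
  if (nrow(X1) != n || nrow(as.matrix(X2)) != n)
    stop("Y, X1, X2 row counts differ")
  qx <- qr(X1)  # pivoted, rank-revealing
  Yt <- qr.resid(qx, Y)
  X2t <- qr.resid(qx, as.matrix(X2))
  list(Y = Yt, X2 = X2t)
}

#' Hierarchical two-round fold-complement subsets
#'
#' Performs `rounds` nested rounds of `folds`-fold random splitting; the
#' retained subsets are the complements of the innermost folds.  With the
#' defaults (5 folds, 2 rounds) a condition with n samples yields 25 subsets
#' each holding about 64\% (80\% x 80\%) of the samples.
#'
#' @param n Number of samples; must be at least folds^rounds.
#' @param folds Folds per round (default 5).
#' @param rounds Nesting depth (default 2).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return list of class `subset_partition`: `subsets` (list of sorted
#'   integer index vectors, deterministic order), `n`, `folds`, `rounds`,
#'   `seed`.
#' @export
hierarchical_subsets <- function(n, folds = 5L, rounds = 2L, seed = 1L) {
  if (n < folds^rounds)
    stop("n (", n, ") must be at least folds^rounds (", folds^rounds, ")")
  subsets <- with_seed(seed, {
    split_level <- function(idx, depth) {
      perm <- sample(idx)
      fid <- rep_len(seq_len(folds), length(idx))
      comps <- lapply(seq_len(folds), function(f) sort(perm[fid != f]))
      if (depth == 1L) return(comps)
      unlist(lapply(comps, split_level, depth = depth - 1L),
             recursive = FALSE)
    }
    split_level(seq_len(n), rounds)
  })
  out <- list(subsets = subsets, n = n, folds = folds, rounds = rounds,
              seed = seed)
  class(out) <- "subset_partition"
  out
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Fit the meta-Lasso over M related datasets
#'
#' Maximizes the penalized Gaussian working log-likelihood
#' sum_m l_m(beta_m0, g, zeta_m) - w sum_p |g_p| - lambda sum_mp |zeta_mp|
#' where the coefficient of regulator p in dataset m decomposes
#' multiplicatively as beta_mp = g_p * zeta_mp: g_p is the overall effect of
#' regulator p and zeta_mp its dataset-specific effect, both L1-penalized.
#' The solver is alternating block coordinate descent with soft-thresholding:
#' given zeta, g is updated by a pooled lasso over the stacked datasets;
#' given g, each zeta_m by a per-dataset lasso; a penalty-optimal rebalancing
#' of each (g_p, zeta_.p) pair resolves the multiplicative scale
#' indeterminacy without ever decreasing the objective.  At convergence the
#' nonzero zeta_.p of each selected regulator are normalized to
#' root-mean-square 1 (g_p absorbs the scale), which fixes the reported
#' decomposition.
#'
#' @param datasets list of M lists, each with `y` (numeric vector) and `x`
#'   (matrix with identical column names/order across datasets).
#' @param w L1 penalty on the overall effects g.
#' @param lambda L1 penalty on the dataset effects zeta.
#' @param zeta_fixed If TRUE, zeta is held at 1 (the fit reduces to a single
#'   pooled lasso in g).
#' @param standardize Center y and center/scale x columns within each dataset
#'   before fitting; per-dataset coefficients and intercepts are reported on
#'   the original scale (g and zeta stay on the standardized scale, where
#'   selection operates).
#' @param max_iter Maximum outer iterations (default 1000).
#' @param tol Convergence tolerance on the maximum parameter change
#'   (default 1e-6).
#' @return Object of class `meta_lasso_fit`: g (named), zeta (M x P), beta
#'   (M x P per-dataset coefficients, original scale), beta0 (length-M
#'   intercepts), rss (per dataset), objective (trace over iterations),
#'   iterations, converged, w, lambda, n (per dataset), regulator_ids.
#' @export
fit_meta_lasso <- function(datasets, w, lambda, zeta_fixed = FALSE,
                           standardize = TRUE, max_iter = 1000L,
                           tol = 1e-6) {
  M <- length(datasets)
  if (M < 1L) stop("need at least one dataset")
  regs <- colnames(datasets[[1L]]$x)
  P <- ncol(datasets[[1L]]$x)
  for (d in datasets) {
    if (!all(is.finite(d$y)) || !all(is.finite(d$x)))
      stop("non-finite values in a dataset")
    if (ncol(d$x) != P || !identical(colnames(d$x), regs))
      stop("all datasets must share the regulator ordering")
    if (length(d$y) != nrow(d$x)) stop("y / x size mismatch in a dataset")
  }
  if (is.null(regs)) regs <- paste0("p", seq_len(P))
  nm <- vapply(datasets, function(d) length(d$y), integer(1L))
  grp <- rep(seq_len(M), nm)
  N <- sum(nm)

  ybar <- numeric(M); xbar <- matrix(0, M, P); xsd <- matrix(1, M, P)
  Xs <- matrix(0, N, P); ys <- numeric(N)
  for (m in seq_len(M)) {
    rows <- which(grp == m)
    x <- as.matrix(datasets[[m]]$x); y <- datasets[[m]]$y
    if (standardize) {
      ybar[m] <- mean(y)
      xbar[m, ] <- colMeans(x)
      x <- sweep(x, 2L, xbar[m, ])
      s <- sqrt(colSums(x^2) / length(y))
      s[s <= 0] <- 1
      xsd[m, ] <- s
      x <- sweep(x, 2L, s, "/")
      y <- y - ybar[m]
    }
    Xs[rows, ] <- x
    ys[rows] <- y
  }

  g <- numeric(P)
  zeta <- matrix(1, M, P)
  if (zeta_fixed && missing(lambda)) lambda <- 0
  r <- ys  # residual at beta = 0
  ss_mp <- rowsum(Xs^2, grp)  # M x P column sums of squares per dataset

  penalty <- function(g, zeta)
    w * sum(abs(g)) + lambda * sum(abs(zeta))
  obj_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    g_old <- g; zeta_old <- zeta
    # --- g block: pooled lasso on columns Xs[,p] * zeta[grp, p]
    for (p in seq_len(P)) {
      if (!zeta_fixed && g[p] == 0 && all(zeta[, p] == 0)) {
        # re-entry trial: reactivate (g_p, zeta_.p = 1) only when the joint
        # move improves the penalized objective (keeps descent monotone)
        col <- Xs[, p]
        denom <- sum(col * col)
        if (denom <= 0) next
        gnew <- soft_threshold(sum(col * r), w) / denom
        if (gnew != 0) {
          rnew <- r - gnew * col
          dobj <- -0.5 * (sum(rnew^2) - sum(r^2)) -
            w * abs(gnew) - lambda * M
          if (dobj > 1e-12) {
            zeta[, p] <- 1
            g[p] <- gnew
            r <- rnew
          }
        }
        next
      }
      col <- Xs[, p] * zeta[grp, p]
      denom <- sum(col * col)
      if (denom <= 0) {
        if (g[p] != 0) { r <- r + g[p] * col; g[p] <- 0 }
        next
      }
      rho <- sum(col * r) + denom * g[p]
      gnew <- soft_threshold(rho, w) / denom
      if (gnew != g[p]) {
        r <- r - (gnew - g[p]) * col
        g[p] <- gnew
      }
    }
    # --- rebalance multiplicative scale (never increases the objective)
    if (!zeta_fixed && w > 0 && lambda > 0) {
      for (p in seq_len(P)) {
        az <- sum(abs(zeta[, p]))
        if (g[p] != 0 && az > 0) {
          s <- sqrt(lambda * az / (w * abs(g[p])))
          s <- min(max(s, 1e-3), 1e3)
          g[p] <- g[p] * s
          zeta[, p] <- zeta[, p] / s
        }
      }
    }
    # --- zeta block: per-dataset lasso on columns Xs[,p] * g_p
    if (!zeta_fixed) {
      for (p in seq_len(P)) {
        if (g[p] == 0) {
          # likelihood is flat in zeta_.p; the penalty is minimized at 0
          zeta[, p] <- 0
          next
        }
        colg <- Xs[, p] * g[p]
        denom_m <- ss_mp[, p] * g[p]^2
        rho_m <- as.numeric(rowsum(colg * r, grp)) + denom_m * zeta[, p]
        znew <- ifelse(denom_m > 0,
                       soft_threshold(rho_m, lambda) / pmax(denom_m, 1e-300),
                       0)
        dz <- znew - zeta[, p]
        if (any(dz != 0)) {
          r <- r - dz[grp] * colg
          zeta[, p] <- znew
        }
      }
    }
    obj_trace <- c(obj_trace, -0.5 * sum(r^2) - penalty(g, zeta))
    delta <- max(abs(g - g_old), abs(zeta - zeta_old))
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("meta-Lasso did not converge in ", max_iter,
            " iterations (last change ", signif(max(abs(g - g_old)), 3),
            "); returning best iterate")

  # reporting normalization: RMS of nonzero zeta_.p set to 1
  if (!zeta_fixed) {
    for (p in seq_len(P)) {
      nz <- zeta[, p] != 0
      if (g[p] != 0 && any(nz)) {
        s <- sqrt(mean(zeta[nz, p]^2))
        zeta[, p] <- zeta[, p] / s
        g[p] <- g[p] * s
      }
    }
  }

  beta_std <- sweep(zeta, 2L, g, "*")     # standardized scale
  beta <- beta_std / xsd                  # original scale
  beta0 <- if (standardize)
    ybar - rowSums(beta * xbar) else numeric(M)
  rss <- as.numeric(rowsum(r^2, grp))
  names(g) <- regs
  colnames(zeta) <- colnames(beta) <- regs
  out <- list(g = g, zeta = zeta, beta = beta, beta0 = beta0, rss = rss,
              n = nm, objective = obj_trace, iterations = it,
              converged = converged, w = w, lambda = lambda,
              regulator_ids = regs, zeta_fixed = zeta_fixed)
  class(out) <- "meta_lasso_fit"
  out
}

#' Choose the (w, lambda) penalty pair by aggregate BIC
#'
#' Fits the meta-Lasso at every grid point and minimizes
#' sum_m n_m log(RSS_m / n_m) + log(sum n_m) * df, where df counts the
#' nonzero per-dataset coefficients g_p * zeta_mp.  Ties are broken toward
#' the larger (w, lambda) (the sparser model).
#'
#' @param datasets As in [fit_meta_lasso()].
#' @param w_grid,lambda_grid Non-empty penalty grids.
#' @param ... Passed to [fit_meta_lasso()].
#' @return list with `w`, `lambda`, `bic` (full grid data.frame) and `fit`
#'   (the winning fit).
#' @export
select_tuning <- function(datasets, w_grid, lambda_grid, ...) {
  stopifnot(length(w_grid) >= 1L, length(lambda_grid) >= 1L)
  grid <- expand.grid(w = sort(w_grid), lambda = sort(lambda_grid))
  fits <- vector("list", nrow(grid))
  bic <- numeric(nrow(grid))
  ntot <- sum(vapply(datasets, function(d) length(d$y), integer(1L)))
  for (i in seq_len(nrow(grid))) {
    f <- fit_meta_lasso(datasets, w = grid$w[i], lambda = grid$lambda[i],
                        ...)
    df <- sum(f$beta != 0)
    bic[i] <- sum(f$n * log(pmax(f$rss, 1e-12) / f$n)) + log(ntot) * df
    fits[[i]] <- f
  }
  best <- which(bic <= min(bic) + 1e-12)
  # among ties prefer the largest w, then the largest lambda
  best <- best[order(grid$w[best], grid$lambda[best],
                     decreasing = TRUE)][1L]
  list(w = grid$w[best], lambda = grid$lambda[best],
       bic = cbind(grid, bic = bic), fit = fits[[best]])
}

#' Extract the selected regulators of a fit
#'
#' A regulator is selected when its overall effect g_p is nonzero in the
#' final model; the reported sign is that of g_p times the median of its
#' dataset effects over the subsets where the regulator is active (zero
#' entries only say a subset dropped it, not that its direction is zero).
#'
#' @param fit A `meta_lasso_fit`.
#' @param gene_id,condition Optional labels copied into the result.
#' @return data.frame with regulator_id, g_effect, sign, n_subsets_nonzero
#'   (and gene_id / condition when given), of class `regulator_selection`.
#' @export
select_regulators <- function(fit, gene_id = NULL, condition = NULL) {
  sel <- which(abs(fit$g) > 1e-8)
  med_z <- if (length(sel) > 0L)
    apply(fit$zeta[, sel, drop = FALSE], 2L, function(z)
      stats::median(z[z != 0])) else numeric(0)
  out <- data.frame(
    regulator_id = fit$regulator_ids[sel],
    g_effect = unname(fit$g[sel]),
    sign = sign(unname(fit$g[sel]) * med_z),
    n_subsets_nonzero = if (length(sel) > 0L)
      colSums(fit$zeta[, sel, drop = FALSE] != 0) else integer(0),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(gene_id))
    out <- cbind(gene_id = rep(gene_id, nrow(out)), out)
  if (!is.null(condition))
    out <- cbind(condition = rep(condition, nrow(out)), out)
  class(out) <- c("regulator_selection", "data.frame")
  out
}

#' Cancer-level and pan-cancer consistency of per-condition selections
#'
#' A regulator enters a cancer's specific set when it is selected for the
#' gene in at least ceil(stage_fraction x analysed stages) of that cancer's
#' conditions; it enters the common (pan-cancer) set when it is in the
#' cancer-specific set of at least ceil(cancer_fraction x analysed cancers)
#' cancers.
#'
#' @param selections data.frame with columns gene_id, regulator_id,
#'   cancer_type, stage (one row per selected regulator per condition).
#' @param analysed data.frame of analysed conditions with columns
#'   cancer_type, stage (e.g. from [list_conditions()]).
#' @param stage_fraction,cancer_fraction Voting fractions (default 0.5).
#' @return list with `cancer_specific` (gene_id, regulator_id, cancer_type,
#'   n_stages_selected, n_stages) and `common` (gene_id, regulator_id,
#'   n_cancers, n_cancers_total).
#' @export
hierarchical_consistency <- function(selections, analysed,
                                     stage_fraction = 0.5,
                                     cancer_fraction = 0.5) {
  n_stages <- table(analysed$cancer_type)
  empty_cs <- data.frame(gene_id = character(), regulator_id = character(),
                         cancer_type = character(),
                         n_stages_selected = integer(), n_stages = integer())
  if (nrow(selections) == 0L)
    return(list(cancer_specific = empty_cs,
                common = data.frame(gene_id = character(),
                                    regulator_id = character(),
                                    n_cancers = integer(),
                                    n_cancers_total = integer())))
  key <- paste(selections$gene_id, selections$regulator_id,
               selections$cancer_type, sep = "\r")
  cnt <- tapply(selections$stage, key,
                function(s) length(unique(s)))
  parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  cs <- data.frame(gene_id = parts[, 1L], regulator_id = parts[, 2L],
                   cancer_type = parts[, 3L],
                   n_stages_selected = as.integer(cnt),
                   stringsAsFactors = FALSE)
  cs$n_stages <- as.integer(n_stages[cs$cancer_type])
  cs <- cs[cs$n_stages_selected >= ceiling(stage_fraction * cs$n_stages), ,
           drop = FALSE]
  cs <- cs[order(cs$gene_id, cs$regulator_id, cs$cancer_type), ,
           drop = FALSE]
  rownames(cs) <- NULL

  n_cancers <- length(unique(analysed$cancer_type))
  if (nrow(cs) > 0L) {
    key2 <- paste(cs$gene_id, cs$regulator_id, sep = "\r")
    cnt2 <- table(key2)
    parts2 <- do.call(rbind, strsplit(names(cnt2), "\r", fixed = TRUE))
    common <- data.frame(gene_id = parts2[, 1L],
                         regulator_id = parts2[, 2L],
                         n_cancers = as.integer(cnt2),
                         n_cancers_total = n_cancers,
                         stringsAsFactors = FALSE)
    common <- common[common$n_cancers >=
                       ceiling(cancer_fraction * n_cancers), , drop = FALSE]
    common <- common[order(common$gene_id, common$regulator_id), ,
                     drop = FALSE]
    rownames(common) <- NULL
  } else {
    common <- data.frame(gene_id = character(), regulator_id = character(),
                         n_cancers = integer(), n_cancers_total = integer())
  }
  list(cancer_specific = cs, common = common)
}
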