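#' Read a features-by-samples expression table
#'
#' Parses a TSV whose header row holds sample identifiers and whose first
#' column holds feature (gene or miRNA) identifiers.  Values must be finite,
#' non-negative reals; identifiers must be unique in both dimensions.
#'
#' @param path Path to a TSV file.
#' @param nonnegative Require all values to be non-negative (set to `FALSE`
#'   for signed tables such as copy-number ratios).
#' @return A numeric matrix (features x samples) with feature ids as rownames
#'   and sample ids as colnames, of class `expression_table`.
#' @export
read_expression <- function(path, nonnegative = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("format error: expression table '", path,
         "' is empty or has no sample columns")
  feats <- as.character(raw[[1L]])
  dup <- feats[duplicated(feats)]
  if (length(dup) > 0L)
    stop("format error: duplicated feature id(s): ",
         paste(unique(dup), collapse = ", "))
  samp <- colnames(raw)[-1L]
  dups <- samp[duplicated(samp)]
  if (length(dups) > 0L)
    stop("format error: duplicated sample id(s): ",
         paste(unique(dups), collapse = ", "))
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0L)
      stop("format error: non-numeric cell at row ", bad[1L],
           ", column '", samp[j], "'")
    if (anyNA(v))
      stop("format error: missing value at row ", which(is.na(v))[1L],
           ", column '", samp[j], "'")
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- feats
  colnames(m) <- samp
  if (any(!is.finite(m)))
    stop("format error: non-finite expression value in '", path, "'")
  if (nonnegative && any(m < 0))
    stop("format error: negative expression value in '", path, "'")
  class(m) <- c("expression_table", class(m))
  m
}

#' Write a features-by-samples table as TSV
#'
#' @param x Numeric matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param header Optional character vector of commented (`#`) header lines.
#' @export
write_expression <- function(x, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0L) writeLines(paste0("# ", header), con)
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, scientific = FALSE,
                                   trim = TRUE)), collapse = "\t")
  }, character(1L))
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sheet assigns samples to a cancer type, a tumor stage (I-IV) and a
#' tumor/normal status.  Every tumor sample must carry a stage and every
#' cancer type must have at least one normal sample (its control group).
#' Normal samples shared between cancers are listed once per cancer.
#'
#' @param path Path to a TSV with columns sample_id, cancer_type, stage,
#'   status.
#' @return A data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_sheet(ss)
}

#' Validate a sample-sheet data.frame
#' @param ss data.frame with columns sample_id, cancer_type, stage, status.
#' @return The validated data.frame, classed `sample_sheet`.
#' @export
validate_sample_sheet <- function(ss) {
  need <- c("sample_id", "cancer_type", "stage", "status")
  miss <- setdiff(need, colnames(ss))
  if (length(miss) > 0L)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  ss$stage <- as.character(ss$stage)
  ss$status <- as.character(ss$status)
  if (!all(ss$status %in% c("tumor", "normal")))
    stop("sample sheet status must be 'tumor' or 'normal'")
  tum <- ss$status == "tumor"
  if (any(tum & (is.na(ss$stage) | ss$stage == "")))
    stop("every tumor sample must have a stage")
  if (!all(ss$stage[tum] %in% c("I", "II", "III", "IV")))
    stop("tumor stage must be one of I, II, III, IV")
  dup <- duplicated(ss[, c("sample_id", "cancer_type")])
  if (any(dup))
    stop("duplicated (sample_id, cancer_type) row(s) in sample sheet")
  for (cc in unique(ss$cancer_type)) {
    if (!any(ss$cancer_type == cc & ss$status == "normal"))
      stop("cancer type '", cc, "' has no normal samples")
  }
  class(ss) <- c("sample_sheet", "data.frame")
  ss
}

#' Enumerate the (cancer, stage) condition grid of a sample sheet
#'
#' A condition is one (cancer type, stage) stratum of tumor samples; its
#' control group is that cancer's normal samples.
#'
#' @param ss A sample sheet (see [read_sample_sheet()]).
#' @param require_tumor If TRUE (default) only conditions with at least one
#'   tumor sample are returned; if FALSE the full cancer x stage grid.
#' @return data.frame with columns cancer_type, stage, condition,
#'   n_tumor, n_normal.
#' @export
list_conditions <- function(ss, require_tumor = TRUE) {
  cancers <- sort(unique(ss$cancer_type))
  stages <- c("I", "II", "III", "IV")
  grid <- expand.grid(stage = stages, cancer_type = cancers,
                      stringsAsFactors = FALSE)[, c(2L, 1L)]
  grid$condition <- paste(grid$cancer_type, grid$stage, sep = ":")
  grid$n_tumor <- mapply(function(cc, st)
    sum(ss$cancer_type == cc & ss$stage == st & ss$status == "tumor"),
    grid$cancer_type, grid$stage)
  grid$n_normal <- vapply(grid$cancer_type, function(cc)
    sum(ss$cancer_type == cc & ss$status == "normal"), integer(1L),
    USE.NAMES = FALSE)
  if (require_tumor) grid <- grid[grid$n_tumor > 0L, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Read a GMT pathway collection
#'
#' Standard GMT: one pathway per line -- name, description, then
#' tab-separated member genes.  Duplicate members within a line are
#' deduplicated (set semantics).
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (pathway -> gene set), of class
#'   `pathway_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    out <- structure(list(), names = character())
    class(out) <- "pathway_collection"
    return(out)
  }
  out <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("format error: GMT line ", i, " has fewer than 3 fields")
    nm[i] <- f[1L]
    out[[i]] <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
  }
  names(out) <- nm
  class(out) <- "pathway_collection"
  out
}

#' Write a pathway collection as GMT
#' @param pw Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(pw, path) {
  lines <- vapply(seq_along(pw), function(i)
    paste(c(names(pw)[i], "synthetic", pw[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a generic TSV with a commented header block
#' @param path Path to a TSV.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data.frame as TSV with a commented provenance header
#'
#' All tabular outputs carry a `#` header block recording the tool version,
#' the run seed and a digest of the configuration, so a result file can be
#' traced back to the run that produced it.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param seed Integer seed recorded in the header (NULL to omit).
#' @param config_digest Config digest string recorded in the header.
#' @export
write_tsv <- function(df, path, seed = NULL, config_digest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("mirmeta"))
  writeLines(paste0("# mirmeta ", ver), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(config_digest))
    writeLines(paste0("# config: ", config_digest), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' FNV-1a hash of a character representation (config digest)
#'
#' Small 32-bit FNV-1a hash used to stamp output files with a digest of the
#' run configuration.
#'
#' @param x Any R object; deparsed before hashing.
#' @return Hex string.
#' @export
fnv1a <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  codes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in codes) {
    # xor on the low 24 bits (code points < 2^24), keep the high byte
    h <- (h %/% 16777216) * 16777216 + bitwXor(h %% 16777216, b)
    # 32-bit multiply by the FNV prime, split to stay within double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default run configuration
#'
#' Collects every tunable of the pipeline with its default.  Thresholds:
#' site alpha is the Bonferroni-adjusted significance level for binding
#' sites; DE fold-change/alpha define differential expression; the
#' expression floor is the minimum median tumor expression for an
#' interaction to be applicable; module q-value is the FDR level of the
#' module report.
#'
#' @param seed Integer random seed recorded in every output header.
#' @param ... Overrides for any default field.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    site_alpha = 0.05,
    de_fold_change = 2,
    de_alpha = 0.05,
    pseudocount = 0.5,
    expression_floor = 0,      # median tumor expression must exceed this
    enrich_alpha = 0.05,       # per-pathway enrichment cut inside Eq.-15 counting
    involvement_alpha = 0.05,
    module_q = 0.05,
    k_min = 1L,
    k_max = 5L,
    pathway_mirna_cap = 30L,
    folds = 5L,
    rounds = 2L,
    w_grid = c(0.1, 0.2, 0.4),     # scaled penalty units, see meta_lasso()
    lambda_grid = c(0.1, 0.2, 0.4),
    stage_fraction = 0.5,      # consistency vote across stages
    cancer_fraction = 0.5,     # consistency vote across cancers
    stability_reps = 20L,
    stability_genes = 2L,
    candidate_cap = Inf,
    rs_normalization = "global",  # or "condition"
    paths = list()
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$site_alpha > 0, cfg$site_alpha < 1,
            cfg$de_alpha > 0, cfg$de_alpha < 1,
            cfg$module_q > 0, cfg$module_q < 1,
            cfg$k_min >= 1L, cfg$k_max >= cfg$k_min)
  if (cfg$k_max > 5L)
    warning("k_max > 5: module enumeration may be very large")
  cfg$digest <- fnv1a(cfg[setdiff(names(cfg), "digest")])
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#' @param path Path to a .yaml/.yml or .json file of config overrides.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  ov <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json")
  do.call(run_config, ov)
}
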