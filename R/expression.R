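#' Construct an expression matrix with sample metadata
#'
#' @param values Numeric genes x samples matrix (normalized, log scale)
#'   with gene ids as rownames and sample ids as colnames.
#' @param metadata Data frame keyed by column `sample`; typically carries
#'   `group`, `sex`, `age`, `batch`, `region`.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, metadata) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            is.data.frame(metadata), "sample" %in% names(metadata))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(metadata$sample)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  only_matrix <- setdiff(colnames(values), metadata$sample)
  only_meta <- setdiff(metadata$sample, colnames(values))
  if (length(only_matrix) || length(only_meta)) {
    stop("samples present in only one input",
         if (length(only_matrix)) paste0("; matrix only: ",
                                         paste(only_matrix, collapse = ", ")),
         if (length(only_meta)) paste0("; metadata only: ",
                                       paste(only_meta, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  metadata <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples; metadata: %s\n",
              nrow(x$values), ncol(x$values),
              paste(setdiff(names(x$metadata), "sample"), collapse = ", ")))
  invisible(x)
}

#' Load an expression matrix and its sample metadata from TSV
#'
#' @param matrix_path TSV with gene ids in the first column and sample ids
#'   in the header.
#' @param metadata_path TSV keyed by a `sample` column.
#' @return An `ExpressionMatrix`.
#' @export
load_expression <- function(matrix_path, metadata_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character")
  genes <- raw[[1]]
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals),
                                     dimnames = list(NULL, colnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s'",
                 genes[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  rownames(num) <- genes
  metadata <- utils::read.delim(metadata_path, check.names = FALSE)
  expression_matrix(num, metadata)
}

#' Write an expression matrix (and metadata) to TSV
#' @param x An `ExpressionMatrix`.
#' @param matrix_path,metadata_path Output TSV paths (`NULL` skips).
#' @return Invisibly, the matrix path.
#' @export
write_expression <- function(x, matrix_path, metadata_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Residualize expression on covariates
#'
#' Removes covariate effects (e.g. sex, age) gene-by-gene by ordinary
#' least squares, keeping each gene's grand mean, so downstream
#' discretization operates on covariate-corrected values.
#'
#' @param expr An `ExpressionMatrix`.
#' @param covariates Character vector of metadata column names.
#' @return An `ExpressionMatrix` with corrected values.
#' @export
residualize_expression <- function(expr, covariates) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  covariates <- intersect(covariates, names(expr$metadata))
  if (!length(covariates)) return(expr)
  mm <- stats::model.matrix(
    stats::reformulate(covariates), data = expr$metadata)
  fit <- stats::lm.fit(mm, t(expr$values))
  resid <- t(fit$residuals) + rowMeans(expr$values)
  dimnames(resid) <- dimnames(expr$values)
  expression_matrix(resid, expr$metadata)
}

#' Per-gene covariate-adjusted differential expression
#'
#' Ordinary least squares per gene: expression on a two-level group
#' indicator plus covariates. Reports the group coefficient (log
#' fold-change for log-scale input), its standard error, the two-sided t
#' p-value, and Benjamini-Hochberg q-values across all tested genes.
#' Genes with (numerically) zero residual variance are flagged and
#' assigned p = 1.
#'
#' @param expr An `ExpressionMatrix`.
#' @param group Metadata column holding the two group labels.
#' @param covariates Character vector of metadata columns to adjust for
#'   (skipped, with a message, when constant).
#' @param reference Reference group level; the coefficient is
#'   non-reference minus reference. Defaults to the first level.
#' @return Data frame: `gene`, `lfc`, `se`, `p`, `q`, `flag`.
#' @export
differential_expression <- function(expr, group = "group",
                                    covariates = character(0),
                                    reference = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  md <- expr$metadata
  if (!group %in% names(md)) stop("group column '", group,
                                  "' not in metadata", call. = FALSE)
  g <- factor(md[[group]])
  if (nlevels(g) != 2L) stop("differential_expression requires exactly two groups",
                             call. = FALSE)
  if (min(table(g)) < 2L) stop("need at least 2 samples per group", call. = FALSE)
  if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
  keep <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(md)) stop("covariate '", cv, "' not in metadata",
                                 call. = FALSE)
    if (length(unique(md[[cv]])) > 1L) keep <- c(keep, cv) else
      message("covariate '", cv, "' is constant; dropped")
  }
  df <- data.frame(.g = g, md[, keep, drop = FALSE])
  mm <- stats::model.matrix(stats::reformulate(c(".g", keep)), data = df)
  if (qr(mm)$rank < ncol(mm)) {
    stop("design is collinear (group confounded with covariates)", call. = FALSE)
  }
  fit <- stats::lm.fit(mm, t(expr$values))
  coefs <- t(fit$coefficients)
  res <- t(fit$residuals)
  dfree <- ncol(expr$values) - fit$rank
  sigma2 <- rowSums(res^2) / dfree
  xtx_inv <- chol2inv(chol(crossprod(mm)))
  gcol <- grep("^\\.g", colnames(mm))[1]
  lfc <- coefs[, gcol]
  se <- sqrt(sigma2 * xtx_inv[gcol, gcol])
  flag <- sigma2 < 1e-12
  tstat <- ifelse(flag, 0, lfc / se)
  p <- ifelse(flag, 1, 2 * stats::pt(-abs(tstat), df = dfree))
  out <- data.frame(gene = rownames(expr$values), lfc = lfc, se = se,
                    p = p, q = bh_adjust(p), flag = flag, row.names = NULL)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order (`stats::p.adjust`, method `"BH"`).
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
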