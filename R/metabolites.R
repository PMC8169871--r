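#' Construct / load a long-format metabolite concentration table
#'
#' One record per subject x region x metabolite with left-censoring (LOD)
#' annotation and subject-level pathology covariates. Expected columns:
#' `subject`, `cohort`, `region`, `metabolite`, `concentration`,
#' `below_lod` (logical), `lod`, `missing` (logical), `group` (e.g.
#' AD/ASY/CN), `sex`, `age`, and optionally `cerad`, `braak`.
#'
#' @param x Data frame with the columns above.
#' @return A `MetaboliteTable` (data frame subclass).
#' @export
metabolite_table <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("subject", "cohort", "region", "metabolite", "concentration",
                "below_lod", "lod", "missing", "group", "sex", "age")
  absent <- setdiff(required, names(x))
  if (length(absent)) stop("metabolite table lacks columns: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  key <- paste(x$subject, x$region, x$metabolite, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate subject x region x metabolite records", call. = FALSE)
  }
  present <- !x$missing & !x$below_lod
  if (any(present & (is.na(x$concentration) | x$concentration <= 0))) {
    stop("present concentrations must be positive", call. = FALSE)
  }
  class(x) <- c("MetaboliteTable", "data.frame")
  x
}

#' @rdname metabolite_table
#' @param path TSV file with the `MetaboliteTable` columns.
#' @export
load_metabolites <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE)
  for (cl in c("below_lod", "missing")) x[[cl]] <- as.logical(x[[cl]])
  metabolite_table(x)
}

#' Write a metabolite table to TSV
#' @param x A `MetaboliteTable`.
#' @param path Output path.
#' @export
write_metabolites <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Exclude metabolites with excessive missingness
#'
#' A value is counted missing when no concentration was obtained (either
#' below the detection limit or absent for other reasons). The fraction is
#' computed per metabolite within each cohort x region stratum; a
#' metabolite exceeding `max_missing_fraction` in any stratum is excluded
#' from all analyses. Metabolites at exactly the threshold are retained.
#'
#' @param table A `MetaboliteTable`.
#' @param max_missing_fraction Exclusion threshold (default 0.30).
#' @return The filtered table, with an `exclusions` attribute (data frame:
#'   metabolite, cohort, region, missing_fraction for dropped strata).
#' @export
qc_filter <- function(table, max_missing_fraction = 0.30) {
  stopifnot(inherits(table, "MetaboliteTable"), nrow(table) > 0)
  absent <- table$missing | table$below_lod
  strata <- paste(table$metabolite, table$cohort, table$region, sep = "\r")
  frac <- tapply(absent, strata, mean)
  info <- do.call(rbind, strsplit(names(frac), "\r", fixed = TRUE))
  excl <- data.frame(metabolite = info[, 1], cohort = info[, 2],
                     region = info[, 3], missing_fraction = as.numeric(frac),
                     row.names = NULL)
  excl <- excl[excl$missing_fraction > max_missing_fraction, , drop = FALSE]
  dropped <- unique(excl$metabolite)
  out <- table[!table$metabolite %in% dropped, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "exclusions") <- excl
  out
}

#' Impute left-censored concentrations at LOD/2
#'
#' Values flagged below the limit of detection are not missing at random;
#' each is filled with its metabolite-specific LOD threshold divided by 2.
#' Other records are untouched.
#'
#' @param table A `MetaboliteTable`.
#' @return The table with below-LOD concentrations filled.
#' @export
impute_lod <- function(table) {
  stopifnot(inherits(table, "MetaboliteTable"))
  idx <- which(table$below_lod & !table$missing)
  if (length(idx)) {
    bad <- idx[is.na(table$lod[idx]) | table$lod[idx] <= 0]
    if (length(bad)) {
      stop("below-LOD records without a positive LOD threshold (e.g. ",
           table$metabolite[bad[1]], ", subject ", table$subject[bad[1]], ")",
           call. = FALSE)
    }
    table$concentration[idx] <- table$lod[idx] / 2
  }
  table
}

metab_predictor_score <- function(table, predictor,
                                  group_scores = c(CN = 0, ASY = 1, AD = 2)) {
  if (predictor == "group") {
    lv <- unique(as.character(table$group))
    unknown <- setdiff(lv, names(group_scores))
    if (length(unknown)) stop("group levels without a score: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    unname(group_scores[as.character(table$group)])
  } else {
    if (!predictor %in% names(table)) stop("predictor column '", predictor,
                                           "' not in table", call. = FALSE)
    as.numeric(table[[predictor]])
  }
}

#' Repeated-measures metabolite association models
#'
#' For each metabolite, fits a linear model of log2 concentration over
#' both brain regions jointly, with region-specific intercepts and
#' region-interacted predictor, sex and age terms (plus a cohort indicator
#' when `include_cohort`). Standard errors are Huber-White cluster-robust,
#' clustered on subject, which leaves the within-subject covariance
#' unstructured. Disease status enters as a single ordered score
#' (CN = 0, ASY = 1, AD = 2), so a negative coefficient means lower
#' concentration with increasing disease severity; pathology models
#' substitute the continuous CERAD or Braak score for disease status.
#'
#' @param table A `MetaboliteTable`, already filtered ([qc_filter()]) and
#'   imputed ([impute_lod()]).
#' @param predictor `"group"`, `"cerad"` or `"braak"`.
#' @param include_cohort Add a cohort fixed effect (used for pooled fits).
#' @param group_scores Named scores for the disease-status coding.
#' @return Data frame: `metabolite`, `region`, `predictor`, `beta`,
#'   `se`, `p`, `n_subjects`, `scope`.
#' @export
fit_metabolite_models <- function(table,
                                  predictor = c("group", "cerad", "braak"),
                                  include_cohort = FALSE,
                                  group_scores = c(CN = 0, ASY = 1, AD = 2)) {
  stopifnot(inherits(table, "MetaboliteTable"))
  predictor <- match.arg(predictor)
  tab <- table[!table$missing & !is.na(table$concentration), , drop = FALSE]
  if (any(tab$concentration <= 0)) {
    stop("non-positive concentrations; log2 undefined (run impute_lod first?)",
         call. = FALSE)
  }
  tab$y <- log2(tab$concentration)
  tab$score <- metab_predictor_score(tab, predictor, group_scores)
  if (length(unique(tab$score)) < 2L) {
    stop("predictor '", predictor, "' has a single level; cannot fit",
         call. = FALSE)
  }
  scope <- if (include_cohort) "pooled" else
    paste(unique(as.character(tab$cohort)), collapse = "+")
  out <- list()
  for (met in sort(unique(tab$metabolite))) {
    d <- tab[tab$metabolite == met, , drop = FALSE]
    if (length(unique(d$score)) < 2L) next
    d$region <- factor(d$region)
    d$sexn <- as.numeric(factor(d$sex))
    rhs <- "0 + region + region:score + region:sexn + region:age"
    if (include_cohort && length(unique(d$cohort)) > 1L) {
      rhs <- paste(rhs, "+ cohort")
    }
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
    vc <- sandwich::vcovCL(fit, cluster = d$subject, type = "HC1")
    ct <- lmtest::coeftest(fit, vcov. = vc)
    for (reg in levels(d$region)) {
      cf <- paste0("region", reg, ":score")
      if (!cf %in% rownames(ct) || is.na(ct[cf, 1])) next
      out[[length(out) + 1L]] <- data.frame(
        metabolite = met, region = reg, predictor = predictor,
        beta = unname(ct[cf, 1]), se = unname(ct[cf, 2]),
        p = unname(ct[cf, 4]),
        n_subjects = length(unique(d$subject[d$region == reg])),
        scope = scope, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||% data.frame()
}

#' Pool convergent cross-cohort associations
#'
#' Compares the per-cohort coefficient signs for every metabolite x
#' region x predictor. Convergent associations (same direction; an exact
#' zero counts as concordant with either sign) are refitted on the
#' combined cohorts with a cohort fixed effect and reported as primary
#' pooled results (raw p). Divergent associations, and metabolites seen in
#' only one cohort, remain cohort-specific secondary results intended for
#' [cluster_fdr()].
#'
#' @param results_a,results_b Per-cohort outputs of
#'   [fit_metabolite_models()] on the same predictor.
#' @param table The combined two-cohort `MetaboliteTable` (filtered and
#'   imputed) used for the pooled refits.
#' @param predictor Predictor the results refer to.
#' @param group_scores Disease-status coding for refits.
#' @return List with data frames `pooled` and `cohort_specific`.
#' @export
convergence_pool <- function(results_a, results_b, table,
                             predictor = c("group", "cerad", "braak"),
                             group_scores = c(CN = 0, ASY = 1, AD = 2)) {
  predictor <- match.arg(predictor)
  key <- function(x) paste(x$metabolite, x$region, sep = "\r")
  ka <- key(results_a)
  kb <- key(results_b)
  common <- intersect(ka, kb)
  concordant <- character(0)
  for (k in common) {
    ba <- results_a$beta[ka == k]
    bb <- results_b$beta[kb == k]
    if (sign(ba) == sign(bb) || ba == 0 || bb == 0) {
      concordant <- c(concordant, k)
    }
  }
  pooled_fit <- fit_metabolite_models(table, predictor = predictor,
                                      include_cohort = TRUE,
                                      group_scores = group_scores)
  kp <- key(pooled_fit)
  pooled <- pooled_fit[kp %in% concordant, , drop = FALSE]
  rownames(pooled) <- NULL
  spec_a <- results_a[!(ka %in% concordant), , drop = FALSE]
  spec_b <- results_b[!(kb %in% concordant), , drop = FALSE]
  cohort_specific <- rbind(spec_a, spec_b)
  cohort_specific$only_one_cohort <-
    !(key(cohort_specific) %in% common)
  rownames(cohort_specific) <- NULL
  list(pooled = pooled, cohort_specific = cohort_specific)
}

#' Pathway-cluster false-discovery-rate adjustment
#'
#' Benjamini-Hochberg adjustment of cohort-specific results within each a
#' priori biochemical pathway cluster (e.g. biosynthesis, enzymatic
#' catabolism, non-enzymatic catabolism), separately per region x
#' predictor x scope family, with significance flagged at adjusted
#' p < `alpha`.
#'
#' @param results Data frame of model results (needs `metabolite`,
#'   `region`, `predictor`, `scope`, `p`).
#' @param cluster_map Data frame with columns `metabolite`, `cluster`
#'   assigning every metabolite to exactly one cluster.
#' @param alpha Significance level on the adjusted scale.
#' @return `results` with added `cluster`, `q`, `significant` columns.
#' @export
cluster_fdr <- function(results, cluster_map, alpha = 0.05) {
  stopifnot(is.data.frame(results), is.data.frame(cluster_map),
            all(c("metabolite", "cluster") %in% names(cluster_map)))
  if (anyDuplicated(cluster_map$metabolite)) {
    stop("cluster map assigns a metabolite to more than one cluster",
         call. = FALSE)
  }
  if (!nrow(results)) {
    results$cluster <- character(0)
    results$q <- numeric(0)
    results$significant <- logical(0)
    return(results)
  }
  idx <- match(results$metabolite, cluster_map$metabolite)
  if (anyNA(idx)) {
    stop("metabolites without a cluster assignment: ",
         paste(unique(results$metabolite[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  results$cluster <- cluster_map$cluster[idx]
  fam <- interaction(results$cluster, results$region, results$predictor,
                     results$scope, drop = TRUE)
  results$q <- stats::ave(results$p, fam,
                          FUN = function(p) bh_adjust(p))
  results$significant <- results$q < alpha
  results
}
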