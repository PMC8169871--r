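#' 2x2 contingency counts of reaction activity by group
#'
#' @param activity An `ActivityMatrix` or binary reactions x samples matrix.
#' @param labels Named vector mapping sample id to one of exactly two
#'   group labels, or a factor/character vector aligned with the matrix
#'   columns and named by them.
#' @param reaction Reaction id.
#' @param group_order Optional length-2 character vector fixing which
#'   level is group 1 (e.g. `c("AD", "CN")`).
#' @return Named integer vector `c(a, b, c, d)`: group-1 active, group-1
#'   inactive, group-2 active, group-2 inactive.
#' @export
activity_contingency <- function(activity, labels, reaction,
                                 group_order = NULL) {
  act <- if (inherits(activity, "ActivityMatrix")) activity$activity else activity
  stopifnot(reaction %in% rownames(act))
  labels <- resolve_labels(act, labels, group_order)
  x <- act[reaction, names(labels)]
  a <- sum(x == 1L & labels == levels(labels)[1])
  b <- sum(x == 0L & labels == levels(labels)[1])
  cc <- sum(x == 1L & labels == levels(labels)[2])
  d <- sum(x == 0L & labels == levels(labels)[2])
  c(a = a, b = b, c = cc, d = d)
}

resolve_labels <- function(act, labels, group_order = NULL) {
  if (is.null(names(labels))) {
    stop("'labels' must be named by sample id", call. = FALSE)
  }
  unlabeled <- setdiff(colnames(act), names(labels))
  if (length(unlabeled)) {
    stop("unlabeled samples: ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  }
  labels <- labels[colnames(act)]
  labels <- if (is.null(group_order)) factor(labels) else
    factor(labels, levels = group_order)
  if (anyNA(labels)) stop("sample labels outside the declared groups",
                          call. = FALSE)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("exactly two groups required, found: ",
         paste(levels(droplevels(labels)), collapse = ", "), call. = FALSE)
  }
  labels
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every table no more probable than the observed one (probability-mass
#' rule, with the customary `1 + 1e-7` tie tolerance). `rule = "doubling"`
#' instead doubles the smaller one-sided tail (capped at 1).
#'
#' @param a,b,c,d Nonnegative integer counts (group 1 active/inactive,
#'   group 2 active/inactive).
#' @param rule Two-sided rule: `"probability"` (default) or `"doubling"`.
#' @return p-value in `[0, 1]`; degenerate margins give p = 1.
#' @export
fisher_p <- function(a, b, c, d, rule = c("probability", "doubling")) {
  rule <- match.arg(rule)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  m <- a + c   # total active
  n <- b + d   # total inactive
  k <- a + b   # group-1 size
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  if (rule == "probability") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  min(1, p)
}

#' Cross-product odds ratio with zero-cell conventions
#'
#' Sample odds ratio `(a d) / (b c)` for a 2x2 activity table. When the
#' numerator is zero (and the denominator positive) the ratio is reported
#' as 0; a zero denominator with positive numerator gives `Inf`; when both
#' products are zero no ratio is defined and `NA` is returned. These are
#' the conventions used to render network-comparison tables (a literal
#' `0.000` / `Inf` / `NA`).
#'
#' @inheritParams fisher_p
#' @return Numeric odds ratio, `Inf`, or `NA`.
#' @export
odds_ratio_convention <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  num <- a * d
  den <- b * c
  if (num == 0 && den == 0) return(NA_real_)
  if (den == 0) return(Inf)
  num / den
}

#' Render an odds ratio using the table conventions
#' @param or Numeric odds ratio (possibly `Inf`/`NA`).
#' @return Character: `"0.000"`, `"Inf"`, `"NA"` or the ratio to 3 decimals.
#' @export
format_odds_ratio <- function(or) {
  vapply(or, function(x) {
    if (is.na(x)) "NA" else if (is.infinite(x)) "Inf" else sprintf("%.3f", x)
  }, character(1))
}

#' Compare reaction activity between two groups
#'
#' One Fisher exact test per reaction on the active/inactive counts of the
#' two groups, with cross-product odds ratios under the zero-cell
#' conventions. Significance is flagged at raw p < `alpha` (the
#' network-level convention); a BH-adjusted column is also emitted for
#' transparency.
#'
#' @inheritParams activity_contingency
#' @param reactions Optional reaction-id subset to compare (e.g. the
#'   reactions controlled by an a priori gene list).
#' @param alpha Raw significance threshold (default 0.05).
#' @param rule Two-sided rule passed to [fisher_p()].
#' @param model Optional `MetabolicModel` used to annotate subsystems.
#' @return Data frame (one row per reaction, ordered by reaction id):
#'   `reaction`, `subsystem`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `odds_ratio_label`, `p`, `q`, `significant`.
#' @export
compare_groups <- function(activity, labels, reactions = NULL,
                           alpha = 0.05, group_order = NULL,
                           rule = "probability", model = NULL) {
  act <- if (inherits(activity, "ActivityMatrix")) activity$activity else activity
  labels <- resolve_labels(act, labels, group_order)
  rids <- sort(rownames(act))
  if (!is.null(reactions)) {
    missing <- setdiff(reactions, rids)
    if (length(missing)) stop("unknown reactions: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    rids <- sort(intersect(rids, reactions))
  }
  g1 <- labels == levels(labels)[1]
  g2 <- labels == levels(labels)[2]
  rows <- lapply(rids, function(rid) {
    x <- act[rid, names(labels)]
    a <- sum(x[g1] == 1L)
    b <- sum(x[g1] == 0L)
    cc <- sum(x[g2] == 1L)
    d <- sum(x[g2] == 0L)
    or <- odds_ratio_convention(a, b, cc, d)
    data.frame(reaction = rid,
               subsystem = if (is.null(model)) "" else
                 model$reactions[[rid]]$subsystem %||% "",
               a = a, b = b, c = cc, d = d,
               odds_ratio = or,
               odds_ratio_label = format_odds_ratio(or),
               p = fisher_p(a, b, cc, d, rule = rule),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  attr(out, "groups") <- levels(labels)
  out
}
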