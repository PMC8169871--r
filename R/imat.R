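#' Pooled discretization thresholds
#'
#' Pools every gene x sample expression value in a dataset and returns the
#' empirical 25th and 75th percentiles (linear-interpolation quantiles,
#' `stats::quantile` type 7). Genes above `q75` in a given sample are
#' treated as highly expressed, below `q25` lowly expressed, and in
#' between moderately expressed.
#'
#' @param x An `ExpressionMatrix` (see [load_expression()]) or a numeric
#'   matrix/vector of expression values.
#' @return List with elements `q25` and `q75`.
#' @export
pooled_thresholds <- function(x) {
  vals <- if (inherits(x, "ExpressionMatrix")) x$values else x
  vals <- as.numeric(vals)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("cannot compute thresholds from an empty matrix",
                          call. = FALSE)
  q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE, type = 7)
  list(q25 = q[1], q75 = q[2])
}

#' Map gene expression onto reactions through GPR rules
#'
#' Isoenzymes (`or`) receive the maximum expression of their genes, enzyme
#' complexes (`and`) the minimum. Reactions without a gene association, or
#' whose GPR references a gene missing from `gene_values`, get `NA`
#' (missing genes are reported via `message()`).
#'
#' @param model A `MetabolicModel`.
#' @param gene_values Named numeric vector of per-gene expression values.
#' @return Named numeric vector over all model reactions.
#' @export
reaction_expression <- function(model, gene_values) {
  stopifnot(inherits(model, "MetabolicModel"),
            is.numeric(gene_values), !is.null(names(gene_values)))
  out <- vapply(model$reactions, function(r) gpr_value(r$gpr, gene_values),
                numeric(1))
  skipped <- vapply(model$reactions, function(r) {
    !is.null(r$gpr) && !all(gpr_genes(r$gpr) %in% names(gene_values))
  }, logical(1))
  if (any(skipped)) {
    message("reactions skipped (GPR genes missing from expression data): ",
            paste(names(model$reactions)[skipped], collapse = ", "))
  }
  out
}

#' Partition reactions into high / low / moderate expression states
#'
#' Strict inequalities: a mapped reaction value above `q75` is high, below
#' `q25` low; values equal to a threshold, `NA` values and reactions with
#' no gene evidence stay moderate and do not constrain the activity
#' optimization.
#'
#' @param reaction_values Named numeric vector from [reaction_expression()].
#' @param thresholds List with `q25`, `q75` from [pooled_thresholds()].
#' @return List with character vectors `high` and `low` (disjoint).
#' @export
assign_states <- function(reaction_values, thresholds) {
  stopifnot(is.numeric(reaction_values), !is.null(names(reaction_values)),
            is.list(thresholds), thresholds$q25 <= thresholds$q75)
  ok <- !is.na(reaction_values)
  list(high = names(reaction_values)[ok & reaction_values > thresholds$q75],
       low = names(reaction_values)[ok & reaction_values < thresholds$q25])
}

# Phase-one simplex (Bland's rule) for {A x = b, 0 <= x <= w}.
# Standard form: x + s = w with slack s, plus one artificial per equality
# row; minimizing the artificial sum decides feasibility. Bland's
# smallest-index pivoting guarantees finite termination under degeneracy.
# Returns list(feasible, x) with x of length ncol(A).
phase1_simplex <- function(A, b, w) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  # tableau columns: x (n), s (n), artificials (m), RHS
  ncols <- 2L * n + m
  T <- matrix(0, m + n, ncols + 1L)
  T[seq_len(m), seq_len(n)] <- A
  T[seq_len(m), 2L * n + seq_len(m)] <- diag(m)
  T[m + seq_len(n), seq_len(n)] <- diag(n)
  T[m + seq_len(n), n + seq_len(n)] <- diag(n)
  T[, ncols + 1L] <- c(b, w)
  basis <- c(2L * n + seq_len(m), n + seq_len(n))
  # objective row for minimizing the artificial sum, in canonical form
  obj <- numeric(ncols + 1L)
  obj[2L * n + seq_len(m)] <- 1
  for (i in seq_len(m)) obj <- obj - T[i, ]
  # tolerances tied to the data scale: pivoting must not stop while real
  # improvement remains, and only a residual at rounding-error level may
  # pass as feasible (the smallest genuine infeasibility gap in these
  # systems is set by the bounds, orders of magnitude above this)
  scale <- max(1, abs(b), w)
  eps <- 1e-11 * scale
  repeat {
    enter <- 0L
    for (j in seq_len(ncols)) {
      if (obj[j] < -eps) { enter <- j; break }          # Bland: first index
    }
    if (enter == 0L) break
    col <- T[, enter]
    rows <- which(col > eps)
    if (!length(rows)) return(list(feasible = FALSE, x = NULL))
    ratios <- T[rows, ncols + 1L] / col[rows]
    best <- min(ratios)
    cand <- rows[ratios <= best + eps]
    leave <- cand[which.min(basis[cand])]               # Bland tie-break
    piv <- T[leave, enter]
    T[leave, ] <- T[leave, ] / piv
    fac <- T[, enter]
    fac[leave] <- 0
    T <- T - outer(fac, T[leave, ])
    obj <- obj - obj[enter] * T[leave, ]
    basis[leave] <- enter
  }
  resid <- -obj[ncols + 1L]
  if (resid > 1e-9 * scale) return(list(feasible = FALSE, x = NULL))
  x <- numeric(ncols)
  x[basis] <- T[, ncols + 1L]
  list(feasible = TRUE, x = x[seq_len(n)])
}

# Feasibility of {S v = 0, lb <= v <= ub} on the shifted variables
# x = v - lb in [0, ub - lb]. Variables with zero-width bounds are fixed
# and eliminated first, as are equality rows that become trivial.
# Returns the flux vector when feasible.
lp_flux_feasible <- function(S, lb, ub, tol = 1e-9) {
  if (any(lb > ub + 1e-12)) return(list(feasible = FALSE, v = NULL))
  v0 <- lb
  free <- (ub - lb) > tol
  if (nrow(S) == 0L || !any(free)) {
    ok <- nrow(S) == 0L || max(abs(S %*% v0)) <= 1e-9
    return(list(feasible = ok, v = if (ok) pmin(pmax(v0, lb), ub) else NULL))
  }
  b3 <- as.vector(-S %*% v0)
  A3 <- S[, free, drop = FALSE]
  trivial <- rowSums(abs(A3)) <= tol
  if (any(trivial)) {
    if (any(abs(b3[trivial]) > 1e-9)) return(list(feasible = FALSE, v = NULL))
    A3 <- A3[!trivial, , drop = FALSE]
    b3 <- b3[!trivial]
  }
  if (nrow(A3) == 0L) return(list(feasible = TRUE, v = v0))
  res <- phase1_simplex(A3, b3, (ub - lb)[free])
  if (!res$feasible) return(list(feasible = FALSE, v = NULL))
  v <- v0
  v[free] <- pmin(res$x, (ub - lb)[free]) + lb[free]
  list(feasible = TRUE, v = v)
}

# Per-reaction indicator options implied by high/low states and epsilon.
# A high reaction can be satisfied forward (v >= eps), backward (v <= -eps)
# when its bounds admit it, or left unsatisfied; a low reaction can be
# forced off (v = 0) or left unsatisfied.
imat_indicator_options <- function(lb, ub, high, low, epsilon) {
  opts <- list()
  for (r in high) {
    o <- list()
    if (ub[r] >= epsilon) o <- c(o, list(list(rid = r, dir = "fwd")))
    if (lb[r] <= -epsilon) o <- c(o, list(list(rid = r, dir = "rev")))
    opts[[r]] <- o
  }
  for (r in low) {
    o <- list()
    if (lb[r] <= 0 && ub[r] >= 0) o <- c(o, list(list(rid = r, dir = "off")))
    opts[[r]] <- o
  }
  opts
}

tighten_bounds <- function(lb, ub, choice, epsilon) {
  r <- choice$rid
  switch(choice$dir,
         fwd = lb[r] <- max(lb[r], epsilon),
         rev = ub[r] <- min(ub[r], -epsilon),
         off = { lb[r] <- 0; ub[r] <- 0 })
  list(lb = lb, ub = ub)
}

#' Solve the iMAT activity optimization for one sample
#'
#' Finds a steady-state flux distribution maximizing agreement with the
#' discretized expression data: each highly expressed reaction scores one
#' point when it carries flux of magnitude at least `epsilon` (in either
#' direction), and each lowly expressed reaction scores one point when its
#' flux is exactly zero, subject to `S v = 0` and the box bounds. The
#' mixed-integer program is solved exactly by branch-and-bound over the
#' indicator constraints: every indicator is a pure bound tightening, so
#' node feasibility is a linear-programming feasibility check, infeasible
#' partial assignments prune their whole subtree (tightening is monotone),
#' and a node whose satisfied-plus-remaining count cannot beat the
#' incumbent is discarded. The search order (reactions sorted by id;
#' satisfy-forward, then satisfy-backward, then relax) is deterministic, so
#' the returned optimum is reproducible.
#'
#' @param model A `MetabolicModel`, with media constraints already applied.
#' @param states List with `high` and `low` reaction-id vectors, as from
#'   [assign_states()].
#' @param epsilon Minimum flux magnitude counted as active (default 1).
#' @return An `ImatSolution`: `flux` (named vector), `objective` (integer),
#'   `indicator` (data frame: reaction, state, y), `status`, `epsilon`.
#' @export
solve_imat <- function(model, states, epsilon = 1) {
  stopifnot(inherits(model, "MetabolicModel"), epsilon > 0)
  high <- intersect(states$high, names(model$reactions))
  low <- setdiff(intersect(states$low, names(model$reactions)), high)
  bad <- setdiff(c(states$high, states$low), names(model$reactions))
  if (length(bad)) stop("state sets reference unknown reactions: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  S <- stoichiometric_matrix(model)
  bounds <- flux_bounds(model)
  lb <- stats::setNames(bounds$lower_bound, bounds$reaction)
  ub <- stats::setNames(bounds$upper_bound, bounds$reaction)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("solve_imat requires finite flux bounds", call. = FALSE)
  }
  base <- lp_flux_feasible(S, lb, ub)
  if (!base$feasible) {
    stop("model infeasible under current constraints; review media constraints",
         call. = FALSE)
  }
  opts <- imat_indicator_options(lb, ub, sort(high), sort(low), epsilon)
  n_ind <- length(opts)

  best <- new.env(parent = emptyenv())
  best$objective <- -1L
  best$lb <- NULL
  best$ub <- NULL
  best$choices <- NULL

  search <- function(i, lb, ub, count, choices) {
    if (count + (n_ind - i + 1L) <= best$objective) return(invisible())
    if (i > n_ind) {
      if (count > best$objective) {
        best$objective <- count
        best$lb <- lb
        best$ub <- ub
        best$choices <- choices
      }
      return(invisible())
    }
    for (choice in opts[[i]]) {
      tb <- tighten_bounds(lb, ub, choice, epsilon)
      if (lp_flux_feasible(S, tb$lb, tb$ub)$feasible) {
        search(i + 1L, tb$lb, tb$ub, count + 1L,
               c(choices, stats::setNames(choice$dir, choice$rid)))
      }
    }
    search(i + 1L, lb, ub, count, choices)  # leave indicator unsatisfied
  }
  search(1L, lb, ub, 0L, character(0))

  sol <- lp_flux_feasible(S, best$lb, best$ub)
  flux <- stats::setNames(sol$v, names(model$reactions))
  indicator <- data.frame(
    reaction = names(opts) %||% character(0),
    state = c(rep("high", length(high)), rep("low", length(low)))[
      match(names(opts), c(sort(high), sort(low)))],
    y = ifelse(names(opts) %in% names(best$choices),
               best$choices[names(opts)], "unsat"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(flux = flux, objective = best$objective,
                 indicator = indicator, status = "optimal",
                 epsilon = epsilon,
                 bounds_opt = list(lb = best$lb, ub = best$ub)),
            class = "ImatSolution")
}

#' @export
print.ImatSolution <- function(x, ...) {
  cat(sprintf("ImatSolution: objective %d of %d indicators, status %s, epsilon %g\n",
              x$objective, nrow(x$indicator), x$status, x$epsilon))
  invisible(x)
}

#' Exhaustive oracle for the iMAT optimum
#'
#' Enumerates every assignment of the indicator variables (for each highly
#' expressed reaction: forward-active, backward-active or unsatisfied; for
#' each lowly expressed reaction: off or unsatisfied), checks feasibility
#' of the implied bound-tightened steady-state system, and returns the
#' maximum feasible indicator count. Intended as an independent check on
#' [solve_imat()]; capped at 16 indicator reactions.
#'
#' @inheritParams solve_imat
#' @return Integer objective value.
#' @export
enumerate_optimum <- function(model, states, epsilon = 1) {
  stopifnot(inherits(model, "MetabolicModel"), epsilon > 0)
  high <- sort(intersect(states$high, names(model$reactions)))
  low <- sort(setdiff(intersect(states$low, names(model$reactions)), high))
  if (length(high) + length(low) > 16L) {
    stop("enumerate_optimum is exhaustive; limited to 16 indicator reactions",
         call. = FALSE)
  }
  S <- stoichiometric_matrix(model)
  bounds <- flux_bounds(model)
  lb <- stats::setNames(bounds$lower_bound, bounds$reaction)
  ub <- stats::setNames(bounds$upper_bound, bounds$reaction)
  opts <- imat_indicator_options(lb, ub, high, low, epsilon)
  # option index 0 = unsatisfied; 1..k = the satisfiable directions
  n_opt <- vapply(opts, length, integer(1)) + 1L
  if (!length(opts)) {
    return(if (lp_flux_feasible(S, lb, ub)$feasible) 0L else
      stop("model infeasible under current constraints", call. = FALSE))
  }
  grid <- expand.grid(lapply(n_opt, seq_len), KEEP.OUT.ATTRS = FALSE)
  counts <- rowSums(grid > 1L)
  ord <- order(counts, decreasing = TRUE)
  best <- -1L
  for (idx in ord) {
    cnt <- counts[idx]
    if (cnt <= best) break  # sorted by count: nothing better remains
    tlb <- lb
    tub <- ub
    for (j in seq_along(opts)) {
      k <- grid[idx, j]
      if (k > 1L) {
        tb <- tighten_bounds(tlb, tub, opts[[j]][[k - 1L]], epsilon)
        tlb <- tb$lb
        tub <- tb$ub
      }
    }
    if (lp_flux_feasible(S, tlb, tub)$feasible) best <- as.integer(cnt)
  }
  if (best < 0L) stop("model infeasible under current constraints",
                      call. = FALSE)
  best
}

#' Call binary reaction activity from an iMAT solution
#'
#' @param solution An `ImatSolution` with status `"optimal"`.
#' @param tol Nonnegative flux magnitude below which a reaction is called
#'   inactive (default `1e-6`).
#' @return Named integer vector over reactions (active = 1, inactive = 0).
#' @export
call_activity <- function(solution, tol = 1e-6) {
  stopifnot(inherits(solution, "ImatSolution"), tol >= 0)
  if (!identical(solution$status, "optimal")) {
    stop("activity can only be called from an optimal solution (status: ",
         solution$status, ")", call. = FALSE)
  }
  stats::setNames(as.integer(abs(solution$flux) > tol), names(solution$flux))
}

#' Robust activity calling at the iMAT optimum
#'
#' Alternate optimal flux vectors can flip borderline reactions between
#' active and inactive. This mode holds the optimal indicator assignment
#' fixed (its tightened bounds) and calls a reaction active when it *can*
#' carry flux of magnitude at least `epsilon` in some steady-state flux
#' vector consistent with that optimum, rather than relying on the single
#' vertex the solver happened to return.
#'
#' @param model The `MetabolicModel` the solution was computed on.
#' @param solution An `ImatSolution` from [solve_imat()].
#' @param epsilon Flux magnitude defining activity; defaults to the
#'   solution's epsilon.
#' @return Named integer activity vector over reactions.
#' @export
call_activity_robust <- function(model, solution, epsilon = NULL) {
  stopifnot(inherits(model, "MetabolicModel"), inherits(solution, "ImatSolution"))
  if (!identical(solution$status, "optimal")) {
    stop("activity can only be called from an optimal solution", call. = FALSE)
  }
  if (is.null(epsilon)) epsilon <- solution$epsilon
  S <- stoichiometric_matrix(model)
  lb <- solution$bounds_opt$lb
  ub <- solution$bounds_opt$ub
  out <- stats::setNames(integer(length(lb)), names(lb))
  for (r in names(lb)) {
    can_fwd <- ub[r] >= epsilon && {
      l2 <- lb
      l2[r] <- max(l2[r], epsilon)
      lp_flux_feasible(S, l2, ub)$feasible
    }
    can_rev <- !can_fwd && lb[r] <= -epsilon && {
      u2 <- ub
      u2[r] <- min(u2[r], -epsilon)
      lp_flux_feasible(S, lb, u2)$feasible
    }
    out[r] <- as.integer(can_fwd || can_rev)
  }
  out
}

#' Predict per-sample reaction activity from expression data
#'
#' Full iMAT arm for a dataset: optionally residualizes expression on
#' covariates (sex/age correction), pools all values for the quantile
#' thresholds, maps each sample's gene values onto reactions through the
#' GPR rules, solves the activity optimization per sample, and assembles
#' the binary reactions x samples activity matrix.
#'
#' @param model A `MetabolicModel` (apply media constraints first, e.g.
#'   with [apply_media_constraints()]).
#' @param expr An `ExpressionMatrix`.
#' @param epsilon Minimum active flux magnitude.
#' @param tol Activity-calling tolerance on \|flux\|.
#' @param residualize Correct expression for covariates (columns of the
#'   sample metadata, e.g. `c("sex", "age")`) before discretization;
#'   `NULL` disables.
#' @param quantile_mode `"global"` pools all genes and samples (default);
#'   `"per_gene"` computes each gene's own quantiles across samples.
#' @return An `ActivityMatrix`: binary `activity` matrix, `thresholds`,
#'   `epsilon`, `tol`, per-sample objectives.
#' @export
predict_activity <- function(model, expr, epsilon = 1, tol = 1e-6,
                             residualize = NULL,
                             quantile_mode = c("global", "per_gene")) {
  stopifnot(inherits(model, "MetabolicModel"), inherits(expr, "ExpressionMatrix"))
  quantile_mode <- match.arg(quantile_mode)
  if (!is.null(residualize)) {
    expr <- residualize_expression(expr, residualize)
  }
  vals <- expr$values
  thresholds <- pooled_thresholds(vals)
  rids <- names(model$reactions)
  samples <- colnames(vals)
  act <- matrix(NA_integer_, nrow = length(rids), ncol = length(samples),
                dimnames = list(rids, samples))
  objectives <- stats::setNames(integer(length(samples)), samples)
  for (s in samples) {
    gv <- vals[, s]
    rx <- suppressMessages(reaction_expression(model, gv))
    thr <- if (quantile_mode == "global") thresholds else {
      # per-gene quantiles: state assignment per gene, then per reaction
      qg <- t(apply(vals, 1, stats::quantile, probs = c(0.25, 0.75),
                    names = FALSE, type = 7))
      gshift <- gv
      gshift[] <- 0
      gshift[gv > qg[, 2]] <- 1
      gshift[gv < qg[, 1]] <- -1
      rxs <- suppressMessages(reaction_expression(model, gshift))
      rx <- rxs
      list(q25 = -0.5, q75 = 0.5)
    }
    states <- assign_states(rx, thr)
    sol <- solve_imat(model, states, epsilon = epsilon)
    act[, s] <- call_activity(sol, tol = tol)[rids]
    objectives[s] <- sol$objective
  }
  structure(list(activity = act, thresholds = thresholds, epsilon = epsilon,
                 tol = tol, objectives = objectives,
                 quantile_mode = quantile_mode),
            class = "ActivityMatrix")
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf("ActivityMatrix: %d reactions x %d samples (epsilon %g, tol %g)\n",
              nrow(x$activity), ncol(x$activity), x$epsilon, x$tol))
  invisible(x)
}

#' Write / read a binary activity matrix as TSV
#'
#' First column `reaction`, one 0/1 column per sample; provenance
#' (epsilon, tolerance, quantile mode) in `#`-prefixed header lines.
#'
#' @param x An `ActivityMatrix`.
#' @param path Output TSV path.
#' @return `path` (write) or an `ActivityMatrix` (read).
#' @export
write_activity <- function(x, path) {
  stopifnot(inherits(x, "ActivityMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# epsilon=%.10g", x$epsilon),
               sprintf("# tol=%.10g", x$tol),
               sprintf("# quantile_mode=%s", x$quantile_mode)), con)
  df <- data.frame(reaction = rownames(x$activity), x$activity,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  hdr <- readLines(path, n = 50L)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, "="), "", hit[1]) else default
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  act <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(act) <- "integer"
  rownames(act) <- df[[1]]
  structure(list(activity = act,
                 thresholds = NULL,
                 epsilon = as.numeric(get("epsilon", "1")),
                 tol = as.numeric(get("tol", "1e-6")),
                 objectives = NULL,
                 quantile_mode = get("quantile_mode", "global")),
            class = "ActivityMatrix")
}
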