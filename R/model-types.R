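#' Construct a reaction
#'
#' @param id Reaction identifier (unique within a model).
#' @param stoich Named numeric vector mapping metabolite ids to
#'   stoichiometric coefficients; negative = consumed, positive = produced.
#' @param lower_bound,upper_bound Flux bounds; `lower_bound < 0` marks the
#'   reaction reversible.
#' @param gpr Gene association: a rule string (parsed with [parse_gpr()]),
#'   a GPR tree, or `NULL`/`""` for no association.
#' @param subsystem Free-text pathway/subsystem label.
#' @return A `Reaction` object (list).
#' @export
reaction <- function(id, stoich, lower_bound = -1000, upper_bound = 1000,
                     gpr = NULL, subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- unlist(stoich)
  if (length(stoich)) {
    stopifnot(is.numeric(stoich), !is.null(names(stoich)), all(nzchar(names(stoich))))
    stoich <- stoich[stoich != 0]
  } else {
    stoich <- stats::setNames(numeric(0), character(0))
  }
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': lower_bound must not exceed upper_bound", id),
         call. = FALSE)
  }
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  structure(list(id = id, stoich = stoich,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, subsystem = subsystem),
            class = "Reaction")
}

#' Construct a metabolic network model
#'
#' A stoichiometry-based reconstruction: metabolites, reactions with flux
#' bounds and gene associations, and the gene namespace. Metabolites flagged
#' `boundary = TRUE` sit outside the mass-balanced system (sources/sinks)
#' and are excluded from the stoichiometric matrix, as in SBML's
#' `boundaryCondition`.
#'
#' @param metabolites Data frame with columns `id`, and optionally `name`,
#'   `compartment`, `boundary` (logical).
#' @param reactions List of [reaction()] objects.
#' @param genes Character vector of gene ids; derived from the GPRs when
#'   omitted.
#' @param name,version Free-text model identity.
#' @return A `MetabolicModel` object.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            name = "model", version = "") {
  if (is.character(metabolites)) metabolites <- data.frame(id = metabolites)
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  metabolites <- metabolites[, c("id", "name", "compartment", "boundary")]
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.list(reactions))
  rid <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rid)) {
    stop("duplicate reaction ids: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "), call. = FALSE)
  }
  names(reactions) <- rid
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), metabolites$id)
    if (length(unknown)) {
      stop(sprintf("reaction '%s' references undeclared metabolites: %s",
                   r$id, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  gpr_gene_set <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  if (is.null(genes)) {
    genes <- sort(gpr_gene_set)
  } else {
    genes <- unique(as.character(genes))
    missing <- setdiff(gpr_gene_set, genes)
    if (length(missing)) {
      stop("GPR rules reference undeclared genes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 genes = genes, name = name, version = version),
            class = "MetabolicModel")
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf("MetabolicModel '%s'%s: %d reactions, %d metabolites (%d boundary), %d genes\n",
              x$name, if (nzchar(x$version)) paste0(" v", x$version) else "",
              length(x$reactions), nrow(x$metabolites),
              sum(x$metabolites$boundary), length(x$genes)))
  invisible(x)
}

#' @export
print.Reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]
  rhs <- x$stoich[x$stoich > 0]
  fmt <- function(s) if (!length(s)) "" else
    paste(ifelse(abs(s) == 1, names(s), paste(abs(s), names(s))), collapse = " + ")
  arrow <- if (x$lower_bound < 0) "<=>" else "-->"
  cat(sprintf("%s: %s %s %s  [%g, %g]%s\n", x$id, fmt(lhs), arrow, fmt(rhs),
              x$lower_bound, x$upper_bound,
              if (is.null(x$gpr)) "" else paste0("  gpr: ", deparse_gpr(x$gpr))))
  invisible(x)
}

#' Reaction ids of a model
#' @param model A `MetabolicModel`.
#' @return Character vector of reaction ids in model order.
#' @export
reaction_ids <- function(model) {
  stopifnot(inherits(model, "MetabolicModel"))
  names(model$reactions)
}

#' Stoichiometric matrix
#'
#' Mass-balanced metabolites (non-boundary) by reactions coefficient matrix
#' `S`; steady state requires `S v = 0`.
#'
#' @param model A `MetabolicModel`.
#' @return Numeric matrix with metabolite ids as rownames and reaction ids
#'   as colnames.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "MetabolicModel"))
  mets <- model$metabolites$id[!model$metabolites$boundary]
  S <- matrix(0, nrow = length(mets), ncol = length(model$reactions),
              dimnames = list(mets, names(model$reactions)))
  for (r in model$reactions) {
    keep <- intersect(names(r$stoich), mets)
    if (length(keep)) S[keep, r$id] <- r$stoich[keep]
  }
  S
}

#' Flux bounds of a model
#' @param model A `MetabolicModel`.
#' @return Data frame with columns `reaction`, `lower_bound`, `upper_bound`.
#' @export
flux_bounds <- function(model) {
  stopifnot(inherits(model, "MetabolicModel"))
  data.frame(reaction = names(model$reactions),
             lower_bound = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
             upper_bound = vapply(model$reactions, `[[`, numeric(1), "upper_bound"),
             row.names = NULL)
}
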