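#' Read a metabolic model from SBML or JSON
#'
#' Supports SBML Level 3 with fbc-style flux bounds, boundary-condition
#' species and gene-product associations, and a COBRA-style JSON dialect
#' (top-level keys `metabolites`, `reactions`, `genes`; each reaction
#' carries `id`, `metabolites`, `lower_bound`, `upper_bound`,
#' `gene_reaction_rule`, `subsystem`). Reactions without declared bounds
#' default to `(-1000, 1000)` when marked reversible and `(0, 1000)`
#' otherwise, with a warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @param default_bound Magnitude used when a file omits flux bounds.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "json"),
                       default_bound = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
         json = read_model_json(path, default_bound),
         sbml = read_model_sbml(path, default_bound))
}

#' Write a metabolic model to SBML or JSON
#'
#' @param model A `MetabolicModel`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  stopifnot(inherits(model, "MetabolicModel"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path, default_bound) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("malformed JSON model file '", path,
                                         "': ", conditionMessage(e), call. = FALSE))
  if (!all(c("metabolites", "reactions") %in% names(x))) {
    stop("malformed JSON model: missing 'metabolites' or 'reactions' key",
         call. = FALSE)
  }
  mets <- data.frame(
    id = vapply(x$metabolites, function(m) m$id, character(1)),
    name = vapply(x$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(x$metabolites, function(m) m$compartment %||% "c", character(1)),
    boundary = vapply(x$metabolites, function(m) isTRUE(m$boundary), logical(1))
  )
  missing_bounds <- character(0)
  rxns <- lapply(x$reactions, function(r) {
    lb <- r$lower_bound
    ub <- r$upper_bound
    if (is.null(lb) || is.null(ub)) {
      missing_bounds <<- c(missing_bounds, r$id)
      rev <- isTRUE(r$reversible)
      if (is.null(lb)) lb <- if (rev) -default_bound else 0
      if (is.null(ub)) ub <- default_bound
    }
    reaction(id = r$id, stoich = unlist(r$metabolites),
             lower_bound = lb, upper_bound = ub,
             gpr = r$gene_reaction_rule %||% NULL,
             subsystem = r$subsystem %||% "")
  })
  if (length(missing_bounds)) {
    warning("missing flux bounds defaulted for reactions: ",
            paste(missing_bounds, collapse = ", "), call. = FALSE)
  }
  genes <- if (!is.null(x$genes)) unlist(x$genes) else NULL
  metabolic_model(mets, rxns, genes = genes,
                  name = x$id %||% "model", version = x$version %||% "")
}

write_model_json <- function(model, path) {
  out <- list(
    id = model$name,
    version = model$version,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           boundary = m$boundary)
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, metabolites = as.list(r$stoich),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = deparse_gpr(r$gpr), subsystem = r$subsystem)
    }),
    genes = as.list(model$genes)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" ",
                   "version=\"1\" fbc:required=\"false\">"),
            SBML_CORE_NS, SBML_FBC_NS),
    sprintf("  <model id=\"%s\" name=\"%s\" fbc:strict=\"true\">",
            esc(model$name), esc(model$version)))
  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf("      <compartment id=\"%s\" constant=\"true\"/>", esc(comps)),
             "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      paste0("      <species id=\"M_%s\" name=\"%s\" compartment=\"%s\" ",
             "boundaryCondition=\"%s\" hasOnlySubstanceUnits=\"false\" ",
             "constant=\"false\"/>"),
      esc(m$id), esc(m$name), esc(m$compartment),
      if (m$boundary) "true" else "false"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in model$reactions) {
    lines <- c(lines,
      sprintf("      <parameter id=\"R_%s_lb\" value=\"%s\" constant=\"true\"/>",
              esc(r$id), num(r$lower_bound)),
      sprintf("      <parameter id=\"R_%s_ub\" value=\"%s\" constant=\"true\"/>",
              esc(r$id), num(r$upper_bound)))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  gpr_xml <- function(g, indent) {
    pad <- strrep(" ", indent)
    if (identical(g$type, "gene")) {
      return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>",
                     pad, esc(g$gene)))
    }
    tag <- if (identical(g$type, "or")) "fbc:or" else "fbc:and"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(g$args, gpr_xml, indent = indent + 2L)),
      sprintf("%s</%s>", pad, tag))
  }
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      paste0("      <reaction id=\"R_%s\" reversible=\"%s\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"R_%s_lb\" fbc:upperFluxBound=\"R_%s_ub\">"),
      esc(r$id), if (r$lower_bound < 0) "true" else "false",
      esc(r$id), esc(r$id)))
    if (nzchar(r$subsystem)) {
      lines <- c(lines,
        "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
        sprintf("          <p>SUBSYSTEM: %s</p>", esc(r$subsystem)),
        "        </body></notes>")
    }
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lines <- c(lines, "        <listOfReactants>",
        sprintf(paste0("          <speciesReference species=\"M_%s\" ",
                       "stoichiometry=\"%s\" constant=\"true\"/>"),
                esc(names(subs)), num(abs(subs))),
        "        </listOfReactants>")
    }
    if (length(prods)) {
      lines <- c(lines, "        <listOfProducts>",
        sprintf(paste0("          <speciesReference species=\"M_%s\" ",
                       "stoichiometry=\"%s\" constant=\"true\"/>"),
                esc(names(prods)), num(prods)),
        "        </listOfProducts>")
    }
    if (!is.null(r$gpr)) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gpr_xml(r$gpr, 10L), "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "    <fbc:listOfGeneProducts>")
  for (g in model$genes) {
    lines <- c(lines, sprintf(
      "      <fbc:geneProduct fbc:id=\"G_%s\" fbc:label=\"%s\"/>", esc(g), esc(g)))
  }
  lines <- c(lines, "    </fbc:listOfGeneProducts>", "  </model>", "</sbml>")
  writeLines(lines, path)
}

# attribute lookup that tolerates namespace prefixes
xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

sbml_ns_map <- function(doc) {
  urls <- unique(unlist(xml2::xml_ns(doc)))
  pick <- function(pattern, fallback) {
    hit <- grep(pattern, urls, value = TRUE)
    if (length(hit)) hit[1] else fallback
  }
  c(c = pick("sbml/level3/version[0-9]+/core", SBML_CORE_NS),
    f = pick("/fbc/", SBML_FBC_NS),
    x = "http://www.w3.org/1999/xhtml")
}

read_model_sbml <- function(path, default_bound) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ns <- sbml_ns_map(doc)
  mdl <- xml2::xml_find_first(doc, ".//c:model", ns)
  if (inherits(mdl, "xml_missing")) stop("malformed SBML: no <model> element",
                                         call. = FALSE)
  sp <- xml2::xml_find_all(mdl, ".//c:listOfSpecies/c:species", ns)
  mets <- data.frame(
    id = strip_prefix(vapply(sp, xattr, character(1), "id"), "M_"),
    name = vapply(sp, function(s) {
      nm <- xattr(s, "name"); if (is.na(nm)) strip_prefix(xattr(s, "id"), "M_") else nm
    }, character(1)),
    compartment = vapply(sp, xattr, character(1), "compartment"),
    boundary = vapply(sp, xattr, character(1), "boundaryCondition") == "true"
  )
  mets$boundary[is.na(mets$boundary)] <- FALSE
  pars <- xml2::xml_find_all(mdl, ".//c:listOfParameters/c:parameter", ns)
  parval <- stats::setNames(as.numeric(vapply(pars, xattr, character(1), "value")),
                            vapply(pars, xattr, character(1), "id"))
  gps <- xml2::xml_find_all(mdl, ".//f:listOfGeneProducts/f:geneProduct", ns)
  gene_label <- stats::setNames(
    vapply(gps, function(g) {
      lb <- xattr(g, "label")
      if (is.na(lb)) strip_prefix(xattr(g, "id"), "G_") else lb
    }, character(1)),
    vapply(gps, xattr, character(1), "id"))

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xattr(node, "geneProduct")
      lab <- if (ref %in% names(gene_label)) gene_label[[ref]] else strip_prefix(ref, "G_")
      return(list(type = "gene", gene = lab))
    }
    kids <- xml2::xml_find_all(node, "./*")
    gpr_node(if (nm == "or") "or" else "and", lapply(kids, parse_assoc))
  }

  rnodes <- xml2::xml_find_all(mdl, ".//c:listOfReactions/c:reaction", ns)
  missing_bounds <- character(0)
  rxns <- lapply(rnodes, function(rn) {
    rid <- strip_prefix(xattr(rn, "id"), "R_")
    coef <- function(xp, sign) {
      refs <- xml2::xml_find_all(rn, xp, ns)
      if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(
        sign * as.numeric(vapply(refs, xattr, character(1), "stoichiometry")),
        strip_prefix(vapply(refs, xattr, character(1), "species"), "M_"))
    }
    stoich <- c(coef("./c:listOfReactants/c:speciesReference", -1),
                coef("./c:listOfProducts/c:speciesReference", +1))
    lbp <- xattr(rn, "lowerFluxBound")
    ubp <- xattr(rn, "upperFluxBound")
    rev <- identical(xattr(rn, "reversible"), "true")
    if (is.na(lbp) || is.na(ubp) || !all(c(lbp, ubp) %in% names(parval))) {
      missing_bounds <<- c(missing_bounds, rid)
      lb <- if (rev) -default_bound else 0
      ub <- default_bound
    } else {
      lb <- parval[[lbp]]
      ub <- parval[[ubp]]
    }
    assoc <- xml2::xml_find_first(rn, "./f:geneProductAssociation/*", ns)
    gpr <- if (inherits(assoc, "xml_missing")) NULL else parse_assoc(assoc)
    note <- xml2::xml_find_first(rn, ".//x:p[starts-with(text(), 'SUBSYSTEM:')]", ns)
    subsystem <- if (inherits(note, "xml_missing")) "" else
      trimws(sub("^SUBSYSTEM:", "", xml2::xml_text(note)))
    reaction(id = rid, stoich = stoich, lower_bound = lb, upper_bound = ub,
             gpr = gpr, subsystem = subsystem)
  })
  if (length(missing_bounds)) {
    warning("missing flux bounds defaulted for reactions: ",
            paste(missing_bounds, collapse = ", "), call. = FALSE)
  }
  metabolic_model(mets, rxns, genes = unname(gene_label),
                  name = xattr(mdl, "id") %||% "model",
                  version = xattr(mdl, "name") %||% "")
}

#' Reactions controlled by a gene list
#'
#' Returns every reaction whose gene association mentions at least one of
#' the listed genes (any-leaf membership: a reaction enabled by
#' `"g_listed or g_other"` counts).
#'
#' @param model A `MetabolicModel`.
#' @param genes Nonempty character vector of gene ids; ids absent from the
#'   model match nothing (reported via `message()`).
#' @return Character vector of reaction ids, sorted.
#' @export
reactions_for_genes <- function(model, genes) {
  stopifnot(inherits(model, "MetabolicModel"))
  if (length(genes) == 0L) stop("'genes' must be a nonempty gene list",
                                call. = FALSE)
  genes <- as.character(genes)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    message("genes not in model (matched nothing): ",
            paste(unknown, collapse = ", "))
  }
  hits <- vapply(model$reactions,
                 function(r) length(intersect(gpr_genes(r$gpr), genes)) > 0L,
                 logical(1))
  sort(names(model$reactions)[hits])
}

#' Constrain uptake/synthesis rates
#'
#' Raises the lower bounds of selected reactions, e.g. to force minimal
#' glucose uptake, oxygen uptake and macromolecule synthesis activity in
#' every context-specific simulation, leaving all other reactions
#' unconstrained.
#'
#' @param model A `MetabolicModel`.
#' @param constraints Named numeric vector (`reaction id -> new lower
#'   bound`) or data frame with columns `reaction`, `lower_bound`.
#' @return A model copy with only the listed lower bounds changed.
#' @export
apply_media_constraints <- function(model, constraints) {
  stopifnot(inherits(model, "MetabolicModel"))
  if (is.data.frame(constraints)) {
    constraints <- stats::setNames(constraints$lower_bound, constraints$reaction)
  }
  if (length(constraints) == 0L) return(model)
  stopifnot(is.numeric(constraints), !is.null(names(constraints)))
  for (rid in names(constraints)) {
    if (!rid %in% names(model$reactions)) {
      stop("media constraint references unknown reaction: ", rid, call. = FALSE)
    }
    new_lb <- constraints[[rid]]
    if (new_lb > model$reactions[[rid]]$upper_bound) {
      stop(sprintf("media constraint for '%s' (lower bound %g) exceeds its upper bound %g",
                   rid, new_lb, model$reactions[[rid]]$upper_bound), call. = FALSE)
    }
    model$reactions[[rid]]$lower_bound <- new_lb
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A priori cholesterol-homeostasis gene panel
#'
#' The bundled panel of genes encoding enzymes of de novo cholesterol
#' biosynthesis (pre- and post-squalene), enzymatic cholesterol
#' catabolism (oxysterol formation) and esterification, used to select
#' the reaction subset of a genome-scale model via
#' [reactions_for_genes()]. Shipped as an editable TSV
#' (`extdata/cholesterol_gene_panel.tsv`); the panel is configuration,
#' not an assertion of completeness.
#'
#' @param path Alternative panel TSV (columns `gene`, `pathway`).
#' @return Data frame with columns `gene`, `pathway`.
#' @export
cholesterol_gene_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cholesterol_gene_panel.tsv",
                        package = "sterolflux", mustWork = TRUE)
  }
  utils::read.delim(path, comment.char = "#")
}
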