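#' Generate a toy mass-balanced metabolic network
#'
#' Builds a connected linear pathway with optional branches, a
#' glucose-like uptake (`EX_glc`), an oxygen-like uptake (`EX_o2`) feeding
#' one oxygen-consuming internal reaction, and a macromolecule-synthesis
#' sink (`SINK_macro`), so the standard minimal-activity constraints
#' (lower bounds 0.01 / 0.01 / 0.0001) are applicable. Internal reactions
#' carry randomly sampled GPRs; with probability `and_fraction` a
#' multi-gene rule is an enzyme complex (`and`), otherwise isoenzymes
#' (`or`). Zero flux is always feasible before media constraints.
#'
#' @param n_reactions Number of internal chain reactions (>= 3).
#' @param n_branches Number of side branches to boundary exports.
#' @param and_fraction Probability that a multi-gene GPR is a complex.
#' @param bound Flux-bound magnitude (bounds are `[0, bound]` for the
#'   irreversible steps, `[-bound, bound]` for reversible ones).
#' @param reversible_fraction Fraction of internal reactions made
#'   reversible.
#' @param seed Integer seed; fixed seed gives identical models.
#' @return List: `model` (a `MetabolicModel`) and `truth` (data frame of
#'   reaction -> genes annotations).
#' @export
make_toy_network <- function(n_reactions = 6, n_branches = 1,
                             and_fraction = 0.3, bound = 1000,
                             reversible_fraction = 0.2, seed = 1) {
  if (n_reactions < 3) stop("n_reactions must be at least 3", call. = FALSE)
  if (n_branches < 0 || and_fraction < 0 || and_fraction > 1) {
    stop("invalid generator sizes", call. = FALSE)
  }
  set.seed(seed)
  n_chain_mets <- n_reactions + 1L
  mets <- data.frame(id = c(paste0("A", seq_len(n_chain_mets)), "o2"))
  rxns <- list(
    reaction("EX_glc", c(A1 = 1), 0, bound),
    reaction("EX_o2", c(o2 = 1), 0, bound))
  o2_step <- sample(n_reactions, 1)
  gene_pool <- sprintf("g%03d", seq_len(3L * n_reactions + 3L * max(1L, n_branches)))
  gi <- 0L
  next_genes <- function(k) {
    gs <- gene_pool[gi + seq_len(k)]
    gi <<- gi + k
    gs
  }
  random_gpr <- function() {
    k <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    gs <- next_genes(k)
    if (k == 1L) return(gs)
    op <- if (stats::runif(1) < and_fraction) " and " else " or "
    paste(gs, collapse = op)
  }
  for (i in seq_len(n_reactions)) {
    st <- stats::setNames(c(-1, 1), c(paste0("A", i), paste0("A", i + 1)))
    if (i == o2_step) st <- c(st, o2 = -1)
    rev <- i != o2_step && stats::runif(1) < reversible_fraction
    rxns[[length(rxns) + 1L]] <-
      reaction(sprintf("r%02d", i), st, if (rev) -bound else 0, bound,
               gpr = random_gpr())
  }
  if (n_branches > 0) {
    for (bidx in seq_len(n_branches)) {
      from <- sample(2:n_reactions, 1)
      bm <- paste0("B", bidx)
      mets <- rbind(mets, data.frame(id = bm))
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("br%02d", bidx),
                 stats::setNames(c(-1, 1), c(paste0("A", from), bm)),
                 0, bound, gpr = random_gpr())
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("EX_b%02d", bidx), stats::setNames(-1, bm), 0, bound)
    }
  }
  rxns[[length(rxns) + 1L]] <-
    reaction("SINK_macro", stats::setNames(-1, paste0("A", n_chain_mets)),
             0, bound)
  model <- metabolic_model(mets, rxns, name = "toy_network",
                           version = as.character(seed))
  truth <- data.frame(
    reaction = names(model$reactions),
    genes = vapply(model$reactions,
                   function(r) paste(gpr_genes(r$gpr), collapse = ";"),
                   character(1)),
    row.names = NULL)
  list(model = model, truth = truth)
}

#' Standard minimal-activity media constraints for toy networks
#'
#' Lower bounds forcing glucose uptake, oxygen uptake and macromolecule
#' synthesis to stay active (0.01, 0.01, 0.0001 flux units).
#'
#' @param glc,o2,macro Reaction ids of the three constrained processes.
#' @return Named numeric vector for [apply_media_constraints()].
#' @export
default_media_constraints <- function(glc = "EX_glc", o2 = "EX_o2",
                                      macro = "SINK_macro") {
  stats::setNames(c(0.01, 0.01, 0.0001), c(glc, o2, macro))
}

#' Pedagogical cholesterol pathway model
#'
#' A fixed 12-reaction, 11-metabolite toy network tracing acetyl-CoA
#' through HMG-CoA and mevalonate to lanosterol, then to cholesterol by
#' either of the two parallel post-lanosterol routes (the Bloch branch via
#' desmosterol and the Kandutsch-Russell branch via
#' 7-dehydrocholesterol), with enzymatic catabolism to
#' 24S-hydroxycholesterol and bile acid, and esterification for storage.
#' GPRs use the pathway's enzyme genes (ACAT2, HMGCS1, HMGCR, SQLE, LSS,
#' SC5D, DHCR24, DHCR7, CYP46A1, HSD3B7, SOAT1). Stoichiometry is
#' pedagogical (unit coefficients), not biochemical; the bile-acid and
#' ester pools are boundary metabolites so either exit can drain flux.
#'
#' @return A `MetabolicModel` with 12 reactions and 11 metabolites.
#' @export
mini_cholesterol_fixture <- function() {
  mets <- data.frame(
    id = c("accoa", "aacoa", "hmgcoa", "mev", "lanosterol", "desmosterol",
           "chol7dhc", "chol", "ohc24s", "bileacid", "cholesterylester"),
    name = c("acetyl-CoA", "acetoacetyl-CoA", "HMG-CoA", "(R)-mevalonate",
             "lanosterol", "desmosterol", "7-dehydrocholesterol",
             "cholesterol", "24S-hydroxycholesterol", "bile acid pool",
             "cholesteryl ester pool"),
    compartment = "c",
    boundary = c(rep(FALSE, 9), TRUE, TRUE))
  bio <- "de novo cholesterol biosynthesis"
  cat_e <- "cholesterol catabolism (enzymatic)"
  rxns <- list(
    reaction("EX_accoa", c(accoa = 1), 0, 1000, subsystem = "exchange"),
    reaction("r_acat2", c(accoa = -1, aacoa = 1), -1000, 1000,
             gpr = "ACAT2", subsystem = bio),
    reaction("r_hmgcs1", c(aacoa = -1, hmgcoa = 1), 0, 1000,
             gpr = "HMGCS1", subsystem = bio),
    reaction("r_hmgcr", c(hmgcoa = -1, mev = 1), 0, 1000,
             gpr = "HMGCR", subsystem = bio),
    reaction("r_mev_lanosterol", c(mev = -1, lanosterol = 1), 0, 1000,
             gpr = "SQLE and LSS", subsystem = bio),
    reaction("r_bloch_desmosterol", c(lanosterol = -1, desmosterol = 1),
             0, 1000, gpr = "SC5D", subsystem = bio),
    reaction("r_dhcr24", c(desmosterol = -1, chol = 1), 0, 1000,
             gpr = "DHCR24", subsystem = bio),
    reaction("r_kr_7dhc", c(lanosterol = -1, chol7dhc = 1), 0, 1000,
             gpr = "DHCR24", subsystem = bio),
    reaction("r_dhcr7", c(chol7dhc = -1, chol = 1), 0, 1000,
             gpr = "DHCR7", subsystem = bio),
    reaction("r_cyp46a1", c(chol = -1, ohc24s = 1), 0, 1000,
             gpr = "CYP46A1", subsystem = cat_e),
    reaction("r_hsd3b7", c(ohc24s = -1, bileacid = 1), 0, 1000,
             gpr = "HSD3B7", subsystem = cat_e),
    reaction("r_soat1", c(chol = -1, cholesterylester = 1), 0, 1000,
             gpr = "SOAT1", subsystem = "cholesterol esterification"))
  metabolic_model(mets, rxns, name = "mini_cholesterol", version = "1")
}

#' Simulate an expression matrix with planted group-differential genes
#'
#' Gene baselines are drawn once from a normal distribution on the log2
#' scale; samples in the second group are shifted by `delta` on the
#' planted genes; i.i.d. noise is added everywhere. The returned truth
#' records the planted genes and, via the GPR structure, the reactions
#' expected to differ in activity between groups.
#'
#' @param model `MetabolicModel` whose genes the matrix covers.
#' @param n_per_group Samples per group (length-2 or scalar).
#' @param planted_genes Genes shifted in the second group (subset of the
#'   model's genes).
#' @param delta Shift applied to planted genes in group 2 (required; sign
#'   sets the direction).
#' @param planted_baseline Baseline of the planted genes; defaults to
#'   `baseline_mean + 2.5`, putting them above the pooled 75th percentile
#'   in group 1 so a negative `delta` can carry them below the 25th
#'   percentile in group 2.
#' @param baseline_mean,baseline_sd Gene baseline distribution (log2).
#' @param noise_sd Residual noise standard deviation.
#' @param groups Length-2 group labels; defaults to `c("CN", "AD")` so the
#'   shifted group is the disease group.
#' @param seed Integer seed.
#' @return List: `expr` (an `ExpressionMatrix`) and `truth` (planted
#'   genes, delta, affected reactions).
#' @export
simulate_expression <- function(model, n_per_group = 20, planted_genes,
                                delta, planted_baseline = NULL,
                                baseline_mean = 7, baseline_sd = 1.5,
                                noise_sd = 0.3, groups = c("CN", "AD"),
                                seed = 1) {
  stopifnot(inherits(model, "MetabolicModel"))
  if (missing(delta) || is.null(delta) || is.na(delta)) {
    stop("'delta' (planted shift) must be set explicitly", call. = FALSE)
  }
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  genes <- model$genes
  unknown <- setdiff(planted_genes, genes)
  if (length(unknown)) stop("planted genes not in model: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  set.seed(seed)
  n <- sum(n_per_group)
  group <- rep(groups, n_per_group)
  samples <- sprintf("S%03d", seq_len(n))
  baseline <- stats::rnorm(length(genes), baseline_mean, baseline_sd)
  names(baseline) <- genes
  if (length(planted_genes)) {
    if (is.null(planted_baseline)) planted_baseline <- baseline_mean + 2.5
    baseline[planted_genes] <- planted_baseline
  }
  vals <- matrix(baseline, nrow = length(genes), ncol = n,
                 dimnames = list(genes, samples))
  vals[planted_genes, group == groups[2]] <-
    vals[planted_genes, group == groups[2]] + delta
  vals <- vals + matrix(stats::rnorm(length(genes) * n, 0, noise_sd),
                        nrow = length(genes))
  metadata <- data.frame(
    sample = samples, group = group,
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(stats::rnorm(n, 85, 7), 1),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    region = "simulated")
  affected <- if (length(planted_genes))
    reactions_for_genes(model, planted_genes) else character(0)
  list(expr = expression_matrix(vals, metadata),
       truth = list(planted_genes = planted_genes, delta = delta,
                    groups = groups, affected_reactions = affected))
}

#' Default planted effect profile for the metabolomics generator
#'
#' Region-specific disease-severity slopes on the log2 scale for a small
#' panel of sterol metabolites, with magnitudes in the 0.1-0.3 range
#' typical of brain sterol case-control differences (the lanosterol MFG
#' slope of -0.278 anchors the biosynthesis arm). Metabolites without an
#' entry are null.
#'
#' @return Data frame: `metabolite`, `region`, `beta`.
#' @export
default_metabolite_effects <- function() {
  data.frame(
    metabolite = c("lanosterol", "lanosterol",
                   "ohc24s", "ohc7a",
                   "ketochol7", "ohc7b", "epoxychol5a6a"),
    region = c("MFG", "ITG", "ITG", "ITG", "ITG", "ITG", "ITG"),
    beta = c(-0.278, -0.09, -0.113, 0.154, 0.304, 0.237, 0.199))
}

#' Simulate a two-cohort, two-region metabolomics table
#'
#' Emulates a pair of brain-autopsy cohorts with AD / asymptomatic (ASY) /
#' control (CN) groups, two regions per subject (ITG, MFG), left-censoring
#' at a per-metabolite limit of detection, additional missingness at
#' random, and ordinal CERAD (0-3) / Braak (0-6) pathology scores whose
#' means rise from CN through ASY to AD. Log2 concentrations follow
#' `baseline + beta_region * severity + subject effect + noise`, where the
#' subject effect is shared across regions so the within-subject
#' correlation equals `rho`. Default group sizes mirror a small
#' (15 AD / 6 ASY / 8 CN) and a larger (31 AD / 18 ASY / 22 CN) cohort.
#'
#' @param n_per_group Named list (per cohort) of named group sizes, e.g.
#'   `list(BLSA = c(CN = 8, ASY = 6, AD = 15), ROS = c(CN = 22, ASY = 18,
#'   AD = 31))`.
#' @param effects Data frame `metabolite`, `region`, `beta` of planted
#'   slopes per unit disease score (CN = 0, ASY = 1, AD = 2);
#'   metabolites default to [default_metabolite_effects()].
#' @param metabolites Metabolite panel; defaults to the effect table's
#'   metabolites plus two null fillers.
#' @param baseline_log2 Baseline log2 concentration (per metabolite,
#'   recycled).
#' @param rho Within-subject correlation across regions, in `[0, 1)`.
#' @param sigma Total residual standard deviation on the log2 scale.
#' @param lod_quantile Fraction of each metabolite's concentration
#'   distribution censored at the limit of detection (0 = none).
#' @param missing_fraction Additional missing-at-random record fraction.
#' @param seed Integer seed.
#' @return List: `table` (a `MetaboliteTable`) and `truth` (planted
#'   betas, rho, sigma, censoring settings).
#' @export
simulate_metabolomics <- function(
    n_per_group = list(BLSA = c(CN = 8, ASY = 6, AD = 15),
                       ROS = c(CN = 22, ASY = 18, AD = 31)),
    effects = default_metabolite_effects(),
    metabolites = NULL,
    baseline_log2 = 4,
    rho = 0.5, sigma = 0.45,
    lod_quantile = 0.05, missing_fraction = 0.02,
    seed = 1) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (any(unlist(n_per_group) < 3)) {
    stop("need at least 3 subjects per cohort x group cell", call. = FALSE)
  }
  set.seed(seed)
  regions <- c("ITG", "MFG")
  if (is.null(metabolites)) {
    metabolites <- unique(c(effects$metabolite, "cholesterol", "desmosterol"))
  }
  base <- stats::setNames(rep_len(baseline_log2, length(metabolites)),
                          metabolites)
  cerad_mean <- c(CN = 0.3, ASY = 2.2, AD = 2.6)
  braak_mean <- c(CN = 2.7, ASY = 3.6, AD = 4.8)
  subj_rows <- list()
  for (cohort in names(n_per_group)) {
    sizes <- n_per_group[[cohort]]
    for (grp in names(sizes)) {
      for (i in seq_len(sizes[[grp]])) {
        subj_rows[[length(subj_rows) + 1L]] <- data.frame(
          cohort = cohort, group = grp,
          subject = sprintf("%s_%s_%02d", cohort, grp, i))
      }
    }
  }
  subjects <- do.call(rbind, subj_rows)
  nsub <- nrow(subjects)
  subjects$sex <- sample(c("F", "M"), nsub, replace = TRUE)
  subjects$age <- round(stats::rnorm(nsub, 88, 7), 1)
  subjects$cerad <- pmin(3, pmax(0, round(
    stats::rnorm(nsub, cerad_mean[subjects$group], 0.6))))
  subjects$braak <- pmin(6, pmax(0, round(
    stats::rnorm(nsub, braak_mean[subjects$group], 1.0))))
  score <- c(CN = 0, ASY = 1, AD = 2)[subjects$group]

  tau <- sqrt(rho) * sigma      # shared subject effect
  eps <- sqrt(1 - rho) * sigma  # region-specific noise
  recs <- list()
  for (met in metabolites) {
    bmet <- stats::setNames(rep(0, length(regions)), regions)
    hit <- effects[effects$metabolite == met, , drop = FALSE]
    if (nrow(hit)) bmet[hit$region] <- hit$beta
    u <- stats::rnorm(nsub, 0, tau)
    for (reg in regions) {
      y <- base[[met]] + bmet[[reg]] * score + u +
        stats::rnorm(nsub, 0, eps)
      recs[[length(recs) + 1L]] <- data.frame(
        subject = subjects$subject, cohort = subjects$cohort, region = reg,
        metabolite = met, log2conc = y,
        group = subjects$group, sex = subjects$sex, age = subjects$age,
        cerad = subjects$cerad, braak = subjects$braak)
    }
  }
  tab <- do.call(rbind, recs)
  tab$concentration <- 2^tab$log2conc
  tab$log2conc <- NULL
  # left-censor at the per-metabolite LOD quantile
  tab$below_lod <- FALSE
  tab$lod <- NA_real_
  for (met in metabolites) {
    sel <- tab$metabolite == met
    lod <- if (lod_quantile > 0)
      stats::quantile(tab$concentration[sel], lod_quantile, names = FALSE)
    else 0
    tab$lod[sel] <- lod
    cens <- sel & tab$concentration < lod
    tab$below_lod[cens] <- TRUE
    tab$concentration[cens] <- NA_real_
  }
  tab$missing <- FALSE
  if (missing_fraction > 0) {
    mar <- !tab$below_lod &
      stats::runif(nrow(tab)) < missing_fraction
    tab$missing[mar] <- TRUE
    tab$concentration[mar] <- NA_real_
  }
  rownames(tab) <- NULL
  list(table = metabolite_table(tab),
       truth = list(effects = effects, rho = rho, sigma = sigma,
                    lod_quantile = lod_quantile,
                    missing_fraction = missing_fraction,
                    baseline_log2 = base,
                    group_scores = c(CN = 0, ASY = 1, AD = 2)))
}

#' Default pathway-cluster map for the simulated metabolite panel
#' @return Data frame: `metabolite`, `cluster`.
#' @export
default_cluster_map <- function() {
  data.frame(
    metabolite = c("lanosterol", "cholesterol", "desmosterol",
                   "ohc24s", "ohc7a",
                   "ketochol7", "ohc7b", "epoxychol5a6a"),
    cluster = c(rep("de novo cholesterol biosynthesis", 3),
                rep("cholesterol catabolism (enzymatic)", 2),
                rep("cholesterol catabolism (non-enzymatic)", 3)))
}
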