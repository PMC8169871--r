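# small constructed table: 2 subjects x 2 regions x metabolites
tiny_metab_table <- function() {
  grid <- expand.grid(subject = c("p1", "p2", "p3", "p4"),
                      region = c("ITG", "MFG"),
                      metabolite = c("m1", "m2"),
                      stringsAsFactors = FALSE)
  grid$cohort <- ifelse(grid$subject %in% c("p1", "p2"), "A", "B")
  grid$group <- rep(c("CN", "AD"), length.out = nrow(grid))
  grid$sex <- "F"
  grid$age <- 85
  grid$concentration <- seq(1, 2, length.out = nrow(grid))
  grid$below_lod <- FALSE
  grid$lod <- 0.8
  grid$missing <- FALSE
  metabolite_table(grid)
}

test_that("the 30% missingness rule drops strictly above threshold", {
  # one metabolite, one cohort x region stratum with 100 records
  mk <- function(n_absent) {
    df <- data.frame(subject = sprintf("p%03d", 1:100), cohort = "A",
                     region = "ITG", metabolite = "m", concentration = 1,
                     below_lod = FALSE, lod = 0.5, missing = FALSE,
                     group = rep(c("CN", "AD"), 50), sex = "F", age = 80)
    if (n_absent > 0) {
      df$below_lod[seq_len(n_absent)] <- TRUE
      df$concentration[seq_len(n_absent)] <- NA
    }
    metabolite_table(df)
  }
  expect_equal(nrow(qc_filter(mk(31))), 0)          # 31% missing: excluded
  expect_equal(nrow(qc_filter(mk(30))), 100)        # exactly 30%: retained
  out <- qc_filter(mk(0))
  expect_equal(nrow(out), 100)                      # no missingness: identity
  expect_equal(nrow(attr(out, "exclusions")), 0)
  excl <- attr(qc_filter(mk(31)), "exclusions")
  expect_equal(excl$missing_fraction, 0.31)
})

test_that("a stratum breach excludes the metabolite from all analyses", {
  tab <- tiny_metab_table()
  # make m1 fully missing in cohort A x ITG only
  hit <- tab$metabolite == "m1" & tab$cohort == "A" & tab$region == "ITG"
  tab$missing[hit] <- TRUE
  tab$concentration[hit] <- NA
  out <- qc_filter(metabolite_table(as.data.frame(tab)))
  expect_false("m1" %in% out$metabolite)
  expect_true("m2" %in% out$metabolite)
})

test_that("below-LOD concentrations are imputed at half the threshold", {
  tab <- tiny_metab_table()
  tab$below_lod[1] <- TRUE
  tab$concentration[1] <- NA
  tab$lod[1] <- 0.8
  out <- impute_lod(tab)
  expect_equal(out$concentration[1], 0.4)
  expect_equal(out$concentration[-1], tab$concentration[-1])
  # no censored records: identity
  expect_identical(impute_lod(tiny_metab_table()), tiny_metab_table())
  # metabolite-specific thresholds imputed independently
  tab2 <- tiny_metab_table()
  tab2$below_lod[c(1, 9)] <- TRUE
  tab2$concentration[c(1, 9)] <- NA
  tab2$lod[1] <- 0.8
  tab2$lod[9] <- 0.2
  out2 <- impute_lod(tab2)
  expect_equal(out2$concentration[c(1, 9)], c(0.4, 0.1))
  # censored record without a threshold is an error
  tab3 <- tiny_metab_table()
  tab3$below_lod[2] <- TRUE
  tab3$concentration[2] <- NA
  tab3$lod[2] <- NA
  expect_error(impute_lod(tab3), "LOD threshold")
})

test_that("filtering and imputation are independent of metabolite labels", {
  sim <- simulate_metabolomics(seed = 13)
  tab <- sim$table
  relabel <- setNames(paste0("X_", sort(unique(tab$metabolite))),
                      sort(unique(tab$metabolite)))
  tab2 <- tab
  tab2$metabolite <- unname(relabel[tab$metabolite])
  out1 <- impute_lod(qc_filter(tab))
  out2 <- impute_lod(qc_filter(tab2))
  expect_equal(out2$concentration, out1$concentration)
  expect_identical(unname(relabel[out1$metabolite]), out2$metabolite)
})

test_that("planted region-specific slopes are recovered", {
  eff <- data.frame(metabolite = "lan", region = "MFG", beta = -0.5)
  n50 <- list(A = c(CN = 17, ASY = 16, AD = 17),
              B = c(CN = 17, ASY = 16, AD = 17))
  betas <- ses <- numeric(40)
  for (r in 1:40) {
    sim <- simulate_metabolomics(n_per_group = n50, effects = eff,
                                 metabolites = "lan", rho = 0.5, sigma = 0.45,
                                 lod_quantile = 0, missing_fraction = 0,
                                 seed = 5000 + r)
    fit <- fit_metabolite_models(sim$table, "group", include_cohort = TRUE)
    row <- fit[fit$region == "MFG", ]
    betas[r] <- row$beta
    ses[r] <- row$se
  }
  expect_lt(abs(mean(betas) + 0.5), 0.15)
  cover <- mean(abs(betas + 0.5) < qt(0.975, df = 99) * ses)
  expect_gt(cover, 0.85)
  # the null region stays null
  fit <- fit_metabolite_models(
    simulate_metabolomics(n_per_group = n50, effects = eff,
                          metabolites = "lan", lod_quantile = 0,
                          missing_fraction = 0, seed = 77)$table,
    "group", include_cohort = TRUE)
  expect_lt(abs(fit$beta[fit$region == "ITG"]), 0.3)
})

test_that("degenerate designs and bad concentrations are rejected", {
  tab <- tiny_metab_table()
  one_group <- as.data.frame(tab)
  one_group$group <- "AD"
  expect_error(fit_metabolite_models(metabolite_table(one_group), "group"),
               "single level")
  neg <- as.data.frame(tab)
  neg$concentration[1] <- -1
  expect_error(
    fit_metabolite_models(suppressWarnings(metabolite_table(neg)), "group"),
    "positive|log2")
})

test_that("pathology models use the continuous scores", {
  eff <- data.frame(metabolite = "lan", region = "ITG", beta = -0.2)
  sim <- simulate_metabolomics(effects = eff, metabolites = "lan",
                               lod_quantile = 0, missing_fraction = 0,
                               seed = 61)
  fit_c <- fit_metabolite_models(sim$table, "cerad", include_cohort = TRUE)
  fit_b <- fit_metabolite_models(sim$table, "braak", include_cohort = TRUE)
  expect_identical(unique(fit_c$predictor), "cerad")
  # CERAD rises with disease severity, so the planted negative disease
  # slope surfaces as a negative pathology slope
  expect_lt(fit_c$beta[fit_c$region == "ITG"], 0)
  expect_lt(fit_b$beta[fit_b$region == "ITG"], 0)
})

test_that("convergent associations pool and divergent ones stay cohort-specific", {
  res_a <- data.frame(metabolite = c("m1", "m2"), region = "ITG",
                      predictor = "group", beta = c(-0.2, 0.1),
                      se = 0.1, p = 0.1, n_subjects = 20, scope = "A")
  res_b <- data.frame(metabolite = c("m1", "m2"), region = "ITG",
                      predictor = "group", beta = c(-0.3, -0.1),
                      se = 0.1, p = 0.1, n_subjects = 20, scope = "B")
  sim <- simulate_metabolomics(
    effects = data.frame(metabolite = c("m1", "m2"), region = "ITG",
                         beta = c(-0.25, 0)),
    metabolites = c("m1", "m2"), lod_quantile = 0, missing_fraction = 0,
    seed = 3)
  pooled <- convergence_pool(res_a, res_b, sim$table, "group")
  expect_true(all(pooled$pooled$metabolite == "m1"))
  expect_true(all(pooled$pooled$scope == "pooled"))
  expect_true(all(pooled$cohort_specific$metabolite == "m2"))
  expect_identical(sort(unique(pooled$cohort_specific$scope)), c("A", "B"))
  # an exactly-zero slope counts as concordant with either sign
  res_b0 <- res_b
  res_b0$beta <- c(-0.3, 0)
  pooled0 <- convergence_pool(res_a, res_b0, sim$table, "group")
  expect_setequal(unique(pooled0$pooled$metabolite), c("m1", "m2"))
  # a metabolite seen in one cohort only is flagged cohort-specific
  pooled1 <- convergence_pool(res_a[1, ], res_b, sim$table, "group")
  only <- pooled1$cohort_specific
  expect_true(any(only$metabolite == "m2" & only$only_one_cohort))
})

test_that("pooled analyses never use fewer subjects than either cohort", {
  sim <- simulate_metabolomics(seed = 29)
  tab <- impute_lod(qc_filter(sim$table))
  fa <- fit_metabolite_models(
    metabolite_table(as.data.frame(tab)[tab$cohort == "BLSA", ]), "group")
  fb <- fit_metabolite_models(
    metabolite_table(as.data.frame(tab)[tab$cohort == "ROS", ]), "group")
  pooled <- convergence_pool(fa, fb, tab, "group")$pooled
  for (i in seq_len(nrow(pooled))) {
    na <- fa$n_subjects[fa$metabolite == pooled$metabolite[i] &
                          fa$region == pooled$region[i]]
    nb <- fb$n_subjects[fb$metabolite == pooled$metabolite[i] &
                          fb$region == pooled$region[i]]
    expect_gte(pooled$n_subjects[i], max(na, nb))
  }
})

test_that("cluster FDR adjusts within clusters independently", {
  res <- data.frame(
    metabolite = c("a1", "a2", "a3", "a4", "b1"),
    region = "ITG", predictor = "group", scope = "A",
    p = c(0.01, 0.02, 0.03, 0.04, 0.2))
  cmap <- data.frame(metabolite = c("a1", "a2", "a3", "a4", "b1"),
                     cluster = c(rep("biosynthesis", 4), "catabolism"))
  out <- cluster_fdr(res, cmap)
  expect_equal(out$q[1:4], rep(0.04, 4))  # BH by hand
  expect_equal(out$q[5], 0.2)             # singleton cluster: q = p
  # perturbing one cluster leaves the other unchanged
  res2 <- res
  res2$p[1] <- 0.0001
  out2 <- cluster_fdr(res2, cmap)
  expect_equal(out2$q[5], out$q[5])
  expect_error(cluster_fdr(rbind(res, data.frame(
    metabolite = "zz", region = "ITG", predictor = "group", scope = "A",
    p = 0.5)), cmap), "without a cluster")
  cmap_dup <- rbind(cmap, data.frame(metabolite = "a1", cluster = "catabolism"))
  expect_error(cluster_fdr(res, cmap_dup), "more than one")
})

test_that("metabolite tables round-trip through TSV", {
  sim <- simulate_metabolomics(seed = 41)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolites(sim$table, path)
  back <- load_metabolites(path)
  expect_equal(nrow(back), nrow(sim$table))
  expect_equal(back$concentration, sim$table$concentration, tolerance = 1e-9)
  expect_identical(back$below_lod, sim$table$below_lod)
})
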