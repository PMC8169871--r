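test_that("pooled thresholds are linear-interpolation quantiles", {
  th <- pooled_thresholds(matrix(1:8, nrow = 2))
  expect_equal(th$q25, 2.75)
  expect_equal(th$q75, 6.25)
  # constant matrix: degenerate spread, everything later stays moderate
  thc <- pooled_thresholds(matrix(3, 4, 4))
  expect_equal(thc$q25, 3)
  expect_equal(thc$q75, 3)
  expect_error(pooled_thresholds(numeric(0)), "empty")
  # at most a quarter of pooled values strictly exceed q75 (up to the
  # one-observation discreteness of interpolated sample quantiles)
  set.seed(1)
  for (i in 1:5) {
    v <- rnorm(sample(10:200, 1))
    th <- pooled_thresholds(v)
    expect_lte(mean(v > th$q75), 0.25 + 1 / length(v))
    expect_lte(mean(v < th$q25), 0.25 + 1 / length(v))
  }
})

test_that("reaction expression maps GPRs by max/min and skips missing genes", {
  m <- metabolic_model(
    data.frame(id = "A"),
    list(reaction("iso", c(A = 1), 0, 10, gpr = "g1 or g2"),
         reaction("cplx", c(A = -1), 0, 10, gpr = "g1 and g2"),
         reaction("nested", c(A = -1), 0, 10, gpr = "g1 and (g2 or g3)"),
         reaction("nogpr", c(A = 1), 0, 10),
         reaction("orphan", c(A = -1), 0, 10, gpr = "g9")))
  vals <- c(g1 = 2, g2 = 5, g3 = 4)
  expect_message(rx <- reaction_expression(m, vals), "orphan")
  expect_equal(rx[["iso"]], 5)
  expect_equal(rx[["cplx"]], 2)
  expect_equal(rx[["nested"]], min(2, max(5, 4)))
  expect_true(is.na(rx[["nogpr"]]))
  expect_true(is.na(rx[["orphan"]]))
})

test_that("state assignment uses strict thresholds and leaves gaps moderate", {
  th <- list(q25 = 2.75, q75 = 6.25)
  rv <- c(r_hi = 7, r_edge = 6.25, r_mid = 5, r_lo = 1, r_edge2 = 2.75,
          r_na = NA_real_)
  st <- assign_states(rv, th)
  expect_identical(st$high, "r_hi")
  expect_identical(st$low, "r_lo")
  expect_length(intersect(st$high, st$low), 0)
})

test_that("solve_imat handles the three-reaction chain cases", {
  m <- chain_model()
  # high interior reaction: pushed to carry at least epsilon
  sol <- solve_imat(m, list(high = "r_ab", low = character(0)), epsilon = 1)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 1L)
  expect_gte(sol$flux[["r_ab"]], 1)
  # mass balance forces the exchanges to match: all three called active
  expect_identical(unname(call_activity(sol)), c(1L, 1L, 1L))
  # low interior reaction, nothing forced: all-zero flux is optimal
  sol0 <- solve_imat(m, list(high = character(0), low = "r_ab"), epsilon = 1)
  expect_equal(sol0$objective, 1L)
  expect_equal(unname(sol0$flux), c(0, 0, 0))
  # series conflict: upstream high vs downstream low, only one satisfiable
  solc <- solve_imat(m, list(high = "EX_in", low = "r_ab"), epsilon = 1)
  expect_equal(solc$objective, 1L)
  expect_equal(enumerate_optimum(m, list(high = "EX_in", low = "r_ab")), 1L)
  # empty states: objective zero
  expect_equal(solve_imat(m, list(high = character(0), low = character(0)))$objective, 0L)
  expect_equal(enumerate_optimum(m, list(high = character(0), low = character(0))), 0L)
})

test_that("activity calling thresholds flux magnitude", {
  m <- chain_model()
  sol <- solve_imat(m, list(high = "r_ab", low = character(0)), epsilon = 1)
  sol$flux <- setNames(c(1.0, 0.0, 1e-9), names(sol$flux))
  expect_identical(unname(call_activity(sol, tol = 1e-6)), c(1L, 0L, 0L))
  sol$status <- "infeasible"
  expect_error(call_activity(sol), "optimal")
})

test_that("solver matches the exhaustive oracle on random toy instances", {
  # a further 200 instances run in the acceptance suite; this is the
  # fast per-module check
  for (seed in 1:25) {
    set.seed(seed)
    inst <- random_imat_instance(seed)
    sol <- solve_imat(inst$model, inst$states, epsilon = 1)
    expect_equal(sol$objective,
                 enumerate_optimum(inst$model, inst$states, epsilon = 1),
                 info = paste("seed", seed))
  }
})

test_that("returned fluxes satisfy mass balance, bounds and media constraints", {
  for (seed in 1:10) {
    set.seed(seed)
    inst <- random_imat_instance(seed + 100)
    sol <- solve_imat(inst$model, inst$states, epsilon = 1)
    S <- stoichiometric_matrix(inst$model)
    v <- sol$flux[colnames(S)]
    expect_lt(max(abs(S %*% v)), 1e-6)
    fb <- flux_bounds(inst$model)
    expect_true(all(v >= fb$lower_bound - 1e-9))
    expect_true(all(v <= fb$upper_bound + 1e-9))
    expect_gte(v[["EX_glc"]], 0.01)
    expect_gte(v[["EX_o2"]], 0.01)
    expect_gte(v[["SINK_macro"]], 0.0001)
  }
})

test_that("objective is monotone in the high set and scale invariant", {
  set.seed(99)
  for (i in 1:8) {
    inst <- random_imat_instance(i + 300, max_states = 6)
    obj <- solve_imat(inst$model, inst$states, epsilon = 1)$objective
    # adding one more high reaction changes the optimum by at most +1
    free <- setdiff(reaction_ids(inst$model),
                    c(inst$states$high, inst$states$low))
    if (length(free)) {
      states2 <- inst$states
      states2$high <- c(states2$high, free[1])
      obj2 <- solve_imat(inst$model, states2, epsilon = 1)$objective
      expect_gte(obj2, obj)
      expect_lte(obj2, obj + 1L)
    }
    # scaling all bounds and epsilon by a common factor leaves it unchanged
    scaled <- inst$model
    for (rid in reaction_ids(scaled)) {
      scaled$reactions[[rid]]$lower_bound <- scaled$reactions[[rid]]$lower_bound * 10
      scaled$reactions[[rid]]$upper_bound <- scaled$reactions[[rid]]$upper_bound * 10
    }
    expect_equal(solve_imat(scaled, inst$states, epsilon = 10)$objective, obj)
  }
})

test_that("epsilon larger than every bound forbids forward satisfaction", {
  m <- chain_model(bound = 10)
  sol <- solve_imat(m, list(high = c("EX_in", "r_ab"), low = character(0)),
                    epsilon = 50)
  expect_equal(sol$objective, 0L)
})

test_that("infeasible constraint systems are reported", {
  m <- metabolic_model(
    data.frame(id = "A"),
    list(reaction("must_in", c(A = 1), 2, 10),
         reaction("no_out", c(A = -1), 0, 1)))
  expect_error(solve_imat(m, list(high = character(0), low = character(0))),
               "infeasible")
})

test_that("robust activity calling is at least as permissive as the vertex call", {
  for (seed in 1:5) {
    inst <- random_imat_instance(seed + 700)
    sol <- solve_imat(inst$model, inst$states, epsilon = 1)
    vert <- call_activity(sol, tol = 1e-6)
    rob <- call_activity_robust(inst$model, sol)
    active_vertex <- names(vert)[vert == 1 & abs(sol$flux) >= 1]
    expect_true(all(rob[active_vertex] == 1L))
  }
})

test_that("per-sample activity prediction recovers planted branch shutdown", {
  m <- mini_cholesterol_fixture()
  sim <- simulate_expression(m, n_per_group = 8,
                             planted_genes = c("CYP46A1", "HSD3B7"),
                             delta = -5, seed = 21)
  act <- predict_activity(m, sim$expr, residualize = c("sex", "age"))
  expect_identical(dim(act$activity), c(12L, 16L))
  expect_true(all(act$activity %in% 0:1))
  ad <- sim$expr$metadata$sample[sim$expr$metadata$group == "AD"]
  cn <- sim$expr$metadata$sample[sim$expr$metadata$group == "CN"]
  expect_lt(mean(act$activity["r_cyp46a1", ad]),
            mean(act$activity["r_cyp46a1", cn]))
})

test_that("activity matrices round-trip through TSV with provenance", {
  m <- mini_cholesterol_fixture()
  sim <- simulate_expression(m, n_per_group = 3,
                             planted_genes = "CYP46A1", delta = -5, seed = 3)
  act <- predict_activity(m, sim$expr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity(act, path)
  act2 <- read_activity(path)
  expect_identical(act2$activity, act$activity)
  expect_equal(act2$epsilon, act$epsilon)
  expect_equal(act2$tol, act$tol)
})

test_that("LP feasibility agrees with constructed ground truth", {
  # feasible by construction: S rows orthogonal to a known interior point
  set.seed(123)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    mrow <- sample(2:4, 1)
    vstar <- runif(n, -5, 5)
    S <- t(vapply(seq_len(mrow), function(j) {
      w <- rnorm(n)
      w - sum(w * vstar) / sum(vstar^2) * vstar
    }, numeric(n)))
    dimnames(S) <- list(paste0("m", seq_len(mrow)), paste0("r", seq_len(n)))
    lb <- setNames(vstar - runif(n, 0.1, 2), colnames(S))
    ub <- setNames(vstar + runif(n, 0.1, 2), colnames(S))
    res <- sterolflux:::lp_flux_feasible(S, lb, ub)
    expect_true(res$feasible)
    expect_lt(max(abs(S %*% res$v)), 1e-6)
    expect_true(all(res$v >= lb - 1e-9 & res$v <= ub + 1e-9))
  }
  # structurally infeasible: forced production into a dead end
  S2 <- matrix(1, 1, 1, dimnames = list("A", "rx"))
  expect_false(sterolflux:::lp_flux_feasible(
    S2, setNames(1, "rx"), setNames(10, "rx"))$feasible)
})
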