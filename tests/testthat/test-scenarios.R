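test_that("flux LPs on a hand-checkable box polytope", {
  ## {0 <= x,y <= 1, x + y <= 1.5} via a slack-flux system
  ts <- slack_system(R = matrix(c(1, 1), 1), rhs = 1.5, up = c(1, 1))
  r <- solve_flux_lp(ts$system, ts$b, ts$bounds, "x1", "max")
  expect_equal(r$status, "optimal")
  expect_equal(r$value, 1)
  expect_equal(unname(r$fluxes["x1"]), 1)
  ## per-flux extremes agree with the brute-force vertex oracle
  V <- brute_vertices(matrix(c(1, 1), 1), 1.5, c(1, 1))
  for (j in 1:2) {
    expect_equal(solve_flux_lp(ts$system, ts$b, ts$bounds, paste0("x", j), "min")$value,
                 min(V[, j]))
    expect_equal(solve_flux_lp(ts$system, ts$b, ts$bounds, paste0("x", j), "max")$value,
                 max(V[, j]))
  }
  ## every enumerated cluster is an oracle vertex
  tab <- enumerate_scenarios(ts$system, ts$b, ts$bounds, objectives = c("x1", "x2"))
  for (k in seq_len(tab$n_clusters)) {
    pt <- tab$vectors[match(k, tab$records$cluster), c("x1", "x2")]
    expect_true(any(apply(V, 1, function(v) all(abs(v - pt) < 1e-7))))
  }
})

test_that("infeasible phenotypes produce a structured diagnosis", {
  st <- study_setup()
  ## an ATP window no flux distribution can reach
  ph <- phenotype_constraints(yxatp_range = c(1, 1.2))
  bad <- build_bounds(st$system, ph)
  r <- solve_flux_lp(st$system, compute_load_vector(mu = 0.2), bad, "r_TCA", "min")
  expect_match(r$status, "infeasible")
  expect_match(r$status, "ATP window")
})

test_that("calibration recovers a known load vector from noiseless vertices", {
  st <- study_setup()
  truth <- compute_load_vector(mu = 0.2)
  tab <- enumerate_scenarios(st$system, truth, st$bounds)
  vecs <- lapply(seq_len(min(4, nrow(tab$vectors))), function(i) tab$vectors[i, ])
  fit <- calibrate_loads(st$system, st$bounds, printed = vecs, anchors = NULL,
                         use_prior = FALSE)
  b_true <- load_as_b(truth, st$system)
  b_fit <- load_as_b(fit, st$system)
  expect_lt(max(abs(b_fit - b_true)), 1e-6)
  expect_lt(attr(fit, "max_residual"), 1e-6)
})

test_that("calibrated engine reproduces the printed scenario table", {
  st <- study_setup()
  cal <- calibrate_loads(st$system, st$bounds)
  expect_lt(attr(cal, "max_residual"), 0.1)   # no fallback triggered
  tab <- classify_co_optimal(enumerate_scenarios(st$system, cal, st$bounds))
  expect_equal(tab$n_clusters, 5L)
  ## minimizing TCA flux is the biomass-rate-maximal solution with Y_X/S 0.45
  r <- solve_flux_lp(st$system, cal, st$bounds, "r_TCA", "min")
  expect_equal(round(r$yxs, 2), 0.45)
  expect_equal(round(r$yxatp, 1), 10)
  bm <- biomass_max_equivalence(st$system, cal, st$bounds)
  expect_true(attr(bm, "same_cluster_as_min_tca"))
  ## tolerance = Inf marks every objective co-optimal everywhere
  everything <- classify_co_optimal(tab, tol = Inf)
  expect_true(all(vapply(everything$co_optimal, length, 0L) == nrow(tab$records)))
})

test_that("FVA sandwich holds on random feasible points", {
  st <- study_setup()
  cal <- calibrate_loads(st$system, st$bounds)
  tab <- enumerate_scenarios(st$system, cal, st$bounds)
  lo <- vapply(colnames(tab$vectors), function(f)
    tab$optima[paste("MIN", f)] %||% -Inf, 0)
  hi <- vapply(colnames(tab$vectors), function(f)
    tab$optima[paste("MAX", f)] %||% Inf, 0)
  set.seed(42)
  reg <- registry_fluxes(st$system)
  b <- load_as_b(cal, st$system)
  for (i in 1:50) {
    w <- stats::rexp(nrow(tab$vectors))
    pt <- colSums(tab$vectors * (w / sum(w)))   # convex combination is feasible
    expect_lt(max(abs(st$system$A %*% pt - b)), 1e-6 * max(1, max(abs(b))))
    expect_true(all(pt[reg] >= lo[reg] - 1e-7))
    expect_true(all(pt[reg] <= hi[reg] + 1e-7))
  }
})

test_that("NADPH breakdown bookkeeping", {
  st <- study_setup()
  v <- stats::setNames(rep(0, length(st$system$flux_order)), st$system$flux_order)
  ## HMP = 1 (2 NADPH), one TCA entry (1), one malic-enzyme unit (1)
  v[c("r_HMP", "r_TCA", "r_ME")] <- 1
  fr <- nadph_breakdown(v, st$system)
  expect_equal(unname(fr[c("HMP", "ICDH", "malic_enzyme")]), c(0.5, 0.25, 0.25))
  expect_equal(sum(fr), 1)
  v["r_ME"] <- 0
  expect_equal(unname(nadph_breakdown(v, st$system)["malic_enzyme"]), 0)
  v[] <- 0
  expect_error(nadph_breakdown(v, st$system), "zero total NADPH")
})

test_that("tight-acetate flux ranges sit inside the loose-acetate ranges", {
  st <- study_setup()
  cal <- calibrate_loads(st$system, st$bounds)
  loose <- build_bounds(st$system, phenotype_constraints(acetate_mode = "loose"))
  tab_t <- enumerate_scenarios(st$system, cal, st$bounds)
  tab_l <- enumerate_scenarios(st$system, cal, loose)
  for (f in registry_fluxes(st$system)) {
    expect_lte(tab_l$optima[[paste("MIN", f)]], tab_t$optima[[paste("MIN", f)]] + 1e-7)
    expect_gte(tab_l$optima[[paste("MAX", f)]], tab_t$optima[[paste("MAX", f)]] - 1e-7)
  }
  ## the looser byproduct window genuinely widens at least one flux range
  widened <- any(vapply(registry_fluxes(st$system), function(f)
    tab_l$optima[[paste("MAX", f)]] > tab_t$optima[[paste("MAX", f)]] + 1e-6, TRUE))
  expect_true(widened)
})
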