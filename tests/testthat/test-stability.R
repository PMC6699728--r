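p95 <- fitness_params(eps_A = 0.95, eps_B = 0.95, eps_Rev = 0.96)

test_that("monomorphic states are fixed points of the reduced haplotype map", {
  m2 <- reduced_model("two_allele", p95)
  wild <- c(1, 0, 0, 0)
  expect_equal(reduced_step(wild, m2), wild)
  full <- c(0, 0, 0, 1)
  expect_equal(reduced_step(full, m2), full)
})

test_that("the reduced model reproduces the full genotype model's allele dynamics at m = 0", {
  m2 <- reduced_model("two_allele", p95)
  x <- c(0.5, 0, 0, 0.5)                    # gamete pool of a 1:1 release
  tr <- run_scenario(scenario_config(params = p95, m = 0, generations = 80L))
  for (t in 0:80) {
    af <- underdrive:::reduced_allele_freqs(x, m2)
    expect_equal(unname(af$A[["A"]]), tr$A[t + 1], tolerance = 1e-10)
    expect_equal(unname(af$B[["b"]]), tr$b[t + 1], tolerance = 1e-10)
    x <- reduced_step(x, m2)
  }
})

test_that("equilibrium search finds the wild-type and introgression equilibria", {
  m2 <- reduced_model("two_allele", p95)
  eq <- find_equilibria(m2)
  pts <- lapply(eq, `[[`, "point")
  is_wild_eq <- vapply(pts, function(x) x[[1]] > 1 - 1e-8, logical(1))
  expect_true(any(is_wild_eq))
  # interior introgression equilibrium: most mass on the double-construct
  # haplotype but a residual wild fraction
  is_intro <- vapply(pts, function(x) x[[4]] > 0.5 && x[[1]] > 1e-6 &&
                       x[[1]] < 0.5, logical(1))
  expect_true(any(is_intro))
  intro <- eq[[which(is_intro)[1]]]
  expect_lt(intro$residual, 1e-10)
  expect_equal(intro$classification, "stable")
  # starting at wild-type converges there immediately
  eq_w <- find_equilibria(m2, starts = list(c(1, 0, 0, 0)))
  expect_lt(eq_w[[1]]$residual, 1e-10)
})

test_that("at eps = 1 a symmetric interior threshold point is an unstable fixed point", {
  m1 <- reduced_model("two_allele", fitness_params(eps_A = 1, eps_B = 1))
  # brute-force residual scan over symmetric linkage-equilibrium states,
  # then polish the best grid candidate
  best <- NULL
  for (w in seq(0.05, 0.95, by = 0.05)) {
    for (cc in seq(0, (1 - w) / 2, by = 0.025)) {
      x <- c(w, cc, cc, 1 - w - 2 * cc)
      r <- tryCatch(max(abs(reduced_step(x, m1) - x)), error = function(e) NA)
      if (!is.na(r) && (is.null(best) || r < best$r)) best <- list(x = x, r = r)
    }
  }
  eq <- find_equilibria(m1, starts = list(best$x))
  interior <- Filter(function(e) all(e$point > 0.05), eq)
  expect_gte(length(interior), 1L)
  expect_equal(interior[[1]]$classification, "unstable")
  expect_equal(interior[[1]]$point[[2]], interior[[1]]$point[[3]],
               tolerance = 1e-8)
})

test_that("stability classification matches the known equilibrium structure", {
  for (eps in c(0.5, 0.9, 0.95, 1.0)) {
    m2 <- reduced_model("two_allele", fitness_params(eps_A = eps, eps_B = eps))
    wild <- classify_stability(m2, c(1, 0, 0, 0))
    expect_equal(wild$classification, "stable")
  }
  # introgression equilibrium of the two-allele model at eps = 0.95
  m2 <- reduced_model("two_allele", p95)
  eq <- find_equilibria(m2, starts = list(c(0.1, 0, 0, 0.9)))
  intro <- eq[[which.max(vapply(eq, function(e) e$point[[4]], numeric(1)))]]
  expect_equal(intro$classification, "stable")
  # the same point is destabilized by introducing the free-suppressor allele
  m3 <- reduced_model("three_allele", p95)
  p3 <- numeric(9)
  p3[c(1, 2, 4, 5)] <- intro$point
  r3 <- classify_stability(m3, p3)
  expect_equal(r3$classification, "unstable")
  expect_error(classify_stability(m2, c(0.6, 0.1, 0.1, 0.2)), "fixed point")
})

test_that("spectral-radius calls agree with perturbation simulations", {
  set.seed(41)
  m2 <- reduced_model("two_allele", p95)
  wild <- classify_stability(m2, c(1, 0, 0, 0))
  chk <- stability_by_perturbation(m2, c(1, 0, 0, 0), n = 50, steps = 2000)
  expect_equal(chk$consistent_with, wild$classification)
  eq <- find_equilibria(m2, starts = list(c(0.1, 0, 0, 0.9)))
  intro <- eq[[which.max(vapply(eq, function(e) e$point[[4]], numeric(1)))]]
  chk2 <- stability_by_perturbation(m2, unname(intro$point), n = 50,
                                    steps = 2000)
  expect_equal(chk2$consistent_with, "stable")
  m3 <- reduced_model("three_allele", p95)
  p3 <- numeric(9)
  p3[c(1, 2, 4, 5)] <- intro$point
  chk3 <- stability_by_perturbation(m3, p3, n = 20, steps = 2000)
  expect_equal(chk3$consistent_with, "unstable")
})

test_that("free-suppressor reversal succeeds when its fitness matches or beats the drive's", {
  expect_true(reversal_feasible(0.95, 0.96, 0.01)$success)
  expect_true(reversal_feasible(0.95, 0.95, 0.1)$success)
  # slight disadvantage: fails at tiny releases, succeeds at large ones
  expect_false(reversal_feasible(0.95, 0.94, 0.01)$success)
  expect_true(reversal_feasible(0.95, 0.94, 4)$success)
})

test_that("free-suppressor recovery time is insensitive to the release ratio", {
  rec <- vapply(c(0.01, 0.1, 1), function(a)
    as.numeric(reversal_feasible(0.95, 0.96, a)$recovery_generations),
    numeric(1))
  expect_true(all(is.finite(rec)))
  cv <- stats::sd(rec) / mean(rec)
  expect_lt(cv, 0.5)
})
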