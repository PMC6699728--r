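test_that("release initial conditions follow G_wild = 1/(1+alpha), G_rel = alpha/(1+alpha)", {
  s <- initialize_population(1)
  expect_equal(s$freq[genotype_index("aabb")], 0.5)
  expect_equal(s$freq[genotype_index("AABB")], 0.5)
  expect_equal(sum(s$freq), 1)
  s0 <- initialize_population(0)
  expect_equal(s0$freq[genotype_index("aabb")], 1)
  s2 <- initialize_population(2)
  expect_equal(s2$freq[genotype_index("AABB")], 2 / 3)
  expect_error(initialize_population(-0.1), "alpha")
})

test_that("monomorphic viable populations are fixed points of the step", {
  p <- fitness_params(eps_A = 0.95, eps_B = 0.95)
  wild <- population_state(replace(numeric(2025), genotype_index("aabb"), 1))
  w1 <- step_population(wild, p, m = 1e-4)   # nothing transgenic to mutate
  expect_equal(w1$freq, wild$freq)
  expect_equal(w1$generation, 1L)
  hom <- population_state(replace(numeric(2025), genotype_index("AABB"), 1))
  h1 <- step_population(hom, p, m = 0)
  expect_equal(h1$freq, hom$freq)
})

test_that("one step from a 50:50 release matches the explicit mating-pair computation", {
  p <- fitness_params(eps_A = 0.95, eps_B = 0.95)
  s <- initialize_population(1)
  s1 <- step_population(s, p, m = 0)
  expected <- oracle_step(s$freq, p, m = 0)
  expect_equal(s1$freq, expected, tolerance = 1e-12)
  # closed form for the double heterozygote: the gamete pool is half A:B,
  # half a:b, so proportional AaBb mass is 0.5 * Omega_AaBb, normalized by
  # Omega_bar = 0.25 * 0.95^4 + 0.5 * 0.95^2 + 0.25
  obar <- 0.25 * 0.95^4 + 0.5 * 0.95^2 + 0.25
  expect_equal(s1$freq[genotype_index("AaBb")], 0.5 * 0.95^2 / obar)
  expect_equal(s1$freq[genotype_index("AABB")], 0.25 * 0.95^4 / obar)
  expect_equal(s1$freq[genotype_index("aabb")], 0.25 / obar)
})

test_that("releases rescale the resident population and add the released genotype", {
  s <- initialize_population(1)
  s100 <- s
  for (t in 1:5) s100 <- step_population(s100, fitness_params(), m = 0)
  r <- release_event(5L, c("A_LC", "A_LC", "B_LC", "B_LC"), 2)
  sr <- apply_release(s100, r)
  expect_equal(sr$freq[genotype_index(c("A_LC", "A_LC", "B_LC", "B_LC"))], 2 / 3)
  expect_equal(sum(sr$freq), 1)
  expect_equal(apply_release(s100, release_event(5L, "aabb", 0))$freq, s100$freq)
  ra <- apply_release(s100, release_event(5L, "aabb", 0.01))
  expect_equal(ra$freq[genotype_index("aabb")],
               s100$freq[genotype_index("aabb")] / 1.01 + 0.01 / 1.01)
  expect_error(release_event(0L, "AAbb", 1), "viable")
})

test_that("the recursion conserves mass, kills non-viable genotypes and tracks allele sums", {
  g <- enumerate_genotypes()
  p <- fitness_params(eps_A = 0.9, eps_B = 0.92, eps_AM = 0.95, eps_BM = 0.93)
  s <- initialize_population(1.5)
  for (t in 1:25) {
    s <- step_population(s, p, m = 1e-3)
    expect_equal(sum(s$freq), 1, tolerance = 1e-12)
    expect_true(all(s$freq[!g$viable] == 0))
    af <- allele_frequencies(s)
    expect_equal(sum(af$A), 1, tolerance = 1e-12)
    expect_equal(sum(af$B), 1, tolerance = 1e-12)
  }
})

test_that("allele frequencies count allele copies per genotype", {
  het <- population_state(replace(numeric(2025), genotype_index("AaBb"), 1))
  af <- allele_frequencies(het)
  expect_equal(unname(af$A[c("a", "A")]), c(0.5, 0.5))
  expect_equal(unname(af$B[c("b", "B")]), c(0.5, 0.5))
  af0 <- allele_frequencies(initialize_population(0))
  expect_equal(unname(af0$A["a"]), 1)
  afmix <- allele_frequencies(initialize_population(1))
  expect_equal(unname(afmix$A["A"]), 0.5)
  expect_equal(unname(afmix$B["B"]), 0.5)
})

test_that("scenario runs are deterministic and respect the release schedule", {
  cfg <- scenario_config(m = 1e-5, generations = 60L,
                         releases = list(release_event(0L, "AABB", 1),
                                         release_event(30L, "aabb", 2)))
  tr1 <- run_scenario(cfg)
  tr2 <- run_scenario(cfg)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_equal(nrow(tr1), 61L)
  # the generation-30 row is the post-release state: wild-type jumps up
  expect_gt(tr1$a[31], tr1$a[30] / 3 + 2 / 3 - 0.05)
  # per-locus allele frequencies sum to one in every recorded generation
  labsA <- enumerate_alleles("A")$label
  labsB <- enumerate_alleles("B")$label
  expect_equal(rowSums(tr1[labsA]), rep(1, 61), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(tr1[labsB]), rep(1, 61), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(scenario_config(m = -1e-6), "3m")
  expect_error(scenario_config(generations = 0), "generations")
  expect_error(scenario_config(releases = list(release_event(10L, "AABB", 1),
                                               release_event(5L, "aabb", 1))),
               "strictly increasing")
  expect_error(scenario_config(releases = list(release_event(50L, "AABB", 1)),
                               generations = 10L), "horizon")
})

test_that("a supra-threshold mutation-free release reaches a stable introgression equilibrium", {
  tr <- run_scenario(scenario_config(
    params = fitness_params(eps_A = 0.95, eps_B = 0.95), m = 0,
    generations = 3000L, stop_stationary = 1e-13))
  expect_equal(attr(tr, "termination"), "stop_stationary")
  final_A <- tail(tr$A, 1)
  expect_gt(final_A, 0.9)       # transgenes persist at high frequency
  expect_lt(final_A, 1)         # interior equilibrium retains some wild
  # a small sub-threshold release is eliminated instead
  tr2 <- run_scenario(scenario_config(
    params = fitness_params(eps_A = 0.95, eps_B = 0.95), m = 0,
    releases = list(release_event(0L, "AABB", 0.2)),
    generations = 3000L, stop_stationary = 1e-13))
  expect_lt(tail(tr2$A, 1), 1e-6)
})
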