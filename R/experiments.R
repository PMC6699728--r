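# Scenario drivers and summary statistics: mutation sweeps, time-to-
# wild-type and efficacious-period metrics, reversal-threshold bisection,
# and the wild-type vs free-suppressor strategy comparison.

#' Maximum allele frequencies over a trajectory
#'
#' @param tr A trajectory from [run_scenario()].
#' @return Named numeric vector: for each of the 18 alleles, the maximum
#'   frequency attained over the recorded generations.
#' @export
max_allele_frequencies <- function(tr) {
  cols <- allele_columns(tr)
  vapply(tr[cols], max, numeric(1))
}

allele_columns <- function(tr) {
  labs <- c(enumerate_alleles("A")$label, enumerate_alleles("B")$label)
  missing <- setdiff(labs, names(tr))
  if (length(missing))
    stop("trajectory lacks allele columns: ", paste(missing, collapse = ", "))
  labs
}

#' Generations until the wild-type alleles recover
#'
#' First recorded generation at which the minimum over the two loci of
#' the wild-type allele frequency exceeds `threshold`.
#'
#' @param tr A trajectory from [run_scenario()].
#' @param threshold Frequency threshold in (0, 1).
#' @return Generation count (integer); `NA` if the threshold is never
#'   reached within the recorded horizon.
#' @export
time_to_wildtype <- function(tr, threshold = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  wild_min <- pmin(tr[["a"]], tr[["b"]])
  hit <- which(wild_min > threshold)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(tr$generation[hit[1L]])
}

#' Efficacious period of the drive's cargo
#'
#' Number of recorded generations in which, at *both* loci, the summed
#' frequency of cargo-functional transgenic alleles (the intact construct
#' plus lethal- and/or suppressor-knockout alleles that retain a working
#' cargo) exceeds `threshold`.
#'
#' @param tr A trajectory from [run_scenario()].
#' @param threshold Frequency threshold in (0, 1).
#' @return Integer generation count.
#' @export
efficacious_period <- function(tr, threshold = 0.85) {
  stopifnot(threshold > 0, threshold < 1)
  alA <- enumerate_alleles("A"); alB <- enumerate_alleles("B")
  cfA <- alA$label[!alA$is_wild & alA$functional_cargo]
  cfB <- alB$label[!alB$is_wild & alB$functional_cargo]
  sumA <- rowSums(tr[cfA]); sumB <- rowSums(tr[cfB])
  sum(sumA > threshold & sumB > threshold)
}

#' Sweep mutation rates and fitness regimes
#'
#' Runs the canonical 1:1 intact-homozygote release for each combination
#' of per-gene mutation rate and fitness regime and tabulates the summary
#' metrics: the maximum frequency reached by any mutated transgenic
#' allele, the generations until wild-type alleles exceed 0.95 (and 0.90),
#' and the efficacious period (cargo-functional transgene frequency above
#' 0.85 at both loci).
#'
#' @param m_values Mutation rates to sweep.
#' @param regimes List of `c(eps_intact, eps_mutated)` pairs applied to
#'   both loci.
#' @param generations Horizon per run.
#' @param alpha Initial release ratio.
#' @param stop_wild Early-stop wild-type frequency passed to the runs
#'   (must exceed every threshold used by the metrics).
#' @return Data frame with one row per (m, regime) combination.
#' @export
mutation_sweep <- function(m_values = c(1e-4, 1e-5, 1e-6),
                           regimes = list(c(0.95, 0.96), c(0.90, 0.92)),
                           generations = 200000L, alpha = 1,
                           stop_wild = 0.96) {
  rows <- lapply(regimes, function(rg) {
    lapply(m_values, function(m) {
      pars <- fitness_params(eps_A = rg[1], eps_B = rg[1],
                             eps_AM = rg[2], eps_BM = rg[2])
      tr <- run_scenario(scenario_config(
        params = pars, m = m,
        releases = list(release_event(0L, "AABB", alpha)),
        generations = generations, stop_wild = stop_wild))
      mx <- max_allele_frequencies(tr)
      mut_labels <- setdiff(names(mx), c("a", "A", "b", "B"))
      data.frame(m = m, eps = rg[1], eps_M = rg[2],
                 max_mutant_allele = max(mx[mut_labels]),
                 t_wild_095 = time_to_wildtype(tr, 0.95),
                 t_wild_090 = time_to_wildtype(tr, 0.90),
                 efficacious_085 = efficacious_period(tr, 0.85),
                 generations_run = max(tr$generation))
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}

# Establish a UD system: 1:1 AABB release iterated `generations` steps in
# the full genotype model. Returns the raw frequency vector.
establish_ud <- function(params, m = 0, alpha = 1, generations = 100L) {
  eng <- full_engine()
  f <- percopy_fitness(params)
  omega <- omega_vector(eng, f$A, f$B)
  mutation <- if (m > 0)
    list(MA = mutation_matrix(m, "A"), MB = mutation_matrix(m, "B"))
  G <- numeric(eng$nG)
  G[genotype_index("aabb")] <- 1 / (1 + alpha)
  G[genotype_index("AABB")] <- alpha / (1 + alpha)
  for (t in seq_len(generations)) G <- step_core(eng, G, omega, mutation)
  G
}

# Decide whether a post-release state eliminates all transgenes:
# success once the larger per-locus non-wild allele frequency drops below
# `tol` while non-increasing; failure on a stationary state that still
# carries transgenes, or at the generation cap.
reversal_outcome <- function(G, omega, mutation, tol = 1e-3,
                             cap = 50000L) {
  eng <- full_engine()
  nw <- function(G) {
    af <- engine_allele_freqs(eng, G)
    max(1 - af$A[1], 1 - af$B[1])
  }
  nw_prev <- nw(G)
  for (t in seq_len(cap)) {
    Gn <- step_core(eng, G, omega, mutation)
    nwt <- nw(Gn)
    if (nwt < tol && nwt <= nw_prev)
      return(list(success = TRUE, generations = t, state = Gn))
    if (max(abs(Gn - G)) < 1e-13)
      return(list(success = FALSE, generations = t, state = Gn))
    G <- Gn; nw_prev <- nwt
  }
  warning("reversal outcome undecided at the generation cap; treated as failure")
  list(success = FALSE, generations = cap, state = G)
}

#' Minimal release ratio that reverses an established UD system
#'
#' Establishes the drive with a 1:1 intact-homozygote release iterated
#' `release_generation` generations (mutation-free by default), applies a
#' reversal release at ratio `alpha` -- wild-type individuals (`aabb`) or
#' double-homozygous free-suppressor carriers (`A_LC A_LC B_LC B_LC`,
#' whose per-copy fitness is set to `eps_Rev`) -- and bisects on `alpha`
#' for the smallest release that eliminates all transgenic alleles (both
#' per-locus non-wild frequencies below `1e-3` and non-increasing).
#'
#' @param strategy `"wildtype"` or `"free_suppressor"`.
#' @param params A [fitness_params()] object; for the free-suppressor
#'   strategy the mutated-construct classes are assigned `eps_Rev`.
#' @param release_generation Generations of establishment before reversal.
#' @param m Per-gene mutation rate during the whole experiment.
#' @param tol Bisection tolerance on `alpha`.
#' @param alpha_min_probe Smallest ratio probed first; if it already
#'   succeeds it is returned (threshold effectively absent).
#' @param alpha_max Bracket-expansion limit; an error is signalled if no
#'   success is found at or below it.
#' @return List: `alpha` (threshold estimate, midpoint of the final
#'   bracket), `bracket` (`c(fail, succeed)`), `strategy`, `probes`
#'   (data frame of every `alpha` tried and its outcome).
#' @examples
#' \donttest{
#' reversal_threshold("wildtype",
#'   fitness_params(eps_A = 0.95, eps_B = 0.95))$alpha   # ~ 1.75
#' }
#' @export
reversal_threshold <- function(strategy = c("wildtype", "free_suppressor"),
                               params = fitness_params(),
                               release_generation = 100L, m = 0,
                               tol = 0.005, alpha_min_probe = 0.005,
                               alpha_max = 16) {
  strategy <- match.arg(strategy)
  if (strategy == "free_suppressor")
    params <- fitness_params(eps_A = params$eps_A, eps_B = params$eps_B,
                             eps_AM = params$eps_Rev, eps_BM = params$eps_Rev,
                             eps_Rev = params$eps_Rev)
  released <- switch(strategy, wildtype = "aabb",
                     free_suppressor = "A_LC A_LC B_LC B_LC")
  eng <- full_engine()
  f <- percopy_fitness(params)
  omega <- omega_vector(eng, f$A, f$B)
  mutation <- if (m > 0)
    list(MA = mutation_matrix(m, "A"), MB = mutation_matrix(m, "B"))
  G_est <- establish_ud(params, m = m, generations = release_generation)
  rel_idx <- genotype_index(released)
  probes <- data.frame(alpha = numeric(0), success = logical(0))
  try_alpha <- function(a) {
    G <- G_est / (1 + a)
    G[rel_idx] <- G[rel_idx] + a / (1 + a)
    out <- reversal_outcome(G, omega, mutation)
    probes[nrow(probes) + 1L, ] <<- list(a, out$success)
    out$success
  }
  if (try_alpha(alpha_min_probe))
    return(list(alpha = alpha_min_probe, bracket = c(0, alpha_min_probe),
                strategy = strategy, probes = probes))
  lo <- alpha_min_probe
  hi <- 0.25
  while (!try_alpha(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > alpha_max)
      stop("no successful release found for alpha <= ", alpha_max)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (try_alpha(mid)) hi <- mid else lo <- mid
  }
  list(alpha = (lo + hi) / 2, bracket = c(lo, hi), strategy = strategy,
       probes = probes)
}

#' Compare the wild-type and free-suppressor reversal strategies
#'
#' Runs the two reversal scenarios side by side in the full genotype
#' model: a 1:1 intact-homozygote UD release, then at
#' `release_generation` either a wild-type or a free-suppressor release
#' at ratio `alpha` (default 2:1). The comparison is mutation-free by
#' default so the free-suppressor release must act on its own. Recovery
#' is the first generation at which both per-locus non-wild allele
#' frequencies fall below `1e-3`.
#'
#' @param params A [fitness_params()] object (`eps_Rev` is used for the
#'   free-suppressor construct's per-copy fitness).
#' @param alpha Reversal release ratio.
#' @param release_generation Generation of the reversal release.
#' @param m Per-gene mutation rate.
#' @param generations Horizon per run.
#' @return List: `recovery` (named vector of recovery generations,
#'   measured from the initial UD release), `trajectories` (list of the
#'   two `ud_trajectory` objects).
#' @export
compare_strategies <- function(params = fitness_params(), alpha = 2,
                               release_generation = 100L, m = 0,
                               generations = 20000L) {
  run_one <- function(strategy) {
    pars <- params
    released <- "aabb"
    if (strategy == "free_suppressor") {
      pars <- fitness_params(eps_A = params$eps_A, eps_B = params$eps_B,
                             eps_AM = params$eps_Rev, eps_BM = params$eps_Rev,
                             eps_Rev = params$eps_Rev)
      released <- "A_LC A_LC B_LC B_LC"
    }
    run_scenario(scenario_config(
      params = pars, m = m,
      releases = list(release_event(0L, "AABB", 1),
                      release_event(release_generation, released, alpha)),
      generations = generations, stop_wild = 1 - 1e-3))
  }
  trs <- list(wildtype = run_one("wildtype"),
              free_suppressor = run_one("free_suppressor"))
  recovery <- vapply(trs, function(tr) {
    t <- time_to_wildtype(tr, 1 - 1e-3)
    if (is.na(t)) NA_real_ else as.numeric(t)
  }, numeric(1))
  list(recovery = recovery, trajectories = trs)
}
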