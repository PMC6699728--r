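# The discrete-generation deterministic recursion: mating via the gamete
# pool, mutation at gamete production, viability selection on offspring,
# and normalization by mean fitness -- plus scheduled release events.

#' Construct a population state
#'
#' @param freq Numeric vector of 2025 genotype frequencies (normalized to
#'   sum 1 if `normalize = TRUE`).
#' @param generation Generation counter (0 = post-release initial state).
#' @param normalize Normalize `freq` to sum 1.
#' @return An object of class `ud_population`.
#' @export
population_state <- function(freq, generation = 0L, normalize = FALSE) {
  eng <- full_engine()
  stopifnot(length(freq) == eng$nG, all(freq >= 0))
  if (normalize) freq <- freq / sum(freq)
  if (abs(sum(freq) - 1) > 1e-9)
    stop("genotype frequencies must sum to 1")
  structure(list(freq = as.numeric(freq), generation = as.integer(generation)),
            class = "ud_population")
}

#' @export
print.ud_population <- function(x, ...) {
  af <- allele_frequencies(x)
  cat(sprintf("Two-locus UD population state, generation %d\n", x$generation))
  cat(sprintf("  wild-type allele frequency: a = %.6g, b = %.6g\n",
              af$A[["a"]], af$B[["b"]]))
  cat(sprintf("  genotypes with frequency > 1e-6: %d\n",
              sum(x$freq > 1e-6)))
  invisible(x)
}

#' Initial conditions for a transgenic release
#'
#' A release at ratio `alpha` (introduced : resident) into a wild-type
#' population puts the released genotype at frequency `alpha / (1 + alpha)`
#' and wild-type homozygotes at `1 / (1 + alpha)`; all other genotypes
#' start at zero. Released individuals carry no mutations.
#'
#' @param alpha Release ratio (introduced/resident), `>= 0`.
#' @param genotype Released genotype (default the non-mutated double
#'   homozygote `"AABB"`); any form accepted by [is_viable()].
#' @return A `ud_population` at generation 0.
#' @examples
#' initialize_population(1)      # 1:1 release of AABB
#' @export
initialize_population <- function(alpha = 1, genotype = "AABB") {
  if (!is.finite(alpha) || alpha < 0) stop("release ratio alpha must be >= 0")
  eng <- full_engine()
  G <- numeric(eng$nG)
  G[genotype_index("aabb")] <- 1
  s <- population_state(G, generation = 0L)
  apply_release(s, release_event(0L, genotype, alpha))
}

#' A scheduled release event
#'
#' @param generation Generation at which the release happens; the release
#'   is applied to the state after that many steps, before the next one.
#'   Generation 0 releases define the initial condition.
#' @param genotype Released genotype (must be viable); released
#'   individuals carry no mutations.
#' @param alpha Release ratio, introduced relative to the entire resident
#'   population at the moment of release.
#' @return An object of class `ud_release`.
#' @export
release_event <- function(generation, genotype, alpha) {
  if (!is.finite(alpha) || alpha < 0) stop("release ratio alpha must be >= 0")
  idx <- genotype_index(genotype)
  if (!enumerate_genotypes()$viable[idx])
    stop("released genotype must be viable")
  structure(list(generation = as.integer(generation), genotype = genotype,
                 index = idx, alpha = alpha),
            class = "ud_release")
}

#' Apply a release to a population state
#'
#' All resident genotype frequencies are rescaled by `1 / (1 + alpha)` and
#' the released genotype gains `alpha / (1 + alpha)`.
#'
#' @param state A `ud_population`.
#' @param release A [release_event()].
#' @return The post-release `ud_population` (same generation counter).
#' @export
apply_release <- function(state, release) {
  stopifnot(inherits(state, "ud_population"), inherits(release, "ud_release"))
  a <- release$alpha
  G <- state$freq / (1 + a)
  G[release$index] <- G[release$index] + a / (1 + a)
  population_state(G, state$generation)
}

#' One generation of the full genotype recursion
#'
#' The update is: (i) the adult population emits a gamete pool by free
#' segregation of the two loci; (ii) gametes mutate independently through
#' the per-locus mutation matrices; (iii) offspring proportional genotype
#' frequencies arise by random union of two independent gametes and are
#' weighted by relative fitness (viability selection included); (iv) the
#' mean fitness of the offspring pool normalizes frequencies to sum 1.
#' Non-viable genotypes have frequency exactly 0 afterwards.
#'
#' @param state A `ud_population` (post-selection, normalized).
#' @param params A [fitness_params()] object.
#' @param m Per-gene mutation rate (ignored when `mutation` is given).
#' @param mutation Optional list with per-locus matrices `MA`, `MB` (as
#'   from [mutation_matrix()]) to avoid rebuilding them in loops.
#' @return The next-generation `ud_population`.
#' @examples
#' s <- initialize_population(1)
#' step_population(s, fitness_params(), m = 1e-6)
#' @export
step_population <- function(state, params = fitness_params(), m = 0,
                            mutation = NULL) {
  stopifnot(inherits(state, "ud_population"))
  eng <- full_engine()
  f <- percopy_fitness(params)
  omega <- omega_vector(eng, f$A, f$B)
  if (is.null(mutation) && m > 0)
    mutation <- list(MA = mutation_matrix(m, "A"), MB = mutation_matrix(m, "B"))
  G <- step_core(eng, state$freq, omega, mutation)
  population_state(G, state$generation + 1L)
}

# inner loop shared by step_population()/run_scenario(); mutation = NULL
# skips the (identity) mutation stage
step_core <- function(engine, G, omega, mutation = NULL) {
  pool <- gamete_pool(engine, G)
  if (!is.null(mutation))
    pool <- mutate_pool(pool, mutation$MA, mutation$MB, engine$nA, engine$nB)
  union_select(engine, pool, omega)
}

#' Per-locus allele frequencies of a population state
#'
#' `freq(allele) = sum_i G_i * (copies of the allele in genotype i) / 2`;
#' each locus vector sums to 1.
#'
#' @param state A `ud_population`.
#' @return List with named 9-vectors `A` and `B`.
#' @examples
#' allele_frequencies(initialize_population(1))
#' @export
allele_frequencies <- function(state) {
  stopifnot(inherits(state, "ud_population"))
  eng <- full_engine()
  af <- engine_allele_freqs(eng, state$freq)
  names(af$A) <- eng$allelesA$label
  names(af$B) <- eng$allelesB$label
  af
}

#' Scenario configuration
#'
#' Bundles everything one deterministic run needs: fitness parameters,
#' the per-gene mutation rate, the release schedule, the horizon, and
#' optional early-stopping rules. Defaults mirror the canonical mutation
#' experiment: a 1:1 release of intact double homozygotes with intact
#' constructs at 5% fitness cost and mutated constructs at 4%.
#'
#' @param params A [fitness_params()] object.
#' @param m Per-gene mutation rate per generation (`0 <= 3m <= 1`).
#' @param releases List of [release_event()]s with strictly increasing
#'   generations.
#' @param generations Horizon (number of steps to iterate), `>= 1`.
#' @param record_genotypes Also record the full 2025-genotype frequency
#'   vector each generation (column-bound; large).
#' @param stop_wild Stop early once the minimum over loci of the wild-type
#'   allele frequency exceeds this value (`NULL` = never). No further
#'   releases may be scheduled after stopping.
#' @param stop_stationary Stop early once the sup-norm change of the
#'   genotype frequency vector over one generation falls below this value
#'   and no further releases are scheduled (`NULL` = never).
#' @return An object of class `ud_scenario`.
#' @export
scenario_config <- function(params = fitness_params(), m = 1e-6,
                            releases = list(release_event(0L, "AABB", 1)),
                            generations = 10000L,
                            record_genotypes = FALSE,
                            stop_wild = NULL, stop_stationary = NULL) {
  stopifnot(inherits(params, "fitness_params"))
  if (!is.finite(m) || m < 0 || 3 * m > 1)
    stop("mutation rate must satisfy 0 <= m and 3m <= 1")
  generations <- as.integer(generations)
  if (generations < 1) stop("generations must be >= 1")
  if (!all(vapply(releases, inherits, logical(1), "ud_release")))
    stop("releases must be a list of release_event() objects")
  gens <- vapply(releases, `[[`, integer(1), "generation")
  if (length(gens) > 1 && any(diff(gens) <= 0))
    stop("release generations must be strictly increasing")
  if (any(gens > generations))
    stop("release scheduled beyond the simulation horizon")
  structure(list(params = params, m = m, releases = releases,
                 generations = generations,
                 record_genotypes = isTRUE(record_genotypes),
                 stop_wild = stop_wild, stop_stationary = stop_stationary),
            class = "ud_scenario")
}

#' Run a scenario
#'
#' Iterates the deterministic recursion over the configured horizon,
#' applying releases at their scheduled generations (a release at
#' generation t modifies the state after t steps, before step t + 1; the
#' recorded row for t is the post-release state). The run is fully
#' deterministic: identical configurations give bit-identical trajectories.
#'
#' @param config A [scenario_config()].
#' @return A data frame of class `ud_trajectory`: column `generation`,
#'   then the 18 allele-frequency columns labelled with the allele names
#'   (locus A then locus B), then 2025 `G<i>` columns if
#'   `record_genotypes`. Attributes: `config`, `final_state`
#'   (`ud_population`), `termination` (one of `"horizon"`, `"stop_wild"`,
#'   `"stop_stationary"`), `release_generations`.
#' @examples
#' tr <- run_scenario(scenario_config(m = 1e-4, generations = 200))
#' tail(tr[, c("generation", "a", "A", "b", "B")], 3)
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "ud_scenario"))
  eng <- full_engine()
  f <- percopy_fitness(config$params)
  omega <- omega_vector(eng, f$A, f$B)
  mutation <- if (config$m > 0)
    list(MA = mutation_matrix(config$m, "A"), MB = mutation_matrix(config$m, "B"))
  rel_gens <- vapply(config$releases, `[[`, integer(1), "generation")

  T_ <- config$generations
  AF <- matrix(NA_real_, T_ + 1L, eng$nA + eng$nB)
  GM <- if (config$record_genotypes) matrix(NA_real_, T_ + 1L, eng$nG)

  G <- numeric(eng$nG)
  G[genotype_index("aabb")] <- 1
  termination <- "horizon"
  t_last <- T_
  for (t in 0:T_) {
    if (t > 0) {
      Gprev <- G
      G <- step_core(eng, G, omega, mutation)
    }
    for (r in config$releases[rel_gens == t]) {
      G <- G / (1 + r$alpha)
      G[r$index] <- G[r$index] + r$alpha / (1 + r$alpha)
    }
    af <- engine_allele_freqs(eng, G)
    AF[t + 1L, ] <- c(af$A, af$B)
    if (config$record_genotypes) GM[t + 1L, ] <- G
    no_more_releases <- !any(rel_gens > t)
    if (!is.null(config$stop_wild) && no_more_releases &&
        min(af$A[1], af$B[1]) > config$stop_wild) {
      termination <- "stop_wild"; t_last <- t; break
    }
    if (!is.null(config$stop_stationary) && t > 0 && no_more_releases &&
        !any(rel_gens == t) &&
        max(abs(G - Gprev)) < config$stop_stationary) {
      termination <- "stop_stationary"; t_last <- t; break
    }
  }
  keep <- seq_len(t_last + 1L)
  tr <- data.frame(generation = keep - 1L, AF[keep, , drop = FALSE])
  names(tr) <- c("generation", eng$allelesA$label, eng$allelesB$label)
  if (config$record_genotypes) {
    gm <- as.data.frame(GM[keep, , drop = FALSE])
    names(gm) <- paste0("G", seq_len(eng$nG))
    tr <- cbind(tr, gm)
  }
  attr(tr, "config") <- config
  attr(tr, "final_state") <- population_state(G, t_last)
  attr(tr, "termination") <- termination
  attr(tr, "release_generations") <- rel_gens
  class(tr) <- c("ud_trajectory", "data.frame")
  tr
}
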