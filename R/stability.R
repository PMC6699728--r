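# Mutation-free reduced haplotype models and numerical stability analysis.
#
# The reduced models restrict the allele set at each locus to {wild-type,
# intact construct} (two-allele) or {wild-type, intact construct,
# free-suppressor} (three-allele, free suppressor = suppressor functional
# only) and iterate the exact m = 0 gamete-frequency recursion of the
# genotype model on that restricted set. The state is the gamete
# (haplotype) pool emitted by the current adults; one step is random union
# of gametes, viability selection, mean-fitness normalization, and gamete
# production by the resulting adults. Equilibria are located numerically
# and classified by the spectral radius of the Jacobian of the map in
# simplex coordinates.

#' Reduced mutation-free haplotype model
#'
#' @param type `"two_allele"` (wild + intact construct per locus) or
#'   `"three_allele"` (adds a free-suppressor allele, carrying only a
#'   functional suppressor, with per-copy fitness `eps_Rev`).
#' @param params A [fitness_params()] object; the reduced model uses
#'   `eps_A`, `eps_B` and (three-allele only) `eps_Rev`.
#' @return An object of class `ud_reduced_model` with fields `engine`,
#'   `omega`, `nH`, `haplotypes` (labels), and `wild_h` masks used for
#'   allele-frequency summaries.
#' @examples
#' reduced_model("two_allele", fitness_params(eps_A = 0.95, eps_B = 0.95))
#' @export
reduced_model <- function(type = c("two_allele", "three_allele"),
                          params = fitness_params()) {
  type <- match.arg(type)
  stopifnot(inherits(params, "fitness_params"))
  mk <- function(labels) {
    n <- length(labels)
    data.frame(label = labels,
               is_wild = c(TRUE, rep(FALSE, n - 1L)),
               functional_lethal     = c(FALSE, TRUE,  FALSE)[seq_len(n)],
               functional_suppressor = c(FALSE, TRUE,  TRUE)[seq_len(n)],
               functional_cargo      = c(FALSE, TRUE,  FALSE)[seq_len(n)],
               stringsAsFactors = FALSE)
  }
  if (type == "two_allele") {
    alA <- mk(c("a", "A")); alB <- mk(c("b", "B"))
    fA <- c(1, params$eps_A); fB <- c(1, params$eps_B)
  } else {
    alA <- mk(c("a", "A", "A_Rev")); alB <- mk(c("b", "B", "B_Rev"))
    fA <- c(1, params$eps_A, params$eps_Rev)
    fB <- c(1, params$eps_B, params$eps_Rev)
  }
  eng <- build_engine(alA, alB)
  structure(list(type = type, params = params, engine = eng,
                 omega = omega_vector(eng, fA, fB), nH = eng$nH,
                 haplotypes = haplotype_labels(eng)),
            class = "ud_reduced_model")
}

#' One generation of the reduced haplotype recursion
#'
#' Random union of two independent gametes from the pool, viability
#' selection with mean-fitness normalization, then gamete production by
#' the resulting adults (no mutation: `m = 0` throughout this module).
#'
#' @param freqs Haplotype frequency vector (length `model$nH`, sum 1).
#' @param model A [reduced_model()].
#' @return Next-generation haplotype frequency vector.
#' @export
reduced_step <- function(freqs, model) {
  stopifnot(inherits(model, "ud_reduced_model"))
  G <- union_select(model$engine, freqs, model$omega)
  gamete_pool(model$engine, G)
}

# Per-locus allele frequencies implied by a haplotype pool (the pool's
# marginals equal the emitting adults' allele frequencies when m = 0).
reduced_allele_freqs <- function(freqs, model) {
  eng <- model$engine
  Q <- matrix(freqs, nrow = eng$nB, ncol = eng$nA)
  list(A = stats::setNames(colSums(Q), eng$allelesA$label),
       B = stats::setNames(rowSums(Q), eng$allelesB$label))
}

# Map in simplex coordinates: drop the last haplotype frequency.
reduced_map_simplex <- function(model) {
  n <- model$nH
  function(x) reduced_step(c(x, 1 - sum(x)), model)[-n]
}

# Central-difference Jacobian of the simplex-coordinate map.
simplex_jacobian <- function(model, point, h = 1e-7) {
  Fm <- reduced_map_simplex(model)
  x0 <- point[-model$nH]
  n <- length(x0)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- numeric(n); e[k] <- h
    J[, k] <- (Fm(x0 + e) - Fm(x0 - e)) / (2 * h)
  }
  J
}

#' Classify the stability of a fixed point
#'
#' Computes the numerical Jacobian of the one-generation map in simplex
#' coordinates (central differences, step `1e-7`; dropping the last
#' coordinate removes the spurious unit eigenvalue of the normalization)
#' and classifies the fixed point by its spectral radius: stable if
#' `< 1`, unstable if `> 1`, marginal if within `1e-6` of 1.
#'
#' @param model A [reduced_model()].
#' @param point A fixed point of [reduced_step()] (residual `< 1e-8`
#'   required).
#' @return A list of class `ud_equilibrium`: `point`, `residual`,
#'   `spectral_radius`, `classification`.
#' @export
classify_stability <- function(model, point) {
  stopifnot(inherits(model, "ud_reduced_model"))
  resid <- max(abs(reduced_step(point, model) - point))
  if (resid >= 1e-8)
    stop("not a fixed point: residual ", format(resid), " >= 1e-8")
  J <- simplex_jacobian(model, point)
  rho <- max(Mod(eigen(J, only.values = TRUE)$values))
  cls <- if (abs(rho - 1) < 1e-6) "marginal" else if (rho < 1) "stable" else "unstable"
  structure(list(point = stats::setNames(point, model$haplotypes),
                 residual = resid, spectral_radius = rho,
                 classification = cls),
            class = "ud_equilibrium")
}

#' @export
print.ud_equilibrium <- function(x, ...) {
  cat(sprintf("Fixed point (%s): spectral radius %.8g, residual %.3g\n",
              x$classification, x$spectral_radius, x$residual))
  nz <- x$point[x$point > 1e-8]
  cat("  haplotypes:", paste(sprintf("%s = %.6g", names(nz), nz),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Locate equilibria of a reduced model
#'
#' From each start, two searches run: (i) iterate [reduced_step()] until
#' the state is (numerically) stationary, then polish by Newton's method
#' on `F(x) - x` in simplex coordinates; (ii) Newton directly from the
#' start (this also finds unstable fixed points that iteration flees).
#' Converged points (residual `< 1e-10`) are merged within `1e-8` and
#' classified.
#'
#' @param model A [reduced_model()].
#' @param starts List of haplotype frequency vectors; defaults to the
#'   simplex corners, the barycentre, and symmetric mixtures.
#' @param max_iter Iteration cap per start.
#' @return List of `ud_equilibrium` reports.
#' @examples
#' m <- reduced_model("two_allele", fitness_params(eps_A = 0.95, eps_B = 0.95))
#' eq <- find_equilibria(m)
#' sapply(eq, `[[`, "classification")
#' @export
find_equilibria <- function(model, starts = NULL, max_iter = 20000L) {
  stopifnot(inherits(model, "ud_reduced_model"))
  n <- model$nH
  if (is.null(starts)) {
    starts <- lapply(seq_len(n), function(k) { v <- numeric(n); v[k] <- 1; v })
    starts <- c(starts, list(rep(1 / n, n)))
    # symmetric wild/full-construct mixtures straddling the invasion threshold
    full <- numeric(n); full[n] <- 1   # last haplotype carries both constructs
    wild <- numeric(n); wild[1] <- 1
    for (w in c(0.25, 0.5, 0.75))
      starts <- c(starts, list(w * wild + (1 - w) * full))
  }
  found <- list()
  add_point <- function(x) {
    resid <- max(abs(reduced_step(x, model) - x))
    if (!is.finite(resid) || resid >= 1e-10) return(invisible(NULL))
    for (p in found) if (max(abs(p - x)) < 1e-8) return(invisible(NULL))
    found[[length(found) + 1L]] <<- x
  }
  newton <- function(x) {
    for (it in 1:50) {
      Fx <- reduced_step(x, model)
      g <- (Fx - x)[-n]
      if (max(abs(g)) < 1e-14) break
      J <- simplex_jacobian(model, x)
      dx <- tryCatch(solve(J - diag(n - 1L), -g), error = function(e) NULL)
      if (is.null(dx) || !all(is.finite(dx))) return(NULL)
      xn <- x[-n] + dx
      x <- c(xn, 1 - sum(xn))
      if (any(x < -1e-6) || any(x > 1 + 1e-6)) return(NULL)
    }
    pmin(pmax(x, 0), 1) / sum(pmin(pmax(x, 0), 1))
  }
  for (s in starts) {
    # a start whose offspring are all non-viable (mean fitness zero) is
    # reported as non-convergent rather than failing the whole search
    tryCatch({
      x <- s / sum(s)
      for (it in seq_len(max_iter)) {
        xn <- reduced_step(x, model)
        if (max(abs(xn - x)) < 1e-13) { x <- xn; break }
        x <- xn
      }
      add_point(x)
      xp <- newton(x)
      if (!is.null(xp)) add_point(xp)
      xd <- newton(s / sum(s))
      if (!is.null(xd)) add_point(xd)
    }, error = function(e) invisible(NULL))
  }
  lapply(found, function(p) classify_stability(model, p))
}

#' Check a stability call against perturbation simulations
#'
#' Draws random perturbations of the given size around a fixed point (by
#' mixing with random points of the simplex), iterates the reduced map,
#' and records whether each trajectory returns to the fixed point or
#' diverges from it.
#'
#' @param model A [reduced_model()].
#' @param point Fixed point.
#' @param n Number of random perturbations.
#' @param size Perturbation size (mixing weight, sup-norm bound).
#' @param steps Iteration cap per perturbation.
#' @return A list: `n`, `returned`, `diverged`, `undecided`, and
#'   `consistent_with` (`"stable"` if all perturbations returned,
#'   `"unstable"` if any diverged, otherwise `"undecided"`).
#' @export
stability_by_perturbation <- function(model, point, n = 1000L, size = 1e-4,
                                      steps = 5000L) {
  stopifnot(inherits(model, "ud_reduced_model"))
  nH <- model$nH
  returned <- diverged <- shrunk <- 0L
  for (k in seq_len(n)) {
    u <- stats::rexp(nH)
    x <- (1 - size) * point + size * u / sum(u)
    d0 <- max(abs(x - point))
    d <- d0
    for (it in seq_len(steps)) {
      x <- reduced_step(x, model)
      d <- max(abs(x - point))
      if (d < size * 1e-3) { returned <- returned + 1L; break }
      if (d > size * 100) { diverged <- diverged + 1L; break }
    }
    if (d < d0) shrunk <- shrunk + 1L
  }
  list(n = n, returned = returned, diverged = diverged,
       undecided = n - returned - diverged, shrunk = shrunk,
       consistent_with = if (diverged > 0L) "unstable"
                         else if (returned == n) "stable" else "undecided")
}

#' Feasibility of free-suppressor reversal (reduced model)
#'
#' Simulates the mutation-free three-allele model from the
#' post-introgression state of an established UD system (a 1:1 release of
#' intact double homozygotes iterated `release_generation` generations in
#' the two-allele model), applies a release of double-homozygous
#' free-suppressor carriers at ratio `alpha`, and iterates until the
#' population is fully wild-type or stationary.
#'
#' @param eps Per-copy fitness of the UD constructs (both loci).
#' @param eps_rev Per-copy fitness of the free-suppressor construct.
#' @param alpha Release ratio of the free-suppressor release.
#' @param release_generation Generations of UD establishment before the
#'   reversal release.
#' @param max_generations Iteration cap after the release.
#' @param eliminate_tol Per-locus non-wild allele frequency below which
#'   (while non-increasing) the population counts as fully wild-type.
#' @return List: `success`, `recovery_generations` (generations from the
#'   reversal release to full wild-type; `NA` on failure), `final`
#'   (haplotype pool), `model`.
#' @examples
#' reversal_feasible(eps = 0.95, eps_rev = 0.96, alpha = 0.01)$success
#' @export
reversal_feasible <- function(eps, eps_rev, alpha,
                              release_generation = 100L,
                              max_generations = 200000L,
                              eliminate_tol = 1e-3) {
  stopifnot(eps >= 0, eps <= 1, eps_rev >= 0, eps_rev <= 1, alpha >= 0)
  pars <- fitness_params(eps_A = eps, eps_B = eps, eps_Rev = eps_rev)
  m2 <- reduced_model("two_allele", pars)
  # 1:1 release of AABB into wild: gamete pool half a:b, half A:B
  x <- numeric(4); x[1] <- 0.5; x[4] <- 0.5
  for (t in seq_len(release_generation)) x <- reduced_step(x, m2)
  m3 <- reduced_model("three_allele", pars)
  # embed: two-allele haplotype (x, y) -> three-allele index (x - 1) * 3 + y
  x3 <- numeric(9)
  x3[c(1, 2, 4, 5)] <- x[c(1, 2, 3, 4)]
  rev_h <- 9L  # (A_Rev, B_Rev)
  x3 <- (x3 + alpha * replace(numeric(9), rev_h, 1)) / (1 + alpha)
  nonwild <- function(v) {
    af <- reduced_allele_freqs(v, m3)
    max(1 - af$A[[1]], 1 - af$B[[1]])
  }
  nw_prev <- nonwild(x3)
  success <- FALSE
  recovery <- NA_integer_
  for (t in seq_len(max_generations)) {
    xn <- reduced_step(x3, m3)
    nw <- nonwild(xn)
    if (nw < eliminate_tol && nw <= nw_prev) {
      success <- TRUE; recovery <- t; x3 <- xn; break
    }
    if (max(abs(xn - x3)) < 1e-14) { x3 <- xn; break }
    x3 <- xn; nw_prev <- nw
  }
  list(success = success, recovery_generations = recovery, final = x3,
       model = m3)
}
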