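# Allele and genotype state space for two-locus engineered underdominance.
#
# Each transgenic construct carries three components: a lethal effector (L),
# a suppressor of the *other* construct's lethal (S), and a cargo gene (C).
# Loss-of-function mutation can knock out any subset of the three, giving
# nine allele states per locus: the wild-type allele, the intact construct,
# and the 7 partially/fully mutated constructs. Subscripts in allele labels
# name the knocked-out (non-functional) components.

.ud_cache <- new.env(parent = emptyenv())

#' Enumerate the nine allele states at one locus
#'
#' Returns the canonical ordered allele table for a locus of the two-locus
#' underdominance system: the wild-type allele first, then the intact
#' construct, then single-, double- and triple-knockout alleles with the
#' knocked-out components ordered lethal < suppressor < cargo. A subscript
#' letter in a label means that component is non-functional (e.g. `A_LC`
#' retains only a functional suppressor).
#'
#' @param locus `"A"` or `"B"`.
#' @return A data frame with one row per allele and columns `label`,
#'   `locus`, `is_wild`, `functional_lethal`, `functional_suppressor`,
#'   `functional_cargo`.
#' @examples
#' enumerate_alleles("A")$label
#' @export
enumerate_alleles <- function(locus = c("A", "B")) {
  locus <- match.arg(locus)
  key <- paste0("alleles_", locus)
  if (!is.null(.ud_cache[[key]])) return(.ud_cache[[key]])
  # knockout subsets in canonical order: none, L, S, C, LS, LC, SC, LSC
  knocked <- list(character(0), "L", "S", "C", c("L", "S"), c("L", "C"),
                  c("S", "C"), c("L", "S", "C"))
  base <- locus
  labels <- vapply(knocked, function(k) {
    if (length(k) == 0) base else paste0(base, "_", paste(k, collapse = ""))
  }, character(1))
  tab <- data.frame(
    label = c(tolower(base), labels),
    locus = locus,
    is_wild = c(TRUE, rep(FALSE, 8L)),
    functional_lethal     = c(FALSE, vapply(knocked, function(k) !("L" %in% k), logical(1))),
    functional_suppressor = c(FALSE, vapply(knocked, function(k) !("S" %in% k), logical(1))),
    functional_cargo      = c(FALSE, vapply(knocked, function(k) !("C" %in% k), logical(1))),
    stringsAsFactors = FALSE
  )
  .ud_cache[[key]] <- tab
  tab
}

# Unordered allele pairs (i <= j) at a locus, in lexicographic order.
# 45 pairs for 9 alleles.
allele_pairs <- function(n) {
  i <- rep.int(seq_len(n), times = n - seq_len(n) + 1L)
  j <- unlist(lapply(seq_len(n), function(k) k:n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Enumerate all two-locus genotypes
#'
#' Builds the full genotype table: every unordered allele pair at locus A
#' (45 pairs) crossed with every unordered pair at locus B, 2025 genotypes
#' in total, each with a canonical integer index. Viability is decided by
#' the cross-suppression rule: a genotype is non-viable when it carries at
#' least one functional lethal at one locus and no functional suppressor at
#' the other locus (in either direction); lethality is all-or-nothing and
#' any single suppressor copy gives full rescue.
#'
#' @return A data frame with columns `index`, `a1`, `a2`, `b1`, `b2`
#'   (allele labels, canonically ordered within each locus pair) and
#'   `viable`.
#' @examples
#' g <- enumerate_genotypes()
#' nrow(g)            # 2025
#' sum(!g$viable)     # 819
#' @export
enumerate_genotypes <- function() {
  if (!is.null(.ud_cache$genotypes)) return(.ud_cache$genotypes)
  aA <- enumerate_alleles("A")
  aB <- enumerate_alleles("B")
  pA <- allele_pairs(nrow(aA))
  pB <- allele_pairs(nrow(aB))
  nPA <- nrow(pA)
  nPB <- nrow(pB)
  gA <- rep(seq_len(nPA), each = nPB)
  gB <- rep(seq_len(nPB), times = nPA)
  lethA <- aA$functional_lethal[pA[, 1]] | aA$functional_lethal[pA[, 2]]
  suppA <- aA$functional_suppressor[pA[, 1]] | aA$functional_suppressor[pA[, 2]]
  lethB <- aB$functional_lethal[pB[, 1]] | aB$functional_lethal[pB[, 2]]
  suppB <- aB$functional_suppressor[pB[, 1]] | aB$functional_suppressor[pB[, 2]]
  viable <- !((lethA[gA] & !suppB[gB]) | (lethB[gB] & !suppA[gA]))
  tab <- data.frame(
    index = seq_along(gA),
    a1 = aA$label[pA[gA, 1]], a2 = aA$label[pA[gA, 2]],
    b1 = aB$label[pB[gB, 1]], b2 = aB$label[pB[gB, 2]],
    viable = viable,
    stringsAsFactors = FALSE
  )
  .ud_cache$genotypes <- tab
  tab
}

# Parse a genotype specification into allele indices.
# Accepts: a single genotype index; a character vector of 4 allele labels
# (a1, a2, b1, b2); or one string, either whitespace-separated labels
# ("A_LC A_LC B_LC B_LC") or 4 bare letters from {a,A,b,B} ("AABB").
# Returns list(iA = sorted pair of locus-A allele indices, iB = likewise).
parse_genotype <- function(g) {
  aA <- enumerate_alleles("A")
  aB <- enumerate_alleles("B")
  if (is.numeric(g) && length(g) == 1L) {
    stopifnot(g >= 1, g <= 2025)
    pA <- allele_pairs(9L); pB <- allele_pairs(9L)
    gA <- (g - 1L) %/% 45L + 1L
    gB <- (g - 1L) %% 45L + 1L
    return(list(iA = unname(pA[gA, ]), iB = unname(pB[gB, ])))
  }
  if (is.character(g) && length(g) == 1L) {
    g <- if (grepl("\\s", g)) strsplit(trimws(g), "\\s+")[[1]] else {
      if (!grepl("^[aAbB]{4}$", g))
        stop("compact genotype strings may only use the bare letters a, A, b, B")
      strsplit(g, "")[[1]]
    }
  }
  if (!is.character(g) || length(g) != 4L)
    stop("genotype must be an index, four allele labels, or a parseable string")
  iA <- match(g[1:2], aA$label)
  iB <- match(g[3:4], aB$label)
  if (anyNA(iA) || anyNA(iB))
    stop("unknown allele label in genotype: ", paste(g, collapse = " "),
         " (first two labels must be locus A, last two locus B)")
  list(iA = sort(iA), iB = sort(iB))
}

# Canonical index in 1..2025 for a parsed genotype.
genotype_index <- function(g) {
  p <- parse_genotype(g)
  pair_idx <- function(i, j, n = 9L) {
    # lexicographic index of unordered pair (i <= j) among C(n+1, 2)
    (i - 1L) * (n + 1L) - ((i - 1L) * i) %/% 2L + (j - i + 1L)
  }
  gA <- pair_idx(p$iA[1], p$iA[2])
  gB <- pair_idx(p$iB[1], p$iB[2])
  (gA - 1L) * 45L + gB
}

#' Genotype viability under the cross-suppression rule
#'
#' A genotype is non-viable exactly when it has one or more functional
#' lethal effectors at one locus and zero functional suppressors at the
#' other locus (in either direction). Any number of functional lethal
#' copies is fully suppressed by any number (one or more) of cross-locus
#' suppressor copies; unsuppressed lethals are fully penetrant.
#'
#' @param g A genotype: canonical index in 1..2025, four allele labels
#'   (locus A pair then locus B pair), or a single parseable string such
#'   as `"AABB"` or `"A_LC A_LC B B"`.
#' @return `TRUE` if viable, `FALSE` otherwise.
#' @examples
#' is_viable("aabb")  # TRUE: no constructs
#' is_viable("AAbb")  # FALSE: unsuppressed lethals at locus A
#' @export
is_viable <- function(g) {
  enumerate_genotypes()$viable[genotype_index(g)]
}

#' Construct copy counts of a genotype
#'
#' Counts the four construct classes entering the multiplicative fitness
#' model: `beta` non-mutated (intact) locus-A constructs, `phi` mutated
#' locus-A constructs (any knockout class), and `mu`, `psi` analogously at
#' locus B. Wild-type alleles are counted in no class.
#'
#' @inheritParams is_viable
#' @return Named integer vector `c(beta, phi, mu, psi)`, each in 0..2.
#' @examples
#' copy_counts("AABB")          # beta = 2, mu = 2
#' copy_counts("A A_L B B_LC")  # one intact and one mutated copy per locus
#' @export
copy_counts <- function(g) {
  p <- parse_genotype(g)
  c(beta = sum(p$iA == 2L),
    phi  = sum(p$iA >= 3L),
    mu   = sum(p$iB == 2L),
    psi  = sum(p$iB >= 3L))
}

#' Relative-fitness parameters
#'
#' Per-copy relative fitnesses of the construct classes. Each intact
#' locus-A (locus-B) construct multiplies fitness by `eps_A` (`eps_B`);
#' each mutated construct, regardless of which or how many components are
#' knocked out, multiplies it by `eps_AM` (`eps_BM`). `eps_Rev` is the
#' per-copy fitness of a free-suppressor construct and is used only by the
#' three-allele reduced model of [reduced_model()].
#'
#' @param eps_A,eps_B Per-copy fitness of intact constructs, in \[0, 1\].
#' @param eps_AM,eps_BM Per-copy fitness of mutated constructs, in \[0, 1\].
#' @param eps_Rev Per-copy fitness of a free-suppressor construct.
#' @return An object of class `fitness_params`.
#' @examples
#' fitness_params(eps_A = 0.95, eps_B = 0.95, eps_AM = 0.96, eps_BM = 0.96)
#' @export
fitness_params <- function(eps_A = 0.95, eps_B = 0.95,
                           eps_AM = 0.96, eps_BM = 0.96,
                           eps_Rev = 0.96) {
  p <- list(eps_A = eps_A, eps_B = eps_B, eps_AM = eps_AM, eps_BM = eps_BM,
            eps_Rev = eps_Rev)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all relative fitnesses must lie in [0, 1]")
  structure(p, class = "fitness_params")
}

#' @export
print.fitness_params <- function(x, ...) {
  cat("Relative fitness per construct copy:\n")
  cat(sprintf("  intact:          eps_A = %g, eps_B = %g\n", x$eps_A, x$eps_B))
  cat(sprintf("  mutated:         eps_AM = %g, eps_BM = %g\n", x$eps_AM, x$eps_BM))
  cat(sprintf("  free suppressor: eps_Rev = %g\n", x$eps_Rev))
  invisible(x)
}

#' Relative fitness of a genotype
#'
#' The multiplicative fitness model: with copy counts
#' `(beta, phi, mu, psi)` and lethality indicator `gamma` (1 if the
#' genotype is non-viable under the cross-suppression rule, else 0),
#'
#' \deqn{\Omega = \epsilon_A^{\beta} \epsilon_{AM}^{\phi}
#'   \epsilon_B^{\mu} \epsilon_{BM}^{\psi} (1 - \gamma).}
#'
#' All mutated constructs at a locus share the single per-copy fitness
#' `eps_AM` / `eps_BM` regardless of which components are knocked out.
#'
#' @inheritParams is_viable
#' @param params A [fitness_params()] object.
#' @return Relative fitness in \[0, 1\] (0 for non-viable genotypes).
#' @examples
#' genotype_fitness("AABB", fitness_params(eps_A = 0.95, eps_B = 0.95))
#' @export
genotype_fitness <- function(g, params = fitness_params()) {
  stopifnot(inherits(params, "fitness_params"))
  cc <- copy_counts(g)
  gamma <- if (is_viable(g)) 0 else 1
  params$eps_A^cc[["beta"]] * params$eps_AM^cc[["phi"]] *
    params$eps_B^cc[["mu"]] * params$eps_BM^cc[["psi"]] * (1 - gamma)
}
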