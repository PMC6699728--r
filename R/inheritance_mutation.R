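# Mendelian gamete production for two unlinked loci and the single-step
# per-gene loss-of-function mutation transition applied at gamete
# production.

#' Gamete (haplotype) distribution of a genotype
#'
#' Free segregation at two unlinked loci: each of the two alleles at a
#' locus is transmitted with probability 1/2 and the haplotype probability
#' is the product of the per-locus marginals. Mutation is *not* applied
#' here; see [apply_mutation()].
#'
#' @inheritParams is_viable
#' @return Named numeric vector of length 81 over haplotypes, named
#'   `"<A-allele>:<B-allele>"`, summing to 1.
#' @examples
#' d <- gamete_distribution("AaBb")
#' d[d > 0]   # four haplotypes at 1/4 each
#' @export
gamete_distribution <- function(g) {
  eng <- full_engine()
  idx <- genotype_index(g)
  d <- as.vector(eng$SEG[idx, ])
  names(d) <- haplotype_labels(eng)
  d
}

haplotype_labels <- function(engine) {
  paste(engine$allelesA$label[engine$A_of_h],
        engine$allelesB$label[engine$B_of_h], sep = ":")
}

#' Per-locus loss-of-function mutation matrix
#'
#' Builds the 9 x 9 single-generation allele transition matrix for one
#' locus. A transgenic allele with k still-functional components moves to
#' each of its k single-component knockouts with probability `m` and stays
#' unchanged with probability 1 - k m, so the intact construct mutates at
#' total rate 3m. Multiple component losses in one generation are excluded
#' by construction. The wild-type allele and the fully mutated construct
#' are absorbing, and no transition ever restores function (no
#' back-mutation).
#'
#' @param m Per-gene mutation rate per generation; requires `0 <= 3m <= 1`.
#' @param locus `"A"` or `"B"`.
#' @return Row-stochastic 9 x 9 matrix with allele labels on both
#'   dimensions; rows are source alleles.
#' @examples
#' M <- mutation_matrix(1e-6)
#' M["A", c("A", "A_L", "A_S", "A_C")]
#' @export
mutation_matrix <- function(m, locus = c("A", "B")) {
  locus <- match.arg(locus)
  if (!is.finite(m) || m < 0 || 3 * m > 1)
    stop("mutation rate must satisfy 0 <= m and 3m <= 1")
  al <- enumerate_alleles(locus)
  n <- nrow(al)
  flags <- as.matrix(al[, c("functional_lethal", "functional_suppressor",
                            "functional_cargo")])
  M <- diag(n)
  for (r in which(!al$is_wild)) {
    for (comp in which(flags[r, ])) {
      tf <- flags[r, ]
      tf[comp] <- FALSE
      tgt <- which(!al$is_wild & flags[, 1] == tf[1] & flags[, 2] == tf[2] &
                     flags[, 3] == tf[3])
      M[r, tgt] <- M[r, tgt] + m
      M[r, r] <- M[r, r] - m
    }
  }
  dimnames(M) <- list(al$label, al$label)
  M
}

#' Apply gamete-production mutation to a haplotype distribution
#'
#' Pushes an 81-haplotype gamete distribution through the per-locus
#' mutation matrices; the joint transition is the Kronecker product of the
#' two 9 x 9 matrices, applied here in factored form. Row-stochasticity
#' conserves total probability exactly.
#'
#' @param d Haplotype distribution (length 81, as from
#'   [gamete_distribution()]).
#' @param MA,MB Per-locus mutation matrices from [mutation_matrix()]; `MB`
#'   defaults to the same rate structure as `MA`.
#' @return Mutated haplotype distribution of the same length and names.
#' @examples
#' d <- gamete_distribution("AABB")
#' dm <- apply_mutation(d, mutation_matrix(1e-4, "A"), mutation_matrix(1e-4, "B"))
#' sum(dm)   # 1
#' @export
apply_mutation <- function(d, MA, MB = NULL) {
  eng <- full_engine()
  if (is.null(MB)) MB <- MA
  out <- mutate_pool(as.vector(d), MA, MB, eng$nA, eng$nB)
  names(out) <- names(d)
  out
}

# pool is indexed h = (x - 1) * nB + y; as a (nB x nA) matrix Q with
# Q[y, x] = pool[h] the mutated pool is t(MB) %*% Q %*% MA.
mutate_pool <- function(pool, MA, MB, nA, nB) {
  Q <- matrix(pool, nrow = nB, ncol = nA)
  as.vector(crossprod(MB, Q) %*% MA)
}
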