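# Independent brute-force oracles. These deliberately re-derive the state
# space, the viability rule, mutation and the mating-table recursion from
# first principles, without touching the package's precomputed engine, so
# that tests compare two independent code paths.

# Allele bookkeeping by still-functional component sets, in the package's
# canonical order (wild, intact, then knockouts L < S < C):
#   1 wild | 2 {L,S,C} | 3 {S,C} | 4 {L,C} | 5 {L,S} | 6 {C} | 7 {S} | 8 {L} | 9 {}
oracle_func_sets <- list(character(0), c("L", "S", "C"), c("S", "C"),
                         c("L", "C"), c("L", "S"), "C", "S", "L", character(0))
oracle_is_wild <- c(TRUE, rep(FALSE, 8L))

# unordered pairs (i <= j) of 9 alleles, lexicographic: 45 rows
oracle_pairs <- function() {
  out <- matrix(0L, 0L, 2L)
  for (i in 1:9) for (j in i:9) out <- rbind(out, c(i, j))
  out
}

# Count non-viable genotypes by looping over all 45 x 45 locus-pair
# combinations and applying the lethal/suppressor rule directly.
oracle_nonviable_count <- function() {
  prs <- oracle_pairs()
  has <- function(k, comp) !oracle_is_wild[k] && comp %in% oracle_func_sets[[k]]
  n_bad <- 0L
  for (pa in seq_len(nrow(prs))) {
    lethA <- has(prs[pa, 1], "L") || has(prs[pa, 2], "L")
    suppA <- has(prs[pa, 1], "S") || has(prs[pa, 2], "S")
    for (pb in seq_len(nrow(prs))) {
      lethB <- has(prs[pb, 1], "L") || has(prs[pb, 2], "L")
      suppB <- has(prs[pb, 1], "S") || has(prs[pb, 2], "S")
      if ((lethA && !suppB) || (lethB && !suppA)) n_bad <- n_bad + 1L
    }
  }
  n_bad
}

# 9 x 9 per-locus mutation matrix built from the component sets alone.
oracle_mutation_matrix <- function(m) {
  M <- diag(9)
  for (k in which(!oracle_is_wild)) {
    for (x in oracle_func_sets[[k]]) {
      rest <- setdiff(oracle_func_sets[[k]], x)
      tgt <- which(!oracle_is_wild &
                     vapply(oracle_func_sets, setequal, logical(1), rest))
      M[k, tgt] <- M[k, tgt] + m
      M[k, k] <- M[k, k] - m
    }
  }
  M
}

# One generation by the explicit genotype-mating-pair table: every ordered
# parent pair contributes its offspring distribution (per-locus Mendelian
# marginals, mutated at gamete production, paired into unordered offspring
# pairs), weighted by the parent frequencies; then fitness weighting and
# mean-fitness normalization. Genotype index = (pairA - 1) * 45 + pairB.
oracle_step <- function(G, params, m = 0) {
  prs <- oracle_pairs()
  M <- oracle_mutation_matrix(m)
  has <- function(k, comp) !oracle_is_wild[k] && comp %in% oracle_func_sets[[k]]
  marg <- function(pair) {
    v <- numeric(9)
    v[pair[1]] <- v[pair[1]] + 0.5
    v[pair[2]] <- v[pair[2]] + 0.5
    as.vector(t(M) %*% v)
  }
  pair_dist <- function(v1, v2) {
    P <- outer(v1, v2)
    D <- numeric(45)
    k <- 0L
    for (i in 1:9) for (j in i:9) {
      k <- k + 1L
      D[k] <- if (i == j) P[i, i] else P[i, j] + P[j, i]
    }
    D
  }
  support <- which(G > 0)
  Graw <- numeric(2025)
  margA <- lapply(support, function(g) marg(prs[(g - 1L) %/% 45L + 1L, ]))
  margB <- lapply(support, function(g) marg(prs[(g - 1L) %% 45L + 1L, ]))
  for (u in seq_along(support)) for (v in seq_along(support)) {
    w <- G[support[u]] * G[support[v]]
    DA <- pair_dist(margA[[u]], margA[[v]])
    DB <- pair_dist(margB[[u]], margB[[v]])
    Graw <- Graw + w * as.vector(t(outer(DA, DB)))
  }
  # fitness: per-copy class fitness x binary viability, from first principles
  fA <- c(1, params$eps_A, rep(params$eps_AM, 7))
  fB <- c(1, params$eps_B, rep(params$eps_BM, 7))
  omega <- numeric(2025)
  for (g in 1:2025) {
    pa <- prs[(g - 1L) %/% 45L + 1L, ]
    pb <- prs[(g - 1L) %% 45L + 1L, ]
    lethA <- has(pa[1], "L") || has(pa[2], "L")
    suppA <- has(pa[1], "S") || has(pa[2], "S")
    lethB <- has(pb[1], "L") || has(pb[2], "L")
    suppB <- has(pb[1], "S") || has(pb[2], "S")
    viable <- !((lethA && !suppB) || (lethB && !suppA))
    omega[g] <- fA[pa[1]] * fA[pa[2]] * fB[pb[1]] * fB[pb[2]] * viable
  }
  Gtil <- Graw * omega
  Gtil / sum(Gtil)
}

# Random post-selection population state supported on a few viable
# genotypes (Dirichlet weights).
random_viable_state <- function(support_size = 10L) {
  viable_idx <- which(enumerate_genotypes()$viable)
  idx <- sample(viable_idx, support_size)
  w <- stats::rexp(support_size)
  G <- numeric(2025)
  G[idx] <- w / sum(w)
  G
}
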