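# Internal recursion engine.
#
# The per-generation map works on the gamete (haplotype) pool rather than
# on the 2025 x 2025 mating table: parents emit gametes by free segregation
# of the two loci, gametes mutate, offspring form by random union of two
# gametes, and viability selection plus mean-fitness normalization gives
# the next adult genotype distribution. The precomputed pieces are
#   SEG  (nG x nH sparse): genotype -> gamete haplotype probabilities,
#   AGG  (nG x nH^2 sparse): ordered gamete pair -> offspring genotype,
#   CA/CB (nG x nA): per-genotype allele dosage / 2 for allele frequencies.
# Haplotype h = (x - 1) * nB + y for locus-A allele x and locus-B allele y.
# The same machinery serves both the full 9-allele model and the reduced
# 2- and 3-allele stability models.

build_engine <- function(allelesA, allelesB) {
  nA <- nrow(allelesA)
  nB <- nrow(allelesB)
  nH <- nA * nB
  pA <- allele_pairs(nA)
  pB <- allele_pairs(nB)
  nPA <- nrow(pA)
  nPB <- nrow(pB)
  nG <- nPA * nPB
  gA <- rep(seq_len(nPA), each = nPB)   # per-genotype locus-A pair index
  gB <- rep(seq_len(nPB), times = nPA)

  lethA <- allelesA$functional_lethal[pA[, 1]] | allelesA$functional_lethal[pA[, 2]]
  suppA <- allelesA$functional_suppressor[pA[, 1]] | allelesA$functional_suppressor[pA[, 2]]
  lethB <- allelesB$functional_lethal[pB[, 1]] | allelesB$functional_lethal[pB[, 2]]
  suppB <- allelesB$functional_suppressor[pB[, 1]] | allelesB$functional_suppressor[pB[, 2]]
  viable <- !((lethA[gA] & !suppB[gB]) | (lethB[gB] & !suppA[gA]))

  # SEG: each genotype emits <= 4 haplotypes with probability 1/4 each
  # (coincident entries merge for homozygous loci).
  i1 <- pA[gA, 1]; i2 <- pA[gA, 2]
  j1 <- pB[gB, 1]; j2 <- pB[gB, 2]
  rows <- rep(seq_len(nG), times = 4L)
  cols <- c((i1 - 1L) * nB + j1, (i1 - 1L) * nB + j2,
            (i2 - 1L) * nB + j1, (i2 - 1L) * nB + j2)
  SEG <- Matrix::sparseMatrix(i = rows, j = cols, x = 0.25,
                              dims = c(nG, nH))

  # AGG: ordered gamete pair (h1 from parent 1, h2 from parent 2) ->
  # offspring genotype; column k is the column-major index of outer(pool, pool).
  pair_lookup <- matrix(0L, nA, nA)
  pair_lookup[pA] <- seq_len(nPA)
  pair_lookup[pA[, c(2, 1)]] <- seq_len(nPA)
  pairB_lookup <- matrix(0L, nB, nB)
  pairB_lookup[pB] <- seq_len(nPB)
  pairB_lookup[pB[, c(2, 1)]] <- seq_len(nPB)
  A_of_h <- rep(seq_len(nA), each = nB)
  B_of_h <- rep(seq_len(nB), times = nA)
  h1 <- rep(seq_len(nH), times = nH)   # varies fastest: rows of outer()
  h2 <- rep(seq_len(nH), each = nH)
  gidx <- (pair_lookup[cbind(A_of_h[h1], A_of_h[h2])] - 1L) * nPB +
    pairB_lookup[cbind(B_of_h[h1], B_of_h[h2])]
  AGG <- Matrix::sparseMatrix(i = gidx, j = seq_len(nH * nH), x = 1,
                              dims = c(nG, nH * nH))

  # allele dosage (in halves) per genotype and locus
  CA <- matrix(0, nG, nA)
  CA[cbind(seq_len(nG), i1)] <- CA[cbind(seq_len(nG), i1)] + 0.5
  CA[cbind(seq_len(nG), i2)] <- CA[cbind(seq_len(nG), i2)] + 0.5
  CB <- matrix(0, nG, nB)
  CB[cbind(seq_len(nG), j1)] <- CB[cbind(seq_len(nG), j1)] + 0.5
  CB[cbind(seq_len(nG), j2)] <- CB[cbind(seq_len(nG), j2)] + 0.5

  list(allelesA = allelesA, allelesB = allelesB,
       nA = nA, nB = nB, nH = nH, nG = nG,
       pairsA = pA, pairsB = pB, gA = gA, gB = gB,
       i1 = i1, i2 = i2, j1 = j1, j2 = j2,
       viable = viable, SEG = SEG, AGG = AGG, CA = CA, CB = CB,
       A_of_h = A_of_h, B_of_h = B_of_h)
}

full_engine <- function() {
  if (is.null(.ud_cache$engine))
    .ud_cache$engine <- build_engine(enumerate_alleles("A"),
                                     enumerate_alleles("B"))
  .ud_cache$engine
}

# Per-allele per-copy fitness vectors for the full 9-allele model:
# wild 1, intact construct eps_A, every mutated class eps_AM.
percopy_fitness <- function(params) {
  list(A = c(1, params$eps_A, rep(params$eps_AM, 7L)),
       B = c(1, params$eps_B, rep(params$eps_BM, 7L)))
}

# Genotype fitness vector Omega over the engine's genotype space from
# per-copy per-allele fitness vectors (multiplicative, zero if non-viable).
omega_vector <- function(engine, fA, fB) {
  fA[engine$i1] * fA[engine$i2] * fB[engine$j1] * fB[engine$j2] *
    as.numeric(engine$viable)
}

# Gamete pool (length nH, sums to 1) emitted by an adult genotype
# distribution G (length nG, sums to 1).
gamete_pool <- function(engine, G) {
  as.vector(Matrix::crossprod(engine$SEG, G))
}

# Random union of gametes + selection + normalization: adult genotype
# distribution of the next generation from a (possibly mutated) pool.
union_select <- function(engine, pool, omega) {
  Graw <- as.vector(engine$AGG %*% as.vector(outer(pool, pool)))
  Gtil <- Graw * omega
  obar <- sum(Gtil)
  if (obar <= 0)
    stop("degenerate population: mean fitness is zero (all offspring non-viable)")
  G <- Gtil / obar
  # zero round-off negatives
  G[G < 0 & G > -1e-15] <- 0
  G
}

# Per-locus allele frequencies (each sums to 1) of an adult distribution.
engine_allele_freqs <- function(engine, G) {
  list(A = as.vector(crossprod(engine$CA, G)),
       B = as.vector(crossprod(engine$CB, G)))
}
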