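# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately written as plain loops over nodes/edges/triples so
# that the vectorized implementations are checked against a second,
# independent route.

randomDigraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n) < p, n, n)
  diag(A) <- FALSE
  rownames(A) <- colnames(A) <- sprintf("n%02d", seq_len(n))
  A
}

oracleDegrees <- function(A) {
  n <- nrow(A)
  kin <- kout <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j]) {
      kout[i] <- kout[i] + 1L
      kin[j] <- kin[j] + 1L
    }
  }
  list(kIn = kin, kOut = kout, k = kin + kout)
}

oracleDensity <- function(A) {
  n <- nrow(A)
  K <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && A[i, j]) K <- K + 1L
  K / (n^2 - n)
}

oracleReciprocity <- function(A) {
  n <- nrow(A)
  K <- 0L; R <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (A[i, j]) {
      K <- K + 1L
      if (A[j, i]) R <- R + 1L
    }
  }
  if (K == 0) return(NA_real_)
  R / K
}

# directed transitivity by exhaustive enumeration over ordered triples
oracleTransitivity <- function(A) {
  n <- nrow(A)
  B <- A * 1
  diag(B) <- 0
  tri <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (h in seq_len(n)) {
    if (i == j || i == h || j == h) next
    tri <- tri + (B[i, j] + B[j, i]) * (B[i, h] + B[h, i]) *
      (B[j, h] + B[h, j])
  }
  tri <- tri / 2            # t_i carries a leading 1/2
  denom <- 0
  for (i in seq_len(n)) {
    ktot <- sum(B[i, ]) + sum(B[, i])
    recip <- sum(B[i, ] * B[, i])
    denom <- denom + ktot * (ktot - 1) - 2 * recip
  }
  if (denom == 0) return(0)
  tri / denom
}

# small anatomy fixture with named compartments:
# - pharynx: p1, p2 (head)
# - nerve ring: r1 (stratum 1), r2 (strata 1,2), r3 (stratum 3)
# - ventral cord (head side): v1, v2 share the thin bundle "ventral_cord"
# - tail bundle: t1, t2
toyAnnotation <- function() {
  nm <- c("p1", "p2", "r1", "r2", "r3", "v1", "v2", "t1", "t2")
  NeuronAnnotation(
    neuron = nm,
    bundles = list("pharynx", "pharynx",
                   "nerve_ring", c("nerve_ring", "ventral_cord"),
                   "nerve_ring", "ventral_cord", "ventral_cord",
                   "tail_bundle", "tail_bundle"),
    region = c("head", "head", "head", "head", "head", "head", "head",
               "tail", "tail"),
    strata = list(integer(0), integer(0), 1L, c(1L, 2L), 3L,
                  integer(0), integer(0), integer(0), integer(0)),
    bundleUniverse = c("pharynx", "nerve_ring", "ventral_cord",
                       "tail_bundle"))
}

toyRoster <- function(nm) NeuronRoster(nm)

toyExpression <- function(mat, roster = NULL) {
  if (is.null(roster)) roster <- NeuronRoster(colnames(mat))
  PeptideExpression(mat, roster)
}

rankRange <- function(x) {
  levels <- c("contact_stratum", "contact_thin_bundle", "short", "mid",
              "long", "unreachable")
  match(x, levels)
}
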