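# Independent oracles and small fixture builders used across the suite.

# O(N*M) brute-force contact count, the definitional oracle
brute_contacts <- function(a, b, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    n <- n + sum(d2 < cutoff^2)
  }
  n
}

# brute-force minimum pair distance
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Kabsch rigid-body fit of P onto Q (n x 3 matrices); returns fitted P
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(P0 %*% R, 2, cq, `+`)
}

kabsch_rmsd <- function(P, Q) {
  F <- kabsch_fit(P, Q)
  sqrt(mean(rowSums((F - Q)^2)))
}

# quick synthetic run with small defaults for unit tests
quick_sim <- function(n_frames = 200L, seed = 1L, ...) {
  simulate_trajectory(synthetic_params(n_frames = n_frames, seed = seed, ...))
}

# tiny hand-built two-strand duplex system (3 bp, C1' atoms only) plus one
# histone chain of 4 core CA atoms, for bp-center and contact tests
toy_duplex_system <- function() {
  chains <- list(A = histone_chain("H4", 1L, 20L,
                                   core_annotations = list(alpha1 = c(5L, 8L))))
  dna <- dna_duplex(core_bp = 3L, linker_bp = 0L, inner_outer_boundary = 2L)
  atoms <- data.frame(
    eleno = 1:10,
    elety = c(rep("CA", 4), rep("C1'", 6)),
    chain = c(rep("A", 4), rep("I", 3), rep("J", 3)),
    resno = c(5:8, 1:3, 3:1),
    role = c(rep("core", 4), rep("dna", 6)),
    bp_index = c(rep(NA, 4), -1L, 0L, 1L, 1L, 0L, -1L),
    strand = c(rep(NA, 4), 1L, 1L, 1L, 2L, 2L, 2L),
    element = c(rep("alpha1", 4), rep(NA, 6)),
    mass = c(rep(12, 4), rep(325, 6)),
    stringsAsFactors = FALSE)
  # strand1 C1' at x = -10, 0, 10 (y = 2); strand2 partners at y = -2
  xyz <- c(30, 0, 0,  30, 3, 0,  30, 6, 0,  30, 9, 0,
           -10, 2, 0,  0, 2, 0,  10, 2, 0,
           10, -2, 0,  0, -2, 0,  -10, -2, 0)
  nucleosome_system(chains, dna, atoms, xyz)
}
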