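# Independent oracles used against the package implementations. Each one
# follows a different algorithmic route than the code it checks.

# Horn's quaternion-eigenvalue method for optimal superposition rmsd
quaternion_superpose_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)  # S[i,j] = sum a_i b_j
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(e2, 0))
}

# exhaustive all-pairs neighbor search
brute_pairs_within <- function(xyz_a, xyz_b, cutoff) {
  d <- sqrt(outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
              2 * xyz_a %*% t(xyz_b))
  which(d <= cutoff, arr.ind = TRUE)
}

# naive quadruple-loop CUTRE
naive_cutre <- function(pae, plddt, T_set, B_set) {
  acc <- 0
  for (i in T_set) for (j in B_set) acc <- acc + pae[i, j] * plddt[i] / 100
  for (j in B_set) for (i in T_set) acc <- acc + pae[j, i] * plddt[j] / 100
  acc / (2 * length(T_set) * length(B_set))
}

# Monte-Carlo Shrake-Rupley: random sphere points instead of a lattice
mc_sasa_total <- function(model, probe = 1.4, n_mc = 1e5, seed = 42,
                          radii = default_radii()) {
  atoms <- model$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- radii[atoms$element] + probe
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    p <- matrix(rnorm(3 * n_mc), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      if (sqrt(sum((xyz[j, ] - xyz[i, ])^2)) > r[i] + r[j]) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > r[j]^2
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

# shared small fixtures
fixture_helix_model <- function(n = 30) {
  at <- build_ideal_backbone(list(c("helix", n)))
  binderscreen:::new_complex_model(at, "A", character(0))
}

fixture_bundle_complex <- function(min_gap = 5, seed = 7) {
  binder <- build_ideal_backbone(list(c("helix", 12), c("coil", 3),
                                      c("helix", 12), c("coil", 3),
                                      c("helix", 12)))
  target <- build_ideal_backbone(list(c("helix", 15)), chain_id = "B")
  make_complex(binder, target, min_gap = min_gap, seed = seed)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
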