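# Deterministic synthetic stand-ins for the generative stages: idealized
# backbones built from internal coordinates, rigid complex assembly,
# white-noise backbone perturbation, and PAE/pLDDT matrices with
# controllable block structure. These drive the whole test surface in place
# of GPU inference.

# ideal trans-peptide internal coordinates, Angstrom / degrees
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
OMEGA <- 180

# canonical phi/psi per segment type
SEGMENT_TORSIONS <- list(helix  = c(phi = -57, psi = -47),
                         strand = c(phi = -139, psi = 135),
                         coil   = c(phi = -75, psi = 150))

# place atom D from A-B-C with bond |CD|, angle B-C-D, torsion A-B-C-D (NeRF)
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealized poly-alanine backbone chain
#'
#' Constructs N, CA, C, O atoms for each residue from ideal bond lengths and
#' angles (N-CA 1.458, CA-C 1.525, C-N 1.329 A; omega = 180) with per-type
#' phi/psi (helix -57/-47, strand -139/135). The carbonyl O is placed with
#' standard sp2 geometry in the peptide plane, anti to the next amide N.
#' Fully deterministic.
#'
#' @param segments list of `c(type, length)` pairs or a data.frame with
#'   columns type ("helix"/"strand"/"coil") and length (residues)
#' @param chain_id chain id for the built chain
#' @param torsions named list overriding per-type phi/psi (degrees)
#' @return an atom data.frame for the single built chain (4 atoms per
#'   residue), ready for [make_complex()] or [new_complex_model()]
#' @export
build_ideal_backbone <- function(segments, chain_id = "A",
                                 torsions = SEGMENT_TORSIONS) {
  if (is.data.frame(segments)) {
    seg_types <- segments$type; seg_lens <- segments$length
  } else {
    seg_types <- vapply(segments, function(s) as.character(s[1]), "")
    seg_lens <- vapply(segments, function(s) as.integer(s[2]), 1L)
  }
  stopifnot(all(seg_types %in% names(torsions)), all(seg_lens >= 1))
  types <- rep(seg_types, seg_lens)
  n <- length(types)
  phi <- vapply(types, function(tp) torsions[[tp]]["phi"], 0)
  psi <- vapply(types, function(tp) torsions[[tp]]["psi"], 0)

  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  a <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BOND_N_CA, ANGLE_C_N_CA, OMEGA)
      C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    # carbonyl O needs the next N; last residue uses a virtual one via psi
    n_next <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_N, ANGLE_CA_C_N,
                         psi[i])
    u1 <- n_next - C[i, ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- CA[i, ] - C[i, ]; u2 <- u2 / sqrt(sum(u2^2))
    bis <- u1 + u2; bis <- bis / sqrt(sum(bis^2))
    O[i, ] <- C[i, ] - BOND_C_O * bis
  }

  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chain_id, resno = i, ins = "", resid = "ALA",
               aa = "A", atom = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               o = 1, b = 0, stringsAsFactors = FALSE)
  }))
  atoms
}

#' Build an idealized antiparallel two-strand pair as one chain
#'
#' Two ideal strands; the second is flipped and its placement grid-searched
#' so inter-strand N...O distances fall in hydrogen-bonding range
#' (2.6-3.3 A), emulating an isolated beta-hairpin backbone.
#'
#' @param n_per_strand residues per strand
#' @param chain_id chain id
#' @return atom data.frame of a single chain
#' @export
build_antiparallel_pair <- function(n_per_strand = 6, chain_id = "A") {
  s1 <- build_ideal_backbone(list(c("strand", n_per_strand)), chain_id)
  # align the strand axis (first CA -> last CA) with +x, center at origin
  M <- atom_xyz(s1)
  ca <- M[s1$atom == "CA", , drop = FALSE]
  d <- ca[nrow(ca), ] - ca[1, ]; d <- d / sqrt(sum(d^2))
  ax <- c(0, d[3], -d[2])              # d x (1,0,0)
  s <- sqrt(sum(ax^2))
  if (s > 1e-9) {
    ax <- ax / s; th <- atan2(s, d[1])
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    M <- M %*% t(R)
  }
  M <- sweep(M, 2, colMeans(M))
  s1[, c("x", "y", "z")] <- M

  # strand 2: antiparallel copy (180 degrees about z), placed by maximizing
  # the number of inter-strand N...O contacts at hydrogen-bond distance
  M2 <- M %*% t(matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3))
  o1 <- M[s1$atom == "O", , drop = FALSE]
  n1 <- M[s1$atom == "N", , drop = FALSE]
  o2 <- M2[s1$atom == "O", , drop = FALSE]
  n2 <- M2[s1$atom == "N", , drop = FALSE]
  pd2 <- function(A, B) outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  in_range <- function(d2) sum(d2 > 2.7^2 & d2 < 3.2^2)
  best <- NULL; best_score <- -1
  for (dx in seq(-5, 5, by = 0.25)) {
    for (dy in seq(3.6, 6, by = 0.1)) {
      for (dz in seq(-2, 2, by = 0.25)) {
        sh <- c(dx, dy, dz)
        score <- in_range(pd2(o1, sweep(n2, 2, sh, "+"))) +
                 in_range(pd2(n1, sweep(o2, 2, sh, "+")))
        if (score > best_score) { best_score <- score; best <- sh }
      }
    }
  }
  s2 <- s1
  s2[, c("x", "y", "z")] <- sweep(M2, 2, best, "+")
  s2$resno <- s2$resno + n_per_strand + 2L   # numbering gap at the turn
  rbind(s1, s2)
}

#' Assemble a rigid binder-target complex at a controlled gap
#'
#' The binder chain is rigidly translated along a fixed approach axis so
#' that the minimum inter-chain atom distance equals `min_gap` (within
#' 0.1 A). Chains are labelled A (binder) and B (target).
#'
#' @param binder_atoms,target_atoms atom data.frames (e.g. from
#'   [build_ideal_backbone()])
#' @param min_gap desired minimum inter-chain distance, Angstrom
#' @param seed seed selecting the approach axis
#' @return a `complex_model` with binder chain A and target chain B
#' @export
make_complex <- function(binder_atoms, target_atoms, min_gap = 5,
                         seed = 1) {
  stopifnot(min_gap >= 0)
  b <- binder_atoms; t <- target_atoms
  b$chain <- "A"; t$chain <- "B"
  bx <- atom_xyz(b); tx <- atom_xyz(t)
  axis <- with_seed(seed, { v <- rnorm(3); v / sqrt(sum(v^2)) })
  # start from centroids superposed, then slide the binder out along axis
  bx0 <- sweep(bx, 2, colMeans(bx) - colMeans(tx))
  gap_at <- function(s) min_distance(sweep(bx0, 2, s * axis, "+"), tx)
  hi <- 1
  while (gap_at(hi) < min_gap + 1 && hi < 1e4) hi <- hi * 2
  # slide to the closest-approach offset first, then out to the target gap
  opt <- optimize(gap_at, c(-hi, hi), tol = 1e-3)
  if (opt$objective > min_gap) {
    stop("could not place binder at the requested gap", call. = FALSE)
  }
  root <- uniroot(function(s) gap_at(s) - min_gap, c(opt$minimum, hi),
                  tol = 1e-4)
  bx_final <- sweep(bx0, 2, root$root * axis, "+")
  if (abs(gap_at(root$root) - min_gap) > 0.1) {
    stop("could not place binder at the requested gap", call. = FALSE)
  }
  b[, c("x", "y", "z")] <- bx_final
  new_complex_model(rbind(b, t), "A", "B")
}

#' Perturb a backbone with white noise
#'
#' Adds i.i.d. Gaussian offsets (sd `sigma` per coordinate) to every atom;
#' the mock counterpart of partial-diffusion re-noising of a validated
#' backbone.
#'
#' @param atoms atom data.frame (one chain) or a `complex_model`
#' @param sigma noise sd per coordinate, Angstrom
#' @param seed RNG seed
#' @return same type as the input, with perturbed coordinates
#' @export
perturb_backbone <- function(atoms, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  is_model <- inherits(atoms, "complex_model")
  at <- if (is_model) atoms$atoms else atoms
  if (sigma > 0) {
    noise <- with_seed(seed, matrix(rnorm(3 * nrow(at), sd = sigma),
                                    ncol = 3))
    at[, c("x", "y", "z")] <- atom_xyz(at) + noise
  }
  if (is_model) { atoms$atoms <- at; atoms } else at
}

#' Synthesize a confidence bundle with block structure
#'
#' Builds a PAE matrix whose (chain_i, chain_j) blocks have prescribed
#' means plus truncated-at-zero Gaussian noise, and per-chain pLDDT means
#' clamped to \[0, 100\]; the mock counterpart of an AF2-style scorer.
#'
#' @param span_lengths named integer vector of residues per chain, binder
#'   first
#' @param block_means matrix (chains x chains, dimnames = chain ids) of PAE
#'   block means, Angstrom
#' @param plddt_means named vector of per-chain pLDDT means
#' @param noise_sd Gaussian noise sd (0 = exact block means)
#' @param seed RNG seed
#' @return a `confidence_bundle`
#' @export
synth_confidence <- function(span_lengths, block_means, plddt_means,
                             noise_sd = 0, seed = 1) {
  chains <- names(span_lengths)
  stopifnot(!is.null(chains), all(chains %in% rownames(block_means)),
            all(chains %in% names(plddt_means)), noise_sd >= 0)
  n <- sum(span_lengths)
  spans <- list(); pos <- 0L
  for (ch in chains) {
    spans[[ch]] <- pos + seq_len(span_lengths[[ch]])
    pos <- pos + span_lengths[[ch]]
  }
  with_seed(seed, {
    pae <- matrix(0, n, n)
    for (ci in chains) for (cj in chains) {
      blk <- matrix(block_means[ci, cj], length(spans[[ci]]),
                    length(spans[[cj]]))
      if (noise_sd > 0) {
        blk <- blk + matrix(rnorm(length(blk), sd = noise_sd), nrow(blk))
      }
      pae[spans[[ci]], spans[[cj]]] <- pmax(blk, 0)
    }
    plddt <- unlist(lapply(chains, function(ch) {
      v <- rep(plddt_means[[ch]], span_lengths[[ch]])
      if (noise_sd > 0) v <- v + rnorm(length(v), sd = noise_sd)
      pmin(pmax(v, 0), 100)
    }), use.names = FALSE)
    confidence_bundle(plddt, pae, spans)
  })
}

#' Mock generative stages with a prescribed hit rate
#'
#' Returns a stage contract (backbone_generator, sequence_designer, scorer)
#' whose scorer emits confidence bundles engineered so that a deterministic
#' fraction `hit_rate` of designs pass the default thresholds: design
#' ordinal k is a hit iff floor((k+1) r) - floor(k r) = 1, giving exactly
#' every other design at r = 0.5, none at 0 and all at 1.
#'
#' @param hit_rate fraction of designs that should be hits, in \[0, 1\]
#' @param binder_segments,target_segments backbone recipes for the shared
#'   template complex (defaults: three-helix bundle binder, helical target)
#' @param min_gap binder-target gap of the template complex, Angstrom
#' @param clash_every if > 0, every `clash_every`-th generated backbone is
#'   placed in steric clash so the filter stage has work to do
#' @return a `stage_contract` list
#' @export
mock_stages <- function(hit_rate,
                        binder_segments = list(c("helix", 12), c("coil", 3),
                                               c("helix", 12), c("coil", 3),
                                               c("helix", 12)),
                        target_segments = list(c("helix", 15)),
                        min_gap = 5, clash_every = 0) {
  stopifnot(hit_rate >= 0, hit_rate <= 1)
  binder <- build_ideal_backbone(binder_segments)
  target <- build_ideal_backbone(target_segments, chain_id = "B")
  template <- make_complex(binder, target, min_gap = min_gap, seed = 7)
  clashed <- make_complex(binder, target, min_gap = 0.3, seed = 7)

  is_hit_ordinal <- function(k) {
    floor((k + 1) * hit_rate + 1e-9) - floor(k * hit_rate + 1e-9) >= 1
  }
  structure(list(
    backbone_generator = function(n, length_range, seed) {
      lapply(seq_len(n), function(i) {
        if (clash_every > 0 && i %% clash_every == 0) clashed else template
      })
    },
    sequence_designer = function(model, n_seq, seed) {
      len <- n_residues(model, model$binder_chain)
      with_seed(seed, vapply(seq_len(n_seq), function(i) {
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                     replace = TRUE), collapse = "")
      }, ""))
    },
    scorer = function(model, sequence) {
      ord <- attr(model, "design_ordinal")
      if (is.null(ord)) ord <- 0L
      good <- is_hit_ordinal(ord)
      nb <- n_residues(model, model$binder_chain)
      nt <- sum(vapply(model$target_chains,
                       function(ch) n_residues(model, ch), 0L))
      bm <- matrix(if (good) c(2, 5, 5, 2) else c(8, 20, 20, 8), 2, 2,
                   dimnames = list(c("A", "B"), c("A", "B")))
      synth_confidence(c(A = nb, B = nt), bm,
                       c(A = if (good) 95 else 60, B = 90),
                       noise_sd = 0, seed = 1)
    }), class = "stage_contract")
}
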