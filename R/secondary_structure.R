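# Reduced three-state (H/E/C) secondary-structure assignment from backbone
# geometry, following the Kabsch-Sander hydrogen-bond energy model.
#
# Amide hydrogens are absent from design-pipeline structures, so H is
# placed geometrically: 1.01 A from N, anti to the carbonyl O of the
# preceding residue. The first residue of a chain cannot donate.

KS_Q <- 0.084 * 332      # kcal/mol * A, Kabsch-Sander coupling constant
KS_EMAX <- -0.5          # bond iff E < -0.5 kcal/mol

# backbone coordinate arrays for one chain; errors name the missing residue
backbone_coords <- function(atoms) {
  key <- paste(atoms$resno, atoms$ins, sep = "|")
  keys <- unique(key)
  n <- length(keys)
  get_atom <- function(name) {
    m <- matrix(NA_real_, n, 3)
    sel <- atoms$atom == name
    idx <- match(key[sel], keys)
    m[idx, ] <- as.matrix(atoms[sel, c("x", "y", "z")])
    m
  }
  out <- list(N = get_atom("N"), CA = get_atom("CA"),
              C = get_atom("C"), O = get_atom("O"), keys = keys)
  for (nm in c("N", "CA", "C", "O")) {
    bad <- which(!is.finite(out[[nm]][, 1]))
    if (length(bad)) {
      stop("residue ", keys[bad[1]], " is missing backbone atom ", nm,
           call. = FALSE)
    }
  }
  out
}

# Kabsch-Sander H-bond energies; HB[i, j] TRUE iff the carbonyl of residue i
# accepts a bond from the amide of residue j
ks_hbond_matrix <- function(bb) {
  n <- nrow(bb$N)
  HB <- matrix(FALSE, n, n)
  if (n < 3) return(HB)
  # amide H for donors 2..n
  H <- matrix(NA_real_, n, 3)
  dvec <- bb$C[1:(n - 1), , drop = FALSE] - bb$O[1:(n - 1), , drop = FALSE]
  dvec <- dvec / sqrt(rowSums(dvec^2))
  H[2:n, ] <- bb$N[2:n, , drop = FALSE] + 1.01 * dvec

  cross_dist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 1e-12))
  }
  E <- KS_Q * (1 / cross_dist(bb$O, bb$N) + 1 / cross_dist(bb$C, H) -
               1 / cross_dist(bb$O, H) - 1 / cross_dist(bb$C, bb$N))
  sep <- abs(row(E) - col(E))
  ok <- sep >= 2 & col(E) >= 2 & is.finite(E)
  HB[ok] <- E[ok] < KS_EMAX
  HB
}

#' Assign three-state secondary structure to a chain
#'
#' Backbone hydrogen bonds are detected with the Kabsch-Sander electrostatic
#' energy E = 0.084 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) * 332 kcal/mol
#' (bond iff E < -0.5). Residues spanned by i -> i+4 bonds become H; residues
#' in parallel/antiparallel bridge ladders become E; everything else C.
#' Helix takes priority over strand at conflicts, as in DSSP.
#'
#' @param model a `complex_model`
#' @param chain_id chain to assign
#' @return string over {H, E, C}, one symbol per residue
#' @export
assign_secondary_structure <- function(model, chain_id) {
  bb <- backbone_coords(chain_atoms(model, chain_id))
  n <- nrow(bb$N)
  ss <- rep("C", n)
  if (n < 4) return(paste(ss, collapse = ""))
  HB <- ks_hbond_matrix(bb)

  # alpha helix: CO(i) -> NH(i+4) marks i+1..i+4
  for (i in seq_len(n - 4)) {
    if (HB[i, i + 4]) ss[(i + 1):(i + 4)] <- "H"
  }
  # bridges (j - i >= 3), helix keeps priority; shift() pads with FALSE so
  # boundary terms drop out, e.g. shift(-1, 1)[i, j] == HB[i-1, j+1]
  shift <- function(a, b) {
    out <- matrix(FALSE, n, n)
    ri <- seq_len(n); ci <- seq_len(n)
    rs <- ri + a; cs <- ci + b
    okr <- rs >= 1 & rs <= n; okc <- cs >= 1 & cs <= n
    out[ri[okr], ci[okc]] <- HB[rs[okr], cs[okc]]
    out
  }
  anti <- (HB & t(HB)) | (shift(-1, 1) & t(shift(-1, 1)))
  para <- (shift(-1, 0) & t(shift(0, 1))) | (t(shift(-1, 0)) & shift(0, 1))
  bridge <- (anti | para) & (col(HB) - row(HB) >= 3)
  in_bridge <- apply(bridge, 1, any) | apply(bridge, 2, any)
  ss[in_bridge & ss != "H"] <- "E"
  paste(ss, collapse = "")
}

#' Maximal H/E segments of a secondary-structure string
#'
#' Runs of H shorter than `min_len_h` and runs of E shorter than `min_len_e`
#' are relabelled coil.
#'
#' @param ss string over {H, E, C}
#' @param min_len_h minimum helix run length (residues)
#' @param min_len_e minimum strand run length (residues)
#' @return data.frame(type, start, end) with zero-based inclusive bounds,
#'   ordered, non-overlapping
#' @export
segmentize <- function(ss, min_len_h = 4, min_len_e = 2) {
  sym <- strsplit(ss, "")[[1]]
  if (length(sym) && !all(sym %in% c("H", "E", "C"))) {
    stop("secondary-structure symbols must be H, E or C", call. = FALSE)
  }
  r <- rle(sym)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- (r$values == "H" & r$lengths >= min_len_h) |
          (r$values == "E" & r$lengths >= min_len_e)
  data.frame(type = ifelse(r$values[keep] == "H", "helix", "strand"),
             start = starts[keep] - 1L, end = ends[keep] - 1L,
             stringsAsFactors = FALSE)
}

#' Classify binder backbone topology
#'
#' Flags the two backbone classes that are hard to express experimentally:
#' a single long helix (exactly one segment, helical, at least
#' `long_helix_min` residues) and an isolated beta-hairpin (exactly two
#' strand segments and no helix at all). Everything else is retained.
#'
#' @param ss secondary-structure string from [assign_secondary_structure()]
#' @param long_helix_min minimum length for the long-helix rejection
#' @param min_len_h,min_len_e run-length minima passed to [segmentize()]
#' @return list(klass, segments, helix_fraction, rejected, reason)
#' @export
classify_topology <- function(ss, long_helix_min = 40,
                              min_len_h = 4, min_len_e = 2) {
  segs <- segmentize(ss, min_len_h, min_len_e)
  n_h <- sum(segs$type == "helix")
  n_e <- sum(segs$type == "strand")
  helix_fraction <- if (nchar(ss)) {
    sum(strsplit(ss, "")[[1]] == "H") / nchar(ss)
  } else 0
  klass <- "other"; reason <- ""
  if (nrow(segs) == 1 && n_h == 1 &&
      segs$end[1] - segs$start[1] + 1L >= long_helix_min) {
    klass <- "single_helix"
    reason <- sprintf("single helix of %d residues (>= %d)",
                      segs$end[1] - segs$start[1] + 1L, long_helix_min)
  } else if (n_e == 2 && n_h == 0) {
    klass <- "hairpin"
    reason <- "isolated two-strand hairpin"
  }
  list(klass = klass, segments = segs, helix_fraction = helix_fraction,
       rejected = klass != "other", reason = reason)
}
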