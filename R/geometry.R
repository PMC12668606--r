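# Rigid-body superposition and neighbor search shared by the backbone
# filters and the interface metrics.

#' Kabsch least-squares superposition
#'
#' Computes the optimal rigid transform (proper rotation + translation)
#' mapping `mobile` onto `reference` in the least-squares sense, with the
#' reflection corrected through the sign of the smallest singular value.
#'
#' @param mobile n x 3 matrix of coordinates to move
#' @param reference n x 3 matrix of coordinates to match
#' @return a `superposition`: list(rotation 3x3, translation length-3, rmsd)
#'   such that transformed = mobile %*% t(rotation) + translation
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3) {
    stop("point sets must be equal-length n x 3 matrices", call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points for superposition", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                     # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30)) {
    stop("degenerate (collinear) point configuration", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  moved <- mobile %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sp a `superposition` from [kabsch_superpose()]
#' @param xyz n x 3 coordinate matrix
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sp, xyz) {
  xyz <- as.matrix(xyz)
  xyz %*% t(sp$rotation) + matrix(sp$translation, nrow(xyz), 3, byrow = TRUE)
}

#' All inter-set atom pairs within a distance cutoff
#'
#' Cell-list neighbor search over two coordinate sets; contract-identical to
#' exhaustive all-pairs search with an inclusive (<=) boundary.
#'
#' @param xyz_a,xyz_b n x 3 coordinate matrices
#' @param cutoff distance cutoff, Angstrom (> 0)
#' @return data.frame(i, j, dist): row indices into `xyz_a` / `xyz_b` and
#'   their Euclidean distance, for every pair with dist <= cutoff
#' @export
pairs_within <- function(xyz_a, xyz_b, cutoff) {
  stopifnot(cutoff > 0)
  xyz_a <- as.matrix(xyz_a); xyz_b <- as.matrix(xyz_b)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (!nrow(xyz_a) || !nrow(xyz_b)) return(empty)

  # small problems: one vectorized distance matrix beats any spatial index
  if (as.double(nrow(xyz_a)) * nrow(xyz_b) <= 2e6) {
    d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
      2 * tcrossprod(xyz_a, xyz_b)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    return(data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
                      dist = sqrt(pmax(d2[hit], 0))))
  }

  cell_of <- function(xyz) {
    k <- floor(xyz / cutoff)
    paste(k[, 1], k[, 2], k[, 3], sep = ",")
  }
  keys_b <- cell_of(xyz_b)
  bins <- split(seq_len(nrow(xyz_b)), keys_b)

  ka <- floor(xyz_a / cutoff)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (i in seq_len(nrow(xyz_a))) {
    neigh_keys <- paste(ka[i, 1] + off[, 1], ka[i, 2] + off[, 2],
                        ka[i, 3] + off[, 3], sep = ",")
    cand <- unlist(bins[neigh_keys], use.names = FALSE)
    if (!length(cand)) next
    d2 <- (xyz_b[cand, 1] - xyz_a[i, 1])^2 +
          (xyz_b[cand, 2] - xyz_a[i, 2])^2 +
          (xyz_b[cand, 3] - xyz_a[i, 3])^2
    hit <- d2 <= cutoff^2
    if (any(hit)) {
      out_i <- c(out_i, rep.int(i, sum(hit)))
      out_j <- c(out_j, cand[hit])
      out_d <- c(out_d, sqrt(d2[hit]))
    }
  }
  data.frame(i = out_i, j = out_j, dist = out_d)
}

#' Minimum inter-set atom distance
#' @inheritParams pairs_within
#' @return the smallest Euclidean distance between the two sets
#' @export
min_distance <- function(xyz_a, xyz_b) {
  xyz_a <- as.matrix(xyz_a); xyz_b <- as.matrix(xyz_b)
  best <- Inf
  # chunked exhaustive scan; sets in this pipeline are a few thousand atoms
  step <- 2000L
  for (s in seq(1, nrow(xyz_a), by = step)) {
    ia <- s:min(s + step - 1L, nrow(xyz_a))
    d2 <- outer(rowSums(xyz_a[ia, , drop = FALSE]^2),
                rowSums(xyz_b^2), "+") -
      2 * xyz_a[ia, , drop = FALSE] %*% t(xyz_b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}
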