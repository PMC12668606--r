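# Shrake-Rupley solvent-accessible surface area.
#
# Sphere points come from a deterministic Fibonacci lattice so results are
# bit-reproducible across runs and platforms. Radii are a fixed united-atom
# table (C 1.70, N 1.55, O 1.52, S 1.80 A) shipped as plain text and
# overridable per call.

#' Atomic radii table
#'
#' Reads the united-atom van der Waals radii shipped with the package
#' (plain TSV: element, radius in Angstrom).
#'
#' @return named numeric vector of radii by element symbol
#' @export
default_radii <- function() {
  path <- system.file("extdata", "atomic_radii.tsv", package = "binderscreen")
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  setNames(tab$radius, tab$element)
}

# deterministic unit sphere points (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param model a `complex_model`
#' @param probe probe radius, Angstrom (water: 1.4)
#' @param n_points sphere test points per atom (>= 92)
#' @param chain_subset if given, SASA of those chains computed in isolation
#' @param radii named radii vector (defaults to the shipped table)
#' @param on_unknown "error" or "default" (use 1.8 A with a warning) for
#'   elements absent from the radii table
#' @return list(per_atom numeric vector, total, probe_radius, n_points)
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               chain_subset = NULL, radii = default_radii(),
                               on_unknown = c("error", "default")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(n_points >= 92, probe >= 0)
  atoms <- if (is.null(chain_subset)) model$atoms else
    model$atoms[model$atoms$chain %in% chain_subset, , drop = FALSE]
  if (!nrow(atoms)) stop("no atoms selected for SASA", call. = FALSE)

  r_at <- radii[atoms$element]
  if (any(is.na(r_at))) {
    bad <- unique(atoms$element[is.na(r_at)])
    if (on_unknown == "error") {
      stop("no radius for element(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    warning("using default radius 1.8 A for: ", paste(bad, collapse = ", "))
    r_at[is.na(r_at)] <- 1.8
  }
  xyz <- atom_xyz(atoms)
  n <- nrow(xyz)
  sphere <- fibonacci_sphere(n_points)

  # neighbor candidates: pairs closer than the largest possible overlap
  max_cut <- 2 * max(r_at) + 2 * probe
  pr <- pairs_within(xyz, xyz, max_cut)
  pr <- pr[pr$i != pr$j & pr$dist <= r_at[pr$i] + r_at[pr$j] + 2 * probe, ]
  neigh <- split(pr$j, factor(pr$i, levels = seq_len(n)))

  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    R <- r_at[i] + probe
    pts <- sphere * R + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    nb <- neigh[[i]]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      rj <- (r_at[j] + probe)^2
      d2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
            (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- d2 > rj
    }
    per_atom[i] <- 4 * pi * R^2 * sum(acc) / n_points
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_points = n_points),
            class = "sasa_result")
}

#' Buried surface area on complex formation (dSASA)
#'
#' SASA(binder alone) + SASA(targets alone) - SASA(complex); non-negative up
#' to numerical tolerance, and symmetric in which side is called the binder.
#'
#' @inheritParams shrake_rupley_sasa
#' @return dSASA in Angstrom^2
#' @export
dsasa <- function(model, probe = 1.4, n_points = 960,
                  radii = default_radii()) {
  if (!length(model$target_chains)) {
    stop("dSASA needs at least one target chain", call. = FALSE)
  }
  s_b <- shrake_rupley_sasa(model, probe, n_points,
                            chain_subset = model$binder_chain, radii = radii)
  s_t <- shrake_rupley_sasa(model, probe, n_points,
                            chain_subset = model$target_chains, radii = radii)
  s_c <- shrake_rupley_sasa(model, probe, n_points,
                            chain_subset = c(model$binder_chain,
                                             model$target_chains),
                            radii = radii)
  s_b$total + s_t$total - s_c$total
}
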