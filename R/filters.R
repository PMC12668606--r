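# The align-and-filter stage: steric-clash rejection, topology rejection,
# and grafting the full-length target template in place of the cropped
# target used during backbone generation.

#' Steric clash filter
#'
#' A design fails when any binder atom sits within `cutoff` (strictly less
#' than; default 0.5 Angstrom) of any target atom.
#'
#' @param model a `complex_model`
#' @param cutoff clash distance, Angstrom
#' @return list(passes, n_clashes)
#' @export
clash_filter <- function(model, cutoff = 0.5) {
  bx <- atom_xyz(chain_atoms(model, model$binder_chain))
  tx <- atom_xyz(model$atoms[model$atoms$chain %in% model$target_chains, ,
                             drop = FALSE])
  pr <- pairs_within(bx, tx, cutoff)
  n <- sum(pr$dist < cutoff)     # strict boundary
  list(passes = n == 0L, n_clashes = n)
}

#' Combined backbone filter with reasons
#'
#' Applies the clash filter first (cheapest), then the topology filter on the
#' binder chain, so rejected designs never reach scoring.
#'
#' @param model a `complex_model`
#' @param clash_cutoff clash distance, Angstrom
#' @param long_helix_min long-helix rejection threshold, residues
#' @return list(passes, reason, n_clashes, topology) where topology is the
#'   [classify_topology()] verdict (NULL when rejected for clashes)
#' @export
backbone_filter <- function(model, clash_cutoff = 0.5, long_helix_min = 40) {
  cl <- clash_filter(model, clash_cutoff)
  if (!cl$passes) {
    return(list(passes = FALSE,
                reason = sprintf("steric_clash (%d pairs < %.2f A)",
                                 cl$n_clashes, clash_cutoff),
                n_clashes = cl$n_clashes, topology = NULL))
  }
  ss <- assign_secondary_structure(model, model$binder_chain)
  topo <- classify_topology(ss, long_helix_min = long_helix_min)
  list(passes = !topo$rejected,
       reason = if (topo$rejected) topo$klass else "",
       n_clashes = 0L, topology = topo)
}

#' Graft the full-length target template onto a design
#'
#' The template chain is rigidly superposed onto the design's (cropped)
#' target using the CA atoms of their shared residue numbers, then replaces
#' it, giving downstream sequence design and scoring the full structural
#' context. Binder coordinates are never touched.
#'
#' @param design a `complex_model` with one target chain (the cropped target)
#' @param template_model a `complex_model` (or single-chain model) holding
#'   the full-length target
#' @param template_chain chain id of the template target within
#'   `template_model`
#' @param cropped_span optional integer range of residue numbers to use for
#'   the superposition (defaults to all shared numbers)
#' @param rmsd_warn shared-CA rmsd above which the result is flagged
#' @return a `complex_model` (binder + transformed template), with
#'   attributes `graft_rmsd`, `n_shared_ca` and `graft_warning`
#' @export
graft_template <- function(design, template_model, template_chain = NULL,
                           cropped_span = NULL, rmsd_warn = 2.0) {
  if (length(design$target_chains) != 1L) {
    stop("grafting expects a design with exactly one target chain",
         call. = FALSE)
  }
  tgt_id <- design$target_chains
  if (is.null(template_chain)) template_chain <- chain_ids(template_model)[1]
  tgt <- chain_atoms(design, tgt_id)
  tpl <- chain_atoms(template_model, template_chain)

  tgt_ca <- tgt[tgt$atom == "CA", , drop = FALSE]
  tpl_ca <- tpl[tpl$atom == "CA", , drop = FALSE]
  shared <- intersect(tgt_ca$resno, tpl_ca$resno)
  if (!is.null(cropped_span)) shared <- intersect(shared, cropped_span)
  if (length(shared) < 3) {
    stop("fewer than 3 shared CA atoms between design target and template",
         call. = FALSE)
  }
  sp <- kabsch_superpose(
    atom_xyz(tpl_ca[match(shared, tpl_ca$resno), ]),
    atom_xyz(tgt_ca[match(shared, tgt_ca$resno), ]))

  moved <- tpl
  moved[, c("x", "y", "z")] <- apply_superposition(sp, atom_xyz(tpl))
  moved$chain <- tgt_id
  binder <- chain_atoms(design, design$binder_chain)
  out <- new_complex_model(rbind(binder, moved), design$binder_chain, tgt_id)
  attr(out, "graft_rmsd") <- sp$rmsd
  attr(out, "n_shared_ca") <- length(shared)
  attr(out, "graft_warning") <- sp$rmsd > rmsd_warn
  if (sp$rmsd > rmsd_warn) {
    warning(sprintf("graft rmsd %.3f A exceeds %.2f A sanity bound",
                    sp$rmsd, rmsd_warn))
  }
  out
}
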