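# AlphaFold-style confidence metrics for a predicted binder-target complex:
# interface detection, binder pLDDT, interchain PAE, and CUTRE -- the
# pLDDT-weighted average interface PAE (lower = more confident).

#' Bundle per-residue pLDDT with a PAE matrix
#'
#' @param plddt numeric vector of per-residue confidences in \[0, 100\]
#' @param pae square matrix, Angstrom; row i = aligned residue, column j =
#'   scored residue (`pae[i, j]` is the expected error of residue j when the
#'   prediction is aligned on residue i)
#' @param chain_spans named list mapping chain id to the 1-based global
#'   residue indices of that chain, binder first, concatenation order; the
#'   spans must partition `1:length(plddt)`
#' @return a `confidence_bundle`
#' @export
confidence_bundle <- function(plddt, pae, chain_spans) {
  pae <- as.matrix(pae)
  n <- length(plddt)
  if (nrow(pae) != n || ncol(pae) != n) {
    stop("PAE matrix must be square with side = length(plddt)", call. = FALSE)
  }
  if (any(pae < 0)) stop("PAE entries must be >= 0", call. = FALSE)
  if (any(plddt < 0 | plddt > 100)) {
    stop("pLDDT values must lie in [0, 100]", call. = FALSE)
  }
  idx <- sort(unlist(chain_spans, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(n))) {
    stop("chain spans must partition 1:", n, call. = FALSE)
  }
  structure(list(plddt = as.numeric(plddt), pae = pae,
                 chain_spans = chain_spans),
            class = "confidence_bundle")
}

#' Read AF2/ColabFold-style confidence JSON
#'
#' Accepts the common dialects: top-level or nested `pae` /
#' `predicted_aligned_error` for the matrix and `plddt` for the per-residue
#' vector. pLDDT may instead be taken from a model's B-factor column via
#' [plddt_from_bfactor()].
#'
#' @param path JSON file path
#' @param chain_spans as in [confidence_bundle()]
#' @param plddt optional pLDDT vector when the JSON has none
#' @return a `confidence_bundle`
#' @export
read_af2_json <- function(path, chain_spans, plddt = NULL) {
  js <- jsonlite::fromJSON(path)
  if (is.data.frame(js) || (is.list(js) && is.null(names(js)))) js <- js[[1]]
  pae <- js$pae
  if (is.null(pae)) pae <- js$predicted_aligned_error
  if (is.null(pae)) stop("no 'pae'/'predicted_aligned_error' key in ", path,
                         call. = FALSE)
  if (is.null(plddt)) plddt <- js$plddt
  if (is.null(plddt)) stop("no pLDDT in JSON and none supplied", call. = FALSE)
  confidence_bundle(as.numeric(plddt), as.matrix(pae), chain_spans)
}

#' Per-residue pLDDT from the B-factor column
#'
#' AF2-style models store per-residue pLDDT in the B-factor field; this
#' returns one value per residue (that of its first atom), in
#' chain-concatenation order (binder first, then targets).
#'
#' @param model a `complex_model`
#' @return numeric vector, one pLDDT per residue
#' @export
plddt_from_bfactor <- function(model) {
  out <- numeric(0)
  for (ch in c(model$binder_chain, model$target_chains)) {
    ca <- chain_atoms(model, ch)
    key <- paste(ca$resno, ca$ins, sep = "|")
    out <- c(out, ca$b[!duplicated(key)])
  }
  out
}

#' Chain spans of a model in binder-first concatenation order
#' @param model a `complex_model`
#' @return named list of 1-based global residue index vectors
#' @export
model_chain_spans <- function(model) {
  spans <- list()
  pos <- 0L
  for (ch in c(model$binder_chain, model$target_chains)) {
    nr <- n_residues(model, ch)
    spans[[ch]] <- pos + seq_len(nr)
    pos <- pos + nr
  }
  spans
}

#' Interface residues of a complex
#'
#' A residue belongs to the interface when at least one of its atoms lies
#' within `cutoff` (inclusive) of any atom of the opposite chain. Indices
#' are global positions in binder-first chain-concatenation order, matching
#' the PAE matrix of a [confidence_bundle()].
#'
#' @param model a `complex_model`
#' @param cutoff interface distance, Angstrom (default 10)
#' @return list(target_residues, binder_residues, cutoff) -- an
#'   `interface_set`
#' @export
interface_residues <- function(model, cutoff = 10.0) {
  spans <- model_chain_spans(model)
  b_at <- chain_atoms(model, model$binder_chain)
  t_at <- model$atoms[model$atoms$chain %in% model$target_chains, ,
                      drop = FALSE]
  if (!nrow(b_at) || !nrow(t_at)) {
    stop("binder and target chains must be non-empty", call. = FALSE)
  }
  pr <- pairs_within(atom_xyz(b_at), atom_xyz(t_at), cutoff)

  # atom row -> global residue index
  res_index <- function(at, chains) {
    idx <- integer(nrow(at))
    for (ch in chains) {
      sel <- at$chain == ch
      key <- paste(at$resno[sel], at$ins[sel], sep = "|")
      idx[sel] <- spans[[ch]][match(key, unique(key))]
    }
    idx
  }
  b_res <- res_index(b_at, model$binder_chain)
  t_res <- res_index(t_at, model$target_chains)
  structure(list(target_residues = sort(unique(t_res[pr$j])),
                 binder_residues = sort(unique(b_res[pr$i])),
                 cutoff = cutoff),
            class = "interface_set")
}

#' Mean binder pLDDT
#'
#' Arithmetic mean of per-residue pLDDT over the binder chain; the
#' conventional `pLDDT_binder` hit metric (> 80 passes by default).
#'
#' @param bundle a `confidence_bundle`
#' @param binder_chain binder chain id within the bundle's spans
#' @return mean pLDDT
#' @export
plddt_binder <- function(bundle, binder_chain = "A") {
  span <- bundle$chain_spans[[binder_chain]]
  if (!length(span)) stop("empty binder span", call. = FALSE)
  mean(bundle$plddt[span])
}

#' Interchain PAE (PAE_interaction)
#'
#' Symmetric two-block mean: half the sum of the mean PAE over binder-rows x
#' target-columns and over target-rows x binder-columns. The conventional
#' hit metric (< 10 passes by default).
#'
#' @param bundle a `confidence_bundle`
#' @param binder_chain binder chain id
#' @return PAE_interaction in Angstrom
#' @export
pae_interaction <- function(bundle, binder_chain = "A") {
  b <- bundle$chain_spans[[binder_chain]]
  t <- unlist(bundle$chain_spans[setdiff(names(bundle$chain_spans),
                                         binder_chain)],
              use.names = FALSE)
  if (!length(b) || !length(t)) {
    stop("need a non-empty binder span and at least one target span",
         call. = FALSE)
  }
  (mean(bundle$pae[b, t]) + mean(bundle$pae[t, b])) / 2
}

#' CUTRE: pLDDT-weighted average interface PAE
#'
#' Average of the inter-chain PAE restricted to interface residues, each
#' term weighted by the pLDDT (scaled to \[0, 1\]) of the residue the
#' structure is aligned on:
#'
#' CUTRE = 1/(2 N_T N_B) * ( sum over i in T, j in B of PAE_ij * pLDDT_i/100
#'         + sum over j in B, i in T of PAE_ji * pLDDT_j/100 )
#'
#' where T and B are the target and binder interface residue sets. Being a
#' weighted PAE, lower values mean a more confident interface; regions
#' predicted with low pLDDT contribute proportionally less.
#'
#' @param bundle a `confidence_bundle`
#' @param iface an `interface_set` from [interface_residues()]
#' @return the CUTRE score
#' @export
cutre <- function(bundle, iface) {
  T_set <- iface$target_residues
  B_set <- iface$binder_residues
  if (!length(T_set) || !length(B_set)) {
    stop("empty interface: CUTRE is undefined", call. = FALSE)
  }
  w <- bundle$plddt / 100
  term_tb <- sum(bundle$pae[T_set, B_set, drop = FALSE] * w[T_set])
  term_bt <- sum(bundle$pae[B_set, T_set, drop = FALSE] * w[B_set])
  (term_tb + term_bt) / (2 * length(T_set) * length(B_set))
}
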