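# Hit export for downstream work: structures as PDB, binder sequences as
# FASTA, codon-usage reverse translation with cloning flanks, and ungapped
# BLOSUM62 similarity between equal-length binder sequences.

#' Load a codon-usage table
#'
#' Plain TSV with columns `codon` and `per_thousand`; amino-acid assignment
#' comes from the standard genetic code. The shipped default is an
#' E. coli K-12 usage table, the organism binders are typically expressed
#' in; substitute any organism by pointing at another TSV.
#'
#' @param path TSV path (default: shipped E. coli K-12 table)
#' @param name organism label
#' @return a `codon_table`: data.frame(codon, aa, weight) plus a name
#'   attribute
#' @export
load_codon_table <- function(path = NULL, name = "E. coli K-12") {
  if (is.null(path)) {
    path <- system.file("extdata", "codon_usage_ecoli_k12.tsv",
                        package = "binderscreen")
  }
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "per_thousand") %in% names(tab)))
  gc <- Biostrings::GENETIC_CODE
  tab$aa <- as.character(gc[tab$codon])
  if (any(is.na(tab$aa))) {
    stop("invalid codon(s) in table: ",
         paste(tab$codon[is.na(tab$aa)], collapse = ", "), call. = FALSE)
  }
  tab <- tab[tab$aa != "*", c("codon", "aa", "per_thousand")]
  names(tab)[3] <- "weight"
  if (any(tab$weight <= 0)) stop("codon weights must be positive",
                                 call. = FALSE)
  covered <- sort(unique(tab$aa))
  if (!all(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] %in% covered)) {
    stop("codon table does not cover all 20 amino acids", call. = FALSE)
  }
  structure(tab, name = name, class = c("codon_table", "data.frame"))
}

#' Reverse-translate a protein to a DNA coding sequence
#'
#' Produces `flank5 + codons + flank3`. In `"top"` mode each residue gets
#' its highest-usage codon (deterministic); in `"sampled"` mode codons are
#' drawn proportionally to usage under `seed`. Translating the core back
#' with the standard genetic code recovers the protein exactly.
#'
#' @param protein amino-acid string (no X)
#' @param table a `codon_table`
#' @param flank5,flank3 DNA flanks for cloning (may be empty)
#' @param mode "top" or "sampled"
#' @param seed RNG seed for sampled mode
#' @return DNA string
#' @export
reverse_translate <- function(protein, table = load_codon_table(),
                              flank5 = "", flank3 = "",
                              mode = c("top", "sampled"), seed = 1) {
  mode <- match.arg(mode)
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  aas <- strsplit(toupper(protein), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aas %in% valid)) {
    stop("invalid residue(s): ",
         paste(unique(aas[!aas %in% valid]), collapse = ", "), call. = FALSE)
  }
  for (fl in c(flank5, flank3)) {
    if (nzchar(fl) && grepl("[^ACGTacgt]", fl)) {
      stop("flanks must be DNA over A/C/G/T", call. = FALSE)
    }
  }
  by_aa <- split(table[, c("codon", "weight")], table$aa)
  codons <- if (mode == "top") {
    vapply(aas, function(a) {
      cc <- by_aa[[a]]
      cc$codon[which.max(cc$weight)]
    }, "")
  } else {
    with_seed(seed, vapply(aas, function(a) {
      cc <- by_aa[[a]]
      sample(cc$codon, 1, prob = cc$weight)
    }, ""))
  }
  paste0(toupper(flank5), paste(codons, collapse = ""), toupper(flank3))
}

#' Translate a DNA coding sequence (standard genetic code)
#' @param dna DNA string, length a multiple of 3
#' @return amino-acid string
#' @export
translate_dna <- function(dna) {
  if (nchar(dna) %% 3 != 0) stop("length must be a multiple of 3",
                                 call. = FALSE)
  # no.init.codon: a leading TTG/CTG is an ordinary codon here, not a start
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Ungapped BLOSUM62 similarity of two equal-length sequences
#'
#' Position-wise sum of the published BLOSUM62 substitution scores.
#' Sequence-diversity refinement keeps the backbone (and hence length)
#' fixed, so alignment-free scoring against the reference binder applies.
#'
#' @param seq_a,seq_b amino-acid strings of equal length
#' @return integer total score
#' @export
blosum62_score <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  mat <- blosum62_matrix()
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ok <- a %in% std & b %in% std
  if (!all(ok)) {
    stop("unknown residue(s): ",
         paste(unique(c(a[!ok], b[!ok])), collapse = ", "), call. = FALSE)
  }
  sum(mat[cbind(a, b)])
}

blosum62_env <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$mat <- e$BLOSUM62
  }
  blosum62_env$mat
}

#' Extract hit structures and sequences
#'
#' Writes one PDB per hit (with the B-factor column holding per-residue
#' pLDDT when supplied) and one multi-FASTA of binder sequences (headers =
#' design ids, wrapped at 60 columns), plus a JSON manifest.
#'
#' @param records list of hit `score_record`s
#' @param structures named list mapping design id to `complex_model`
#' @param out_dir output directory (created if needed)
#' @param plddt optional named list mapping design id to a per-residue
#'   pLDDT vector in chain-concatenation order
#' @return the manifest (list of files written), invisibly written to
#'   `manifest.json`
#' @export
extract_hits <- function(records, structures, out_dir, plddt = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(pdb = character(0), fasta = NULL,
                   model_note = "models written as stored by the campaign")
  seqs <- character(0)
  for (r in records) {
    id <- r$design_id
    m <- structures[[id]]
    if (is.null(m)) stop("no structure for hit '", id, "'", call. = FALSE)
    if (!is.null(plddt[[id]])) {
      # spread per-residue pLDDT over the atoms of each residue
      spans <- model_chain_spans(m)
      for (ch in names(spans)) {
        ca <- m$atoms$chain == ch
        key <- paste(m$atoms$resno[ca], m$atoms$ins[ca], sep = "|")
        m$atoms$b[ca] <- plddt[[id]][spans[[ch]][match(key, unique(key))]]
      }
    }
    f <- file.path(out_dir, paste0(id, ".pdb"))
    writeLines(sub("\n$", "", write_pdb(m)), f)
    manifest$pdb <- c(manifest$pdb, f)
    seqs[id] <- sequence_of(m, m$binder_chain)
  }
  if (length(seqs)) {
    fa <- file.path(out_dir, "hits.fasta")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fa, width = 60)
    manifest$fasta <- fa
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
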