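#' Study peptide sequences
#'
#' One-letter sequences of the 26-residue cecropin--melittin hybrid peptide
#' and its three N-terminal mutants, as used throughout the package's worked
#' examples.  The wild type is the classic amphiphilic antimicrobial hybrid;
#' the mutants modify only the N-terminal region (aromatic content or
#' charge).
#'
#' Two naming schemes are in circulation for the mutants.  The primary
#' labels (`mutant_A`, `mutant_B`, `mutant_C`) follow the synthesis order:
#' A replaces the N-terminal aromatics with alanine, B replaces the
#' N-terminal lysines with serine, and C carries one extra aromatic residue
#' (L4F).  Because the narrative descriptions of the mutants are sometimes
#' attached to different letters, descriptive aliases are provided and
#' recommended for new code: `extra_aromatic` (one additional N-terminal
#' aromatic), `serine_substituted` (charged residues replaced by serine) and
#' `aromatics_removed`.  `peptide_aliases()` returns the full mapping.
#'
#' @param name Label of the peptide.  One of `"wild_type"`, `"mutant_A"`,
#'   `"mutant_B"`, `"mutant_C"`, or a descriptive alias
#'   (`"aromatics_removed"`, `"serine_substituted"`, `"extra_aromatic"`).
#' @return `get_peptide()` returns a list with elements `name` (the primary
#'   label), `sequence` (one-letter string) and `n_residues`.
#'   `peptide_names()` returns the four primary labels; `peptide_aliases()`
#'   a named character vector mapping aliases to primary labels.
#' @examples
#' get_peptide("wild_type")$sequence
#' get_peptide("serine_substituted")$name   # resolves to mutant_B
#' @export
get_peptide <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% names(.peptide_alias_map)) {
    name <- .peptide_alias_map[[name]]
  }
  if (!name %in% names(.peptide_sequences)) {
    stop("unknown peptide label '", name, "'; known labels: ",
         paste(c(names(.peptide_sequences), names(.peptide_alias_map)),
               collapse = ", "), call. = FALSE)
  }
  seq <- .peptide_sequences[[name]]
  list(name = name, sequence = seq, n_residues = nchar(seq))
}

.peptide_sequences <- list(
  wild_type = "KWKLFKKIGIGAVLKVLTTGLPALIS",
  mutant_A  = "KAKLAKKIGIGAVLKVLTTGLPALIS",
  mutant_B  = "SWSLFSSIGIGAVLKVLTTGLPALIS",
  mutant_C  = "KWKFFKKIGIGAVLKVLTTGLPALIS"
)

# descriptive aliases keyed on what each mutation does to the N-terminus
.peptide_alias_map <- c(
  aromatics_removed  = "mutant_A",
  serine_substituted = "mutant_B",
  extra_aromatic     = "mutant_C"
)

#' @rdname get_peptide
#' @export
peptide_names <- function() names(.peptide_sequences)

#' @rdname get_peptide
#' @export
peptide_aliases <- function() .peptide_alias_map

# expand a one-letter sequence to three-letter residue names (PDB style)
aa1_to_aa3 <- function(seq1) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  letters1 <- strsplit(seq1, "")[[1]]
  bad <- setdiff(letters1, names(map))
  if (length(bad)) {
    stop("sequence contains non-canonical residue code(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  unname(map[letters1])
}
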