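#' Packaged human histone sequences
#'
#' Canonical human histone H2A type 1 and H2A.Z.1 protein sequences (130
#' and 128 residues, numbering includes the initiator methionine so that
#' tail residue indices match the usual conventions: H2A C-tail 121-130,
#' H2A.Z C-tail 123-128). Shipped with the package so no download is
#' required; provenance is documented in the FASTA headers.
#'
#' @return named character vector with elements `H2A` and `H2A.Z`
#' @export
histone_sequences <- function() {
  path <- system.file("extdata", "histone_sequences.fasta",
                      package = "nucdyn")
  read_fasta_sequences(path)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Write protein sequences to a FASTA file
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta_sequences <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Formal side-chain net charge of a sequence range at pH 7
#'
#' Lys and Arg count +1, Asp and Glu -1, His 0 (neutral at pH 7); termini
#' are ignored.
#'
#' @param seq one-letter amino-acid string
#' @param range residue interval `c(first, last)`; default whole sequence
#' @return integer net charge (units of e)
#' @export
net_charge <- function(seq, range = NULL) {
  n <- nchar(seq)
  if (is.null(range)) range <- c(1L, n)
  if (range[1L] < 1L || range[2L] > n || range[1L] > range[2L])
    stop("range outside sequence of length ", n)
  aa <- strsplit(substr(seq, range[1L], range[2L]), "")[[1L]]
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]))
    stop("sequence contains non-standard residues")
  sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
}

#' Percent identity between two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 scoring and affine
#' gaps (open 10, extend 0.5, the usual needle defaults); identity is the
#' number of identical aligned positions divided by the alignment length
#' (gap columns included). A plain identity substitution matrix (match +1,
#' mismatch 0) is available as an option but tends to scatter gaps and
#' lower the identity of diverged pairs.
#'
#' @param seq_a,seq_b one-letter amino-acid strings
#' @param substitution `"BLOSUM62"` or `"identity"`
#' @param gap_open,gap_ext gap penalties
#' @return percent identity in `[0, 100]`
#' @export
percent_identity <- function(seq_a, seq_b, substitution = c("BLOSUM62", "identity"),
                             gap_open = 10, gap_ext = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  substitution <- match.arg(substitution)
  mat <- if (substitution == "BLOSUM62") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  } else {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    m <- matrix(0, 20L, 20L, dimnames = list(aa, aa))
    diag(m) <- 1
    m
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_ext, type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Preset C-terminal tail swap ranges
#'
#' Two conventions circulate for the H2A/H2A.Z C-tail boundaries: the
#' construct ranges H2A 120-130 with H2A.Z 122-128, and the structural
#' annotation H2A 121-130 with H2A.Z 123-128. Both presets are provided;
#' neither is silently preferred.
#'
#' @param preset `"construct"` (120-130 / 122-128) or `"annotation"`
#'   (121-130 / 123-128)
#' @return list with `range_a` (H2A) and `range_z` (H2A.Z)
#' @export
ctail_swap_preset <- function(preset = c("construct", "annotation")) {
  preset <- match.arg(preset)
  if (preset == "construct")
    list(range_a = c(120L, 130L), range_z = c(122L, 128L))
  else
    list(range_a = c(121L, 130L), range_z = c(123L, 128L))
}

#' Swap the C-terminal tails of H2A and H2A.Z sequences
#'
#' Produces the two tail-swap constructs: H2A with the H2A.Z C-tail and
#' H2A.Z with the H2A C-tail. The ranges must be terminal (extend to the
#' end of each sequence); the prefix before the tail is unchanged and the
#' product lengths differ from the parents by the tail-length difference.
#'
#' @param seq_h2a,seq_h2az one-letter sequences
#' @param range_a,range_z tail intervals `c(first, last)`; defaults are
#'   the `"construct"` preset of [ctail_swap_preset()]
#' @return named list `H2A_H2AZtail`, `H2AZ_H2Atail`
#' @export
swap_ctail <- function(seq_h2a, seq_h2az,
                       range_a = c(120L, 130L), range_z = c(122L, 128L)) {
  check_terminal <- function(seq, r, label) {
    if (r[2L] != nchar(seq))
      stop(label, " tail range must be terminal (end at residue ",
           nchar(seq), ")")
    if (r[1L] < 1L || r[1L] > r[2L]) stop("invalid ", label, " tail range")
  }
  check_terminal(seq_h2a, range_a, "H2A")
  check_terminal(seq_h2az, range_z, "H2A.Z")
  tail_a <- substr(seq_h2a, range_a[1L], range_a[2L])
  tail_z <- substr(seq_h2az, range_z[1L], range_z[2L])
  list(
    H2A_H2AZtail = paste0(substr(seq_h2a, 1L, range_a[1L] - 1L), tail_z),
    H2AZ_H2Atail = paste0(substr(seq_h2az, 1L, range_z[1L] - 1L), tail_a)
  )
}
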