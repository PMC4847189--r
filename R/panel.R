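#' Build a repeat reference panel
#'
#' A panel holds the consensus sequence of each repeat family the reads will
#' be mapped against. Tandem satellite entries are mapped against a
#' head-to-tail dimer of their monomer (the monomer concatenated with
#' itself) so that reads straddling the junction between two monomer copies
#' still align end-to-end; interspersed elements are mapped against their
#' plain consensus.
#'
#' @param sequences named character vector of consensus sequences
#'   (A/C/G/T/N; lower case accepted and upper-cased).
#' @param is_tandem logical vector (recycled) marking tandemly repeated
#'   entries; for these the mapping target is the dimer and reported offsets
#'   are monomer offsets in `[0, monomer_length)`.
#' @return an object of class `reference_panel`: a data frame with columns
#'   `name`, `sequence` (monomer/consensus), `is_tandem`, `monomer_length`,
#'   `target` (the actual mapping target sequence).
#' @examples
#' panel <- reference_panel(c(satA = "ACGTACGTAA", ere = "GGGTTTAAACC"),
#'                          is_tandem = c(TRUE, FALSE))
#' panel$monomer_length
#' @export
reference_panel <- function(sequences, is_tandem = TRUE) {
  if (length(sequences) == 0L) stop("empty panel", call. = FALSE)
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("panel sequences must have unique non-empty names", call. = FALSE)
  }
  seqs <- assert_dna(unname(sequences), "panel sequence")
  is_tandem <- rep_len(as.logical(is_tandem), length(seqs))
  df <- data.frame(
    name = nm,
    sequence = seqs,
    is_tandem = is_tandem,
    monomer_length = nchar(seqs),
    target = ifelse(is_tandem, paste0(seqs, seqs), seqs),
    stringsAsFactors = FALSE
  )
  class(df) <- c("reference_panel", "data.frame")
  df
}

#' Read a reference panel from FASTA
#'
#' @param path FASTA file of consensus sequences.
#' @param is_tandem logical vector or named logical giving tandem status per
#'   entry (default: all tandem).
#' @return a [reference_panel()].
#' @export
read_panel_fasta <- function(path, is_tandem = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  if (!is.null(names(is_tandem))) {
    is_tandem <- unname(is_tandem[names(seqs)])
  }
  reference_panel(seqs, is_tandem)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel with %d entries\n", nrow(x)))
  print.data.frame(x[, c("name", "is_tandem", "monomer_length")], row.names = FALSE)
  invisible(x)
}

#' Write panel monomers as FASTA
#' @param panel a [reference_panel()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  ss <- Biostrings::DNAStringSet(setNames(panel$sequence, panel$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
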