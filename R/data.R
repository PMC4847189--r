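#' Bundled synthetic 221-bp satellite monomer
#'
#' A fixed, randomly generated 221-bp monomer shipped with the package as a
#' stand-in for a real centromeric satellite consensus: it reproduces the
#' two desk-checkable properties of the horse 37cen/SAT_EC unit — a length
#' of 221 bp and a GC content that prints as 53 % (117 of 221 bases are G
#' or C) — but its base order is synthetic, not the Repbase entry. Supply
#' the real consensus through [reference_panel()] or
#' [read_panel_fasta()] when available.
#'
#' @return one named DNA string of length 221.
#' @examples
#' m <- satec_monomer()
#' nchar(m)
#' round(gc_content(m))
#' @export
satec_monomer <- function() {
  path <- system.file("extdata", "satEC_synthetic_monomer.fa",
                      package = "satcen", mustWork = TRUE)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), "satEC_synthetic")
}
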