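# ---- normalisation and enrichment -------------------------------------

#' Depth- and length-normalised read count
#'
#' `raw_count / (total_reads * ref_length) * 1e9` — reads per billion
#' sequenced bases of reference (RPKM-like scale). The scale constant is
#' cosmetic: IP/input ratios built from two such values are scale-free.
#'
#' @param raw_count reads assigned to the reference entry.
#' @param total_reads total reads in the sample (mapped + unmapped).
#' @param ref_length reference sequence length in bp (for tandem satellites,
#'   the monomer length — the dimer is only a mapping artifice).
#' @return normalised abundance (vectorised).
#' @examples
#' normalize_count(100, 1e6, 100)  # 1000
#' @export
normalize_count <- function(raw_count, total_reads, ref_length) {
  if (any(total_reads <= 0) || any(ref_length <= 0)) {
    stop("empty sample/reference", call. = FALSE)
  }
  raw_count / (total_reads * ref_length) * 1e9
}

#' IP/input enrichment ratio from raw counts
#'
#' Ratio of normalised abundances; the reference length cancels when both
#' samples use the same reference. A value of 1 means the element is equally
#' represented in the immunoprecipitated and input fractions.
#'
#' @param raw_ip,total_ip IP raw count and sample total.
#' @param raw_input,total_input input raw count and sample total.
#' @param ref_length reference length (same for both samples).
#' @return the ratio, or `NA` (flagged undefined) where the input count is 0.
#' @examples
#' enrichment_ratio(650, 1e6, 100, 1e6, 221)  # 6.5
#' @export
enrichment_ratio <- function(raw_ip, total_ip, raw_input, total_input,
                             ref_length = 1) {
  num <- normalize_count(raw_ip, total_ip, ref_length)
  den <- normalize_count(raw_input, total_input, ref_length)
  ifelse(den == 0, NA_real_, num / den)
}

#' Per-family enrichment table from IP and input mapping results
#'
#' @param map_ip,map_input results of [map_readset()] on the IP and input
#'   read sets (same panel).
#' @param panel the [reference_panel()] both sets were mapped against.
#' @return data frame of class `enrichment_table`: `entry`, `raw_ip`,
#'   `raw_input`, `total_ip`, `total_input`, `ref_length`, `norm_ip`,
#'   `norm_input`, `ratio`, `undefined` (TRUE where the input normalised
#'   count is 0 and the ratio is therefore NA).
#' @export
enrichment_table <- function(map_ip, map_input, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  raw_ip <- map_ip$summary$per_entry[panel$name]
  raw_input <- map_input$summary$per_entry[panel$name]
  tot_ip <- map_ip$summary$total
  tot_in <- map_input$summary$total
  norm_ip <- normalize_count(raw_ip, tot_ip, panel$monomer_length)
  norm_in <- normalize_count(raw_input, tot_in, panel$monomer_length)
  df <- data.frame(entry = panel$name,
                   raw_ip = as.integer(raw_ip),
                   raw_input = as.integer(raw_input),
                   total_ip = tot_ip, total_input = tot_in,
                   ref_length = panel$monomer_length,
                   norm_ip = norm_ip, norm_input = norm_in,
                   ratio = ifelse(norm_in == 0, NA_real_, norm_ip / norm_in),
                   undefined = norm_in == 0,
                   stringsAsFactors = FALSE, row.names = NULL)
  class(df) <- c("enrichment_table", "data.frame")
  df
}

#' Write an enrichment table as TSV
#' @param tab an `enrichment_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- RNA window counting -----------------------------------------------

#' Build an equal-length RNA counting panel
#'
#' Transcript windows must all share one length L so raw read counts are
#' directly comparable without normalisation. Tandem satellite entries are
#' supplied as monomers and counted against their head-to-tail dimer (which
#' must itself have length L, e.g. a 221-bp monomer for L = 442), with
#' counts reported under the monomer name.
#'
#' @param gene_windows named character vector of transcript windows, all of
#'   length L.
#' @param satellite_monomers named character vector of satellite monomers
#'   whose dimers have length L (may be empty).
#' @return a [reference_panel()] whose targets all have length L.
#' @export
rna_window_panel <- function(gene_windows, satellite_monomers = character(0)) {
  lens <- c(nchar(gene_windows), 2L * nchar(satellite_monomers))
  if (length(lens) == 0L) stop("empty panel", call. = FALSE)
  if (length(unique(lens)) != 1L) {
    stop("windows must share one length", call. = FALSE)
  }
  reference_panel(c(satellite_monomers, gene_windows),
                  is_tandem = c(rep(TRUE, length(satellite_monomers)),
                                rep(FALSE, length(gene_windows))))
}

#' Count RNA-seq reads per equal-length window
#'
#' Maps the reads with the same best-hit percent-identity scheme as the
#' ChIP/input data and reports raw counts per window, unnormalised (the
#' equal window length makes them comparable).
#'
#' @param reads RNA read set (data frame `id`,`seq` or character vector).
#' @param windows a panel from [rna_window_panel()].
#' @param cfg a [mapper_config()].
#' @return data frame `name`, `count`; counts sum to the mapped-read total.
#' @export
count_rna_windows <- function(reads, windows, cfg = mapper_config()) {
  res <- map_readset(reads, windows, cfg)
  data.frame(name = names(res$summary$per_entry),
             count = as.integer(res$summary$per_entry),
             stringsAsFactors = FALSE, row.names = NULL)
}
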