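# ---- mapper configuration ---------------------------------------------

#' Mapper configuration
#'
#' @param min_identity minimum fraction of matching positions for a hit to
#'   be reported (default 0.80, i.e. up to 20 % mismatches).
#' @param allow_indels if `TRUE`, score with semi-global edit distance
#'   (identity = 1 - edit distance / read length) instead of the default
#'   substitution-only per-offset comparison.
#' @return list of class `mapper_config`.
#' @export
mapper_config <- function(min_identity = 0.80, allow_indels = FALSE) {
  if (!(min_identity > 0 && min_identity <= 1)) {
    stop("min_identity must lie in (0, 1]", call. = FALSE)
  }
  structure(list(min_identity = min_identity,
                 allow_indels = isTRUE(allow_indels)),
            class = "mapper_config")
}

# ---- alignment ---------------------------------------------------------

#' Map a read set against a repeat reference panel
#'
#' Every read is placed at its best-identity position across all panel
#' targets, both strands, scanning every offset (exact search with early
#' abandonment; tandem entries are scanned on their monomer dimer so reads
#' spanning the head-to-tail junction align end-to-end, and offsets are
#' reported modulo the monomer length). A read is reported only if its best
#' identity reaches `min_identity`. Ties are resolved to the earliest panel
#' entry (flagged `ambiguous`), the smallest offset within an entry, and the
#' plus strand at equal offset.
#'
#' @param reads data frame with `id` and `seq` columns (e.g. from
#'   [simulate_reads()] or [read_fastq()]), or a named character vector.
#' @param panel a [reference_panel()].
#' @param cfg a [mapper_config()].
#' @return list with `hits` (data frame: `id`, `entry`, `offset`, `strand`,
#'   `identity`, `monomer_offset`, `ambiguous`; one row per mapped read) and
#'   `summary` (list: `total`, `mapped`, `unmapped`, `ambiguous`,
#'   `per_entry` named counts summing to `mapped`).
#' @examples
#' panel <- reference_panel(c(sat = "ACGTTGCAGGTCCATAAGGC"), is_tandem = TRUE)
#' res <- map_readset(c(r1 = "GGCACGTT"), panel)  # junction-spanning read
#' res$hits
#' @export
map_readset <- function(reads, panel, cfg = mapper_config()) {
  stopifnot(inherits(panel, "reference_panel"))
  if (is.character(reads)) {
    reads <- data.frame(id = if (is.null(names(reads)))
      sprintf("read%06d", seq_along(reads)) else names(reads),
      seq = unname(reads), stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0L) {
    return(list(hits = empty_hits(),
                summary = list(total = 0L, mapped = 0L, unmapped = 0L,
                               ambiguous = 0L,
                               per_entry = setNames(rep(0L, nrow(panel)),
                                                    panel$name))))
  }
  seqs <- assert_dna(reads$seq, "read")
  res <- cpp_map_reads(seqs, panel$target, panel$is_tandem,
                       panel$monomer_length, cfg$min_identity,
                       cfg$allow_indels)
  hit <- !is.na(res$entry)
  hits <- data.frame(
    id = reads$id[hit],
    entry = panel$name[res$entry[hit]],
    offset = res$offset[hit],
    strand = res$strand[hit],
    identity = res$identity[hit],
    monomer_offset = ifelse(panel$is_tandem[res$entry[hit]],
                            res$offset[hit] %% panel$monomer_length[res$entry[hit]],
                            NA_integer_),
    ambiguous = res$ambiguous[hit],
    stringsAsFactors = FALSE)
  per_entry <- setNames(rep(0L, nrow(panel)), panel$name)
  tab <- table(hits$entry)
  per_entry[names(tab)] <- as.integer(tab)
  list(hits = hits,
       summary = list(total = nrow(reads), mapped = nrow(hits),
                      unmapped = nrow(reads) - nrow(hits),
                      ambiguous = sum(hits$ambiguous),
                      per_entry = per_entry))
}

empty_hits <- function() {
  data.frame(id = character(0), entry = character(0), offset = integer(0),
             strand = character(0), identity = numeric(0),
             monomer_offset = integer(0), ambiguous = logical(0),
             stringsAsFactors = FALSE)
}

#' Align a single read
#'
#' Single-read convenience wrapper around [map_readset()].
#'
#' @param read one DNA string (A/C/G/T/N).
#' @param panel a [reference_panel()].
#' @param cfg a [mapper_config()].
#' @return a one-row hits data frame, or a zero-row one if the read has no
#'   placement at `min_identity`. An all-N read is a no-hit, not an error.
#' @export
align_read <- function(read, panel, cfg = mapper_config()) {
  stopifnot(length(read) == 1L)
  map_readset(c(read1 = read), panel, cfg)$hits
}

# ---- hit table IO ------------------------------------------------------

#' Write alignment hits as TSV
#' @param hits hits data frame from [map_readset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment hit table written by [write_hits()]
#' @param path TSV file.
#' @return hits data frame.
#' @export
read_hits <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
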