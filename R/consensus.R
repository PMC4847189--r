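# ---- base frequency matrix / consensus / logo --------------------------

#' Build a per-position base-frequency matrix from reads mapped to a monomer
#'
#' Each aligned read base is assigned to monomer position
#' `(offset + i) mod monomer_length` (reads on the minus strand are
#' reverse-complemented first, so all counts are on the monomer's plus
#' strand). The resulting matrix is the tested object behind the sequence
#' logo: per-position base counts, frequencies, information content
#' (`2 - Shannon entropy` in bits) and the majority-vote consensus.
#'
#' @param hits hits data frame from [map_readset()], restricted to (or
#'   filtered for) one tandem panel entry.
#' @param reads the read set the hits refer to (data frame `id`, `seq`).
#' @param entry name of the tandem entry to profile (default: the single
#'   entry present in `hits`).
#' @param monomer_length monomer length in bp.
#' @return object of class `base_freq_matrix`: list with `counts` (4 x L
#'   matrix, rows A/C/G/T), `freq` (columns sum to 1 where covered),
#'   `coverage` (per-position base count), `info_bits` (in `[0, 2]`; 0 for
#'   uncovered positions, which are also listed in `uncovered`), `consensus`
#'   and `ambiguous` (positions whose majority vote was tied).
#' @export
build_base_matrix <- function(hits, reads, entry = NULL, monomer_length) {
  if (monomer_length <= 0) stop("monomer_length must be positive", call. = FALSE)
  if (is.null(entry)) {
    entry <- unique(hits$entry)
    if (length(entry) != 1L) {
      stop("hits span several entries; pass `entry`", call. = FALSE)
    }
  }
  h <- hits[hits$entry == entry, , drop = FALSE]
  if (any(h$offset < 0 | h$offset >= monomer_length)) {
    stop("hit offset out of range for monomer_length", call. = FALSE)
  }
  seqs <- setNames(reads$seq, reads$id)[h$id]
  neg <- h$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  counts <- cpp_base_counts(unname(seqs), as.integer(h$offset),
                            as.integer(monomer_length))
  rownames(counts) <- .satcen_bases
  base_freq_matrix(counts)
}

# wrap a 4 x L count matrix into the derived-quantity object
base_freq_matrix <- function(counts) {
  cov <- colSums(counts)
  freq <- counts
  freq[, cov > 0] <- sweep(counts[, cov > 0, drop = FALSE], 2,
                           cov[cov > 0], "/")
  freq[, cov == 0] <- 0
  p <- freq
  ent <- -colSums(ifelse(p > 0, p * log2(p), 0))
  info <- ifelse(cov > 0, 2 - ent, 0)
  cons <- consensus_from_counts(counts)
  structure(list(counts = counts, freq = freq, coverage = cov,
                 info_bits = info, consensus = cons$seq,
                 ambiguous = cons$ambiguous,
                 uncovered = which(cov == 0)),
            class = "base_freq_matrix")
}

consensus_from_counts <- function(counts) {
  L <- ncol(counts)
  cov <- colSums(counts)
  top <- apply(counts, 2, max)
  # ties broken alphabetically: which.max over A,C,G,T row order
  idx <- apply(counts, 2, which.max)
  base <- .satcen_bases[idx]
  base[cov == 0] <- "N"
  tied <- colSums(counts == rep(top, each = 4)) > 1 & cov > 0
  list(seq = paste(base, collapse = ""), ambiguous = which(tied))
}

#' Call the consensus sequence of a base-frequency matrix
#'
#' Per position, the base with the maximal count; ties are broken
#' alphabetically (A < C < G < T) and reported in `ambiguous`; zero-coverage
#' positions emit `N`.
#'
#' @param mat a `base_freq_matrix` (or bare 4 x L count matrix with rows
#'   A,C,G,T).
#' @return list with `seq` (consensus string) and `ambiguous` (integer
#'   positions with tied majority).
#' @export
consensus_call <- function(mat) {
  counts <- if (inherits(mat, "base_freq_matrix")) mat$counts else mat
  consensus_from_counts(counts)
}

#' @export
print.base_freq_matrix <- function(x, ...) {
  cat(sprintf("base_freq_matrix: %d positions, median coverage %.0f, %d ambiguous, %d uncovered\n",
              ncol(x$counts), median(x$coverage), length(x$ambiguous),
              length(x$uncovered)))
  cat("consensus:", substr(x$consensus, 1, 60),
      if (ncol(x$counts) > 60) "..." else "", "\n")
  invisible(x)
}

#' Write a base-frequency matrix as TSV
#'
#' One row per monomer position: counts, frequencies, information content
#' and the consensus base.
#'
#' @param mat a `base_freq_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_base_matrix <- function(mat, path) {
  cons <- strsplit(mat$consensus, "")[[1]]
  df <- data.frame(position = seq_len(ncol(mat$counts)),
                   A = mat$counts["A", ], C = mat$counts["C", ],
                   G = mat$counts["G", ], T = mat$counts["T", ],
                   freqA = mat$freq["A", ], freqC = mat$freq["C", ],
                   freqG = mat$freq["G", ], freqT = mat$freq["T", ],
                   info_bits = mat$info_bits, consensus_base = cons)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' GC content of a DNA sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from numerator
#' and denominator.
#'
#' @param sequence one DNA string.
#' @return GC percentage.
#' @examples
#' gc_content("GGCC")  # 100
#' @export
gc_content <- function(sequence) {
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0)
  s <- assert_dna(sequence, "sequence")
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
  acgt <- sum(f[c("A", "C", "G", "T")])
  if (acgt == 0) stop("no informative bases", call. = FALSE)
  100 * sum(f[c("G", "C")]) / acgt
}
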