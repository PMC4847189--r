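# ---- stringent peak filtering ------------------------------------------

#' Stringent peak selection criteria
#'
#' All four thresholds are strict lower bounds (`>`), so boundary values
#' fail. Defaults are the stringent selection used for CENP-A ChIP peaks:
#' fold enrichment > 5, pile-up > 100, -log10(p) > 100, -log10(q) > 100.
#'
#' @param min_fold_enrichment,min_pileup,min_neg_log10_p,min_neg_log10_q
#'   strict thresholds, all >= 0.
#' @return list of class `peak_filter_criteria`.
#' @export
peak_filter_criteria <- function(min_fold_enrichment = 5,
                                 min_pileup = 100,
                                 min_neg_log10_p = 100,
                                 min_neg_log10_q = 100) {
  v <- c(min_fold_enrichment, min_pileup, min_neg_log10_p, min_neg_log10_q)
  if (any(v < 0)) stop("thresholds must be >= 0", call. = FALSE)
  structure(list(min_fold_enrichment = min_fold_enrichment,
                 min_pileup = min_pileup,
                 min_neg_log10_p = min_neg_log10_p,
                 min_neg_log10_q = min_neg_log10_q),
            class = "peak_filter_criteria")
}

peak_columns <- c("contig", "start", "end", "fold_enrichment", "pileup",
                  "neg_log10_p", "neg_log10_q")

validate_peaks <- function(peaks) {
  miss <- setdiff(peak_columns, names(peaks))
  if (length(miss)) {
    stop("peak table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- peaks[, c("start", "end", "fold_enrichment", "pileup",
                   "neg_log10_p", "neg_log10_q")]
  bad <- which(!stats::complete.cases(num) | peaks$start >= peaks$end |
                 peaks$fold_enrichment < 0 | peaks$pileup < 0 |
                 peaks$neg_log10_p < 0 | peaks$neg_log10_q < 0)
  if (length(bad)) {
    stop(sprintf("malformed peak record at line %d", bad[1]), call. = FALSE)
  }
  invisible(peaks)
}

#' Filter ChIP peaks by the stringent criteria
#'
#' Keeps exactly the records strictly exceeding all four thresholds,
#' preserving input order. Kept/dropped counts are attached as the
#' `"summary"` attribute; [summarize_peaks()] adds per-family tallies.
#'
#' @param peaks data frame with columns `contig`, `start`, `end`,
#'   `fold_enrichment`, `pileup`, `neg_log10_p`, `neg_log10_q`.
#' @param criteria a [peak_filter_criteria()].
#' @return the surviving records, with attribute `summary`
#'   (list `total`, `kept`, `dropped`).
#' @examples
#' pk <- data.frame(contig = "c1", start = 0, end = 100,
#'                  fold_enrichment = c(6, 5), pileup = 150,
#'                  neg_log10_p = 120, neg_log10_q = 110)
#' nrow(filter_peaks(pk))  # 1: fold_enrichment == 5 fails the strict bound
#' @export
filter_peaks <- function(peaks, criteria = peak_filter_criteria()) {
  validate_peaks(peaks)
  keep <- peaks$fold_enrichment > criteria$min_fold_enrichment &
    peaks$pileup > criteria$min_pileup &
    peaks$neg_log10_p > criteria$min_neg_log10_p &
    peaks$neg_log10_q > criteria$min_neg_log10_q
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(total = nrow(peaks), kept = sum(keep),
                               dropped = sum(!keep))
  out
}

#' Tally filtered peaks by repeat family
#'
#' Joins peak records with region classifications and reports per-family
#' counts and fractions — the "N regions, x % consisting of family f" style
#' summary.
#'
#' @param peaks a (filtered) peak table.
#' @param classifications data frame from [classify_regions()] aligned
#'   row-by-row with `peaks` (or joinable via a shared `region` column in
#'   both).
#' @return data frame `family`, `n`, `fraction`.
#' @export
summarize_peaks <- function(peaks, classifications) {
  if ("region" %in% names(peaks) && "region" %in% names(classifications)) {
    fam <- classifications$family[match(peaks$region, classifications$region)]
  } else {
    if (nrow(peaks) != nrow(classifications)) {
      stop("peaks and classifications must align by row or share a region column",
           call. = FALSE)
    }
    fam <- classifications$family
  }
  tab <- table(fam)
  data.frame(family = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Import a MACS-style peak table
#'
#' Accepts tab-separated tables with a header line; column names are
#' matched case-insensitively against common MACS spellings
#' (`chr`/`contig`, `fold_enrichment`, `pileup`, `-log10(pvalue)`,
#' `-log10(qvalue)`), with `column_map` available for dialect drift.
#'
#' @param path TSV file (comment lines starting `#` are skipped).
#' @param column_map optional named character vector mapping this package's
#'   canonical names (see [filter_peaks()]) to the file's column names.
#' @param one_based if `TRUE` (MACS convention), start coordinates are
#'   shifted to 0-based half-open.
#' @return a peak table data frame.
#' @export
read_peak_table <- function(path, column_map = NULL, one_based = TRUE) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  have <- canon(names(df))
  defaults <- list(
    contig = c("contig", "chr", "chrom", "chromosome", "seqnames"),
    start = "start", end = "end",
    fold_enrichment = c("foldenrichment", "fe", "foldchange"),
    pileup = "pileup",
    neg_log10_p = c("neglog10p", "log10pvalue", "log10pvalue", "pvalue10",
                    "log10p"),
    neg_log10_q = c("neglog10q", "log10qvalue", "qvalue10", "log10q"))
  out <- list()
  for (nm in peak_columns) {
    src <- if (!is.null(column_map) && nm %in% names(column_map)) {
      which(names(df) == column_map[[nm]])
    } else {
      which(have %in% canon(defaults[[nm]]))
    }
    if (length(src) == 0L) {
      stop("cannot locate column for ", nm, " in ", path, call. = FALSE)
    }
    out[[nm]] <- df[[src[1L]]]
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (one_based) out$start <- out$start - 1L
  validate_peaks(out)
  out
}

# ---- minimal window-based domain caller --------------------------------

# Benjamini-Hochberg on log10 p-values, done in log space so q-values stay
# meaningful in the -log10 p > 100 regime where raw p underflows to 0.
bh_log10 <- function(log10p) {
  n <- length(log10p)
  o <- order(log10p)
  lq <- log10p[o] + log10(n / seq_len(n))
  lq <- rev(cummin(rev(lq)))
  lq <- pmin(lq, 0)
  out <- numeric(n)
  out[o] <- lq
  out
}

#' Call enrichment domains from IP and input coverage tracks
#'
#' A deliberately minimal window caller so the synthetic pipeline runs end
#' to end without external peak software (it does not emulate MACS's local
#' background model). Non-overlapping windows with depth-normalised
#' smoothed IP/input coverage ratio at or above `min_ratio` are merged into
#' domains; each domain's `fold_enrichment` is its mean window ratio,
#' `pileup` the maximum raw IP coverage, and its p-value a one-sided
#' binomial tail on the approximate read counts in the domain (computed in
#' log space), converted to q by Benjamini-Hochberg across domains.
#'
#' @param ip_track,input_track integer per-base coverage vectors of equal
#'   length.
#' @param window window size in bp.
#' @param min_ratio minimal normalised IP/input window ratio.
#' @param read_length read length used to convert coverage to approximate
#'   read counts.
#' @param total_ip,total_input total reads per sample (defaults estimated
#'   from the tracks).
#' @param contig contig name for the emitted records.
#' @return peak table data frame (possibly zero rows), as for
#'   [filter_peaks()].
#' @export
call_domains <- function(ip_track, input_track, window = 200L,
                         min_ratio = 2, read_length = 100L,
                         total_ip = NULL, total_input = NULL,
                         contig = "chrSim") {
  if (length(ip_track) != length(input_track)) {
    stop("tracks must have the same length", call. = FALSE)
  }
  if (window <= 0) stop("window must be positive", call. = FALSE)
  if (all(input_track == 0)) stop("cannot form ratio", call. = FALSE)
  G <- length(ip_track)
  if (is.null(total_ip)) total_ip <- sum(ip_track) / read_length
  if (is.null(total_input)) total_input <- sum(input_track) / read_length

  nb <- G %/% window
  if (nb == 0L) stop("track shorter than one window", call. = FALSE)
  idx <- rep(seq_len(nb), each = window)
  used <- seq_len(nb * window)
  ip_m <- tapply(ip_track[used], idx, mean)
  in_m <- tapply(input_track[used], idx, mean)
  pc <- read_length / window       # pseudo-coverage of one read per window
  ratio <- ((ip_m + pc) / (in_m + pc)) * (total_input / total_ip)
  qual <- ratio >= min_ratio

  runs <- rle(as.vector(qual))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  if (length(sel) == 0L) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), fold_enrichment = numeric(0),
                      pileup = numeric(0), neg_log10_p = numeric(0),
                      neg_log10_q = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  p0 <- total_ip / (total_ip + total_input)
  rows <- lapply(sel, function(k) {
    b1 <- starts[k]; b2 <- ends[k]
    span <- ((b1 - 1L) * window + 1L):(b2 * window)
    x_ip <- sum(ip_track[span]) / read_length
    x_in <- sum(input_track[span]) / read_length
    n <- round(x_ip + x_in)
    x <- round(x_ip)
    logp <- pbinom(x - 1, n, p0, lower.tail = FALSE, log.p = TRUE) / log(10)
    data.frame(contig = contig, start = (b1 - 1L) * window,
               end = b2 * window,
               fold_enrichment = mean(ratio[b1:b2]),
               pileup = max(ip_track[span]),
               neg_log10_p = -logp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$neg_log10_q <- -bh_log10(-out$neg_log10_p)
  rownames(out) <- NULL
  out
}

#' Per-base coverage track from simulated read ground truth
#'
#' Uses the true start positions encoded in simulated read identifiers to
#' build a coverage vector, standing in for genome alignment (which is
#' outside this package's scope).
#'
#' @param reads data frame from [simulate_reads()].
#' @param genome_length genome length in bp.
#' @param read_length read length in bp.
#' @return integer coverage vector of length `genome_length`.
#' @export
coverage_track <- function(reads, genome_length, read_length = NULL) {
  truth <- parse_read_truth(reads$id)
  if (is.null(read_length)) read_length <- nchar(reads$seq[1])
  d <- integer(genome_length + 1L)
  s <- truth$start + 1L
  e <- pmin(truth$start + read_length, genome_length) + 1L
  ts <- table(s); te <- table(e)
  d[as.integer(names(ts))] <- d[as.integer(names(ts))] + as.integer(ts)
  d[as.integer(names(te))] <- d[as.integer(names(te))] - as.integer(te)
  cumsum(d)[seq_len(genome_length)]
}
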