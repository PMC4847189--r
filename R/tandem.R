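# ---- tandem structure --------------------------------------------------

#' Estimate the fundamental repeat unit length of a sequence
#'
#' For each candidate lag p, computes the self-match fraction
#' `mean(s[i] == s[i + p])` over all valid i (equivalent to the lag-p
#' autocorrelation of the one-hot encoded sequence). Returns the smallest
#' lag among near-maximal lags (within `tol` of the maximum) whose match
#' fraction exceeds `min_match`, so multiples of the fundamental period are
#' not reported. Random sequence scores ~0.25 at every lag and yields `NA`.
#'
#' @param sequence one DNA string.
#' @param min_lag,max_lag lag search range; `max_lag` defaults to half the
#'   sequence length so at least two repeat units support the estimate.
#' @param min_match significance threshold on the match fraction (default
#'   0.7).
#' @param tol near-maximum tolerance within which the smallest lag wins.
#' @return the period in bp, or `NA` (with a warning for too-short input).
#' @examples
#' estimate_period(strrep("ACGTTGCAGG", 8))  # 10
#' @export
estimate_period <- function(sequence, min_lag = 10L, max_lag = NULL,
                            min_match = 0.7, tol = 0.02) {
  s <- assert_dna(sequence, "sequence")
  n <- nchar(s)
  if (is.null(max_lag)) max_lag <- n %/% 2L
  max_lag <- min(max_lag, n - 1L)
  if (n < 2L * min_lag || max_lag < min_lag) {
    warning("sequence too short for period estimation")
    return(NA_integer_)
  }
  v <- utf8ToInt(s)
  lags <- min_lag:max_lag
  match_frac <- vapply(lags, function(p) {
    mean(v[seq_len(n - p)] == v[(p + 1L):n])
  }, numeric(1))
  best <- max(match_frac)
  if (best < min_match) return(NA_integer_)
  lags[which(match_frac >= best - tol)[1L]]
}

#' Locate monomer placements along a sequence
#'
#' Slides the monomer along both strands of the sequence, keeps offsets with
#' identity at or above `min_identity`, and greedily selects
#' non-overlapping placements in order of decreasing identity.
#'
#' @param sequence one DNA string.
#' @param monomer monomer sequence.
#' @param min_identity identity floor per placement.
#' @return data frame `start` (0-based), `end`, `strand`, `identity`,
#'   sorted by `start`.
#' @export
find_placements <- function(sequence, monomer, min_identity = 0.8) {
  s <- assert_dna(sequence, "sequence")
  m <- assert_dna(monomer, "monomer")
  prof <- cpp_identity_profile(s, m)
  if (nrow(prof) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0)))
  }
  lm <- nchar(m)
  cand <- data.frame(
    start = rep(seq_len(nrow(prof)) - 1L, 2L),
    strand = rep(c("+", "-"), each = nrow(prof)),
    identity = c(prof[, 1], prof[, 2]))
  cand <- cand[cand$identity >= min_identity, , drop = FALSE]
  cand <- cand[order(-cand$identity, cand$start), , drop = FALSE]
  taken <- rep(FALSE, nchar(s))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):(cand$start[i] + lm)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$end <- out$start + lm
  out <- out[order(out$start), c("start", "end", "strand", "identity")]
  rownames(out) <- NULL
  out
}

#' Test head-to-tail tandem organization
#'
#' TRUE iff all monomer placements found along the sequence are co-oriented
#' (same strand) and consecutive placements are adjacent, i.e. the gap or
#' overlap between one placement's end and the next one's start is at most
#' `max_gap` bp. Alternating-orientation (head-to-head) arrangements return
#' FALSE.
#'
#' @param sequence one DNA string.
#' @param monomer monomer sequence of the family to test.
#' @param min_identity per-placement identity floor.
#' @param max_gap adjacency tolerance in bp (default 5).
#' @return logical flag; errors if the monomer is not found at all.
#' @export
is_head_to_tail <- function(sequence, monomer, min_identity = 0.8,
                            max_gap = 5L) {
  pl <- find_placements(sequence, monomer, min_identity)
  if (nrow(pl) == 0L) stop("family absent", call. = FALSE)
  if (length(unique(pl$strand)) > 1L) return(FALSE)
  if (nrow(pl) == 1L) return(TRUE)
  gaps <- pl$start[-1L] - pl$end[-nrow(pl)]
  all(abs(gaps) <= max_gap)
}

#' Classify a genomic region by repeat family
#'
#' Tiles the region into monomer-sized windows (window length = smallest
#' tandem monomer in the panel, capped by the region length), assigns each
#' window its best-identity family with the same scoring as the read mapper,
#' and labels the region by the majority family. The reported mean identity
#' is over the winning family's windows. A majority tie is flagged
#' `"mixed"` and resolved to the family with the higher mean identity.
#' Regions whose best mean identity is below `min_identity` are
#' `"unclassified"`.
#'
#' @param sequence region DNA string.
#' @param panel a [reference_panel()].
#' @param cfg a [mapper_config()].
#' @param period if `TRUE`, also run [estimate_period()] on the region (the
#'   slowest step; disable for large region sets).
#' @return one-row data frame: `family`, `mean_identity`, `n_windows`,
#'   `mixed`, `head_to_tail` (NA unless the winning family is tandem),
#'   `period` (from [estimate_period()], NA when `period = FALSE`).
#' @export
classify_region <- function(sequence, panel, cfg = mapper_config(),
                            period = TRUE) {
  stopifnot(inherits(panel, "reference_panel"))
  s <- assert_dna(sequence, "region")
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  win <- min(panel$monomer_length[panel$is_tandem], nchar(s))
  if (length(win) == 0L || !is.finite(win)) win <- min(panel$monomer_length, nchar(s))
  starts <- seq(1L, max(1L, nchar(s) - win + 1L), by = win)
  tiles <- substring(s, starts, pmin(starts + win - 1L, nchar(s)))
  tiles <- tiles[nchar(tiles) >= min(win, nchar(s))]
  res <- map_readset(tiles, panel, cfg)
  h <- res$hits
  if (nrow(h) == 0L) {
    return(data.frame(family = "unclassified", mean_identity = NA_real_,
                      n_windows = length(tiles), mixed = FALSE,
                      head_to_tail = NA, period = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  tab <- sort(table(h$entry), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  mixed <- length(top) > 1L
  mean_id <- vapply(top, function(f) mean(h$identity[h$entry == f]), numeric(1))
  fam <- top[which.max(mean_id)]
  mi <- max(mean_id)
  if (mi < cfg$min_identity) {
    return(data.frame(family = "unclassified", mean_identity = mi,
                      n_windows = length(tiles), mixed = mixed,
                      head_to_tail = NA, period = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  tandem <- panel$is_tandem[panel$name == fam]
  htt <- if (tandem) {
    tryCatch(is_head_to_tail(s, panel$sequence[panel$name == fam],
                             min_identity = cfg$min_identity),
             error = function(e) NA)
  } else NA
  per <- if (period) suppressWarnings(estimate_period(s)) else NA_integer_
  data.frame(family = fam, mean_identity = mi, n_windows = length(tiles),
             mixed = mixed, head_to_tail = htt, period = per,
             stringsAsFactors = FALSE)
}

#' Classify many regions
#'
#' @param sequences character vector (or named vector) of region sequences.
#' @param panel a [reference_panel()].
#' @param cfg a [mapper_config()].
#' @param period estimate the repeat period per region (slowest step; off
#'   by default for large region sets).
#' @return data frame with one row per region (`region` column first).
#' @export
classify_regions <- function(sequences, panel, cfg = mapper_config(),
                             period = FALSE) {
  rows <- lapply(seq_along(sequences), function(i) {
    classify_region(sequences[[i]], panel, cfg, period = period)
  })
  out <- do.call(rbind, rows)
  nm <- names(sequences)
  out <- cbind(data.frame(region = if (is.null(nm))
    sprintf("region%05d", seq_along(sequences)) else nm,
    stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
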