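# ---- slot blot ---------------------------------------------------------

#' Slot-blot IP/input densitometry ratio
#'
#' `(IDV_ip - background) / (IDV_input - background)`; 1.0 means no
#' enrichment. Background defaults to 0 (no subtraction).
#'
#' @param idv_ip,idv_input integrated densitometric values (vectorised).
#' @param background constant background to subtract from both.
#' @return data frame `ratio`, `undefined`; the ratio is `NA` (undefined)
#'   wherever the background-subtracted input is not positive.
#' @examples
#' slot_ratio(200, 100)$ratio  # 2
#' @export
slot_ratio <- function(idv_ip, idv_input, background = 0) {
  if (any(idv_ip < background) || any(idv_input < background)) {
    stop("IDV below background", call. = FALSE)
  }
  den <- idv_input - background
  undef <- den <= 0
  data.frame(ratio = ifelse(undef, NA_real_, (idv_ip - background) / den),
             undefined = undef)
}

# ---- fibre profile segmentation ---------------------------------------

#' Segment a two-channel chromatin fibre profile
#'
#' Per channel, signal-positive intervals are maximal runs of points above
#' `median + k * MAD` of the channel; runs separated by at most `max_gap`
#' points are merged and runs shorter than `min_run` are dropped (noise
#' spikes). The red-positive stretch is the longest red interval; green
#' blocks are clipped to it. The threshold rule is background-relative, so
#' classification is invariant to rescaling both channels.
#'
#' @param profile a `fibre_profile` data frame (`pos`, `red`, `green`).
#' @param k MAD multiplier (default 3).
#' @param min_run minimal run length in samples.
#' @param max_gap sub-threshold gap length merged into a run.
#' @return the profile with attributes `red_stretch` (c(start, end) sample
#'   indices), `green_blocks` (matrix of start/end indices, clipped to the
#'   red stretch) and `coverage` (green-covered fraction of the red
#'   stretch), class `segmented_fibre`.
#' @export
segment_profile <- function(profile, k = 3, min_run = 3L, max_gap = 2L) {
  stopifnot(all(c("pos", "red", "green") %in% names(profile)))
  if (nrow(profile) < 20L) stop("need at least 20 sample points", call. = FALSE)
  if (any(profile$red < 0) || any(profile$green < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  red_iv <- channel_runs(profile$red, k, min_run, max_gap)
  if (nrow(red_iv) == 0L) stop("no satellite signal on fibre", call. = FALSE)
  red_stretch <- red_iv[which.max(red_iv[, 2] - red_iv[, 1]), ]
  green_iv <- channel_runs(profile$green, k, min_run, max_gap)
  if (nrow(green_iv) > 0L) {
    green_iv[, 1] <- pmax(green_iv[, 1], red_stretch[1])
    green_iv[, 2] <- pmin(green_iv[, 2], red_stretch[2])
    green_iv <- green_iv[green_iv[, 2] >= green_iv[, 1], , drop = FALSE]
  }
  red_len <- red_stretch[2] - red_stretch[1] + 1L
  cov <- if (nrow(green_iv)) sum(green_iv[, 2] - green_iv[, 1] + 1L) / red_len else 0
  structure(profile, red_stretch = unname(red_stretch),
            green_blocks = unname(green_iv), coverage = unname(cov),
            class = c("segmented_fibre", class(profile)))
}

# maximal above-threshold runs with gap merging and minimum length
channel_runs <- function(x, k, min_run, max_gap) {
  thr <- median(x) + k * mad(x)
  above <- x > thr
  r <- rle(above)
  # close short gaps between positive runs
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    fill <- inner[!r$values[inner] & r$lengths[inner] <= max_gap &
                    r$values[inner - 1L] & r$values[inner + 1L]]
    r$values[fill] <- TRUE
    above <- inverse.rle(r)
    r <- rle(above)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_run
  cbind(start = starts[sel], end = ends[sel])
}

#' Classify a fibre's CENP-A binding pattern
#'
#' Pattern I: CENP-A (green) covers the whole satellite-positive (red)
#' stretch (coverage fraction >= `high`); pattern III: essentially no
#' CENP-A on the fibre (coverage <= `low`); pattern II: CENP-A in blocks of
#' variable length intermingled in the satellite stretch (everything in
#' between). The cutoffs are this package's operationalisation of the three
#' microscopy patterns and are reported with every summary.
#'
#' @param profile a `segmented_fibre` from [segment_profile()].
#' @param low,high coverage-fraction cutoffs (defaults 0.05 and 0.90).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_fibre <- function(profile, low = 0.05, high = 0.90) {
  if (!inherits(profile, "segmented_fibre")) {
    stop("profile must be segmented first (see segment_profile)", call. = FALSE)
  }
  cov <- attr(profile, "coverage")
  if (cov >= high) "I" else if (cov <= low) "III" else "II"
}

#' Summarize fibre pattern classes
#'
#' @param classes character vector of `"I"/"II"/"III"` calls.
#' @param low,high the cutoffs used, echoed in the output attributes.
#' @return data frame `class`, `count`, `percent` (rounded to the nearest
#'   integer; exact percentages in `percent_exact`), all three classes
#'   always present.
#' @examples
#' summarize_fibres(rep(c("I", "II", "III"), c(15, 7, 3)))
#' @export
summarize_fibres <- function(classes, low = 0.05, high = 0.90) {
  if (length(classes) == 0L) stop("no classified fibres", call. = FALSE)
  stopifnot(all(classes %in% c("I", "II", "III")))
  counts <- vapply(c("I", "II", "III"), function(k) sum(classes == k),
                   integer(1))
  pct <- 100 * counts / sum(counts)
  structure(data.frame(class = c("I", "II", "III"),
                       count = as.integer(counts),
                       percent = round(pct),
                       percent_exact = pct,
                       stringsAsFactors = FALSE, row.names = NULL),
            cutoffs = c(low = low, high = high))
}

#' Segment and classify a set of fibre profiles
#'
#' @param fibres list of `fibre_profile` data frames.
#' @param k,min_run,max_gap segmentation parameters, see
#'   [segment_profile()].
#' @param low,high classification cutoffs, see [classify_fibre()].
#' @return data frame `fibre`, `class`, `coverage`, `n_green_blocks`, plus
#'   `truth_class` when the profiles carry simulation ground truth.
#' @export
classify_fibres <- function(fibres, k = 3, min_run = 3L, max_gap = 2L,
                            low = 0.05, high = 0.90) {
  rows <- lapply(seq_along(fibres), function(i) {
    seg <- segment_profile(fibres[[i]], k = k, min_run = min_run,
                           max_gap = max_gap)
    data.frame(fibre = i,
               class = classify_fibre(seg, low = low, high = high),
               coverage = attr(seg, "coverage"),
               n_green_blocks = nrow(attr(seg, "green_blocks")),
               truth_class = attr(fibres[[i]], "truth_class") %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
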