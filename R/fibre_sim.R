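# ---- chromatin fibre simulation ---------------------------------------

#' Simulate two-channel chromatin fibre intensity traces
#'
#' Generates line profiles mimicking immuno-FISH on extended chromatin
#' fibres: a red channel marking the satellite DNA stretch and a green
#' channel marking CENP-A. Three ground-truth binding patterns are emitted:
#' pattern I (green covers at least `fibre_full_coverage` of the red
#' stretch), pattern II (two or more disjoint green blocks inside the red
#' stretch), and pattern III (green at background level only). Additive
#' Gaussian noise (truncated at zero) is applied to both channels.
#'
#' @param cfg a [sim_config()]; `fibre_counts` gives the number of fibres
#'   per pattern.
#' @return list of `fibre_profile` data frames (`pos`, `red`, `green`), each
#'   carrying attributes `truth_class` (`"I"/"II"/"III"`), `truth_red`
#'   (c(start, end) sample indices of the red stretch) and `truth_green`
#'   (matrix of green block start/end indices).
#' @examples
#' fibres <- simulate_fibres(demo_config(seed = 3))
#' attr(fibres[[1]], "truth_class")
#' @export
simulate_fibres <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- cfg$fibre_counts
  stopifnot(all(counts >= 0))
  set.seed(channel_seed(cfg, "fibres"))
  classes <- rep(c("I", "II", "III"), times = c(counts[["I"]], counts[["II"]],
                                                counts[["III"]]))
  lapply(classes, function(cl) one_fibre(cl, cfg))
}

one_fibre <- function(class, cfg) {
  n <- cfg$fibre_trace_len
  m <- round(n * cfg$fibre_red_frac * runif(1, 0.9, 1.1))
  r0 <- sample.int(n - m - 1L, 1L)          # red stretch start (1-based)
  red_iv <- c(r0, r0 + m - 1L)
  red <- rep(0, n)
  red[red_iv[1]:red_iv[2]] <- cfg$fibre_signal

  blocks <- matrix(integer(0), ncol = 2)
  if (class == "I") {
    cov <- runif(1, max(cfg$fibre_full_coverage, 0.96), 1)
    g <- round(m * cov)
    gs <- red_iv[1] + sample.int(m - g + 1L, 1L) - 1L
    blocks <- matrix(c(gs, gs + g - 1L), ncol = 2)
  } else if (class == "II") {
    nb <- sample(2:4, 1L)
    gtot <- round(m * runif(1, 0.25, 0.6))
    # keep blocks >= 8 samples and gaps >= 5 samples feasible
    nb <- max(2L, min(nb, gtot %/% 8L, (m - gtot) %/% 5L - 1L))
    glens <- rand_partition(gtot, nb, minimum = 8L)
    gaps <- rand_partition(m - gtot, nb + 1L, minimum = 5L)
    gs <- red_iv[1] + cumsum(gaps[seq_len(nb)]) +
      c(0L, cumsum(glens))[seq_len(nb)]
    blocks <- cbind(gs, gs + glens - 1L)
  }
  green <- rep(0, n)
  if (nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) green[blocks[b, 1]:blocks[b, 2]] <- cfg$fibre_signal
  }
  noise <- function(x) pmax(0, x + cfg$fibre_bg + rnorm(n, 0, cfg$fibre_noise_sd))
  structure(data.frame(pos = seq_len(n), red = noise(red), green = noise(green)),
            class = c("fibre_profile", "data.frame"),
            truth_class = class, truth_red = red_iv, truth_green = blocks)
}

#' Write fibre traces as TSV files
#' @param fibres list from [simulate_fibres()].
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_fibre_traces <- function(fibres, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(fibres), function(i) {
    p <- file.path(dir, sprintf("fibre_%03d.tsv", i))
    write.table(as.data.frame(fibres[[i]]), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a fibre trace from TSV
#' @param path TSV with columns `pos`, `red`, `green`.
#' @return a `fibre_profile` data frame.
#' @export
read_fibre_trace <- function(path) {
  df <- read.delim(path)
  if (!all(c("pos", "red", "green") %in% names(df))) {
    stop("fibre trace needs pos, red, green columns: ", path, call. = FALSE)
  }
  structure(df[, c("pos", "red", "green")],
            class = c("fibre_profile", "data.frame"))
}

# ---- slot blot simulation ----------------------------------------------

#' Simulate slot-blot densitometry measurements
#'
#' One row per replicate probe measurement: the input IDV (integrated
#' densitometric value) is drawn around `slot_base_idv` with lognormal
#' spread, the IP IDV is `true_ratio` times it, with multiplicative noise of
#' CV `slot_cv` on both, plus the configured constant background.
#'
#' @param cfg a [sim_config()]; `cfg$slot_blot` gives probes and true ratios.
#' @return data frame `probe`, `replicate`, `idv_ip`, `idv_input`,
#'   `background`, `true_ratio`.
#' @export
simulate_slot_blot <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(channel_seed(cfg, "slot"))
  sb <- cfg$slot_blot
  n <- nrow(sb)
  idv_input <- cfg$slot_base_idv * exp(rnorm(n, 0, 0.2)) *
    (1 + rnorm(n, 0, cfg$slot_cv))
  idv_ip <- sb$true_ratio * idv_input * (1 + rnorm(n, 0, cfg$slot_cv))
  rep_id <- stats::ave(seq_len(n), sb$probe, FUN = seq_along)
  data.frame(probe = sb$probe, replicate = rep_id,
             idv_ip = idv_ip + cfg$slot_background,
             idv_input = idv_input + cfg$slot_background,
             background = cfg$slot_background,
             true_ratio = sb$true_ratio, stringsAsFactors = FALSE)
}
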