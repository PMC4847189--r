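#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the repeat monomer
#' panel, tandem array layout, CENP-A occupancy per family, the IP sampling
#' weight, read set sizes, error rate, transcription weights, fibre counts
#' and slot-blot truth. Identical seed + config gives byte-identical
#' outputs.
#'
#' The IP channel samples fragment start positions with weight
#' `1 + alpha * occupancy(region)` against `1` in the input channel, so the
#' expected normalised IP/input ratio of a family is available in closed
#' form (see [expected_enrichment_ratios()]). When `ip_enrichment_alpha` is
#' `NULL` it is derived at read-simulation time so that the most occupied
#' family's expected ratio equals `target_ratio`.
#'
#' @param seed integer seed governing every random draw.
#' @param monomers data frame with columns `name`, `length`, `gc`,
#'   `is_tandem`, or a named character vector of explicit monomer sequences
#'   (then `is_tandem` is taken from `monomer_is_tandem`).
#' @param monomer_is_tandem named logical, used only with explicit sequences.
#' @param arrays named list; for tandem families an integer vector of
#'   copies per array (one element per array), for interspersed families a
#'   single integer number of scattered copies.
#' @param occupancy named numeric in `[0,1]`: CENP-A-bound fraction per family.
#' @param ip_enrichment_alpha sampling weight advantage of bound chromatin
#'   in the IP channel, or `NULL` to derive it from `target_ratio`.
#' @param target_ratio expected IP/input ratio of the top occupied family
#'   used when `ip_enrichment_alpha` is `NULL`.
#' @param monomer_divergence per-base substitution rate applied
#'   independently to each monomer copy placed in the genome.
#' @param background_length,background_gc random background sequence budget
#'   split between placed regions, and its GC fraction.
#' @param genes named integer vector of transcribed gene-window lengths
#'   embedded in the background.
#' @param transcription named per-base transcription weights (families and
#'   genes); regions absent from it are untranscribed.
#' @param read_length,substitution_error_rate read simulation parameters.
#' @param n_reads_ip,n_reads_input,n_reads_rna reads per channel.
#' @param fibre_counts integer vector `c(I=, II=, III=)` of chromatin fibres
#'   per CENP-A binding pattern.
#' @param fibre_trace_len,fibre_red_frac,fibre_signal,fibre_bg,fibre_noise_sd,
#'   fibre_full_coverage fibre trace geometry: points per trace, fraction of
#'   the trace covered by the satellite (red) stretch, signal and background
#'   intensity levels, additive Gaussian noise SD, and the minimum fraction
#'   of the red stretch covered by green in pattern I.
#' @param slot_blot data frame `probe`, `true_ratio` (one row per replicate
#'   measurement) for the slot-blot generator.
#' @param slot_base_idv,slot_cv,slot_background slot-blot densitometry scale,
#'   multiplicative noise CV, and constant background.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_reads_ip = 1000, n_reads_input = 1000)
#' cfg$target_ratio
#' @export
sim_config <- function(seed = 1L,
                       monomers = data.frame(
                         name = c("satEC", "sat2P1", "satEC137", "ERE1"),
                         length = c(221L, 359L, 137L, 310L),
                         gc = c(0.53, 0.42, 0.40, 0.45),
                         is_tandem = c(TRUE, TRUE, TRUE, FALSE),
                         stringsAsFactors = FALSE),
                       monomer_is_tandem = NULL,
                       arrays = list(satEC = c(30L, 30L),
                                     sat2P1 = c(15L, 15L),
                                     satEC137 = 20L,
                                     ERE1 = 60L),
                       occupancy = c(satEC = 1.0),
                       ip_enrichment_alpha = NULL,
                       target_ratio = 6.5,
                       monomer_divergence = 0.02,
                       background_length = 1600000L,
                       background_gc = 0.42,
                       genes = c(TUBB = 442L, PRKCI = 442L,
                                 TERC = 442L, TK = 442L),
                       transcription = c(satEC = 2, TUBB = 1, PRKCI = 1,
                                         TERC = 1, TK = 1),
                       read_length = 100L,
                       substitution_error_rate = 0.01,
                       n_reads_ip = 200000L,
                       n_reads_input = 200000L,
                       n_reads_rna = 50000L,
                       fibre_counts = c(I = 15L, II = 7L, III = 3L),
                       fibre_trace_len = 300L,
                       fibre_red_frac = 0.4,
                       fibre_signal = 100,
                       fibre_bg = 10,
                       fibre_noise_sd = 5,
                       fibre_full_coverage = 0.95,
                       slot_blot = data.frame(
                         probe = c("satEC", "satEC", "sat2P1", "ERE1"),
                         true_ratio = c(1.8, 2.5, 0.7, 1.0),
                         stringsAsFactors = FALSE),
                       slot_base_idv = 10000,
                       slot_cv = 0.02,
                       slot_background = 0) {
  cfg <- as.list(environment())
  if (is.character(monomers)) {
    nm <- names(monomers)
    if (is.null(nm)) stop("explicit monomers must be named", call. = FALSE)
    seqs <- assert_dna(monomers, "monomer")
    tand <- if (is.null(monomer_is_tandem)) rep(TRUE, length(seqs)) else
      as.logical(monomer_is_tandem[nm])
    cfg$monomers <- data.frame(name = nm, length = nchar(seqs),
                               gc = NA_real_, is_tandem = tand,
                               sequence = unname(seqs),
                               stringsAsFactors = FALSE)
  } else if (is.null(monomers$sequence)) {
    cfg$monomers$sequence <- rep(NA_character_, nrow(monomers))
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  m <- cfg$monomers
  if (is.null(m) || nrow(m) == 0L) stop("empty panel", call. = FALSE)
  if (anyDuplicated(m$name)) stop("duplicate monomer names", call. = FALSE)
  stopifnot(all(m$length >= 1L))
  fr <- c(cfg$occupancy, cfg$substitution_error_rate, cfg$monomer_divergence,
          cfg$background_gc, m$gc[!is.na(m$gc)])
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0,1]", call. = FALSE)
  cnt <- c(cfg$n_reads_ip, cfg$n_reads_input, cfg$n_reads_rna,
           cfg$fibre_counts, unlist(cfg$arrays))
  if (any(cnt < 0)) stop("all counts must be nonnegative", call. = FALSE)
  if (!all(names(cfg$arrays) %in% m$name)) {
    stop("arrays refer to unknown families", call. = FALSE)
  }
  # every sampled fragment (region) must be able to hold one read
  frag <- c(cfg$genes,
            vapply(m$name, function(f) {
              a <- cfg$arrays[[f]]
              len <- m$length[m$name == f]
              if (is.null(a)) Inf else if (m$is_tandem[m$name == f])
                min(a) * len else len
            }, numeric(1)))
  if (cfg$read_length > min(frag)) {
    stop("read_length exceeds the shortest simulated fragment", call. = FALSE)
  }
  if (!is.null(cfg$ip_enrichment_alpha) && cfg$ip_enrichment_alpha < 0) {
    stop("ip_enrichment_alpha must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Scaled-down demonstration configuration
#'
#' Same structure as [sim_config()] but a smaller genome and fewer reads, for
#' examples and quick end-to-end runs.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
demo_config <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               arrays = list(satEC = c(20L), sat2P1 = c(12L),
                             satEC137 = 10L, ERE1 = 6L),
               background_length = 30000L,
               n_reads_ip = 60000L, n_reads_input = 60000L,
               n_reads_rna = 20000L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# stable per-channel seed offsets; keeps derived seeds well below 2^31
channel_seed <- function(cfg, channel) {
  off <- c(genome = 0L, ip = 1L, input = 2L, rna = 3L,
           fibres = 4L, slot = 5L)[channel]
  as.integer(cfg$seed %% 2000000000L) + off
}
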