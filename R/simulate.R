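# ---- sequence helpers --------------------------------------------------

#' Random DNA with an exact GC composition
#'
#' Draws a sequence of length `n` containing exactly `round(n * gc)` G/C
#' bases (split between G and C at random), shuffled uniformly. The exact
#' composition makes the GC content of a generated monomer deterministic at
#' integer-percent resolution regardless of seed.
#'
#' @param n sequence length.
#' @param gc GC fraction in `[0,1]`.
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  n_gc <- round(n * gc)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), n - n_gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

# substitute bases at `rate` in equal- or unequal-length sequences; operates
# on one concatenated raw vector so large read sets stay fast
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs)
  big <- paste(seqs, collapse = "")
  n <- nchar(big)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seqs)
  pos <- sample.int(n, k)
  r <- charToRaw(big)
  cur <- match(rawToChar(r[pos], multiple = TRUE), .satcen_bases)
  keep <- !is.na(cur)                      # leave N untouched
  if (any(keep)) {
    shift <- sample.int(3L, sum(keep), replace = TRUE)
    newb <- .satcen_bases[(cur[keep] - 1L + shift) %% 4L + 1L]
    r[pos[keep]] <- charToRaw(paste(newb, collapse = ""))
  }
  big <- rawToChar(r)
  ends <- cumsum(L)
  substring(big, ends - L + 1L, ends)
}

# split `total` into `parts` nonnegative integers, each >= minimum, random
# proportions; deterministic under the current RNG state
rand_partition <- function(total, parts, minimum = 0L) {
  if (parts == 0L) return(integer(0))
  spare <- total - parts * minimum
  if (spare < 0L) stop("partition infeasible", call. = FALSE)
  w <- runif(parts)
  x <- floor(spare * w / sum(w))
  x[1L] <- x[1L] + (spare - sum(x))
  as.integer(x + minimum)
}

# ---- genome ------------------------------------------------------------

#' Simulate a toy genome of satellite arrays, interspersed elements and genes
#'
#' Lays out, in shuffled order separated by random background stretches:
#' head-to-tail tandem arrays of each tandem monomer family (each copy
#' independently mutated at `monomer_divergence`), scattered single copies of
#' interspersed families, and transcribed gene windows. Coordinates are
#' 0-based half-open and the annotation tiles the genome without gaps or
#' overlaps.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sat_sim` with elements `genome` (one DNA string),
#'   `annotation` (data frame: `chrom`, `start`, `end`, `family`, `kind`,
#'   `occupancy`, `tx_weight`, `copies`, `monomer_length`), `panel`
#'   (a [reference_panel()] of the monomers), `monomers` (named character),
#'   and `cfg`.
#' @examples
#' sim <- simulate_genome(demo_config(seed = 7))
#' head(sim$annotation)
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(channel_seed(cfg, "genome"))
  m <- cfg$monomers
  monomers <- setNames(vapply(seq_len(nrow(m)), function(i) {
    if (!is.null(m$sequence) && !is.na(m$sequence[i])) m$sequence[i]
    else random_dna(m$length[i], m$gc[i])
  }, character(1)), m$name)

  occ_of <- function(f) unname(if (f %in% names(cfg$occupancy)) cfg$occupancy[[f]] else 0)
  tx_of <- function(f) unname(if (f %in% names(cfg$transcription)) cfg$transcription[[f]] else 0)

  units <- list()
  for (f in names(cfg$arrays)) {
    tandem <- m$is_tandem[m$name == f]
    if (tandem) {
      for (cp in cfg$arrays[[f]]) {
        if (cp > 0) units[[length(units) + 1L]] <-
            list(family = f, kind = "array", copies = as.integer(cp))
      }
    } else {
      for (i in seq_len(cfg$arrays[[f]])) {
        units[[length(units) + 1L]] <-
          list(family = f, kind = "interspersed", copies = 1L)
      }
    }
  }
  for (g in names(cfg$genes)) {
    units[[length(units) + 1L]] <-
      list(family = g, kind = "gene", copies = 1L)
  }
  if (length(units) == 0L) stop("empty panel", call. = FALSE)
  units <- units[sample.int(length(units))]

  bg_lens <- rand_partition(cfg$background_length, length(units) + 1L,
                            minimum = max(200L, cfg$read_length))
  pieces <- character(0)
  ann <- list()
  pos <- 0L
  push <- function(seqs, family, kind, copies, mono_len) {
    seq1 <- paste(seqs, collapse = "")
    w <- nchar(seq1)
    pieces[[length(pieces) + 1L]] <<- seq1
    ann[[length(ann) + 1L]] <<- data.frame(
      chrom = "chrSim", start = pos, end = pos + w, family = family,
      kind = kind,
      occupancy = if (kind %in% c("array", "interspersed")) occ_of(family) else 0,
      tx_weight = tx_of(family),
      copies = copies, monomer_length = mono_len, stringsAsFactors = FALSE)
    pos <<- pos + w
  }
  for (i in seq_along(units)) {
    push(random_dna(bg_lens[i], cfg$background_gc), "background", "background", 0L, NA_integer_)
    u <- units[[i]]
    if (u$kind == "gene") {
      push(random_dna(cfg$genes[[u$family]], 0.45), u$family, "gene", 1L, NA_integer_)
    } else {
      mono <- monomers[[u$family]]
      copies <- mutate_bases(rep(mono, u$copies), cfg$monomer_divergence)
      push(copies, u$family, u$kind, u$copies, nchar(mono))
    }
  }
  push(random_dna(bg_lens[length(bg_lens)], cfg$background_gc),
       "background", "background", 0L, NA_integer_)

  ann <- do.call(rbind, ann)
  panel <- reference_panel(monomers, is_tandem = m$is_tandem)
  structure(list(genome = paste(pieces, collapse = ""), annotation = ann,
                 panel = panel, monomers = monomers, cfg = cfg),
            class = "sat_sim")
}

#' @export
print.sat_sim <- function(x, ...) {
  cat(sprintf("sat_sim: genome of %d bp, %d annotated regions, %d families\n",
              nchar(x$genome), nrow(x$annotation), nrow(x$panel)))
  invisible(x)
}

# ---- sampling model ----------------------------------------------------

#' Closed-form expected IP/input enrichment ratios
#'
#' Under the two-state sampling model (input weight 1 per position, IP weight
#' `1 + alpha * occupancy`), the expected normalised IP/input count ratio of
#' family *f* is `(sum_f L (1 + a o) / L_f) * (L_tot / sum_all L (1 + a o))`;
#' reference lengths cancel, so this is also the expected ratio of mapped
#' read fractions.
#'
#' @param annotation annotation table from [simulate_genome()].
#' @param alpha IP weight parameter.
#' @return named numeric vector of expected ratios per family (background
#'   included).
#' @export
expected_enrichment_ratios <- function(annotation, alpha) {
  L <- annotation$end - annotation$start
  w <- L * (1 + alpha * annotation$occupancy)
  W <- sum(w); Ltot <- sum(L)
  fam <- unique(annotation$family)
  setNames(vapply(fam, function(f) {
    i <- annotation$family == f
    (sum(w[i]) / W) / (sum(L[i]) / Ltot)
  }, numeric(1)), fam)
}

#' Solve for the IP weight giving a target enrichment ratio
#'
#' Inverts the closed form of [expected_enrichment_ratios()] for the family
#' of interest. Feasible only while `ratio < L_tot / sum(L * occupancy)`
#' (scaled by the family's occupancy): a family occupying a large genome
#' fraction cannot be arbitrarily enriched.
#'
#' @param annotation annotation table from [simulate_genome()].
#' @param family family name whose expected ratio should equal `ratio`.
#' @param ratio desired expected IP/input ratio (>= 1).
#' @return alpha, a nonnegative scalar.
#' @export
alpha_for_ratio <- function(annotation, family, ratio) {
  stopifnot(ratio >= 1)
  L <- annotation$end - annotation$start
  Ltot <- sum(L)
  B <- sum(L * annotation$occupancy)
  i <- annotation$family == family
  if (!any(i)) stop("unknown family: ", family, call. = FALSE)
  o_f <- sum(L[i] * annotation$occupancy[i]) / sum(L[i])
  if (o_f <= 0) stop("family has zero occupancy; ratio > 1 unattainable", call. = FALSE)
  den <- o_f * Ltot - ratio * B
  if (ratio > 1 && den <= 0) {
    stop(sprintf("ratio %.3g infeasible: family occupies too large a genome fraction",
                 ratio), call. = FALSE)
  }
  if (ratio == 1) return(0)
  Ltot * (ratio - 1) / den
}

resolve_alpha <- function(sim) {
  cfg <- sim$cfg
  if (!is.null(cfg$ip_enrichment_alpha)) return(cfg$ip_enrichment_alpha)
  occ <- cfg$occupancy[cfg$occupancy > 0]
  if (length(occ) == 0L) return(0)
  top <- names(occ)[which.max(occ)]
  alpha_for_ratio(sim$annotation, top, cfg$target_ratio)
}

# ---- reads -------------------------------------------------------------

#' Simulate a sequencing read set from a synthetic genome
#'
#' Draws `n_reads` fixed-length reads. Start positions are sampled per
#' annotated region: the input channel uniformly by region length, the IP
#' channel with weight `1 + alpha * occupancy`, and the RNA channel with
#' weight proportional to the region's per-base transcription weight
#' (untranscribed regions are never sampled). Strands are uniform; per-base
#' substitution errors are applied at `substitution_error_rate`. Read
#' identifiers encode the true source region, family, start and strand.
#'
#' @param sim a `sat_sim` from [simulate_genome()].
#' @param channel one of `"ip"`, `"input"`, `"rna"`.
#' @param n_reads optional override of the per-channel read count in the
#'   configuration.
#' @param alpha optional override of the IP weight (default: the configured
#'   or derived value).
#' @return data frame `id`, `seq` of exactly `n_reads` rows, with the
#'   channel and alpha stored as attributes.
#' @export
simulate_reads <- function(sim, channel = c("ip", "input", "rna"),
                           n_reads = NULL, alpha = NULL) {
  stopifnot(inherits(sim, "sat_sim"))
  channel <- match.arg(channel)
  cfg <- sim$cfg
  if (is.null(n_reads)) {
    n_reads <- switch(channel, ip = cfg$n_reads_ip,
                      input = cfg$n_reads_input, rna = cfg$n_reads_rna)
  }
  stopifnot(n_reads > 0)
  Lr <- cfg$read_length
  G <- nchar(sim$genome)
  if (Lr > G) stop("read_length exceeds genome length", call. = FALSE)
  if (is.null(alpha)) alpha <- resolve_alpha(sim)

  ann <- sim$annotation
  n_valid <- pmax(0L, pmin(ann$end, G - Lr + 1L) - ann$start)
  w <- switch(channel,
              ip = n_valid * (1 + alpha * ann$occupancy),
              input = as.numeric(n_valid),
              rna = n_valid * ann$tx_weight)
  if (sum(w) <= 0) stop("no region is eligible for channel ", channel, call. = FALSE)

  set.seed(channel_seed(cfg, channel))
  rows <- sample.int(nrow(ann), n_reads, replace = TRUE, prob = w)
  starts <- ann$start[rows] + floor(runif(n_reads) * n_valid[rows])
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(sim$genome, starts + 1L, starts + Lr)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  seqs <- mutate_bases(seqs, cfg$substitution_error_rate)
  id <- sprintf("%s%07d|reg=%d|fam=%s|start=%d|strand=%s",
                channel, seq_len(n_reads), rows, ann$family[rows],
                starts, strand)
  structure(data.frame(id = id, seq = seqs, stringsAsFactors = FALSE),
            channel = channel, alpha = alpha)
}

#' Recover ground truth from simulated read identifiers
#'
#' @param ids identifier vector as produced by [simulate_reads()].
#' @return data frame `region` (annotation row index), `family`, `start`
#'   (0-based), `strand`.
#' @export
parse_read_truth <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) stop("identifier lacks truth fields: ", ids[bad][1], call. = FALSE)
  field <- function(k) sub("^[a-z]+=", "", vapply(parts, `[[`, character(1), k))
  data.frame(region = as.integer(field(2L)), family = field(3L),
             start = as.integer(field(4L)), strand = field(5L),
             stringsAsFactors = FALSE)
}

# ---- FASTQ -------------------------------------------------------------

#' Write reads as FASTQ
#'
#' Quality strings are constant `"I"` (the generator models substitution
#' errors, not base qualities).
#'
#' @param reads data frame with `id` and `seq` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Minimal strict reader for the fixed-format FASTQ this package writes;
#' malformed records are reported with their record index.
#'
#' @param path FASTQ file.
#' @return data frame `id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("FASTQ parse error in record %d: truncated record",
                 length(lines) %/% 4L + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error in record %d: malformed header/separator",
                 bad[1]), call. = FALSE)
  }
  data.frame(id = substring(hdr, 2L), seq = toupper(seqs),
             stringsAsFactors = FALSE)
}
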