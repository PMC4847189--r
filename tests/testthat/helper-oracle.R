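# Independent brute-force reference aligner used to cross-check the mapper.
# Pure R, all offsets, both strands; tandem targets are scanned on the dimer
# with offsets restricted to [0, monomer_length) (the canonical range).

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# per-offset match counts of read vs target, accumulated position by
# position so the loop runs over read length, not offsets
oracle_matches <- function(read, target, max_off) {
  r <- strsplit(read, "")[[1]]
  t <- strsplit(target, "")[[1]]
  L <- length(r)
  m <- integer(max_off + 1L)
  for (i in seq_len(L)) {
    ti <- t[i:(i + max_off)]
    m <- m + (ti == r[i] & r[i] != "N")
  }
  m
}

# best hit of one read across a panel, replicating the documented tie rules:
# earliest entry, smallest offset, plus strand first at equal offset
oracle_align <- function(read, panel, min_identity = 0.8) {
  L <- nchar(read)
  best <- list(identity = -1, entry = NA, offset = NA, strand = NA,
               ambiguous = FALSE)
  max_mm <- floor((1 - min_identity) * L + 1e-9)
  rc <- oracle_revcomp(read)
  for (e in seq_len(nrow(panel))) {
    tgt <- panel$target[e]
    if (L > nchar(tgt)) next
    max_off <- nchar(tgt) - L
    if (panel$is_tandem[e]) max_off <- min(max_off, panel$monomer_length[e] - 1L)
    mf <- oracle_matches(read, tgt, max_off)
    mr <- oracle_matches(rc, tgt, max_off)
    for (o in 0:max_off) {
      for (s in c("+", "-")) {
        mm <- L - (if (s == "+") mf[o + 1L] else mr[o + 1L])
        if (mm > max_mm) next
        id <- 1 - mm / L
        if (id > best$identity) {
          best <- list(identity = id, entry = panel$name[e], offset = o,
                       strand = s, ambiguous = FALSE)
        } else if (id == best$identity && panel$name[e] != best$entry) {
          best$ambiguous <- TRUE
        }
      }
    }
  }
  if (best$identity < min_identity) NULL else best
}

# deterministic random DNA for fixtures
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant `k` substitutions at distinct positions
mutate_k <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# tiny two-family config used across tests
tiny_config <- function(seed = 1L, ...) {
  demo_config(seed = seed,
              arrays = list(satEC = c(10L), sat2P1 = c(6L),
                            satEC137 = 5L, ERE1 = 3L),
              background_length = 8000L,
              n_reads_ip = 4000L, n_reads_input = 4000L,
              n_reads_rna = 2000L, ...)
}
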