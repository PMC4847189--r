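test_that("tandem arrays are exact head-to-tail concatenations at zero divergence", {
  cfg <- tiny_config(seed = 3, monomer_divergence = 0)
  sim <- simulate_genome(cfg)
  ann <- sim$annotation
  arr <- ann[ann$family == "satEC" & ann$kind == "array", ]
  expect_equal(arr$end - arr$start, 10L * 221L)
  seq_arr <- substring(sim$genome, arr$start + 1, arr$end)
  expect_identical(seq_arr, strrep(sim$monomers[["satEC"]], 10))
})

test_that("annotation tiles the genome without gaps or overlaps", {
  sim <- simulate_genome(tiny_config(seed = 9))
  ann <- sim$annotation[order(sim$annotation$start), ]
  expect_equal(ann$start[1], 0L)
  expect_equal(ann$end[nrow(ann)], nchar(sim$genome))
  expect_true(all(ann$start < ann$end))
  expect_equal(ann$start[-1], ann$end[-nrow(ann)])
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(monomers = data.frame()), "empty panel")
  expect_error(tiny_config(occupancy = c(satEC = 1.4)), "fractions")
  expect_error(tiny_config(n_reads_ip = -1L), "nonnegative")
  expect_error(tiny_config(read_length = 5000L), "shortest simulated fragment")
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- tiny_config(seed = 21)
  s1 <- simulate_genome(cfg); s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(simulate_reads(s1, "ip"), simulate_reads(s2, "ip"))
  f1 <- simulate_fibres(cfg); f2 <- simulate_fibres(cfg)
  expect_identical(f1, f2)
  expect_identical(simulate_slot_blot(cfg), simulate_slot_blot(cfg))
})

test_that("read sets have exactly n_reads reads of read_length", {
  sim <- simulate_genome(tiny_config(seed = 4))
  for (ch in c("ip", "input", "rna")) {
    r <- simulate_reads(sim, ch, n_reads = 500)
    expect_equal(nrow(r), 500)
    expect_true(all(nchar(r$seq) == 100))
  }
})

test_that("error-free input reads are exact genomic substrings at their true position", {
  sim <- simulate_genome(tiny_config(seed = 6, substitution_error_rate = 0))
  r <- simulate_reads(sim, "input", n_reads = 300)
  truth <- parse_read_truth(r$id)
  raw <- substring(sim$genome, truth$start + 1, truth$start + 100)
  neg <- truth$strand == "-"
  raw[neg] <- revcomp(raw[neg])
  expect_identical(r$seq, raw)
})

test_that("with alpha = 0 the IP channel samples like the input channel", {
  sim <- simulate_genome(tiny_config(seed = 8))
  n <- 20000
  ip <- parse_read_truth(simulate_reads(sim, "ip", n_reads = n, alpha = 0)$id)
  L <- sim$annotation$end - sim$annotation$start
  fam_len <- tapply(L, sim$annotation$family, sum)
  p <- fam_len / sum(fam_len)
  for (f in names(p)) {
    se <- sqrt(p[[f]] * (1 - p[[f]]) / n)
    expect_lt(abs(mean(ip$family == f) - p[[f]]), 3 * se + 1e-12)
  }
})

test_that("input read family fractions converge to genomic length fractions", {
  sim <- simulate_genome(tiny_config(seed = 12, substitution_error_rate = 0))
  n <- 20000
  truth <- parse_read_truth(simulate_reads(sim, "input", n_reads = n)$id)
  L <- sim$annotation$end - sim$annotation$start
  # sampling weight is the number of valid start positions per region
  valid <- pmax(0, pmin(sim$annotation$end, nchar(sim$genome) - 99) -
                  sim$annotation$start)
  p <- tapply(valid, sim$annotation$family, sum) / sum(valid)
  for (f in names(p)) {
    se <- sqrt(p[[f]] * (1 - p[[f]]) / n)
    expect_lt(abs(mean(truth$family == f) - p[[f]]), 3 * se + 1e-12)
  }
})

test_that("RNA reads come only from transcribed regions", {
  sim <- simulate_genome(tiny_config(seed = 13))
  truth <- parse_read_truth(simulate_reads(sim, "rna", n_reads = 2000)$id)
  tx <- sim$annotation$family[sim$annotation$tx_weight > 0]
  expect_true(all(truth$family %in% tx))
})

test_that("fibre generator honours requested counts, classes and geometry", {
  cfg <- tiny_config(seed = 5)
  fibres <- simulate_fibres(cfg)
  expect_length(fibres, 25)
  truth <- vapply(fibres, attr, character(1), "truth_class")
  expect_equal(as.vector(table(factor(truth, c("I", "II", "III")))),
               c(15L, 7L, 3L))
  for (f in fibres) {
    expect_true(all(f$red >= 0) && all(f$green >= 0))
    expect_equal(length(f$red), length(f$green))
    blocks <- attr(f, "truth_green")
    if (nrow(blocks)) {
      expect_true(all(blocks[, 1] >= 1 & blocks[, 2] <= nrow(f)))
    }
  }
  # pattern II truth has 2+ disjoint blocks
  ii <- fibres[truth == "II"]
  nb <- vapply(ii, function(f) nrow(attr(f, "truth_green")), integer(1))
  expect_true(all(nb >= 2))
})

test_that("noiseless single pattern-I fibre is recovered by the classifier", {
  cfg <- tiny_config(seed = 2, fibre_counts = c(I = 1L, II = 0L, III = 0L),
                     fibre_noise_sd = 0)
  fibres <- simulate_fibres(cfg)
  expect_length(fibres, 1)
  seg <- segment_profile(fibres[[1]])
  expect_equal(classify_fibre(seg), "I")
})

test_that("fastq round-trip preserves reads and corrupt files are rejected", {
  sim <- simulate_genome(tiny_config(seed = 30))
  r <- simulate_reads(sim, "input", n_reads = 50)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(r, fq)
  back <- read_fastq(fq)
  expect_identical(back$id, r$id)
  expect_identical(back$seq, r$seq)
  # truncated record
  lines <- readLines(fq)
  writeLines(lines[1:6], fq)
  expect_error(read_fastq(fq), "record 2")
  # bad separator
  lines[3] <- "x"
  writeLines(lines[1:8], fq)
  expect_error(read_fastq(fq), "record 1")
})
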