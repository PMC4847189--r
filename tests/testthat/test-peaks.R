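rand_peaks <- function(n, seed = 1) {
  set.seed(seed)
  start <- sample(0:10000, n, replace = TRUE)
  data.frame(contig = sample(sprintf("contig%03d", 1:50), n, replace = TRUE),
             start = start, end = start + sample(100:2000, n, replace = TRUE),
             fold_enrichment = runif(n, 0, 12),
             pileup = runif(n, 0, 300),
             neg_log10_p = runif(n, 0, 300),
             neg_log10_q = runif(n, 0, 300),
             stringsAsFactors = FALSE)
}

test_that("records strictly above all four thresholds are kept, boundaries dropped", {
  pk <- data.frame(contig = "c", start = 0L, end = 100L,
                   fold_enrichment = c(6, 5, 6, 6, 6),
                   pileup = c(150, 150, 100, 150, 150),
                   neg_log10_p = c(120, 120, 120, 100, 120),
                   neg_log10_q = c(110, 110, 110, 110, 100))
  kept <- filter_peaks(pk)
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "summary"), list(total = 5L, kept = 1L, dropped = 4L))
})

test_that("the filter equals a brute-force four-condition scan on random records", {
  pk <- rand_peaks(1000, seed = 7)
  crit <- peak_filter_criteria()
  kept <- filter_peaks(pk, crit)
  oracle <- pk[sapply(seq_len(nrow(pk)), function(i) {
    pk$fold_enrichment[i] > 5 && pk$pileup[i] > 100 &&
      pk$neg_log10_p[i] > 100 && pk$neg_log10_q[i] > 100
  }), ]
  rownames(oracle) <- NULL
  attr(kept, "summary") <- NULL
  expect_equal(as.data.frame(kept), oracle)
})

test_that("relaxing any single threshold never decreases survivors, and filtering is idempotent", {
  pk <- rand_peaks(600, seed = 9)
  base <- nrow(filter_peaks(pk))
  relax <- list(peak_filter_criteria(min_fold_enrichment = 2),
                peak_filter_criteria(min_pileup = 50),
                peak_filter_criteria(min_neg_log10_p = 50),
                peak_filter_criteria(min_neg_log10_q = 50))
  for (cr in relax) expect_gte(nrow(filter_peaks(pk, cr)), base)
  once <- filter_peaks(pk)
  twice <- filter_peaks(once)
  attr(once, "summary") <- NULL
  attr(twice, "summary") <- NULL
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("malformed records are rejected with their line number", {
  pk <- rand_peaks(10, seed = 11)
  pk$end[4] <- pk$start[4]
  expect_error(filter_peaks(pk), "line 4")
  pk2 <- rand_peaks(10, seed = 11)
  pk2$pileup[7] <- NA
  expect_error(filter_peaks(pk2), "line 7")
})

test_that("MACS-style tables import with case-insensitive header matching", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               paste("Chr", "Start", "End", "Pileup", "-log10(pvalue)",
                     "Fold_Enrichment", "-log10(qvalue)", sep = "\t"),
               paste("ctg1", 101, 400, 150.2, 123.4, 7.1, 111.1, sep = "\t"),
               paste("ctg2", 1, 300, 90.0, 12.0, 2.0, 8.0, sep = "\t")), f)
  pk <- read_peak_table(f)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$start[1], 100)   # 1-based to 0-based
  expect_equal(pk$fold_enrichment, c(7.1, 2.0))
  expect_equal(nrow(filter_peaks(pk)), 1)
  expect_error(suppressWarnings(read_peak_table(tempfile())), "cannot open|No such|missing")
})

test_that("flat equal coverage calls no domains and zero input errors", {
  ip <- rep(50L, 5000); inp <- rep(50L, 5000)
  expect_equal(nrow(call_domains(ip, inp)), 0)
  expect_error(call_domains(ip, rep(0L, 5000)), "cannot form ratio")
  expect_error(call_domains(ip, inp[1:10]), "same length")
})

test_that("a single enriched array yields one domain overlapping the true interval", {
  cfg <- tiny_config(seed = 15, n_reads_ip = 30000L, n_reads_input = 30000L)
  sim <- simulate_genome(cfg)
  ip <- simulate_reads(sim, "ip")
  inp <- simulate_reads(sim, "input")
  G <- nchar(sim$genome)
  pk <- call_domains(coverage_track(ip, G), coverage_track(inp, G),
                     total_ip = 30000, total_input = 30000)
  expect_equal(nrow(pk), 1)
  arr <- sim$annotation[sim$annotation$family == "satEC" &
                          sim$annotation$kind == "array", ]
  expect_lt(pk$start, arr$end)
  expect_gt(pk$end, arr$start)
  # and q-values are BH-monotone in p rank
  pk2 <- rbind(pk, pk, pk)
  pk2$neg_log10_p <- c(200, 150, 180)
  pk2$neg_log10_q <- -satcen:::bh_log10(-pk2$neg_log10_p)
  o <- order(-pk2$neg_log10_p)
  expect_true(all(diff(pk2$neg_log10_q[o]) <= 0))
  expect_true(all(pk2$neg_log10_q <= pk2$neg_log10_p + 1e-9))
})

test_that("filtered synthetic domains classify to the CENP-A-bound family", {
  cfg <- tiny_config(seed = 17, n_reads_ip = 30000L, n_reads_input = 30000L)
  sim <- simulate_genome(cfg)
  ip <- simulate_reads(sim, "ip")
  inp <- simulate_reads(sim, "input")
  G <- nchar(sim$genome)
  pk <- call_domains(coverage_track(ip, G), coverage_track(inp, G),
                     total_ip = 30000, total_input = 30000)
  kept <- filter_peaks(pk)
  expect_gt(nrow(kept), 0)
  for (i in seq_len(nrow(kept))) {
    s <- substring(sim$genome, kept$start[i] + 1, kept$end[i])
    cls <- classify_region(s, sim$panel, period = FALSE)
    expect_equal(cls$family, "satEC")
  }
})
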