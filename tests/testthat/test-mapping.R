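make_panel <- function(seed = 101) {
  set.seed(seed)
  reference_panel(c(satA = rand_seq(221, 0.53), satB = rand_seq(137, 0.4),
                    ere = rand_seq(310, 0.45)),
                  is_tandem = c(TRUE, TRUE, FALSE))
}

test_that("exact substrings map with identity 1 at the right offset", {
  panel <- make_panel()
  read <- substr(panel$sequence[1], 31, 80)
  hit <- align_read(read, panel)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$entry, "satA")
  expect_equal(hit$offset, 30)
  expect_equal(hit$identity, 1)
  expect_equal(hit$strand, "+")
  expect_false(hit$ambiguous)
})

test_that("reads with 25 % mismatches fall below the 0.8 identity threshold", {
  panel <- make_panel()
  set.seed(7)
  read <- mutate_k(substr(panel$sequence[1], 1, 80), 20)  # 25 % of 80
  expect_equal(nrow(align_read(read, panel)), 0)
  # but they map when the threshold admits them
  hit <- align_read(read, panel, mapper_config(min_identity = 0.7))
  expect_equal(hit$entry, "satA")
  expect_equal(hit$identity, 0.75)
})

test_that("junction-spanning reads map on the dimer with identity 1", {
  panel <- make_panel()
  mono <- panel$sequence[1]
  read <- paste0(substr(mono, 197, 221), substr(mono, 1, 25))
  hit <- align_read(read, panel)
  expect_equal(hit$entry, "satA")
  expect_equal(hit$offset, 196)
  expect_equal(hit$monomer_offset, 196)
  expect_equal(hit$identity, 1)
  # brute-force check over the dimer confirms the placement
  orc <- oracle_align(read, panel)
  expect_equal(orc$offset, 196)
  expect_equal(orc$identity, 1)
})

test_that("every error-free read from an infinite tandem array maps with identity 1", {
  panel <- make_panel()
  arr <- strrep(panel$sequence[1], 4)
  set.seed(11)
  starts <- sample(nchar(arr) - 79, 60)
  reads <- substring(arr, starts, starts + 79)
  res <- map_readset(reads, panel)
  expect_equal(res$summary$mapped, 60)
  expect_true(all(res$hits$identity == 1))
  expect_true(all(res$hits$entry == "satA"))
  expect_equal(res$hits$offset, (starts - 1) %% 221)
})

test_that("empty read sets give zeroed summaries", {
  panel <- make_panel()
  res <- map_readset(character(0), panel)
  expect_equal(res$summary$total, 0)
  expect_equal(res$summary$mapped, 0)
  expect_equal(unname(res$summary$per_entry), rep(0L, 3))
  expect_equal(nrow(res$hits), 0)
})

test_that("per-entry counts sum to the mapped total and unique sources stay pure", {
  panel <- make_panel()
  set.seed(13)
  arr <- strrep(panel$sequence[2], 5)
  starts <- sample(nchar(arr) - 59, 80, replace = TRUE)
  reads <- substring(arr, starts, starts + 59)
  res <- map_readset(reads, panel)
  expect_equal(sum(res$summary$per_entry), res$summary$mapped)
  expect_equal(unname(res$summary$per_entry[["satB"]]), res$summary$mapped)
  expect_equal(res$summary$mapped, 80)
})

test_that("reverse-complementing a read flips strand but keeps entry and identity", {
  panel <- make_panel()
  set.seed(17)
  reads <- vapply(1:40, function(i) {
    s <- sample(300, 1)
    mutate_k(substring(panel$target[1 + i %% 3], s %% 100 + 1,
                       s %% 100 + 70), sample(0:10, 1))
  }, character(1))
  a <- map_readset(reads, panel)$hits
  b <- map_readset(revcomp(reads), panel)$hits
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$entry, b$entry)
  expect_equal(a$identity, b$identity)
  expect_true(all(a$strand != b$strand))
})

test_that("lowering min_identity never decreases the mapped-read count", {
  panel <- make_panel()
  set.seed(19)
  reads <- c(vapply(1:50, function(i) rand_seq(60), character(1)),
             vapply(1:50, function(i) {
               mutate_k(substr(panel$sequence[1 + i %% 3], 10, 69),
                        sample(0:20, 1))
             }, character(1)))
  mapped <- vapply(c(0.95, 0.9, 0.8, 0.7, 0.6),
                   function(mi) map_readset(reads, panel,
                                            mapper_config(mi))$summary$mapped,
                   numeric(1))
  expect_true(all(diff(mapped) >= 0))
})

test_that("ties across identical entries are flagged ambiguous and resolved to panel order", {
  dup <- reference_panel(c(first = "ACGTACGTACGTACGTACGT",
                           second = "ACGTACGTACGTACGTACGT"),
                         is_tandem = FALSE)
  hit <- align_read("ACGTACGTACGT", dup)
  expect_equal(hit$entry, "first")
  expect_true(hit$ambiguous)
})

test_that("invalid reads error and all-N reads are no-hits", {
  panel <- make_panel()
  expect_error(align_read("ACGTXZ", panel), "non-ACGTN")
  expect_equal(nrow(align_read(strrep("N", 50), panel)), 0)
})

test_that("the indel mode rescues single-indel reads the substitution mode rejects", {
  panel <- make_panel()
  base <- substr(panel$sequence[1], 41, 100)      # 60-mer
  del <- paste0(substr(base, 1, 29), substr(base, 31, 60))  # one deletion
  strict <- align_read(del, panel, mapper_config(min_identity = 0.9))
  expect_equal(nrow(strict), 0)
  indel <- align_read(del, panel, mapper_config(min_identity = 0.9,
                                                allow_indels = TRUE))
  expect_equal(indel$entry, "satA")
  expect_equal(indel$identity, 1 - 1 / 59)
})

test_that("mapper equals the brute-force oracle on a mixed read set", {
  panel <- make_panel(seed = 202)
  set.seed(23)
  reads <- c(
    vapply(1:60, function(i) rand_seq(50), character(1)),
    vapply(1:90, function(i) {
      e <- 1 + i %% 3
      o <- sample(nchar(panel$sequence[e]) - 10, 1)
      r <- mutate_k(substring(panel$target[e], o, o + 49), sample(0:14, 1))
      if (i %% 2) r else oracle_revcomp(r)
    }, character(1)))
  res <- map_readset(reads, panel)
  hits <- res$hits
  for (i in seq_along(reads)) {
    orc <- oracle_align(reads[i], panel)
    row <- hits[hits$id == sprintf("read%06d", i), ]
    if (is.null(orc)) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$entry, orc$entry)
      expect_equal(row$identity, orc$identity)
      expect_equal(row$offset, orc$offset)
      expect_equal(row$ambiguous, orc$ambiguous)
    }
  }
})
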