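test_that("slot-blot ratios follow the background-subtracted formula", {
  expect_equal(slot_ratio(200, 100)$ratio, 2)
  expect_equal(slot_ratio(150, 150)$ratio, 1)
  expect_equal(slot_ratio(210, 110, background = 10)$ratio, 2)
  r <- slot_ratio(50, 20, background = 20)
  expect_true(r$undefined)
  expect_true(is.na(r$ratio))
  expect_error(slot_ratio(5, 50, background = 10), "below background")
})

test_that("slot ratios are scale-invariant only when background is zero", {
  set.seed(103)
  for (i in 1:15) {
    ip <- runif(1, 100, 1000); inp <- runif(1, 100, 1000)
    cc <- runif(1, 1.5, 8)
    expect_equal(slot_ratio(ip * cc, inp * cc, 0)$ratio,
                 slot_ratio(ip, inp, 0)$ratio)
    bg <- runif(1, 10, 50)
    r1 <- slot_ratio(ip + bg, inp + bg, bg)$ratio
    r2 <- slot_ratio((ip + bg) * cc, (inp + bg) * cc, bg)$ratio
    # scaling signal and background together changes the subtracted ratio
    expect_false(isTRUE(all.equal(r1, r2)) && abs(ip - inp) > 1)
  }
})

test_that("segmentation finds no green blocks in a silent channel", {
  prof <- structure(data.frame(pos = 1:100,
                               red = c(rep(0, 30), rep(50, 40), rep(0, 30)),
                               green = rep(0, 100)),
                    class = c("fibre_profile", "data.frame"))
  seg <- segment_profile(prof)
  expect_equal(nrow(attr(seg, "green_blocks")), 0)
  expect_equal(attr(seg, "coverage"), 0)
  expect_equal(classify_fibre(seg), "III")
})

test_that("a noiseless full-coverage fibre segments to one block spanning the red stretch", {
  cfg <- tiny_config(seed = 7, fibre_counts = c(I = 1L, II = 0L, III = 0L),
                     fibre_noise_sd = 0, fibre_full_coverage = 1)
  f <- simulate_fibres(cfg)[[1]]
  seg <- segment_profile(f)
  expect_equal(unname(attr(seg, "red_stretch")), unname(attr(f, "truth_red")))
  gb <- attr(seg, "green_blocks")
  tg <- attr(f, "truth_green")
  expect_equal(nrow(gb), 1)
  expect_equal(as.vector(gb), as.vector(tg))
  expect_equal(classify_fibre(seg), "I")
})

test_that("segmentation errors are informative", {
  flat <- structure(data.frame(pos = 1:100, red = rep(1, 100),
                               green = rep(1, 100)),
                    class = c("fibre_profile", "data.frame"))
  expect_error(segment_profile(flat), "no satellite signal")
  short <- structure(data.frame(pos = 1:10, red = 1:10, green = 1:10),
                     class = c("fibre_profile", "data.frame"))
  expect_error(segment_profile(short), "20 sample points")
  expect_error(classify_fibre(flat), "segmented")
})

test_that("block boundaries land within 2 samples of truth on noisy fibres", {
  cfg <- tiny_config(seed = 19, fibre_counts = c(I = 40L, II = 40L, III = 20L))
  fibres <- simulate_fibres(cfg)
  for (f in fibres) {
    seg <- segment_profile(f)
    tg <- attr(f, "truth_green")
    gb <- attr(seg, "green_blocks")
    expect_equal(nrow(gb), nrow(tg))
    if (nrow(tg)) {
      expect_true(all(abs(gb - tg) <= 2))
    }
  }
})

test_that("classification cutoffs partition the coverage range", {
  mk <- function(cov) {
    p <- structure(data.frame(pos = 1:100, red = 1, green = 1),
                   class = c("segmented_fibre", "fibre_profile", "data.frame"))
    attr(p, "coverage") <- cov
    p
  }
  expect_equal(classify_fibre(mk(1.0)), "I")
  expect_equal(classify_fibre(mk(0.95)), "I")
  expect_equal(classify_fibre(mk(0.5)), "II")
  expect_equal(classify_fibre(mk(0.0)), "III")
  expect_equal(classify_fibre(mk(0.05)), "III")
  expect_equal(classify_fibre(mk(0.5), low = 0.6), "III")
})

test_that("classification is invariant to rescaling both channels", {
  cfg <- tiny_config(seed = 23, fibre_counts = c(I = 4L, II = 4L, III = 2L))
  for (f in simulate_fibres(cfg)) {
    a <- classify_fibre(segment_profile(f))
    g <- f; g$red <- g$red * 7.3; g$green <- g$green * 7.3
    expect_equal(classify_fibre(segment_profile(g)), a)
  }
})

test_that("at default noise at least 95 % of 200 fibres recover their true class", {
  cfg <- tiny_config(seed = 29, fibre_counts = c(I = 80L, II = 80L, III = 40L))
  fibres <- simulate_fibres(cfg)
  calls <- classify_fibres(fibres)
  expect_equal(nrow(calls), 200)
  expect_gte(mean(calls$class == calls$truth_class), 0.95)
})

test_that("fibre summaries report counts and integer percentages", {
  s <- summarize_fibres(rep(c("I", "II", "III"), c(15, 7, 3)))
  expect_equal(s$count, c(15L, 7L, 3L))
  expect_equal(s$percent, c(60, 28, 12))
  s1 <- summarize_fibres("I")
  expect_equal(s1$percent, c(100, 0, 0))
  expect_error(summarize_fibres(character(0)), "no classified fibres")
  set.seed(107)
  for (i in 1:10) {
    n <- sample(1:50, 3)
    cls <- rep(c("I", "II", "III"), n)
    s <- summarize_fibres(cls)
    expect_equal(sum(s$count), length(cls))
    expect_equal(s$percent_exact, 100 * n / sum(n))
    expect_equal(s$percent, round(100 * n / sum(n)))
  }
})

test_that("fibre trace files round-trip", {
  cfg <- tiny_config(seed = 31, fibre_counts = c(I = 1L, II = 1L, III = 1L))
  fibres <- simulate_fibres(cfg)
  d <- tempfile()
  paths <- write_fibre_traces(fibres, d)
  back <- read_fibre_trace(paths[2])
  expect_equal(back$green, fibres[[2]]$green)
  expect_error(suppressWarnings(read_fibre_trace(tempfile())), "cannot open|No such")
})
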