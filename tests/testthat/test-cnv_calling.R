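test_that("call_cnvs applies the three-consecutive-probe run rule", {
  # the canonical amplification run
  calls <- call_cnvs(make_track(c(0, 0.6, 0.6, 0.6, 0)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sign, "amplification")
  expect_equal(calls$n_probes, 3)
  expect_equal(calls$start, 170)       # first probe of the run
  expect_equal(calls$end, 3 * 170 + 60)

  # run of 2 below minimum -> no call
  expect_equal(nrow(call_cnvs(make_track(c(0, -1.2, -1.2, 0)))), 0)

  # sign change breaks the run: only the 3-probe deletion is called
  calls <- call_cnvs(make_track(c(0.6, 0.6, -0.6, -0.6, -0.6)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sign, "deletion")
  expect_equal(calls$n_probes, 3)

  # threshold is strictly exceeded: 0.5 exactly does not qualify
  expect_equal(nrow(call_cnvs(make_track(rep(0.5, 5)))), 0)
  expect_equal(nrow(call_cnvs(make_track(rep(0.5001, 3)))), 1)

  # runs never cross region boundaries
  tr <- rbind(make_track(c(0.6, 0.6), region_id = "gA"),
              make_track(c(0.6, 0.6), region_id = "gB", start0 = 2 * 170))
  expect_equal(nrow(call_cnvs(tr)), 0)

  # empty and unsorted tracks
  expect_equal(nrow(call_cnvs(make_track(numeric(0)))), 0)
  bad <- make_track(c(0.6, 0.6, 0.6))[c(2, 1, 3), ]
  expect_error(call_cnvs(bad), "sorted")
})

test_that("call_cnvs matches the all-windows oracle on random tracks", {
  # the full 500-track sweep runs in test-acceptance.R; this is a
  # quicker version of the same property
  params <- call_params()
  set.seed(20260910)
  for (rep in 1:150) {
    tr <- random_track(sample(5:200, 1))
    got <- call_cnvs(tr, params)
    want <- oracle_call_cnvs(tr, params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      cols <- c("sample_id", "chrom", "start", "end", "region_id",
                "n_probes", "sign")
      expect_equal(got[, cols], want[, cols], ignore_attr = TRUE)
    }
  }
})

test_that("call counts are monotone in tau and min_probes", {
  set.seed(99)
  for (rep in 1:50) {
    tr <- random_track(80)
    n_base <- nrow(call_cnvs(tr, call_params(tau = 0.5)))
    expect_lte(nrow(call_cnvs(tr, call_params(tau = 0.7))), n_base)
    expect_lte(nrow(call_cnvs(tr, call_params(min_probes = 4))), n_base)
  }
})

test_that("density filter drops sparse calls with an inclusive boundary", {
  calls <- rbind(
    data.frame(sample_id = "s", chrom = "c", start = 0, end = 10000,
               region_id = "g", n_probes = 3, sign = "deletion",
               mean_log2 = -1, length = 10000, density = 10000 / 3),
    data.frame(sample_id = "s", chrom = "c", start = 0, end = 751,
               region_id = "g", n_probes = 6, sign = "deletion",
               mean_log2 = -1, length = 751, density = 751 / 6),
    data.frame(sample_id = "s", chrom = "c", start = 0, end = 6000,
               region_id = "g", n_probes = 3, sign = "deletion",
               mean_log2 = -1, length = 6000, density = 2000))
  out <- density_filter(calls, call_params())
  expect_equal(out$length, c(751, 6000))   # 2000 bp/probe boundary retained
  expect_equal(attr(out, "n_removed"), 1)
})

test_that("emitted calls satisfy density = length / n_probes exactly", {
  set.seed(5)
  for (rep in 1:20) {
    calls <- call_cnvs(random_track(120))
    if (nrow(calls))
      expect_identical(calls$density, calls$length / calls$n_probes)
  }
})

test_that("injected CNVs are recovered exactly at low noise", {
  # |shift| >= 1, >= 3 probes, noise_sd 0.1: per-probe exceedance of the
  # 0.5 threshold in the wrong direction has probability ~ pnorm(-5)
  # full 100-sample version in test-acceptance.R
  lay <- generate_probe_layout(region_set(demo_regions(4), flank = 1000))
  span <- split(lay, lay$region_id)
  n_false <- 0L; n_missed <- 0L; n_samples <- 0L
  for (s in 1:30) {
    reg <- span[[sample(length(span), 1)]]
    i0 <- sample(nrow(reg) - 5, 1)
    truth <- data.frame(sample_id = "pop1_s1", chrom = "chr1",
                        start = reg$start[i0], end = reg$end[i0 + 3],
                        copy_state = sample(c(0L, 1L, 4L), 1))
    cfg <- sim_config(noise_sd = 0.1, seed = s)
    out <- simulate_cgh(lay, cfg, truth = truth)
    tr <- out$tracks[out$tracks$sample_id == "pop1_s1", ]
    calls <- density_filter(call_cnvs(tr), call_params())
    n_samples <- n_samples + 1L
    # reciprocal probe-set identity: exactly the probes under the truth
    on <- tr$start < truth$end & tr$end > truth$start
    expected_probes <- tr[on, ]
    hit <- calls$start == min(expected_probes$start) &
      calls$end == max(expected_probes$end)
    if (!any(hit)) n_missed <- n_missed + 1L
    n_false <- n_false + sum(!hit)
  }
  expect_equal(n_missed, 0L)
  expect_equal(n_false, 0L)
})

test_that("summarize_sample computes the documented statistics", {
  mk <- function(lens, probes = rep(6, length(lens)),
                 signs = rep("deletion", length(lens))) {
    n <- length(lens)
    data.frame(sample_id = rep("s", n), chrom = rep("c", n),
               start = rep(0, n), end = lens, region_id = rep("g", n),
               n_probes = probes, sign = signs, mean_log2 = rep(-1, n),
               length = lens, density = lens / probes)
  }
  s <- summarize_sample(mk(c(700, 800)))
  expect_equal(s$size_median, 750)     # midpoint-of-two convention
  s1 <- summarize_sample(mk(500))
  expect_equal(s1$size_median, 500)
  expect_equal(s1$size_mean, 500)
  s3 <- summarize_sample(mk(c(100, 200, 10000)))
  expect_equal(s3$size_median, 200)
  expect_equal(s3$size_mean, 3433.33, tolerance = 1e-4)
  s0 <- summarize_sample(mk(numeric(0)))
  expect_equal(s0$n_cnvs, 0)
  expect_true(is.na(s0$size_median))
})

test_that("compare_populations runs the named tests", {
  mk <- function(sample, pop, lens, signs)
    data.frame(sample_id = sample, population = pop, chrom = "c",
               start = seq_along(lens) * 10000, end = seq_along(lens) * 10000 + lens,
               region_id = "g", n_probes = pmax(3, lens %/% 170),
               sign = signs, mean_log2 = 1, length = lens,
               density = lens / pmax(3, lens %/% 170))
  # identical call sets in both populations -> KS D = 0, Fisher OR = 1
  lens <- c(500, 700, 900, 1100)
  signs <- rep(c("amplification", "deletion"), 2)
  calls <- rbind(mk("a1", "pop1", lens, signs), mk("b1", "pop2", lens, signs))
  cp <- compare_populations(calls)
  expect_equal(cp$ks$D, rep(0, 3))
  expect_equal(cp$fisher$odds_ratio, 1)
  expect_equal(cp$fisher$p, 1)

  # U = 0 when one group's per-sample counts all exceed the other's
  calls2 <- do.call(rbind, c(
    lapply(1:5, function(i) mk(paste0("a", i), "pop1",
                               rep(500, i), rep("deletion", i))),
    lapply(1:5, function(i) mk(paste0("b", i), "pop2",
                               rep(500, i + 5), rep("deletion", i + 5)))))
  cp2 <- compare_populations(calls2)
  expect_equal(unname(cp2$mwu_counts$U), 0)

  expect_error(compare_populations(calls[calls$population == "pop1", ]),
               "two populations")
})
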