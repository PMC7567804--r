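uniform_profile <- function(build, total, minor, ploidy = NULL) {
  chroms <- build$chroms
  segment_profile("u", data.frame(chrom = chroms$chrom, start = 1,
                                  end = chroms$length, total_cn = total,
                                  minor_cn = minor), ploidy = ploidy)
}

test_that("WGD call follows the major-copy-number length fraction", {
  b <- toy_build(3)
  expect_equal(call_wgd(uniform_profile(b, 2, 1)),
               list(wgd = FALSE, wgd_fraction = 0))
  expect_equal(call_wgd(uniform_profile(b, 4, 2)),
               list(wgd = TRUE, wgd_fraction = 1))
  # 60% of autosomal length at major 2, rest at major 1
  len <- b$chroms$length
  segs <- rbind(
    data.frame(chrom = c("1", "2"), start = 1, end = len[1:2],
               total_cn = 3, minor_cn = 1),
    data.frame(chrom = "3", start = 1, end = len[3], total_cn = 2,
               minor_cn = 1))
  prof <- segment_profile("m", segs)
  res <- call_wgd(prof)
  expect_equal(res$wgd_fraction, sum(len[1:2]) / sum(len))
  expect_true(res$wgd)
  # exactly 50% is not WGD (strict inequality)
  b2 <- toy_build(2)
  half <- rbind(
    data.frame(chrom = "1", start = 1, end = b2$chroms$length[1],
               total_cn = 4, minor_cn = 2),
    data.frame(chrom = "2", start = 1, end = b2$chroms$length[2],
               total_cn = 2, minor_cn = 1))
  expect_false(call_wgd(segment_profile("h", half))$wgd)
  expect_error(call_wgd(segment_profile("x", data.frame(
    chrom = "X", start = 1, end = 100, total_cn = 2, minor_cn = 1))),
    "insufficient")
})

test_that("arm events use the 80% same-direction rule against ploidy", {
  b <- toy_build(1, chrom_len = 10e6)
  arm <- b$arms[b$arms$arm == "p", ]
  base <- data.frame(chrom = "1", start = b$arms$start[2],
                     end = b$arms$end[2], total_cn = 2, minor_cn = 1)
  mk <- function(p_segs) {
    segment_profile("a", rbind(p_segs, base), ploidy = 2)
  }
  # fully at ploidy: neutral
  calls <- call_arm_events(mk(data.frame(chrom = "1", start = arm$start,
                                         end = arm$end, total_cn = 2,
                                         minor_cn = 1)), b)
  expect_equal(calls$call[calls$arm == "p"], "neutral")
  # 85% above ploidy: gain
  cut <- round(arm$start + 0.85 * (arm$end - arm$start + 1)) - 1
  calls <- call_arm_events(mk(data.frame(
    chrom = "1", start = c(arm$start, cut + 1), end = c(cut, arm$end),
    total_cn = c(3, 2), minor_cn = 1)), b)
  expect_equal(calls$call[calls$arm == "p"], "gain")
  expect_equal(calls$frac_gain[calls$arm == "p"], 0.85, tolerance = 1e-6)
  # 50% above, 50% below: neither direction exceeds 0.8
  mid <- round((arm$start + arm$end) / 2)
  calls <- call_arm_events(mk(data.frame(
    chrom = "1", start = c(arm$start, mid + 1), end = c(mid, arm$end),
    total_cn = c(3, 1), minor_cn = c(1, 0))), b)
  expect_equal(calls$call[calls$arm == "p"], "neutral")
  # exactly 80% altered is neutral (strict inequality)
  cut80 <- arm$start + 0.8 * (arm$end - arm$start + 1) - 1
  calls <- call_arm_events(mk(data.frame(
    chrom = "1", start = c(arm$start, cut80 + 1), end = c(cut80, arm$end),
    total_cn = c(3, 2), minor_cn = 1)), b)
  expect_equal(calls$call[calls$arm == "p"], "neutral")
})

test_that("aneuploidy score counts non-neutral arms with a maximum of 39", {
  b <- load_genome_build("grch37")
  neutral <- uniform_profile(b, 2, 1, ploidy = 2)
  expect_equal(aneuploidy_score(suppressWarnings(call_arm_events(neutral, b))), 0)
  # both arms of chr7 gained and chr10 lost: score 4 by enumeration
  segs <- data.frame(chrom = b$chroms$chrom, start = 1, end = b$chroms$length,
                     total_cn = 2, minor_cn = 1)
  segs$total_cn[segs$chrom == "7"] <- 3
  segs$total_cn[segs$chrom == "10"] <- 1
  segs$minor_cn[segs$chrom == "10"] <- 0
  prof <- segment_profile("p", segs, ploidy = 2)
  calls <- call_arm_events(prof, b)
  expect_equal(aneuploidy_score(calls), 4)
  expect_setequal(paste0(calls$chrom, calls$arm)[calls$call != "neutral"],
                  c("7p", "7q", "10p", "10q"))
})

test_that("altered genome fraction covers amplification, loss, deletion and CN-LOH", {
  b <- toy_build(2)
  expect_equal(altered_genome_fraction(uniform_profile(b, 1, 0)), 1)
  expect_equal(altered_genome_fraction(uniform_profile(b, 3, 1)), 0)
  expect_equal(altered_genome_fraction(uniform_profile(b, 2, 0)), 1)  # CN-LOH
  expect_equal(altered_genome_fraction(uniform_profile(b, 6, 1)), 1)  # amp
  # 10% of length at total 0, rest 2+1
  len <- b$chroms$length[1]
  segs <- rbind(
    data.frame(chrom = "1", start = 1, end = round(0.1 * len), total_cn = 0,
               minor_cn = 0),
    data.frame(chrom = "1", start = round(0.1 * len) + 1, end = len,
               total_cn = 2, minor_cn = 1),
    data.frame(chrom = "2", start = 1, end = len, total_cn = 2, minor_cn = 1))
  expect_equal(altered_genome_fraction(segment_profile("f", segs)),
               round(0.1 * len) / (2 * len))
})

test_that("ploidy calls agree with per-basepair brute force on random profiles", {
  b <- toy_build(2, chrom_len = 2e6)
  for (seed in 1:100) {
    prof <- random_profile(b, seed)
    expect_equal(call_wgd(prof)$wgd_fraction, oracle_wgd_fraction(prof, b),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(altered_genome_fraction(prof),
                 oracle_altered_fraction(prof, b),
                 tolerance = 1e-12, info = paste("seed", seed))
    calls <- suppressWarnings(call_arm_events(prof, b))
    expect_equal(calls$call, oracle_arm_calls(prof, b),
                 info = paste("seed", seed))
  }
})

test_that("adding a gained segment never decreases the WGD fraction", {
  b <- toy_build(2, chrom_len = 2e6)
  set.seed(42)
  for (i in 1:20) {
    prof <- random_profile(b, i)
    before <- call_wgd(prof)$wgd_fraction
    seg <- prof$segments
    j <- sample.int(nrow(seg), 1)
    seg$total_cn[j] <- max(seg$total_cn[j], 2 + seg$minor_cn[j])
    after <- call_wgd(segment_profile("g", seg, ploidy = prof$ploidy))
    expect_gte(after$wgd_fraction, before)
  }
})

test_that("WGD truth is recovered on simulated cohorts away from the boundary", {
  build <- toy_build(3, chrom_len = 8e6)
  cfg <- sim_config(seed = 21, n_samples = 12, build = build, snv_count = 0,
                    kataegis_loci = 0, background_sv_rate = 0.1)
  ref <- empty_reference()
  for (i in seq_len(cfg$n_samples)) {
    s <- simulate_sample(cfg, i, reference = ref)
    truth_frac <- s$truth$wgd_fraction
    if (abs(truth_frac - 0.5) < 0.05) next
    expect_equal(call_wgd(s$profile)$wgd, s$truth$wgd,
                 info = paste("sample", i))
  }
})

test_that("arm-call truth is recovered away from the 80% boundary", {
  build <- toy_build(4, chrom_len = 8e6)
  cfg <- sim_config(seed = 33, n_samples = 8, build = build, snv_count = 0,
                    kataegis_loci = 0, background_sv_rate = 0,
                    n_chromothripsis = 0, n_bfb = 0, focal_amp_rate = 1,
                    focal_del_rate = 1)
  ref <- empty_reference()
  for (i in seq_len(cfg$n_samples)) {
    s <- simulate_sample(cfg, i, reference = ref)
    calls <- suppressWarnings(call_arm_events(s$profile, build))
    got <- stats::setNames(calls$call, paste0(calls$chrom, calls$arm))
    truth <- s$truth$arm_calls
    frac <- pmax(calls$frac_gain, calls$frac_loss)[match(names(truth),
                                                  paste0(calls$chrom, calls$arm))]
    away <- frac < 0.75 | frac > 0.85
    expect_equal(got[names(truth)][away], truth[away],
                 info = paste("sample", i))
  }
})
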