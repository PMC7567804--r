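test_that("kataegis detection finds dense clusters and honors thresholds", {
  # 10 mutations spaced 500 bp in a 1-Mb-spaced background
  bg <- seq(1e6, 20e6, by = 1e6)
  cl <- 30e6 + seq(0, by = 500, length.out = 10)
  snvs <- snv_set("s", data.frame(chrom = "1", pos = c(bg, cl), ref = "C",
                                  alt = "T"))
  loci <- detect_kataegis(snvs)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_mutations, 10)
  expect_equal(loci$mean_imd, 500)
  expect_equal(c(loci$start, loci$end), range(cl))
  # 5 mutations at 100 bp: fails the n >= 6 rule
  snvs5 <- snv_set("s", data.frame(
    chrom = "1", pos = c(bg, 30e6 + seq(0, by = 100, length.out = 5)),
    ref = "C", alt = "T"))
  expect_equal(nrow(detect_kataegis(snvs5)), 0)
  # uniform 10 kb spacing: fails the mean <= 1000 rule
  snvs10k <- snv_set("s", data.frame(
    chrom = "1", pos = seq(1e6, by = 1e4, length.out = 50), ref = "C",
    alt = "T"))
  expect_equal(nrow(detect_kataegis(snvs10k)), 0)
  expect_error(detect_kataegis(snvs, gamma = 0), "config error")
  # fewer than 2 mutations on a chromosome yields no loci
  one <- snv_set("s", data.frame(chrom = "1", pos = 5, ref = "C", alt = "T"))
  expect_equal(nrow(detect_kataegis(one)), 0)
})

test_that("the PCF dynamic program matches exhaustive segmentation", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:12, 1)
    # mixture of short and long inter-mutation distances
    imd <- round(10^runif(n, sample(c(1.5, 2), 1), sample(c(5, 6), 1)))
    pos <- cumsum(c(1e6, imd))
    gamma <- sample(c(0.5, 2, 10, 25), 1)
    got <- detect_kataegis(snv_set("s", data.frame(
      chrom = "1", pos = pos, ref = "C", alt = "T")), gamma = gamma)
    want <- oracle_kataegis(pos, gamma)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start, info = paste("seed", seed))
      expect_equal(got$n_mutations, want$n_mutations,
                   info = paste("seed", seed))
      expect_equal(got$mean_imd, want$mean_imd, tolerance = 1e-9,
                   info = paste("seed", seed))
    }
  }
})

test_that("candidate flags fire on clustered, rate-outlier and translocated chromosomes", {
  b <- toy_build(4, chrom_len = 100e6)
  # uniform breakpoints: flag A must not fire
  set.seed(3)
  pos <- sort(round(runif(100, 1, 100e6)))
  ev <- data.frame(chrom1 = "1", pos1 = pos[1:50], strand1 = "+",
                   chrom2 = "1", pos2 = pos[51:100], strand2 = "-",
                   sv_type = "DUP")
  cand <- detect_candidate_chromosomes(rearrangement_set("s", ev), b)
  expect_false(cand$flag_clustered[cand$chrom == "1"])
  # 50 breakpoints confined to a 5 Mb window: KS is overwhelming
  pos2 <- sort(round(runif(50, 50e6, 55e6)))
  ev2 <- data.frame(chrom1 = "1", pos1 = pos2[1:25], strand1 = "+",
                    chrom2 = "1", pos2 = pos2[26:50], strand2 = "-",
                    sv_type = "DUP")
  cand2 <- detect_candidate_chromosomes(rearrangement_set("s", ev2), b)
  expect_true(cand2$flag_clustered[cand2$chrom == "1"])
  expect_lt(cand2$clustered_p[cand2$chrom == "1"], 1e-5)
  # 12 translocations on one chromosome: flag C
  ev3 <- data.frame(chrom1 = "2", pos1 = seq(1e6, 12e6, by = 1e6),
                    strand1 = "+", chrom2 = "3",
                    pos2 = seq(1e6, 12e6, by = 1e6), strand2 = "-",
                    sv_type = "TRA")
  cand3 <- detect_candidate_chromosomes(rearrangement_set("s", ev3), b)
  expect_true(cand3$flag_translocation[cand3$chrom == "2"])
  expect_true(cand3$candidate[cand3$chrom == "2"])
  expect_equal(cand3$translocation_count[cand3$chrom == "2"], 12)
})

test_that("uniform-breakpoint chromosomes are rarely flagged at p < 1e-5", {
  b <- toy_build(1, chrom_len = 100e6)
  set.seed(11)
  flagged <- 0
  for (r in 1:1000) {
    pos <- round(runif(50, 1, 100e6))
    ev <- data.frame(chrom1 = "1", pos1 = pos[1:25], strand1 = "+",
                     chrom2 = "1", pos2 = pos[26:50], strand2 = "-",
                     sv_type = "DUP")
    cand <- detect_candidate_chromosomes(rearrangement_set("s", ev), b)
    flagged <- flagged + cand$flag_clustered[1]
  }
  expect_lte(flagged / 1000, 1e-3)
})

test_that("constructed BFB and chromothripsis chromosomes classify correctly", {
  b <- toy_build(2, chrom_len = 50e6)
  len <- 50e6
  # BFB: terminal loss, amplification, five fold-back inversions
  segs <- rbind(
    data.frame(chrom = "1", start = 1, end = 2e6, total_cn = 1, minor_cn = 0),
    data.frame(chrom = "1", start = 2e6 + 1, end = 4e6, total_cn = 6,
               minor_cn = 1),
    data.frame(chrom = "1", start = 4e6 + 1, end = len, total_cn = 2,
               minor_cn = 1),
    data.frame(chrom = "2", start = 1, end = len, total_cn = 2, minor_cn = 1))
  prof <- segment_profile("bfb", segs, ploidy = 2)
  fb_pos <- seq(2.1e6, 3.9e6, length.out = 5)
  ev <- data.frame(chrom1 = "1", pos1 = fb_pos, strand1 = "+", chrom2 = "1",
                   pos2 = fb_pos + 1e4, strand2 = "+", sv_type = "INV")
  call <- classify_complex_chromosome(prof, rearrangement_set("bfb", ev),
                                      "1", b)
  expect_true(call$telomeric_loss)
  expect_gte(call$foldback_count, 5)
  expect_equal(call$class, "BFB")

  # chromothripsis: oscillating CN with retained heterozygosity
  bounds <- round(seq(10e6, 30e6, length.out = 25))
  ct <- do.call(rbind, lapply(seq_len(24), function(i) {
    data.frame(chrom = "1", start = bounds[i], end = bounds[i + 1] - 1,
               total_cn = if (i %% 2 == 0) 2 else 1,
               minor_cn = if (i %% 2 == 0) 1 else 0)
  }))
  segs2 <- rbind(
    data.frame(chrom = "1", start = 1, end = bounds[1] - 1, total_cn = 2,
               minor_cn = 1),
    ct,
    data.frame(chrom = "1", start = bounds[25], end = len, total_cn = 2,
               minor_cn = 1),
    data.frame(chrom = "2", start = 1, end = len, total_cn = 2, minor_cn = 1))
  prof2 <- segment_profile("ct", segs2, ploidy = 2)
  del_idx <- which(seq_len(24) %% 2 == 1)
  ev2 <- data.frame(chrom1 = "1", pos1 = bounds[del_idx], strand1 = "+",
                    chrom2 = "1", pos2 = bounds[del_idx + 1], strand2 = "-",
                    sv_type = "DEL")
  call2 <- classify_complex_chromosome(prof2, rearrangement_set("ct", ev2),
                                       "1", b)
  expect_gte(call2$cn_switches, 10)
  expect_lte(call2$cn_states, 3)
  expect_gte(call2$het_retention_fraction, 0.5)
  expect_equal(call2$class, "chromothripsis")

  # candidate via translocations only, flat copy number: localized complex
  flat <- segment_profile("lc", data.frame(
    chrom = c("1", "2"), start = 1, end = len, total_cn = 2, minor_cn = 1),
    ploidy = 2)
  ev3 <- data.frame(chrom1 = "1", pos1 = seq(1e6, 12e6, 1e6), strand1 = "+",
                    chrom2 = "2", pos2 = seq(1e6, 12e6, 1e6), strand2 = "-",
                    sv_type = "TRA")
  call3 <- classify_complex_chromosome(flat, rearrangement_set("lc", ev3),
                                       "1", b)
  expect_equal(call3$class, "localized_complex")
})

test_that("planted complex chromosomes are recovered from simulated samples", {
  build <- toy_build(3, chrom_len = 20e6)
  cfg <- sim_config(seed = 51, n_samples = 15, build = build, snv_count = 0,
                    kataegis_loci = 0, background_sv_rate = 0.2,
                    chromothripsis_window = 8e6)
  ref <- empty_reference()
  n_ok <- 0; n_tot <- 0
  for (i in seq_len(cfg$n_samples)) {
    s <- simulate_sample(cfg, i, reference = ref)
    rep <- complex_chromosome_report(s$profile, s$rearrangements, build)
    for (ch in names(s$truth$complex_chroms)) {
      n_tot <- n_tot + 1
      n_ok <- n_ok + (rep$class[rep$chrom == ch] ==
                        s$truth$complex_chroms[[ch]])
    }
  }
  expect_gte(n_ok / n_tot, 0.9)
})

test_that("planted kataegis is found at realistic chromosome scale", {
  # single long chromosome; background at the cohort TMB
  build <- genome_build(data.frame(chrom = "1", length = 1e8,
                                   cen_start = 4e7, cen_end = 4.1e7))
  cfg <- sim_config(seed = 61, n_samples = 6, build = build,
                    kataegis_loci = 1, kataegis_cluster_size = 10,
                    background_sv_rate = 0, n_chromothripsis = 0, n_bfb = 0)
  ref <- simulate_reference(build, 61)
  found <- 0; planted <- 0
  for (i in seq_len(cfg$n_samples)) {
    s <- simulate_sample(cfg, i, reference = ref)
    loci <- detect_kataegis(s$snvs)
    tl <- s$truth$kataegis_loci
    planted <- planted + nrow(tl)
    for (j in seq_len(nrow(tl))) {
      found <- found + any(loci$chrom == tl$chrom[j] &
                             loci$start <= tl$end[j] &
                             loci$end >= tl$start[j])
    }
    # detected loci satisfy the definition
    if (nrow(loci) > 0) {
      expect_true(all(loci$n_mutations >= 6))
      expect_true(all(loci$mean_imd <= 1000))
    }
  }
  expect_gte(found / planted, 0.8)
})
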