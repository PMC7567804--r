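test_that("TMB is mutations per megabase", {
  expect_equal(compute_tmb(6000, 3000), 2)
  expect_equal(compute_tmb(0, 3000), 0)
  expect_error(compute_tmb(10, 0), "positive")
})

test_that("gene CN status reports amplification and homozygous deletion", {
  segs <- data.frame(chrom = "1",
                     start = c(1, 1e6 + 1, 2e6 + 1),
                     end = c(1e6, 2e6, 3e6),
                     total_cn = c(8, 2, 0), minor_cn = c(1, 1, 0))
  prof <- segment_profile("s", segs, ploidy = 2)
  genes <- interval_track("genes", data.frame(
    chrom = "1", start = c(5e5, 1.5e6, 1.9e6), end = c(6e5, 1.6e6, 2.2e6),
    label = c("AMP1", "NEUT", "SPAN")))
  st <- gene_cn_status(prof, genes)
  expect_equal(st$status[st$gene == "AMP1"], "amplified")
  expect_equal(st$status[st$gene == "NEUT"], "none")
  expect_equal(st$status[st$gene == "SPAN"], "homdel")
  # gene spanning an amplified and a deleted segment reports both
  genes2 <- interval_track("genes", data.frame(
    chrom = "1", start = 9e5, end = 2.5e6, label = "BOTH"))
  st2 <- gene_cn_status(prof, genes2)
  expect_equal(st2$status, "amplified+homdel")
})

test_that("gene CN status matches a per-basepair overlap oracle", {
  b <- toy_build(1, chrom_len = 1e4)
  set.seed(23)
  for (rep in 1:30) {
    prof <- random_profile(b, rep)
    starts <- sort(sample(9e3, 3))
    genes <- interval_track("g", data.frame(
      chrom = "1", start = starts, end = starts + sample(500, 3),
      label = paste0("G", 1:3)))
    got <- gene_cn_status(prof, genes)
    want <- oracle_gene_status(prof, genes)
    expect_equal(got$amplified, want$amplified, info = paste("rep", rep))
    expect_equal(got$homdel, want$homdel, info = paste("rep", rep))
  }
})

test_that("TERT-upstream breakpoints are annotated with SE proximity", {
  # minus-strand gene: upstream window is above the locus end
  tert <- list(chrom = "5", start = 1253287, end = 1295184, strand = "-")
  se <- interval_track("se", data.frame(
    chrom = c("11", "11"), start = c(2e6, 9e6), end = c(2.1e6, 9.1e6),
    label = c("SE1", "SE2")))
  ev <- data.frame(
    chrom1 = "5",
    pos1 = c(tert$end + 1e4,       # 10 kb upstream: annotated
             tert$end + 3e4,       # 30 kb upstream: outside the window
             tert$start - 5e3),    # downstream of the gene: not annotated
    strand1 = "+",
    chrom2 = "11", pos2 = c(2.15e6, 5e6, 5e6), strand2 = "-",
    sv_type = "TRA")
  ann <- annotate_tert_breakpoints(rearrangement_set("s", ev), tert, se)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$upstream_distance, 1e4)
  # partner 50 kb from SE1 (gap from 2.15e6 to interval end 2.1e6)
  expect_equal(ann$se_distance, 5e4)
  expect_true(ann$se_proximal)
  # partner 200 kb away from any SE: annotated but not proximal
  ev2 <- data.frame(chrom1 = "5", pos1 = tert$end + 5e3, strand1 = "+",
                    chrom2 = "11", pos2 = 2.3e6, strand2 = "-",
                    sv_type = "TRA")
  ann2 <- annotate_tert_breakpoints(rearrangement_set("s", ev2), tert, se)
  expect_false(ann2$se_proximal)
  expect_equal(ann2$se_distance, 2e5)
  # overlap counts as distance zero
  ev3 <- data.frame(chrom1 = "5", pos1 = tert$end + 5e3, strand1 = "+",
                    chrom2 = "11", pos2 = 2.05e6, strand2 = "-",
                    sv_type = "TRA")
  ann3 <- annotate_tert_breakpoints(rearrangement_set("s", ev3), tert, se)
  expect_equal(ann3$se_distance, 0)
  # plus-strand gene: window below the start
  plus <- list(chrom = "5", start = 1e6, end = 1.1e6, strand = "+")
  ev4 <- data.frame(chrom1 = "5", pos1 = 1e6 - 1e4, strand1 = "+",
                    chrom2 = "11", pos2 = 2.05e6, strand2 = "-",
                    sv_type = "TRA")
  ann4 <- annotate_tert_breakpoints(rearrangement_set("s", ev4), plus, se)
  expect_equal(nrow(ann4), 1)
  expect_equal(ann4$upstream_distance, 1e4)
})

test_that("telomere ratio is a log2 ratio of normalized counts", {
  expect_equal(telomere_ratio(100, 25, 100, 25), 0)
  expect_equal(telomere_ratio(400, 50, 100, 25), 1)
  expect_equal(telomere_ratio(100, 50, 100, 25), -1)
  # antisymmetry under swapping tumor and normal
  set.seed(2)
  for (i in 1:20) {
    v <- runif(4, 1, 100)
    expect_equal(telomere_ratio(v[1], v[2], v[3], v[4]),
                 -telomere_ratio(v[3], v[4], v[1], v[2]), tolerance = 1e-12)
  }
  expect_error(telomere_ratio(0, 1, 1, 1), "positive")
})

test_that("1-Mb binning counts distinct samples per bin", {
  b <- toy_build(2, chrom_len = 5e6)
  mk <- function(id, pos1, pos2 = pos1 + 10) rearrangement_set(id, data.frame(
    chrom1 = "1", pos1 = pos1, strand1 = "+", chrom2 = "1", pos2 = pos2,
    strand2 = "-", sv_type = "DEL"))
  bins <- bin_breakpoints_1mb(list(mk("a", 5e5), mk("b", 5e5), mk("c", 5e5)), b)
  hot <- bins[bins$chrom == "1" & bins$start == 1, ]
  expect_equal(hot$n_samples, 3)
  expect_equal(hot$end, 1e6)
  # both ends of one sample's event in one bin count that sample once
  bins1 <- bin_breakpoints_1mb(list(mk("a", 5e5, 6e5)), b)
  expect_equal(bins1$n_samples, 1)
  # position 1e6 is in the first bin, 1e6 + 1 in the second
  bins2 <- bin_breakpoints_1mb(list(mk("a", 1e6, 1e6 + 1)), b)
  expect_equal(bins2$start, c(1, 1e6 + 1))
  expect_equal(bins2$n_samples, c(1, 1))
})

test_that("every breakpoint end falls in exactly one bin", {
  b <- toy_build(2, chrom_len = 5e6)
  set.seed(8)
  rsets <- lapply(1:5, function(i) {
    p1 <- sort(sample(5e6 - 1e3, 20))
    rearrangement_set(paste0("s", i), data.frame(
      chrom1 = sample(c("1", "2"), 20, TRUE), pos1 = p1, strand1 = "+",
      chrom2 = NA, pos2 = p1 + 500, strand2 = "-", sv_type = "DEL") |>
        transform(chrom2 = chrom1))
  })
  bins <- bin_breakpoints_1mb(rsets, b)
  # per-sample bin membership, recomputed directly
  for (rset in rsets) {
    ends <- data.frame(chrom = c(rset$events$chrom1, rset$events$chrom2),
                       pos = c(rset$events$pos1, rset$events$pos2))
    keys <- unique(paste(ends$chrom, floor((ends$pos - 1) / 1e6) + 1))
    # each end maps to exactly one bin: total distinct keys bounded by ends
    expect_lte(length(keys), nrow(ends))
  }
  expect_equal(sum(bins$n_samples),
               sum(vapply(rsets, function(r) {
                 ends <- data.frame(chrom = c(r$events$chrom1, r$events$chrom2),
                                    pos = c(r$events$pos1, r$events$pos2))
                 length(unique(paste(ends$chrom,
                                     floor((ends$pos - 1) / 1e6) + 1)))
               }, numeric(1))))
})

test_that("sample summaries assemble burden and ploidy statistics", {
  b <- toy_build(2, chrom_len = 5e6)
  prof <- segment_profile("s", data.frame(
    chrom = c("1", "2"), start = 1, end = 5e6, total_cn = 4, minor_cn = 2),
    ploidy = 4)
  rs <- rearrangement_set("s", data.frame(
    chrom1 = "1", pos1 = 1e6, strand1 = "+", chrom2 = "1", pos2 = 2e6,
    strand2 = "-", sv_type = "DEL"))
  snvs <- snv_set("s", data.frame(chrom = "1", pos = c(10, 20), ref = "C",
                                  alt = "T"))
  summ <- sample_summary(prof, rs, snvs, b)
  expect_equal(summ$tmb, 2 / 10)
  expect_equal(summ$rearrangement_count, 1)
  expect_true(summ$wgd)
})
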