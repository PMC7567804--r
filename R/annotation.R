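# Sample- and locus-level annotations: tumor mutational burden, gene-level
# amplification/homozygous-deletion calls, TERT-upstream breakpoints with
# super-enhancer proximity, telomere-length ratios and 1-Mb breakpoint
# recurrence binning.

#' Tumor mutational burden
#'
#' Mutations (SNV/DNV/TNV and indels) per megabase of genome. Tumors at or
#' above 20 mutations/Mb are conventionally labelled TMB-high.
#'
#' @param snv_indel_count total mutation count.
#' @param genome_size_mb genome size in Mb; defaults to nothing — pass
#'   `autosome_length(build)/1e6` or the full reference size.
#' @return mutations per megabase.
#' @export
compute_tmb <- function(snv_indel_count, genome_size_mb) {
  if (genome_size_mb <= 0) stop("genome size must be positive")
  snv_indel_count / genome_size_mb
}

#' Gene-level amplification and homozygous-deletion status
#'
#' A gene is amplified when any overlapping segment has total copy number
#' of at least 6, and homozygously deleted when any overlapping segment
#' has total copy number 0. Both statuses can co-occur for genes spanning
#' a breakpoint.
#'
#' @param profile a `SegmentProfile`.
#' @param genes an `IntervalTrack` of gene intervals.
#' @return data.frame: `gene`, `amplified`, `homdel`, `status` (one of
#'   `"amplified"`, `"homdel"`, `"amplified+homdel"`, `"none"`).
#' @export
gene_cn_status <- function(profile, genes) {
  seg <- profile$segments
  iv <- genes$intervals
  out <- data.frame(gene = iv$label, amplified = FALSE, homdel = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(iv))) {
    s <- seg[seg$chrom == iv$chrom[i] & seg$start <= iv$end[i] &
               seg$end >= iv$start[i], , drop = FALSE]
    out$amplified[i] <- any(s$total_cn >= 6)
    out$homdel[i] <- any(s$total_cn == 0)
  }
  out$status <- ifelse(out$amplified & out$homdel, "amplified+homdel",
                       ifelse(out$amplified, "amplified",
                              ifelse(out$homdel, "homdel", "none")))
  out
}

# Unsigned gap between a point and an interval (0 when inside).
point_interval_gap <- function(pos, start, end) {
  pmax(0, pmax(start - pos, pos - end))
}

#' Annotate breakpoints upstream of TERT with super-enhancer proximity
#'
#' For every rearrangement with one breakpoint inside the window
#' `upstream_window` bp 5' of the gene start (strand-aware: TERT is on the
#' minus strand of GRCh37, so its upstream window lies above the locus
#' end), the distance of the partner breakpoint to the nearest
#' super-enhancer is computed (gap distance, 0 when overlapping). The
#' partner is proximal when within `se_window` bp of a super-enhancer.
#'
#' @param rearrangements a `RearrangementSet`.
#' @param tert_locus list or one-row data.frame with `chrom`, `start`,
#'   `end`, `strand` for the gene.
#' @param se_track an `IntervalTrack` of super-enhancers.
#' @param upstream_window upstream window size in bp (default 20 kb).
#' @param se_window proximity threshold in bp (default 100 kb).
#' @return data.frame, one row per qualifying breakpoint: `event`,
#'   `breakpoint_pos`, `upstream_distance` (bp 5' of the gene start),
#'   `partner_chrom`, `partner_pos`, `se_distance`, `se_proximal`.
#' @export
annotate_tert_breakpoints <- function(rearrangements, tert_locus, se_track,
                                      upstream_window = 2e4, se_window = 1e5) {
  ev <- rearrangements$events
  tert_chrom <- normalize_chrom(tert_locus$chrom)
  minus <- identical(tert_locus$strand, "-")
  # strand-aware upstream window, 5' of the transcription start
  win <- if (minus) c(tert_locus$end + 1, tert_locus$end + upstream_window)
  else c(tert_locus$start - upstream_window, tert_locus$start - 1)
  se <- se_track$intervals
  rows <- list()
  add_row <- function(i, bp_chrom, bp_pos, pa_chrom, pa_pos) {
    if (bp_chrom != tert_chrom || bp_pos < win[1] || bp_pos > win[2]) return()
    se_ch <- se[se$chrom == pa_chrom, , drop = FALSE]
    dist <- if (nrow(se_ch) > 0)
      min(point_interval_gap(pa_pos, se_ch$start, se_ch$end)) else Inf
    up_dist <- if (minus) bp_pos - tert_locus$end else tert_locus$start - bp_pos
    rows[[length(rows) + 1]] <<- data.frame(
      event = i, breakpoint_pos = bp_pos, upstream_distance = up_dist,
      partner_chrom = pa_chrom, partner_pos = pa_pos,
      se_distance = dist, se_proximal = dist <= se_window)
  }
  for (i in seq_len(nrow(ev))) {
    add_row(i, ev$chrom1[i], ev$pos1[i], ev$chrom2[i], ev$pos2[i])
    add_row(i, ev$chrom2[i], ev$pos2[i], ev$chrom1[i], ev$pos1[i])
  }
  if (length(rows) == 0) {
    return(data.frame(event = integer(), breakpoint_pos = numeric(),
                      upstream_distance = numeric(),
                      partner_chrom = character(), partner_pos = numeric(),
                      se_distance = numeric(), se_proximal = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative telomere length
#'
#' Telomeric-repeat read counts are normalized by mean genomic coverage in
#' tumor and matched normal, and the relative telomere length is the log2
#' ratio of the two normalized counts.
#'
#' @param tumor_reads,normal_reads telomeric read counts.
#' @param tumor_mean_cov,normal_mean_cov mean genomic coverage.
#' @return log2 ratio (0 when normalized counts are equal).
#' @export
telomere_ratio <- function(tumor_reads, tumor_mean_cov,
                           normal_reads, normal_mean_cov) {
  if (any(c(tumor_reads, tumor_mean_cov, normal_reads, normal_mean_cov) <= 0)) {
    stop("all inputs must be positive")
  }
  log2((tumor_reads / tumor_mean_cov) / (normal_reads / normal_mean_cov))
}

#' Count samples with breakpoints in 1-Mb bins
#'
#' The genome is tiled into 1-Mb bins starting at position 1 (bins
#' half-open at the top: positions 1..1e6 fall in bin 1). Each bin counts
#' the number of distinct samples contributing at least one breakpoint
#' end.
#'
#' @param rearrangement_sets list of `RearrangementSet`s (one per sample).
#' @param build a `GenomeBuild`.
#' @param bin_size bin width in bp (default 1e6).
#' @return data.frame: `chrom`, `start`, `end`, `n_samples`; only bins
#'   with at least one sample are returned.
#' @export
bin_breakpoints_1mb <- function(rearrangement_sets, build, bin_size = 1e6) {
  hits <- list()
  for (rset in rearrangement_sets) {
    ev <- rset$events
    if (nrow(ev) == 0) next
    ends <- data.frame(chrom = c(ev$chrom1, ev$chrom2),
                       pos = c(ev$pos1, ev$pos2))
    ends <- ends[ends$chrom %in% build$chroms$chrom, , drop = FALSE]
    bin <- floor((ends$pos - 1) / bin_size) + 1
    key <- unique(paste(ends$chrom, bin, sep = ":"))
    hits[[length(hits) + 1]] <- data.frame(sample = rset$sample_id, key = key)
  }
  if (length(hits) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_samples = integer()))
  }
  all_hits <- do.call(rbind, hits)
  tb <- table(all_hits$key)
  parts <- strsplit(names(tb), ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    bin = as.numeric(vapply(parts, `[`, character(1), 2)),
    n_samples = as.integer(tb))
  out$start <- (out$bin - 1) * bin_size + 1
  out$end <- pmin(out$bin * bin_size, chrom_length(build, out$chrom))
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end", "n_samples")]
  rownames(out) <- NULL
  out
}

#' Per-sample summary statistics
#'
#' @param profile a `SegmentProfile`.
#' @param rearrangements a `RearrangementSet`.
#' @param snvs an `SnvSet`.
#' @param build a `GenomeBuild`.
#' @return one-row data.frame: `sample`, `tmb`, `rearrangement_count`,
#'   `wgd`, `aneuploidy_score`, `altered_genome_fraction`.
#' @export
sample_summary <- function(profile, rearrangements, snvs, build) {
  pr <- ploidy_report(profile, build)
  data.frame(sample = profile$sample_id,
             tmb = compute_tmb(nrow(snvs$variants),
                               sum(build$chroms$length) / 1e6),
             rearrangement_count = nrow(rearrangements$events),
             wgd = pr$wgd, aneuploidy_score = pr$aneuploidy_score,
             altered_genome_fraction = pr$altered_genome_fraction)
}
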