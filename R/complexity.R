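# Kataegis detection from inter-mutation distances, and detection plus
# classification of chromosomes carrying localized complex rearrangements
# (breakage-fusion-bridge, chromothripsis, localized complex).

#' Detect kataegis loci by piecewise constant fitting
#'
#' Inter-mutation distances (IMDs) are computed within each chromosome and
#' their log10 values segmented by an exact penalized piecewise-constant
#' fit (dynamic programming minimizing within-segment squared error plus a
#' per-segment penalty `gamma`). A fitted segment of k consecutive IMDs
#' (spanning k + 1 mutations) is reported as a kataegis locus when it
#' contains at least 6 mutations and the arithmetic mean of its raw IMDs
#' is at most 1000 bp.
#'
#' @param snvs an `SnvSet`.
#' @param gamma per-segment penalty on log10(IMD) (default 25).
#' @param min_mutations minimum mutations per locus (default 6).
#' @param max_mean_imd maximum mean raw IMD in bp (default 1000).
#' @return data.frame of loci: `chrom`, `start`, `end` (first and last
#'   mutation positions), `n_mutations`, `mean_imd`.
#' @export
detect_kataegis <- function(snvs, gamma = 25, min_mutations = 6,
                            max_mean_imd = 1000) {
  if (gamma <= 0) stop("config error: gamma must be positive")
  v <- snvs$variants
  loci <- list()
  for (ch in unique(v$chrom)) {
    pos <- sort(v$pos[v$chrom == ch])
    if (length(pos) < 2) next
    imd <- diff(pos)
    segs <- pcf_segments(log10(pmax(imd, 1)), gamma)
    for (s in seq_len(nrow(segs))) {
      i <- segs$start[s]; j <- segs$end[s]
      n_mut <- j - i + 2
      mimd <- mean(imd[i:j])
      if (n_mut >= min_mutations && mimd <= max_mean_imd) {
        loci[[length(loci) + 1]] <- data.frame(
          chrom = ch, start = pos[i], end = pos[j + 1],
          n_mutations = n_mut, mean_imd = mimd)
      }
    }
  }
  if (length(loci) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_mutations = integer(), mean_imd = numeric()))
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

# Exact optimal segmentation of y into constant segments minimizing
# sum(within-segment SSE) + gamma * (number of segments). O(n^2) dynamic
# programming with prefix sums; returns 1-based segment index ranges.
pcf_segments <- function(y, gamma) {
  n <- length(y)
  c1 <- c(0, cumsum(y))
  c2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {  # indices i..j inclusive
    s <- c1[j + 1] - c1[i]
    q <- c2[j + 1] - c2[i]
    q - s^2 / (j - i + 1)
  }
  best <- c(0, rep(Inf, n))   # best[j+1] = optimal cost of y[1..j]
  back <- integer(n)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      cost <- best[i] + sse(i, j) + gamma
      if (cost < best[j + 1]) {
        best[j + 1] <- cost
        back[j] <- i
      }
    }
  }
  ends <- integer(0); starts <- integer(0)
  j <- n
  while (j > 0) {
    i <- back[j]
    starts <- c(i, starts); ends <- c(j, ends)
    j <- i - 1
  }
  data.frame(start = starts, end = ends)
}

#' Flag chromosomes as candidates for localized complex rearrangement
#'
#' Per chromosome, three flags: (A) the breakpoint-end positions depart
#' from a uniform distribution along the chromosome (exact one-sample
#' Kolmogorov-Smirnov test, flagged when p < `p_threshold`); (B) the
#' breakpoints-per-megabase rate exceeds Q75 + 1.5 IQR of the sample's own
#' per-chromosome rate distribution (zero-breakpoint chromosomes included)
#' and the chromosome carries at least `min_breakpoints`; (C) at least
#' `min_translocations` translocation events touch the chromosome. A
#' chromosome is a candidate when any flag fires.
#'
#' @param rearrangements a `RearrangementSet`.
#' @param build a `GenomeBuild`.
#' @param p_threshold flag-A significance threshold (default 1e-5).
#' @param min_breakpoints flag-B minimum breakpoint count (default 35).
#' @param min_translocations flag-C threshold (default 10).
#' @return data.frame, one row per build chromosome: `chrom`,
#'   `breakpoint_count`, `translocation_count`, `rate_per_mb`,
#'   `clustered_p`, `flag_clustered`, `flag_rate`, `flag_translocation`,
#'   `candidate`.
#' @export
detect_candidate_chromosomes <- function(rearrangements, build,
                                         p_threshold = 1e-5,
                                         min_breakpoints = 35,
                                         min_translocations = 10) {
  ev <- rearrangements$events
  chroms <- build$chroms$chrom
  ends <- data.frame(chrom = c(ev$chrom1, ev$chrom2),
                     pos = c(ev$pos1, ev$pos2),
                     tra = rep(ev$sv_type == "TRA", 2),
                     event = rep(seq_len(nrow(ev)), 2))
  out <- data.frame(chrom = chroms, breakpoint_count = 0L,
                    translocation_count = 0L, rate_per_mb = 0,
                    clustered_p = NA_real_, flag_clustered = FALSE,
                    flag_rate = FALSE, flag_translocation = FALSE)
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    e <- ends[ends$chrom == ch, , drop = FALSE]
    out$breakpoint_count[i] <- nrow(e)
    out$translocation_count[i] <-
      length(unique(e$event[e$tra]))
    len <- build$chroms$length[i]
    out$rate_per_mb[i] <- nrow(e) / (len / 1e6)
    if (nrow(e) >= 2) {
      p <- suppressWarnings(
        stats::ks.test(e$pos, "punif", 0, len)$p.value)
      out$clustered_p[i] <- p
      out$flag_clustered[i] <- p < p_threshold
    }
  }
  q <- stats::quantile(out$rate_per_mb, c(0.25, 0.75), names = FALSE)
  cut <- q[2] + 1.5 * (q[2] - q[1])
  out$flag_rate <- out$rate_per_mb > cut &
    out$breakpoint_count >= min_breakpoints
  out$flag_translocation <- out$translocation_count >= min_translocations
  out$candidate <- out$flag_clustered | out$flag_rate | out$flag_translocation
  out
}

#' Classify a candidate chromosome as BFB, chromothripsis or localized
#' complex
#'
#' Evidence computed over the chromosome's clustered region (the span of
#' its breakpoint ends): loss of a telomere-adjacent segment relative to
#' sample ploidy; fold-back inversions (inversion events whose two ends
#' lie within `foldback_span`); copy-number switches between distinct
#' total-CN states; the number of CN states needed to cover 80% of the
#' region; and retention of heterozygosity (length fraction of
#' higher-state segments with minor allele >= 1). Chromothripsis evidence
#' requires oscillation between few states with retained heterozygosity;
#' BFB evidence requires telomeric loss with abundant fold-back
#' inversions or a high inversion/translocation fraction. Both together
#' give BFB/chromothripsis; a candidate matching neither is localized
#' complex.
#'
#' @param profile a `SegmentProfile`.
#' @param rearrangements a `RearrangementSet`.
#' @param chrom chromosome to classify.
#' @param build a `GenomeBuild`.
#' @param foldback_span maximum end-to-end distance of a fold-back
#'   inversion (default 30 kb).
#' @param min_cn_switches chromothripsis oscillation threshold (default 10).
#' @param max_cn_states chromothripsis state-count ceiling (default 3).
#' @param min_het_retention chromothripsis heterozygosity-retention floor
#'   (default 0.5).
#' @param min_foldbacks BFB fold-back count threshold (default 3).
#' @param min_inv_tra_fraction BFB inversion+translocation event-fraction
#'   threshold (default 0.4).
#' @return one-row data.frame with the evidence columns and `class` in
#'   {BFB, chromothripsis, BFB_chromothripsis, localized_complex}.
#' @export
classify_complex_chromosome <- function(profile, rearrangements, chrom, build,
                                        foldback_span = 3e4,
                                        min_cn_switches = 10,
                                        max_cn_states = 3,
                                        min_het_retention = 0.5,
                                        min_foldbacks = 3,
                                        min_inv_tra_fraction = 0.4) {
  chrom <- normalize_chrom(chrom)
  ev <- rearrangements$events
  on_chrom <- ev$chrom1 == chrom | ev$chrom2 == chrom
  e <- ev[on_chrom, , drop = FALSE]
  ends <- c(e$pos1[e$chrom1 == chrom], e$pos2[e$chrom2 == chrom])
  len <- chrom_length(build, chrom)
  seg <- profile$segments[profile$segments$chrom == chrom, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]

  # telomeric loss: a terminal segment below sample ploidy
  telomeric_loss <- FALSE
  if (nrow(seg) > 0) {
    first <- seg[1, ]; last <- seg[nrow(seg), ]
    telomeric_loss <- (first$start <= 1 && first$total_cn < profile$ploidy) ||
      (last$end >= len && last$total_cn < profile$ploidy)
  }

  foldback_count <- sum(e$sv_type == "INV" & !is.na(e$size) &
                          e$size <= foldback_span)
  inv_tra_fraction <- if (nrow(e) > 0)
    mean(e$sv_type %in% c("INV", "TRA")) else 0

  region <- if (length(ends) > 0) range(ends) else c(1, len)
  rs <- seg[seg$end >= region[1] & seg$start <= region[2], , drop = FALSE]
  cn_switches <- if (nrow(rs) > 1) sum(diff(rs$total_cn) != 0) else 0L
  cn_states <- 0L
  het_retention <- 0
  if (nrow(rs) > 0) {
    w <- pmin(rs$end, region[2]) - pmax(rs$start, region[1]) + 1
    by_state <- tapply(w, rs$total_cn, sum)
    by_state <- sort(by_state, decreasing = TRUE)
    covered <- cumsum(by_state) / sum(w)
    cn_states <- which(covered >= 0.8)[1]
    top_states <- as.numeric(names(by_state)[seq_len(min(2, length(by_state)))])
    hi <- max(top_states)
    hi_seg <- rs$total_cn == hi
    if (any(hi_seg)) het_retention <- sum(w[hi_seg & rs$minor_cn >= 1]) /
        sum(w[hi_seg])
  }

  chromothripsis_evidence <- cn_switches >= min_cn_switches &&
    cn_states <= max_cn_states && het_retention >= min_het_retention
  bfb_evidence <- telomeric_loss &&
    (foldback_count >= min_foldbacks ||
       inv_tra_fraction >= min_inv_tra_fraction)
  class <- if (bfb_evidence && chromothripsis_evidence) "BFB_chromothripsis"
  else if (bfb_evidence) "BFB"
  else if (chromothripsis_evidence) "chromothripsis"
  else "localized_complex"

  data.frame(sample = profile$sample_id, chrom = chrom,
             telomeric_loss = telomeric_loss, foldback_count = foldback_count,
             inv_tra_fraction = inv_tra_fraction, cn_switches = cn_switches,
             cn_states = cn_states, het_retention_fraction = het_retention,
             class = class, stringsAsFactors = FALSE)
}

#' Per-chromosome complex-rearrangement report for one sample
#'
#' Runs candidate detection and classifies every candidate chromosome;
#' non-candidates are reported with class `"none"`.
#'
#' @param profile a `SegmentProfile`.
#' @param rearrangements a `RearrangementSet`.
#' @param build a `GenomeBuild`.
#' @param ... threshold arguments passed to
#'   [detect_candidate_chromosomes()] and
#'   [classify_complex_chromosome()].
#' @return data.frame with candidate flags, evidence columns and `class`.
#' @export
complex_chromosome_report <- function(profile, rearrangements, build, ...) {
  dots <- list(...)
  cand_args <- dots[names(dots) %in%
                      c("p_threshold", "min_breakpoints", "min_translocations")]
  class_args <- dots[names(dots) %in%
                       c("foldback_span", "min_cn_switches", "max_cn_states",
                         "min_het_retention", "min_foldbacks",
                         "min_inv_tra_fraction")]
  cand <- do.call(detect_candidate_chromosomes,
                  c(list(rearrangements, build), cand_args))
  cand$class <- "none"
  ev_cols <- c("telomeric_loss", "foldback_count", "inv_tra_fraction",
               "cn_switches", "cn_states", "het_retention_fraction")
  for (col in ev_cols) cand[[col]] <- NA
  for (i in which(cand$candidate)) {
    call <- do.call(classify_complex_chromosome,
                    c(list(profile, rearrangements, cand$chrom[i], build),
                      class_args))
    cand$class[i] <- call$class
    for (col in ev_cols) cand[[col]][i] <- call[[col]]
  }
  cand
}
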