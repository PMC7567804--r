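# Whole-genome doubling, arm-level gain/loss, aneuploidy score and
# altered-genome fraction. All computations are restricted to the autosomal
# genome (chromosomes 1-22); X and Y segments are ignored.

autosomal_segments <- function(profile) {
  seg <- profile$segments
  seg[seg$chrom %in% AUTOSOMES, , drop = FALSE]
}

#' Call whole-genome doubling
#'
#' A tumor has undergone whole-genome duplication when more than 50% of its
#' autosomal genome (length-weighted over segments) carries a major copy
#' number, i.e. the count of the more frequent parental allele, of at least
#' two. The boundary value of exactly 50% is called non-doubled.
#'
#' @param profile a `SegmentProfile`.
#' @return list with `wgd` (logical) and `wgd_fraction` (fraction of
#'   covered autosomal length with major copy number >= 2).
#' @export
call_wgd <- function(profile) {
  seg <- autosomal_segments(profile)
  if (nrow(seg) == 0) stop("insufficient data: no autosomal segments")
  w <- seg$end - seg$start + 1
  major <- seg$total_cn - seg$minor_cn
  frac <- sum(w[major >= 2]) / sum(w)
  list(wgd = frac > 0.5, wgd_fraction = frac)
}

#' Call chromosome-arm gains and losses
#'
#' Each autosomal segment is compared with the (unrounded) sample ploidy:
#' above it the segment is gained, below it lost, equal is neutral. An arm
#' is called gained (lost) when more than 80% of the summed segment length
#' on that arm is altered in that direction. Only counted arms are reported
#' (acrocentric short arms excluded); an arm without covered length is
#' neutral with a warning.
#'
#' @param profile a `SegmentProfile`; segments are split at arm boundaries
#'   internally if needed.
#' @param build a `GenomeBuild`.
#' @param frac_threshold altered-length fraction above which an arm is
#'   called (default 0.8, strict inequality).
#' @return data.frame with one row per counted arm: `chrom`, `arm`, `call`
#'   (gain/loss/neutral), `frac_gain`, `frac_loss`.
#' @export
call_arm_events <- function(profile, build, frac_threshold = 0.8) {
  profile <- split_segments_at_arms(profile, build)
  seg <- autosomal_segments(profile)
  arms <- counted_arms(build)
  out <- arms[, c("chrom", "arm")]
  out$call <- "neutral"
  out$frac_gain <- 0
  out$frac_loss <- 0
  for (i in seq_len(nrow(arms))) {
    s <- seg[seg$chrom == arms$chrom[i] &
               seg$start >= arms$start[i] & seg$end <= arms$end[i], ,
             drop = FALSE]
    if (nrow(s) == 0) {
      warning("no covered length on arm ", arms$chrom[i], arms$arm[i],
              "; called neutral")
      next
    }
    w <- s$end - s$start + 1
    tot <- sum(w)
    fg <- sum(w[s$total_cn > profile$ploidy]) / tot
    fl <- sum(w[s$total_cn < profile$ploidy]) / tot
    out$frac_gain[i] <- fg
    out$frac_loss[i] <- fl
    if (fg > frac_threshold) out$call[i] <- "gain"
    else if (fl > frac_threshold) out$call[i] <- "loss"
  }
  rownames(out) <- NULL
  out
}

#' Aneuploidy score
#'
#' The number of counted autosomal chromosome arms called gained or lost
#' (both arms of every autosome except the acrocentric short arms of
#' chromosomes 13, 14, 15, 21 and 22), for a maximum of 39.
#'
#' @param arm_calls the table returned by [call_arm_events()].
#' @return integer between 0 and 39.
#' @export
aneuploidy_score <- function(arm_calls) {
  sum(arm_calls$call != "neutral")
}

#' Altered genome fraction
#'
#' Fraction of the covered autosomal genome affected by copy-number
#' aberration: amplification (total copy number >= 6), single-copy loss
#' (total 1), homozygous deletion (total 0), or copy-neutral LOH (total 2
#' with minor allele 0).
#'
#' @param profile a `SegmentProfile`.
#' @return fraction in [0, 1].
#' @export
altered_genome_fraction <- function(profile) {
  seg <- autosomal_segments(profile)
  if (nrow(seg) == 0) return(0)
  w <- seg$end - seg$start + 1
  altered <- seg$total_cn >= 6 | seg$total_cn <= 1 |
    (seg$total_cn == 2 & seg$minor_cn == 0)
  sum(w[altered]) / sum(w)
}

#' Per-sample ploidy and aneuploidy report
#'
#' @param profile a `SegmentProfile`.
#' @param build a `GenomeBuild`.
#' @return one-row data.frame: `sample`, `wgd`, `wgd_fraction`,
#'   `aneuploidy_score`, `altered_genome_fraction`.
#' @export
ploidy_report <- function(profile, build) {
  wgd <- call_wgd(profile)
  calls <- suppressWarnings(call_arm_events(profile, build))
  data.frame(sample = profile$sample_id, wgd = wgd$wgd,
             wgd_fraction = wgd$wgd_fraction,
             aneuploidy_score = aneuploidy_score(calls),
             altered_genome_fraction = altered_genome_fraction(profile))
}
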