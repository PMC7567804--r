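# Domain containers and file readers/writers.
#
# Internal coordinates are 1-based inclusive everywhere; BED/BEDPE records
# (0-based half-open on disk) are converted at the boundary.

#' Construct an allele-specific copy-number segment profile
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `total_cn`, `minor_cn` (non-negative integers; minor is the
#'   less frequent allele so `minor_cn <= total_cn - minor_cn`).
#' @param ploidy sample mean ploidy. If `NULL`, the length-weighted mean
#'   total copy number of the segments is used.
#' @param purity tumor purity in (0, 1].
#' @return a `SegmentProfile` object.
#' @export
segment_profile <- function(sample_id, segments, ploidy = NULL, purity = 1) {
  segments <- as.data.frame(segments)
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(segments))) {
    stop("format error: segment table needs columns ",
         paste(need, collapse = ", "))
  }
  segments <- segments[, need]
  segments$chrom <- normalize_chrom(segments$chrom)
  segments <- segments[order(segments$chrom, segments$start), ]
  rownames(segments) <- NULL
  if (nrow(segments) > 0) {
    if (any(segments$end < segments$start)) stop("validation error: end < start")
    if (any(segments$total_cn < 0 | segments$minor_cn < 0)) {
      stop("validation error: negative copy number")
    }
    bad_minor <- segments$minor_cn > segments$total_cn - segments$minor_cn
    if (any(bad_minor)) {
      stop("validation error: minor_cn exceeds major_cn in segment(s) ",
           paste(which(bad_minor), collapse = ", "))
    }
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, ]
      if (nrow(s) > 1) {
        ov <- which(s$start[-1] <= s$end[-nrow(s)])
        if (length(ov) > 0) {
          stop(sprintf(
            "validation error: overlapping segments on chromosome %s: [%d,%d] and [%d,%d]",
            ch, s$start[ov[1]], s$end[ov[1]], s$start[ov[1] + 1], s$end[ov[1] + 1]))
        }
      }
    }
  }
  if (is.null(ploidy)) {
    w <- segments$end - segments$start + 1
    ploidy <- if (nrow(segments) > 0) sum(w * segments$total_cn) / sum(w) else NA_real_
  }
  structure(list(sample_id = sample_id, segments = segments,
                 ploidy = ploidy, purity = purity),
            class = "SegmentProfile")
}

#' @export
print.SegmentProfile <- function(x, ...) {
  cat("SegmentProfile", x$sample_id, "-", nrow(x$segments), "segments, ploidy",
      round(x$ploidy, 3), "purity", x$purity, "\n")
  invisible(x)
}

#' Construct a set of structural rearrangements
#'
#' @param sample_id sample identifier.
#' @param events data.frame with columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`, `sv_type` (one of DEL, DUP, INV, TRA).
#'   Positions are 1-based. TRA events must be inter-chromosomal and all
#'   others intra-chromosomal.
#' @return a `RearrangementSet`; intra-chromosomal events carry a derived
#'   `size = |pos2 - pos1|` column (NA for TRA).
#' @export
rearrangement_set <- function(sample_id, events) {
  events <- as.data.frame(events)
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2", "sv_type")
  if (!all(need %in% names(events))) {
    stop("format error: rearrangement table needs columns ",
         paste(need, collapse = ", "))
  }
  events <- events[, need]
  events$chrom1 <- normalize_chrom(events$chrom1)
  events$chrom2 <- normalize_chrom(events$chrom2)
  if (nrow(events) > 0) {
    if (!all(events$sv_type %in% c("DEL", "DUP", "INV", "TRA"))) {
      stop("format error: unknown sv_type ",
           paste(setdiff(unique(events$sv_type), c("DEL", "DUP", "INV", "TRA")),
                 collapse = ", "))
    }
    if (!all(events$strand1 %in% c("+", "-") & events$strand2 %in% c("+", "-"))) {
      stop("format error: strands must be '+' or '-'")
    }
    inter <- events$chrom1 != events$chrom2
    if (any(inter & events$sv_type != "TRA")) {
      stop("validation error: inter-chromosomal event not typed TRA")
    }
    if (any(!inter & events$sv_type == "TRA")) {
      stop("validation error: TRA event with chrom1 == chrom2")
    }
    if (any(!inter & events$pos1 == events$pos2)) {
      stop("validation error: intra-chromosomal event with size 0")
    }
    events <- events[order(events$chrom1, events$pos1), ]
    rownames(events) <- NULL
  }
  events$size <- ifelse(events$chrom1 == events$chrom2,
                        abs(events$pos2 - events$pos1), NA_real_)
  structure(list(sample_id = sample_id, events = events),
            class = "RearrangementSet")
}

#' @export
print.RearrangementSet <- function(x, ...) {
  cat("RearrangementSet", x$sample_id, "-", nrow(x$events), "events\n")
  invisible(x)
}

#' Construct a set of somatic single-nucleotide variants
#'
#' @param sample_id sample identifier.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; single bases only, `ref != alt`.
#' @return an `SnvSet`, sorted by (chrom, pos).
#' @export
snv_set <- function(sample_id, variants) {
  variants <- as.data.frame(variants)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("format error: SNV table needs columns ", paste(need, collapse = ", "))
  }
  variants <- variants[, need]
  variants$chrom <- normalize_chrom(variants$chrom)
  if (nrow(variants) > 0) {
    bases <- c("A", "C", "G", "T")
    if (!all(variants$ref %in% bases & variants$alt %in% bases)) {
      stop("validation error: ref/alt must be single bases A/C/G/T")
    }
    if (any(variants$ref == variants$alt)) {
      stop("validation error: ref == alt")
    }
    variants <- variants[order(variants$chrom, variants$pos), ]
    rownames(variants) <- NULL
  }
  structure(list(sample_id = sample_id, variants = variants), class = "SnvSet")
}

#' @export
print.SnvSet <- function(x, ...) {
  cat("SnvSet", x$sample_id, "-", nrow(x$variants), "variants\n")
  invisible(x)
}

#' Construct a named interval track (genes, super-enhancers)
#'
#' @param name track name.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `label` and optionally `strand`.
#' @return an `IntervalTrack`.
#' @export
interval_track <- function(name, intervals) {
  intervals <- as.data.frame(intervals)
  need <- c("chrom", "start", "end", "label")
  if (!all(need %in% names(intervals))) {
    stop("format error: interval table needs columns ",
         paste(need, collapse = ", "))
  }
  if (!"strand" %in% names(intervals)) intervals$strand <- "+"
  intervals <- intervals[, c(need, "strand")]
  intervals$chrom <- normalize_chrom(intervals$chrom)
  if (nrow(intervals) > 0 && any(intervals$end < intervals$start)) {
    stop("validation error: interval end < start")
  }
  structure(list(name = name, intervals = intervals), class = "IntervalTrack")
}

# ---- segment TSV ----

#' Read an allele-specific copy-number segment table
#'
#' Expects tab-separated columns `sample`, `chrom`, `start`, `end`,
#' `total_cn`, `minor_cn` preceded by header lines `#ploidy=` and
#' `#purity=`. When a `build` is supplied, segments spanning a centromere
#' are split at the arm boundary so arm-level summaries are well defined.
#'
#' @param path segment TSV path.
#' @param build optional `GenomeBuild` used to split segments at arm
#'   boundaries.
#' @return a `SegmentProfile`.
#' @export
read_segments <- function(path, build = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    as.numeric(sub(paste0("^#", key, "="), "", hit[1]))
  }
  ploidy <- get_meta("ploidy")
  purity <- get_meta("purity")
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          rep("numeric", 4)))
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(tab))) {
    stop("format error: segment table needs columns ",
         paste(need, collapse = ", "))
  }
  sample_id <- if (nrow(tab) > 0) tab$sample[1] else
    sub("\\.[^.]*$", "", basename(path))
  prof <- segment_profile(sample_id, tab[, -1],
                          ploidy = if (is.na(ploidy)) NULL else ploidy,
                          purity = if (is.na(purity)) 1 else purity)
  if (!is.null(build)) prof <- split_segments_at_arms(prof, build)
  prof
}

#' Write a segment profile to TSV
#' @param profile a `SegmentProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#ploidy=%.6g", profile$ploidy),
               sprintf("#purity=%.6g", profile$purity)), con)
  tab <- cbind(sample = profile$sample_id, profile$segments)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split segments at chromosome-arm boundaries
#'
#' Segments overlapping the centromere are cut into their p- and q-arm
#' parts; parts lying wholly inside the centromere are dropped.
#'
#' @param profile a `SegmentProfile`.
#' @param build a `GenomeBuild`.
#' @return a `SegmentProfile` whose segments each lie within one arm.
#' @export
split_segments_at_arms <- function(profile, build) {
  seg <- profile$segments
  if (nrow(seg) == 0) return(profile)
  out <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    arms <- build$arms[build$arms$chrom == s$chrom, ]
    if (nrow(arms) == 0) { out[[i]] <- s; next }
    pieces <- lapply(seq_len(nrow(arms)), function(j) {
      lo <- max(s$start, arms$start[j]); hi <- min(s$end, arms$end[j])
      if (lo > hi) return(NULL)
      p <- s; p$start <- lo; p$end <- hi; p
    })
    pieces <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    out[[i]] <- pieces
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  segment_profile(profile$sample_id, out, ploidy = profile$ploidy,
                  purity = profile$purity)
}

# ---- BEDPE ----

#' Read rearrangements from a BEDPE file
#'
#' Standard 10-column BEDPE (0-based half-open on disk) with an eleventh
#' `sv_type` column in {DEL, DUP, INV, TRA}. Breakpoint positions are
#' converted to 1-based (start + 1).
#'
#' @param path BEDPE path.
#' @param sample_id sample identifier; defaults to the file stem.
#' @return a `RearrangementSet`.
#' @export
read_bedpe <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(rearrangement_set(sample_id, data.frame(
      chrom1 = character(), pos1 = numeric(), strand1 = character(),
      chrom2 = character(), pos2 = numeric(), strand2 = character(),
      sv_type = character())))
  }
  tab <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 11) stop("format error: BEDPE needs 11 columns (10 + sv_type)")
  rearrangement_set(sample_id, data.frame(
    chrom1 = tab[[1]], pos1 = tab[[2]] + 1, strand1 = tab[[9]],
    chrom2 = tab[[4]], pos2 = tab[[5]] + 1, strand2 = tab[[10]],
    sv_type = tab[[11]], stringsAsFactors = FALSE))
}

#' Write rearrangements to BEDPE
#' @param rset a `RearrangementSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(rset, path) {
  ev <- rset$events
  tab <- data.frame(
    chrom1 = ev$chrom1, start1 = ev$pos1 - 1, end1 = ev$pos1,
    chrom2 = ev$chrom2, start2 = ev$pos2 - 1, end2 = ev$pos2,
    name = sprintf("%s_sv%d", rset$sample_id, seq_len(nrow(ev))),
    score = rep(".", nrow(ev)),
    strand1 = ev$strand1, strand2 = ev$strand2, sv_type = ev$sv_type)
  if (nrow(ev) == 0) { file.create(path); return(invisible(path)) }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- VCF ----

#' Read somatic SNVs from a VCF
#'
#' Uses the vcfR parser; only single-base ref/alt records are retained
#' (indels and multi-nucleotide records are dropped).
#'
#' @param path VCF path (v4.x, plain text or gzipped).
#' @param sample_id sample identifier; defaults to the file stem.
#' @return an `SnvSet`.
#' @export
read_snv_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(snv_set(sample_id, data.frame(chrom = character(), pos = numeric(),
                                         ref = character(), alt = character())))
  }
  keep <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "REF"] %in% c("A", "C", "G", "T") & fix[, "ALT"] %in% c("A", "C", "G", "T")
  snv_set(sample_id, data.frame(
    chrom = fix[keep, "CHROM"], pos = as.numeric(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"], stringsAsFactors = FALSE))
}

#' Write somatic SNVs to a VCF 4.2 file
#' @param snvs an `SnvSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=genomplexity",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  v <- snvs$variants
  if (nrow(v) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       v$chrom, as.integer(v$pos), v$ref, v$alt), con)
  }
  invisible(path)
}

# ---- BED tracks ----

#' Read a BED4 interval track
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive in memory. An optional 6th column supplies strand.
#'
#' @param path BED path.
#' @param name track name; defaults to the file stem.
#' @return an `IntervalTrack`.
#' @export
read_bed_track <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(interval_track(name, data.frame(chrom = character(),
                                           start = numeric(), end = numeric(),
                                           label = character())))
  }
  tab <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("format error: BED4 needs at least 4 columns")
  iv <- data.frame(chrom = tab[[1]], start = tab[[2]] + 1, end = tab[[3]],
                   label = tab[[4]], stringsAsFactors = FALSE)
  if (ncol(tab) >= 6) iv$strand <- tab[[6]]
  interval_track(name, iv)
}

#' Write an interval track to BED
#' @param track an `IntervalTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  iv <- track$intervals
  if (nrow(iv) == 0) { file.create(path); return(invisible(path)) }
  tab <- data.frame(chrom = iv$chrom, start = iv$start - 1, end = iv$end,
                    label = iv$label, score = 0, strand = iv$strand)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- sample triplet ----

#' Read one sample's segment, rearrangement and SNV files
#'
#' @param segments_path segment TSV (see [read_segments()]).
#' @param bedpe_path rearrangement BEDPE (see [read_bedpe()]).
#' @param vcf_path SNV VCF (see [read_snv_vcf()]).
#' @param build optional `GenomeBuild` for arm-boundary splitting.
#' @return list with elements `profile`, `rearrangements`, `snvs`.
#' @export
read_sample <- function(segments_path, bedpe_path, vcf_path, build = NULL) {
  profile <- read_segments(segments_path, build = build)
  list(profile = profile,
       rearrangements = read_bedpe(bedpe_path, sample_id = profile$sample_id),
       snvs = read_snv_vcf(vcf_path, sample_id = profile$sample_id))
}

# ---- feature matrices ----

#' Construct a feature matrix
#'
#' @param scheme one of `"SBS96"`, `"SV32"`, `"CN40"`.
#' @param counts numeric matrix, categories x samples, non-negative, with
#'   rownames equal to the scheme's canonical category labels and column
#'   names the sample ids.
#' @return a `FeatureMatrix`.
#' @export
feature_matrix <- function(scheme, counts) {
  scheme <- match.arg(scheme, c("SBS96", "SV32", "CN40"))
  labels <- feature_labels(scheme)
  counts <- as.matrix(counts)
  if (nrow(counts) != length(labels)) {
    stop("validation error: expected ", length(labels), " categories for ",
         scheme, ", got ", nrow(counts))
  }
  if (is.null(rownames(counts))) rownames(counts) <- labels
  if (!identical(rownames(counts), labels)) {
    if (!setequal(rownames(counts), labels)) {
      stop("validation error: category labels do not match scheme ", scheme)
    }
    counts <- counts[labels, , drop = FALSE]
  }
  if (any(!is.finite(counts))) stop("validation error: non-finite entries")
  if (any(counts < 0)) stop("validation error: negative entries")
  structure(list(scheme = scheme, counts = counts), class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat("FeatureMatrix", x$scheme, "-", nrow(x$counts), "categories x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Canonical category labels for a feature scheme
#'
#' @param scheme one of `"SBS96"`, `"SV32"`, `"CN40"`.
#' @return character vector of category labels in canonical order
#'   (96, 32 and 40 labels respectively).
#' @export
feature_labels <- function(scheme) {
  scheme <- match.arg(scheme, c("SBS96", "SV32", "CN40"))
  switch(scheme, SBS96 = sbs96_labels(), SV32 = sv32_labels(),
         CN40 = cn40_labels())
}

#' Write a feature matrix to TSV
#'
#' Categories as rows in canonical order, one column per sample; the first
#' column (`category`) holds the labels. Round-trips losslessly with
#' [read_feature_matrix()].
#'
#' @param matrix a `FeatureMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  if (any(!is.finite(matrix$counts))) stop("validation error: non-finite entries")
  if (any(matrix$counts < 0)) stop("validation error: negative entries")
  tab <- data.frame(category = rownames(matrix$counts), matrix$counts,
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#scheme=", matrix$scheme), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path.
#' @return a `FeatureMatrix`.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  scheme_line <- grep("^#scheme=", lines, value = TRUE)
  if (length(scheme_line) == 0) stop("format error: missing #scheme= header")
  scheme <- sub("^#scheme=", "", scheme_line[1])
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  feature_matrix(scheme, counts)
}
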