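# Category schemes feeding signature inference: the SBS96 pyrimidine-centred
# trinucleotide scheme, the 32-category rearrangement scheme (clustered /
# non-clustered x type x size) and the 40-category copy-number scheme
# (zygosity x total-CN class x size).

SV_TYPES <- c("del", "dup", "inv", "trans")
SV_SIZE_BINS <- c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")
SV_SIZE_BREAKS <- c(0, 1e4, 1e5, 1e6, 1e7, Inf)
CN_SIZE_BINS <- c("0-0.01Mb", "0.01-0.1Mb", "0.1-1Mb", "1-10Mb", ">10Mb")
CN_SIZE_BREAKS <- c(0, 0.01, 0.1, 1, 10, Inf)

sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  flanks <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(flanks, flanks, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))
  }))
}

sv32_labels <- function() {
  unlist(lapply(c("clustered", "non-clustered"), function(cl) {
    c(as.vector(t(outer(c("del", "dup", "inv"), SV_SIZE_BINS,
                        function(ty, sz) paste(cl, ty, sz, sep = ":")))),
      paste(cl, "trans", sep = ":"))
  }))
}

cn40_labels <- function() {
  rows <- list(c("het", "neutral"), c("het", "duplicated"), c("het", "amplified"),
               c("LOH", "deleted"), c("LOH", "neutral"), c("LOH", "duplicated"),
               c("LOH", "amplified"), c("homdel", "deleted"))
  unlist(lapply(rows, function(r)
    paste(r[1], r[2], CN_SIZE_BINS, sep = ":")))
}

size_bin <- function(size, breaks, labels) {
  labels[findInterval(size, breaks, left.open = FALSE, rightmost.closed = FALSE)]
}

# ---- SBS96 ----

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(COMPLEMENT[ch])), collapse = ""), character(1))
}

#' Build the SBS96 mutation catalog for one sample
#'
#' Counts single-base substitutions in the standard 96-category scheme:
#' the six pyrimidine-centred substitution classes (C>A, C>G, C>T, T>A,
#' T>C, T>G) split by the 5' and 3' flanking bases. Variants whose
#' reference base is a purine are reverse-complemented onto the pyrimidine
#' strand. Variants whose trinucleotide context is undefined (chromosome
#' edge, or containing N) are tallied separately and excluded from the 96
#' classes.
#'
#' @param snvs an `SnvSet`.
#' @param reference reference sequence: a `Biostrings::DNAStringSet`, a
#'   named character vector of chromosome sequences, or a FASTA path.
#' @return named numeric vector of length 96 (canonical label order) with
#'   attribute `excluded` giving the number of context-less variants.
#' @export
build_sbs96 <- function(snvs, reference) {
  seqs <- as_reference(reference)
  labels <- sbs96_labels()
  counts <- stats::setNames(numeric(96), labels)
  v <- snvs$variants
  excluded <- 0L
  if (nrow(v) > 0) {
    for (ch in unique(v$chrom)) {
      if (!ch %in% names(seqs)) {
        excluded <- excluded + sum(v$chrom == ch)
        next
      }
      vv <- v[v$chrom == ch, ]
      len <- nchar(seqs[[ch]])
      edge <- vv$pos < 2 | vv$pos > len - 1
      excluded <- excluded + sum(edge)
      vv <- vv[!edge, , drop = FALSE]
      if (nrow(vv) == 0) next
      ctx <- substring(seqs[[ch]], vv$pos - 1, vv$pos + 1)
      ok <- !grepl("[^ACGT]", ctx)
      # the emitted ref allele must agree with the reference sequence
      ok <- ok & substr(ctx, 2, 2) == vv$ref
      excluded <- excluded + sum(!ok)
      vv <- vv[ok, , drop = FALSE]
      ctx <- ctx[ok]
      if (nrow(vv) == 0) next
      purine <- vv$ref %in% c("A", "G")
      ctx[purine] <- revcomp(ctx[purine])
      alt <- vv$alt
      alt[purine] <- unname(COMPLEMENT[alt[purine]])
      lab <- paste0(substr(ctx, 1, 1), "[", substr(ctx, 2, 2), ">", alt, "]",
                    substr(ctx, 3, 3))
      tb <- table(lab)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
  }
  attr(counts, "excluded") <- excluded
  counts
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    out <- as.list(as.character(reference))
  } else if (is.character(reference) && length(reference) == 1 &&
             file.exists(reference)) {
    out <- as.list(as.character(Biostrings::readDNAStringSet(reference)))
  } else if (is.character(reference) && !is.null(names(reference))) {
    out <- as.list(reference)
  } else {
    stop("reference must be a DNAStringSet, named character vector or FASTA path")
  }
  names(out) <- normalize_chrom(sub("\\s.*$", "", names(out)))
  out
}

# ---- breakpoint clustering ----

#' Flag clustered rearrangements
#'
#' All breakpoint ends of a sample are clustered per chromosome by single
#' linkage: consecutive sorted ends closer than `distance_d` fall in the
#' same cluster. An event is clustered when either of its two ends lies in
#' a cluster of at least `min_cluster_size` ends. With `distance_d = 0`
#' every end is its own cluster.
#'
#' @param rearrangements a `RearrangementSet`.
#' @param distance_d single-linkage merge distance in bp (default 1e6).
#' @param min_cluster_size minimum ends per cluster (default 10).
#' @return logical vector, one flag per event (in the order of
#'   `rearrangements$events`).
#' @export
cluster_breakpoints <- function(rearrangements, distance_d = 1e6,
                                min_cluster_size = 10) {
  if (distance_d < 0) stop("config error: distance_d < 0")
  ev <- rearrangements$events
  n <- nrow(ev)
  if (n == 0) return(logical(0))
  ends <- data.frame(
    chrom = c(ev$chrom1, ev$chrom2),
    pos = c(ev$pos1, ev$pos2),
    event = rep(seq_len(n), 2))
  flagged <- logical(n)
  for (ch in unique(ends$chrom)) {
    e <- ends[ends$chrom == ch, ]
    o <- order(e$pos)
    e <- e[o, ]
    gaps <- diff(e$pos)
    cl <- cumsum(c(1, as.integer(!(gaps < distance_d))))
    sizes <- table(cl)
    big <- as.integer(names(sizes)[sizes >= min_cluster_size])
    flagged[unique(e$event[cl %in% big])] <- TRUE
  }
  flagged
}

# ---- SV32 ----

#' Classify rearrangements into the 32-category scheme
#'
#' Events are split by clustered status, type (deletion, duplication,
#' inversion, translocation) and, for intra-chromosomal events, size bin
#' (1-10 kb, 10-100 kb, 100 kb-1 Mb, 1-10 Mb, >10 Mb; half-open on the
#' upper boundary, events under 10 kb fall in the first bin).
#' Translocations carry no size bin, giving 2 x (3 x 5 + 1) = 32
#' categories.
#'
#' @param rearrangements a `RearrangementSet`.
#' @param clustered logical per-event flags from [cluster_breakpoints()];
#'   computed with defaults when omitted.
#' @return named numeric vector of length 32 (canonical label order)
#'   summing to the number of events.
#' @export
classify_sv32 <- function(rearrangements, clustered = NULL) {
  ev <- rearrangements$events
  if (is.null(clustered)) clustered <- cluster_breakpoints(rearrangements)
  stopifnot(length(clustered) == nrow(ev))
  counts <- stats::setNames(numeric(32), sv32_labels())
  if (nrow(ev) == 0) return(counts)
  cl <- ifelse(clustered, "clustered", "non-clustered")
  type <- c(DEL = "del", DUP = "dup", INV = "inv", TRA = "trans")[ev$sv_type]
  lab <- ifelse(type == "trans", paste(cl, type, sep = ":"),
                paste(cl, type, size_bin(ev$size, SV_SIZE_BREAKS, SV_SIZE_BINS),
                      sep = ":"))
  tb <- table(lab)
  counts[names(tb)] <- as.numeric(tb)
  counts
}

# ---- CN40 ----

#' Classify copy-number segments into the 40-category scheme
#'
#' Segments are classified by zygosity (heterozygous, LOH when the minor
#' allele is lost, homozygous deletion when total copy number is 0), total
#' copy number class (0-1 deleted, 2 neutral, 3-4 duplicated, >4
#' amplified) and segment size (0-0.01, 0.01-0.1, 0.1-1, 1-10, >10 Mb,
#' half-open upper boundaries). Impossible combinations (heterozygous
#' deleted; homozygous deletion at total > 0) are excluded, leaving 40
#' categories.
#'
#' @param profile a `SegmentProfile`.
#' @return named numeric vector of length 40 (canonical label order)
#'   summing to the number of segments.
#' @export
classify_cn40 <- function(profile) {
  seg <- profile$segments
  counts <- stats::setNames(numeric(40), cn40_labels())
  if (nrow(seg) == 0) return(counts)
  zyg <- ifelse(seg$total_cn == 0, "homdel",
                ifelse(seg$minor_cn == 0, "LOH", "het"))
  cls <- ifelse(seg$total_cn <= 1, "deleted",
                ifelse(seg$total_cn == 2, "neutral",
                       ifelse(seg$total_cn <= 4, "duplicated", "amplified")))
  size_mb <- (seg$end - seg$start + 1) / 1e6
  lab <- paste(zyg, cls, size_bin(size_mb, CN_SIZE_BREAKS, CN_SIZE_BINS),
               sep = ":")
  tb <- table(lab)
  counts[names(tb)] <- as.numeric(tb)
  counts
}

#' Build a cohort feature matrix
#'
#' @param scheme `"SBS96"`, `"SV32"` or `"CN40"`.
#' @param samples a named list: for SBS96, `SnvSet`s; for SV32,
#'   `RearrangementSet`s; for CN40, `SegmentProfile`s.
#' @param reference reference sequence (SBS96 only); see [build_sbs96()].
#' @param ... further arguments to the per-sample classifier.
#' @return a `FeatureMatrix` with one column per sample.
#' @export
build_feature_matrix <- function(scheme, samples, reference = NULL, ...) {
  scheme <- match.arg(scheme, c("SBS96", "SV32", "CN40"))
  cols <- lapply(samples, function(s) {
    switch(scheme,
           SBS96 = build_sbs96(s, reference),
           SV32 = classify_sv32(s, ...),
           CN40 = classify_cn40(s))
  })
  counts <- do.call(cbind, lapply(cols, as.numeric))
  rownames(counts) <- feature_labels(scheme)
  colnames(counts) <- vapply(samples, function(s) s$sample_id, character(1))
  feature_matrix(scheme, counts)
}
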