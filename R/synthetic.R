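# Synthetic tumor-cohort generator with truth labels. Emits allele-specific
# copy-number segment profiles, rearrangement sets, SNV sets and a shared
# reference sequence, with planted whole-genome doubling, arm gains/losses,
# focal amplification/deletion, chromothripsis and BFB chromosomes, kataegis
# loci and SBS96 signature mixtures.

#' Simulation configuration
#'
#' Defaults reproduce the cohort conditions the analysis assumes: 71% of
#' tumors whole-genome doubled, substantial arm-level aneuploidy, a
#' background rearrangement rate of about 0.18 breakpoint ends per Mb
#' (roughly 280 events on a full genome), a tumor mutational burden of
#' about 2.1 SNVs per Mb drawn from an SBS96 signature mixture, two
#' kataegis loci per sample, and one chromothripsis plus one BFB
#' chromosome per sample.
#'
#' @param seed master seed; each sample derives its own stream from
#'   (seed, sample index).
#' @param n_samples number of tumors to simulate.
#' @param build a `GenomeBuild` or build name (default `"mini"`, the
#'   GRCh37 arm table scaled 1:10).
#' @param wgd_probability probability a sample is whole-genome doubled.
#' @param arm_event_rate expected number of gained/lost counted arms per
#'   sample (Poisson).
#' @param focal_amp_rate,focal_del_rate expected focal amplifications
#'   (total CN >= 6) and homozygous deletions (total CN 0) per genome.
#' @param background_sv_rate background breakpoint ends per Mb.
#' @param n_chromothripsis,n_bfb complex chromosomes planted per sample.
#' @param chromothripsis_breakpoints breakpoints on a chromothripsis
#'   chromosome (>= 40).
#' @param chromothripsis_window shatter window in bp (capped at 40% of the
#'   chromosome).
#' @param kataegis_loci planted kataegis loci per sample.
#' @param kataegis_cluster_size mutations per kataegis locus (>= 6).
#' @param kataegis_spacing_mean mean of the exponential inter-mutation
#'   spacing inside a locus, bp.
#' @param snv_count SNVs per sample; `NULL` means 2.1 per Mb of the build.
#' @param sbs_signature_matrix 96 x K signature matrix (columns sum to 1);
#'   `NULL` means three synthetic signatures from
#'   [synthetic_sbs_signatures()].
#' @param true_exposures length-K exposure vector (shared by all samples)
#'   or K x n_samples matrix; must be non-negative summing to 1.
#' @param sv_category_exposures 32-vector of background SV category
#'   probabilities (canonical SV32 order); default places all mass on the
#'   non-clustered categories, clustered events arising from the planted
#'   complex chromosomes.
#' @param purity emitted sample purity.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1, n_samples = 10, build = "mini",
                       wgd_probability = 0.71, arm_event_rate = 8,
                       focal_amp_rate = 3, focal_del_rate = 2,
                       background_sv_rate = 0.18,
                       n_chromothripsis = 1, n_bfb = 1,
                       chromothripsis_breakpoints = 44,
                       chromothripsis_window = 3e7,
                       kataegis_loci = 2, kataegis_cluster_size = 8,
                       kataegis_spacing_mean = 300,
                       snv_count = NULL, sbs_signature_matrix = NULL,
                       true_exposures = NULL,
                       sv_category_exposures = NULL, purity = 0.7) {
  if (is.character(build)) build <- load_genome_build(build)
  if (wgd_probability < 0 || wgd_probability > 1) {
    stop("config error: wgd_probability outside [0, 1]")
  }
  if (is.null(sbs_signature_matrix)) {
    sbs_signature_matrix <- synthetic_sbs_signatures(3, seed = seed)
  }
  k <- ncol(sbs_signature_matrix)
  if (is.null(true_exposures)) {
    true_exposures <- c(0.5, 0.3, 0.2)[seq_len(min(3, k))]
    if (k > 3) true_exposures <- rep(1 / k, k)
  }
  expo <- if (is.matrix(true_exposures)) true_exposures else
    matrix(true_exposures, nrow = length(true_exposures),
           ncol = max(n_samples, 1))
  if (nrow(expo) != k) stop("config error: exposure length != signature count")
  if (any(expo < 0) || any(abs(colSums(expo) - 1) > 1e-8)) {
    stop("config error: exposure vectors must be non-negative and sum to 1")
  }
  if (is.null(sv_category_exposures)) {
    labels <- sv32_labels()
    sv_category_exposures <- stats::setNames(numeric(32), labels)
    nc <- grepl("^non-clustered", labels)
    # realistic background mix: deletions and duplications dominate,
    # translocations common, sizes spread over all bins
    w <- ifelse(grepl("del", labels[nc]), 0.30 / 5,
                ifelse(grepl("dup", labels[nc]), 0.25 / 5,
                       ifelse(grepl("inv", labels[nc]), 0.20 / 5, 0.25)))
    sv_category_exposures[nc] <- w / sum(w)
  }
  if (length(sv_category_exposures) != 32 ||
      abs(sum(sv_category_exposures) - 1) > 1e-8) {
    stop("config error: sv_category_exposures must be a 32-vector summing to 1")
  }
  if (is.null(snv_count)) {
    snv_count <- round(2.1 * sum(build$chroms$length) / 1e6)
  }
  structure(list(
    seed = seed, n_samples = n_samples, build = build,
    wgd_probability = wgd_probability, arm_event_rate = arm_event_rate,
    focal_amp_rate = focal_amp_rate, focal_del_rate = focal_del_rate,
    background_sv_rate = background_sv_rate,
    n_chromothripsis = n_chromothripsis, n_bfb = n_bfb,
    chromothripsis_breakpoints = chromothripsis_breakpoints,
    chromothripsis_window = chromothripsis_window,
    kataegis_loci = kataegis_loci,
    kataegis_cluster_size = kataegis_cluster_size,
    kataegis_spacing_mean = kataegis_spacing_mean,
    snv_count = snv_count, sbs_signature_matrix = sbs_signature_matrix,
    true_exposures = expo, sv_category_exposures = sv_category_exposures,
    purity = purity), class = "SimulationConfig")
}

#' Generate synthetic SBS96 reference signatures
#'
#' Random sparse probability vectors over the 96 categories, regenerated
#' until all pairwise cosine similarities are at most `max_cosine`, so
#' planted mixtures are identifiable. These are synthetic stand-ins for
#' external reference signatures, suitable for simulation and testing.
#'
#' @param k number of signatures.
#' @param seed integer seed.
#' @param n_active number of categories carrying most of each signature's
#'   mass.
#' @param max_cosine maximum pairwise cosine similarity (default 0.3).
#' @return 96 x k matrix, columns named `SYN1..SYNk`, each summing to 1.
#' @export
synthetic_sbs_signatures <- function(k, seed = 1, n_active = 12,
                                     max_cosine = 0.3) {
  set.seed(seed)
  labels <- sbs96_labels()
  for (attempt in 1:50) {
    W <- matrix(0, 96, k, dimnames = list(labels, paste0("SYN", seq_len(k))))
    for (j in seq_len(k)) {
      active <- sample.int(96, n_active)
      w <- rep(1e-4, 96)
      w[active] <- stats::rexp(n_active) + 0.2
      W[, j] <- w / sum(w)
    }
    sims <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b)
      cosine_similarity(W[, a], W[, b])))
    if (all(sims[upper.tri(sims)] <= max_cosine)) return(W)
  }
  stop("could not generate sufficiently distinct signatures")
}

#' Sample a feature matrix from planted signatures
#'
#' Per-sample category counts are drawn from the mixture
#' `W %*% exposures`, either multinomially at a fixed total or as
#' independent Poisson counts with that expectation.
#'
#' @param W categories x K signature matrix (columns sum to 1).
#' @param exposures K x n matrix of per-sample exposures (columns sum
#'   to 1).
#' @param total_counts mutations per sample (recycled to n).
#' @param scheme feature scheme of the result.
#' @param noise `"multinomial"` or `"poisson"`.
#' @param seed integer seed.
#' @return a `FeatureMatrix`.
#' @export
simulate_feature_matrix <- function(W, exposures, total_counts,
                                    scheme = "SBS96", noise = "multinomial",
                                    seed = 1) {
  noise <- match.arg(noise, c("multinomial", "poisson"))
  set.seed(seed)
  W <- as.matrix(W); exposures <- as.matrix(exposures)
  n <- ncol(exposures)
  total_counts <- rep_len(total_counts, n)
  counts <- vapply(seq_len(n), function(j) {
    p <- as.numeric(W %*% exposures[, j])
    p <- p / sum(p)
    if (noise == "multinomial") {
      as.numeric(stats::rmultinom(1, total_counts[j], p))
    } else {
      as.numeric(stats::rpois(nrow(W), total_counts[j] * p))
    }
  }, numeric(nrow(W)))
  rownames(counts) <- rownames(W) %||% feature_labels(scheme)
  colnames(counts) <- paste0("sim", seq_len(n))
  feature_matrix(scheme, counts)
}

#' Generate a random reference sequence for a build
#'
#' Uniform random A/C/G/T sequence per chromosome, deterministic given the
#' seed. One reference is shared by a simulated cohort.
#'
#' @param build a `GenomeBuild`.
#' @param seed integer seed.
#' @param chroms chromosomes to include (default: autosomes of the build).
#' @return named character vector of chromosome sequences.
#' @export
simulate_reference <- function(build, seed = 1, chroms = NULL) {
  set.seed(seed)
  if (is.null(chroms)) {
    chroms <- intersect(build$chroms$chrom, AUTOSOMES)
  }
  bases <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
  out <- stats::setNames(vector("character", length(chroms)), chroms)
  for (ch in chroms) {
    len <- chrom_length(build, ch)
    out[[ch]] <- rawToChar(bases[sample.int(4, len, replace = TRUE)])
  }
  out
}

#' Write a reference to FASTA
#' @param reference named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(reference)), path)
  invisible(path)
}

# carve an interval with new CN into an existing non-overlapping segment set
carve_segment <- function(segs, start, end, total, minor) {
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$end < start || s$start > end) { out[[length(out) + 1]] <- s; next }
    if (s$start < start) {
      left <- s; left$end <- start - 1
      out[[length(out) + 1]] <- left
    }
    if (s$end > end) {
      right <- s; right$start <- end + 1
      out[[length(out) + 1]] <- right
    }
  }
  out[[length(out) + 1]] <- data.frame(chrom = segs$chrom[1], start = start,
                                       end = end, total_cn = total,
                                       minor_cn = minor)
  res <- do.call(rbind, out)
  res[order(res$start), ]
}

#' Simulate one tumor sample
#'
#' Deterministic given `(config$seed, sample_index)`. SNV positions are
#' chosen so the trinucleotide context in the shared reference matches the
#' sampled SBS96 category; kataegis mutations are placed at TpC sites with
#' C>T/C>G alternates. Chromothripsis chromosomes carry at least 40
#' clustered breakpoints with total copy number oscillating between two
#' states (minor allele retained on the higher state); BFB chromosomes
#' carry a telomere-adjacent loss plus fold-back inversions.
#'
#' @param config a `SimulationConfig`.
#' @param sample_index 1-based sample index.
#' @param reference shared cohort reference from [simulate_reference()];
#'   generated on the fly (from `config$seed`) when omitted, which is slow
#'   for large builds - prefer passing it in.
#' @return list with `profile` (`SegmentProfile`), `rearrangements`
#'   (`RearrangementSet`), `snvs` (`SnvSet`) and `truth` (list: `wgd`,
#'   `wgd_fraction`, `arm_calls`, `complex_chroms`, `kataegis_loci`,
#'   `exposures`).
#' @export
simulate_sample <- function(config, sample_index, reference = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  build <- config$build
  if (is.null(reference)) reference <- simulate_reference(build, config$seed)
  set.seed((config$seed * 2654435L + sample_index * 97L) %% 2147483647L)
  sample_id <- sprintf("SIM%03d", sample_index)
  chroms <- intersect(build$chroms$chrom, AUTOSOMES)

  wgd <- stats::runif(1) < config$wgd_probability
  base_total <- if (wgd) 4L else 2L
  base_minor <- if (wgd) 2L else 1L
  ploidy <- base_total

  # --- complex chromosomes (chosen first; kept free of arm events) ---
  n_complex <- min(config$n_chromothripsis + config$n_bfb, length(chroms))
  complex_chroms <- if (n_complex > 0)
    sample(chroms, n_complex) else character(0)
  ct_chroms <- utils::head(complex_chroms, config$n_chromothripsis)
  bfb_chroms <- utils::tail(complex_chroms, config$n_bfb)

  # --- arm-level gains and losses ---
  arms <- counted_arms(build)
  arms <- arms[!arms$chrom %in% complex_chroms, ]
  arm_calls <- stats::setNames(
    rep("neutral", nrow(counted_arms(build))),
    paste0(counted_arms(build)$chrom, counted_arms(build)$arm))
  n_arm <- min(stats::rpois(1, config$arm_event_rate), nrow(arms))
  hit <- if (n_arm > 0) arms[sample.int(nrow(arms), n_arm), ] else arms[0, ]
  hit$dir <- if (n_arm > 0) sample(c("gain", "loss"), n_arm, TRUE) else character(0)

  # --- per-chromosome segment construction ---
  seg_list <- list()
  sv_rows <- list()
  for (ch in chroms) {
    ch_arms <- build$arms[build$arms$chrom == ch, ]
    segs <- do.call(rbind, lapply(seq_len(nrow(ch_arms)), function(j) {
      key <- paste0(ch, ch_arms$arm[j])
      tot <- base_total; mino <- base_minor
      h <- hit[paste0(hit$chrom, hit$arm) == key, ]
      if (nrow(h) == 1) {
        if (h$dir == "gain") {
          tot <- base_total + 1L
        } else {
          tot <- base_total - 1L
          mino <- min(base_minor, max(0L, tot - base_minor))
        }
        arm_calls[key] <<- h$dir
      }
      mino <- min(mino, tot %/% 2L)
      data.frame(chrom = ch, start = ch_arms$start[j], end = ch_arms$end[j],
                 total_cn = tot, minor_cn = mino)
    }))

    if (ch %in% ct_chroms) {
      res <- plant_chromothripsis(segs, build, ch, base_total, base_minor,
                                  config)
      segs <- res$segs
      sv_rows[[length(sv_rows) + 1]] <- res$sv
    }
    if (ch %in% bfb_chroms) {
      res <- plant_bfb(segs, build, ch, base_total, base_minor)
      segs <- res$segs
      sv_rows[[length(sv_rows) + 1]] <- res$sv
    }
    seg_list[[ch]] <- segs
  }

  # --- focal amplifications and homozygous deletions ---
  # placed only on truth-neutral arms of non-complex chromosomes so the
  # planted arm-call labels stay consistent with the emitted copy number
  n_amp <- stats::rpois(1, config$focal_amp_rate)
  n_del <- stats::rpois(1, config$focal_del_rate)
  focal_arms <- counted_arms(build)
  focal_arms <- focal_arms[!focal_arms$chrom %in% complex_chroms &
                             !paste0(focal_arms$chrom, focal_arms$arm) %in%
                               paste0(hit$chrom, hit$arm), ]
  if (n_amp + n_del > 0 && nrow(focal_arms) > 0) {
    pick <- focal_arms[sample.int(nrow(focal_arms), n_amp + n_del,
                                  replace = TRUE), ]
    pick$kind <- rep(c("amp", "del"), c(n_amp, n_del))
    for (i in seq_len(nrow(pick))) {
      size <- round(10^stats::runif(1, if (pick$kind[i] == "amp") 5 else 4, 6.5))
      lo <- pick$start[i]
      hi <- max(lo, pick$end[i] - size)
      start <- round(stats::runif(1, lo, hi))
      end <- min(start + size - 1, pick$end[i])
      ch <- pick$chrom[i]
      if (pick$kind[i] == "amp") {
        tot <- 6L + stats::rpois(1, 2)
        seg_list[[ch]] <- carve_segment(seg_list[[ch]], start, end, tot, 1L)
      } else {
        seg_list[[ch]] <- carve_segment(seg_list[[ch]], start, end, 0L, 0L)
      }
    }
  }

  segments <- do.call(rbind, seg_list)
  profile <- segment_profile(sample_id, segments, ploidy = ploidy,
                             purity = config$purity)

  # --- background rearrangements ---
  genome_mb <- sum(chrom_length(build, chroms)) / 1e6
  n_bg <- stats::rpois(1, config$background_sv_rate * genome_mb / 2)
  if (n_bg > 0) {
    cats <- sample(sv32_labels(), n_bg, TRUE, prob = config$sv_category_exposures)
    sv_rows[[length(sv_rows) + 1]] <- background_sv_events(cats, build, chroms)
  }
  sv <- do.call(rbind, sv_rows)
  if (is.null(sv)) {
    sv <- data.frame(chrom1 = character(), pos1 = numeric(),
                     strand1 = character(), chrom2 = character(),
                     pos2 = numeric(), strand2 = character(),
                     sv_type = character())
  }
  rearrangements <- rearrangement_set(sample_id, sv)

  # --- SNVs: background mixture plus kataegis loci ---
  expo_col <- ((sample_index - 1) %% ncol(config$true_exposures)) + 1
  exposures <- config$true_exposures[, expo_col]
  mixture <- as.numeric(config$sbs_signature_matrix %*% exposures)
  mixture <- mixture / sum(mixture)
  snv <- place_mixture_snvs(config$snv_count, mixture, reference)
  kat <- plant_kataegis(config, reference)
  all_snv <- rbind(snv, kat$variants)
  all_snv <- all_snv[!duplicated(paste(all_snv$chrom, all_snv$pos)), ]
  snvs <- snv_set(sample_id, all_snv)

  truth <- list(
    wgd = wgd,
    wgd_fraction = call_wgd(profile)$wgd_fraction,
    arm_calls = arm_calls,
    complex_chroms = c(stats::setNames(rep("chromothripsis", length(ct_chroms)),
                                       ct_chroms),
                       stats::setNames(rep("BFB", length(bfb_chroms)),
                                       bfb_chroms)),
    kataegis_loci = kat$loci,
    exposures = exposures)
  list(profile = profile, rearrangements = rearrangements, snvs = snvs,
       truth = truth)
}

# chromothripsis: shatter a window into alternating retained / lost states
plant_chromothripsis <- function(segs, build, ch, base_total, base_minor,
                                 config) {
  ch_arms <- build$arms[build$arms$chrom == ch & build$arms$arm == "q", ]
  arm_len <- ch_arms$end - ch_arms$start + 1
  win <- min(config$chromothripsis_window, floor(0.8 * arm_len))
  w_start <- ch_arms$start + floor(0.1 * arm_len)
  w_end <- w_start + win - 1
  n_bp <- max(40, config$chromothripsis_breakpoints)
  if (n_bp %% 2 == 1) n_bp <- n_bp + 1
  bp <- sort(round(stats::runif(n_bp, w_start, w_end)))
  bp <- unique(bp)
  hi_total <- base_total
  hi_minor <- max(1L, base_minor)
  lo_total <- max(0L, base_total - 1L)
  lo_minor <- min(max(0L, base_minor - 1L), lo_total %/% 2L)
  sv <- list()
  # alternate: odd intervals drop to the low state; their boundary pairs
  # become clustered deletion-type joins, with a few inversions mixed in
  for (i in seq(1, length(bp) - 1, by = 2)) {
    s <- bp[i]; e <- bp[i + 1]
    if (e <= s) next
    segs <- carve_segment(segs, s, e - 1, lo_total, lo_minor)
    type <- if (i %% 10 == 1) "INV" else "DEL"
    sv[[length(sv) + 1]] <- data.frame(
      chrom1 = ch, pos1 = s, strand1 = "+",
      chrom2 = ch, pos2 = e, strand2 = if (type == "INV") "+" else "-",
      sv_type = type)
  }
  # restore explicit hi-state minor (oscillation with retained heterozygosity)
  segs$minor_cn[segs$total_cn == hi_total] <- hi_minor
  segs$minor_cn <- pmin(segs$minor_cn, segs$total_cn %/% 2L)
  list(segs = segs, sv = do.call(rbind, sv))
}

# BFB: telomere-adjacent loss plus fold-back inversions and amplification.
# Sizes scale with the chromosome so short chromosomes keep the terminal
# loss and the fold-back cluster well inside one arm.
plant_bfb <- function(segs, build, ch, base_total, base_minor) {
  len <- chrom_length(build, ch)
  loss_len <- round(stats::runif(1, 0.04, 0.10) * len)
  loss_len <- min(max(loss_len, 2e5), 3e6)
  loss_total <- max(0L, base_total - 1L)
  loss_minor <- min(max(0L, base_minor - 1L), loss_total %/% 2L)
  segs <- carve_segment(segs, 1, loss_len, loss_total, loss_minor)
  # amplified blocks proximal to the lost telomere, from successive cycles
  cluster_span <- min(3e6, round(0.15 * len))
  amp_start <- loss_len + 1
  for (j in 1:2) {
    amp_len <- round(stats::runif(1, 0.1, 0.3) * cluster_span)
    segs <- carve_segment(segs, amp_start, amp_start + amp_len - 1,
                          base_total + 2L + j, 1L)
    amp_start <- amp_start + amp_len
  }
  hi <- min(loss_len + cluster_span, len - 4e4)
  n_fb <- 5 + stats::rpois(1, 2)
  pos1 <- round(stats::runif(n_fb, loss_len, hi))
  span <- round(stats::runif(n_fb, 200, 2.5e4))
  sv <- data.frame(chrom1 = ch, pos1 = pos1, strand1 = "+",
                   chrom2 = ch, pos2 = pos1 + span, strand2 = "+",
                   sv_type = "INV")
  # companion events of the amplification cluster: larger inversions and
  # translocations concentrated in the same region
  n_inv <- 8 + stats::rpois(1, 4)
  ip <- round(stats::runif(n_inv, loss_len, hi))
  isz <- round(stats::runif(n_inv, 5e4, max(1e5, cluster_span / 4)))
  sv <- rbind(sv, data.frame(
    chrom1 = ch, pos1 = ip, strand1 = "+",
    chrom2 = ch, pos2 = pmin(ip + isz, len), strand2 = "+",
    sv_type = "INV"))
  n_tra <- stats::rpois(1, 6)
  if (n_tra > 0) {
    others <- setdiff(intersect(build$chroms$chrom, AUTOSOMES), ch)
    partner <- sample(others, n_tra, replace = TRUE)
    sv <- rbind(sv, data.frame(
      chrom1 = ch, pos1 = round(stats::runif(n_tra, loss_len, hi)),
      strand1 = sample(c("+", "-"), n_tra, TRUE),
      chrom2 = partner,
      pos2 = round(stats::runif(n_tra, 1, chrom_length(build, partner))),
      strand2 = sample(c("+", "-"), n_tra, TRUE),
      sv_type = "TRA"))
  }
  list(segs = segs, sv = sv)
}

# background SV events from SV32 category labels
background_sv_events <- function(cats, build, chroms) {
  lens <- chrom_length(build, chroms)
  rows <- vector("list", length(cats))
  for (i in seq_along(cats)) {
    parts <- strsplit(cats[i], ":", fixed = TRUE)[[1]]
    type <- c(del = "DEL", dup = "DUP", inv = "INV", trans = "TRA")[parts[2]]
    if (type == "TRA") {
      cc <- sample(seq_along(chroms), 2)
      rows[[i]] <- data.frame(
        chrom1 = chroms[cc[1]],
        pos1 = round(stats::runif(1, 1, lens[cc[1]])),
        strand1 = sample(c("+", "-"), 1),
        chrom2 = chroms[cc[2]],
        pos2 = round(stats::runif(1, 1, lens[cc[2]])),
        strand2 = sample(c("+", "-"), 1), sv_type = "TRA")
    } else {
      bin <- match(parts[3], SV_SIZE_BINS)
      lo <- max(SV_SIZE_BREAKS[bin], 1e3)
      hi <- min(SV_SIZE_BREAKS[bin + 1], 5e7)
      size <- round(10^stats::runif(1, log10(lo), log10(hi - 1)))
      ci <- sample(seq_along(chroms), 1, prob = lens)
      len <- lens[ci]
      size <- min(size, len - 2)
      p1 <- round(stats::runif(1, 1, len - size))
      rows[[i]] <- data.frame(
        chrom1 = chroms[ci], pos1 = p1, strand1 = "+",
        chrom2 = chroms[ci], pos2 = p1 + size,
        strand2 = if (type == "INV") "+" else "-", sv_type = type)
    }
  }
  do.call(rbind, rows)
}

# place n background SNVs whose reference trinucleotide context matches the
# SBS96 category drawn from the mixture (rejection sampling on candidate
# positions)
place_mixture_snvs <- function(n, mixture, reference) {
  labels <- sbs96_labels()
  if (n == 0) {
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character()))
  }
  cats <- sample(labels, n, TRUE, prob = mixture)
  want_ctx <- paste0(substr(cats, 1, 1), substr(cats, 3, 3), substr(cats, 7, 7))
  want_alt <- substr(cats, 5, 5)
  need <- table(paste(want_ctx, want_alt, sep = "_"))
  chroms <- names(reference)
  lens <- vapply(reference, nchar, numeric(1))
  got <- list()
  remaining <- as.list(need)
  used <- character(0)
  guard <- 0
  while (sum(unlist(remaining)) > 0 && guard < 200) {
    guard <- guard + 1
    m <- max(2000, 40 * sum(unlist(remaining)))
    ci <- sample(seq_along(chroms), m, TRUE, prob = lens)
    pos <- floor(stats::runif(m, 2, lens[ci] - 1))
    key_pos <- paste(chroms[ci], pos, sep = ":")
    keep <- !duplicated(key_pos) & !key_pos %in% used
    ci <- ci[keep]; pos <- pos[keep]; key_pos <- key_pos[keep]
    ctx <- substring(reference[ci], pos - 1, pos + 1)
    refb <- substr(ctx, 2, 2)
    purine <- refb %in% c("A", "G")
    pyr_ctx <- ctx
    pyr_ctx[purine] <- revcomp(ctx[purine])
    taken <- logical(length(pos))
    for (key in names(remaining)) {
      k <- remaining[[key]]
      if (k <= 0) next
      parts <- strsplit(key, "_", fixed = TRUE)[[1]]
      idx <- which(pyr_ctx == parts[1] & !taken)
      if (length(idx) == 0) next
      take <- utils::head(idx, k)
      taken[take] <- TRUE
      alt <- ifelse(purine[take], unname(COMPLEMENT[parts[2]]), parts[2])
      got[[length(got) + 1]] <- data.frame(
        chrom = chroms[ci[take]], pos = pos[take], ref = refb[take],
        alt = alt, stringsAsFactors = FALSE)
      remaining[[key]] <- k - length(take)
    }
    used <- c(used, key_pos[taken])
  }
  do.call(rbind, got)
}

# plant kataegis loci: clustered TpC mutations with C>T / C>G alternates
plant_kataegis <- function(config, reference) {
  loci <- list(); vars <- list()
  chroms <- names(reference)
  lens <- vapply(reference, nchar, numeric(1))
  n_loci <- config$kataegis_loci
  size <- config$kataegis_cluster_size
  placed <- data.frame(chrom = character(), anchor = numeric())
  for (l in seq_len(n_loci)) {
    ci <- sample(seq_along(chroms), 1, prob = lens)
    ch <- chroms[ci]
    # loci within a sample are kept at least 5 Mb apart so each planted
    # cluster is an independent, well-separated event
    anchor <- NA
    for (try in 1:50) {
      cand <- round(stats::runif(1, 1e5, lens[ci] - 1e5))
      near <- placed$chrom == ch & abs(placed$anchor - cand) < 5e6
      if (!any(near)) { anchor <- cand; break }
    }
    if (is.na(anchor)) next
    placed <- rbind(placed, data.frame(chrom = ch, anchor = anchor))
    win_end <- min(anchor + size * config$kataegis_spacing_mean * 10 + 1e4,
                   lens[ci])
    window <- substring(reference[ci], anchor, win_end)
    tc <- gregexpr("TC", window, fixed = TRUE)[[1]]
    if (tc[1] == -1 || length(tc) < size) next
    tc_pos <- anchor + as.integer(tc)  # genomic position of the C
    # walk forward, snapping each exponential spacing to the next TC site,
    # so the cluster has exactly `size` distinct mutations
    pos <- tc_pos[1]
    for (k in seq_len(size - 1)) {
      target <- pos[k] + max(1, round(stats::rexp(1,
                               1 / config$kataegis_spacing_mean)))
      ahead <- tc_pos[tc_pos > pos[k]]
      if (length(ahead) == 0) break
      pos <- c(pos, ahead[which.min(abs(ahead - target))])
    }
    if (length(pos) < max(6, size)) next
    alt <- sample(c("T", "G"), length(pos), TRUE, prob = c(0.6, 0.4))
    vars[[length(vars) + 1]] <- data.frame(
      chrom = ch, pos = pos, ref = "C", alt = alt, stringsAsFactors = FALSE)
    loci[[length(loci) + 1]] <- data.frame(
      chrom = ch, start = min(pos), end = max(pos),
      n_mutations = length(pos), mean_imd = mean(diff(pos)))
  }
  list(
    variants = if (length(vars)) do.call(rbind, vars) else
      data.frame(chrom = character(), pos = numeric(), ref = character(),
                 alt = character()),
    loci = if (length(loci)) do.call(rbind, loci) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 n_mutations = integer(), mean_imd = numeric()))
}

#' Simulate a cohort and write it to disk
#'
#' Writes per-sample segment TSV, BEDPE and VCF files, a shared reference
#' FASTA, a manifest, per-sample truth tables and the cohort-level
#' expected SBS96 feature matrix (signature mixture times SNV count).
#' Re-running with the same config produces byte-identical files.
#'
#' @param config a `SimulationConfig`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", dir)
  }
  reference <- simulate_reference(config$build, config$seed)
  write_reference_fasta(reference, file.path(dir, "reference.fa"))
  manifest <- list(); truth_rows <- list()
  arm_truth <- list(); complex_truth <- list(); kataegis_truth <- list()
  for (i in seq_len(config$n_samples)) {
    sim <- simulate_sample(config, i, reference = reference)
    id <- sim$profile$sample_id
    seg_path <- file.path(dir, paste0(id, ".segments.tsv"))
    bedpe_path <- file.path(dir, paste0(id, ".bedpe"))
    vcf_path <- file.path(dir, paste0(id, ".vcf"))
    write_segments(sim$profile, seg_path)
    write_bedpe(sim$rearrangements, bedpe_path)
    write_snv_vcf(sim$snvs, vcf_path)
    manifest[[i]] <- data.frame(sample = id, segments = basename(seg_path),
                                bedpe = basename(bedpe_path),
                                vcf = basename(vcf_path))
    truth_rows[[i]] <- data.frame(
      sample = id, wgd = sim$truth$wgd, wgd_fraction = sim$truth$wgd_fraction,
      exposures = paste(sprintf("%.6f", sim$truth$exposures), collapse = ","))
    arm_truth[[i]] <- data.frame(sample = id,
                                 arm = names(sim$truth$arm_calls),
                                 call = unname(sim$truth$arm_calls))
    if (length(sim$truth$complex_chroms) > 0) {
      complex_truth[[i]] <- data.frame(
        sample = id, chrom = names(sim$truth$complex_chroms),
        class = unname(sim$truth$complex_chroms))
    }
    if (nrow(sim$truth$kataegis_loci) > 0) {
      kataegis_truth[[i]] <- cbind(sample = id, sim$truth$kataegis_loci)
    }
  }
  manifest <- do.call(rbind, manifest)
  if (is.null(manifest)) {
    manifest <- data.frame(sample = character(), segments = character(),
                           bedpe = character(), vcf = character())
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_or_empty <- function(rows, path, empty) {
    tab <- if (length(rows)) do.call(rbind, rows) else empty
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_or_empty(truth_rows, file.path(dir, "truth_samples.tsv"),
                     data.frame(sample = character(), wgd = logical(),
                                wgd_fraction = numeric(),
                                exposures = character()))
  write_tsv_or_empty(arm_truth, file.path(dir, "truth_arms.tsv"),
                     data.frame(sample = character(), arm = character(),
                                call = character()))
  write_tsv_or_empty(complex_truth, file.path(dir, "truth_complex.tsv"),
                     data.frame(sample = character(), chrom = character(),
                                class = character()))
  write_tsv_or_empty(kataegis_truth, file.path(dir, "truth_kataegis.tsv"),
                     data.frame(sample = character(), chrom = character(),
                                start = numeric(), end = numeric(),
                                n_mutations = integer(), mean_imd = numeric()))
  if (config$n_samples > 0) {
    expected <- config$sbs_signature_matrix %*% config$true_exposures *
      rep(config$snv_count, each = 1)
    colnames(expected) <- manifest$sample
    write_feature_matrix(feature_matrix("SBS96", expected),
                         file.path(dir, "truth_sbs96_expected.tsv"))
  }
  invisible(manifest)
}
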