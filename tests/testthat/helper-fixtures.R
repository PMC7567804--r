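# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's own code paths: they expand segments to base-pair
# vectors or enumerate search spaces exhaustively.

toy_build <- function(n_chrom = 3, chrom_len = 3e6, cen_frac = 0.5) {
  genome_build(data.frame(
    chrom = as.character(seq_len(n_chrom)),
    length = chrom_len,
    cen_start = round(chrom_len * cen_frac),
    cen_end = round(chrom_len * cen_frac) + round(chrom_len * 0.01)))
}

# random valid segment profile covering every arm of a build
random_profile <- function(build, seed, max_breaks = 4, cn_pool = 0:7) {
  set.seed(seed)
  segs <- do.call(rbind, lapply(seq_len(nrow(build$arms)), function(i) {
    a <- build$arms[i, ]
    k <- sample.int(max_breaks, 1)
    cuts <- sort(unique(c(a$start, sample(seq(a$start, a$end), k - 1), a$end + 1)))
    tot <- sample(cn_pool, length(cuts) - 1, replace = TRUE)
    mino <- vapply(tot, function(t) sample(0:(t %/% 2), 1), numeric(1))
    data.frame(chrom = a$chrom, start = cuts[-length(cuts)],
               end = cuts[-1] - 1, total_cn = tot, minor_cn = mino)
  }))
  segment_profile(sprintf("rand%d", seed), segs, ploidy = 2)
}

# expand a profile's autosomal segments to per-base-pair vectors
bp_expand <- function(profile, build) {
  seg <- profile$segments[profile$segments$chrom %in% as.character(1:22), ]
  list(total = rep(seg$total_cn, seg$end - seg$start + 1),
       minor = rep(seg$minor_cn, seg$end - seg$start + 1),
       chrom = rep(seg$chrom, seg$end - seg$start + 1),
       pos = unlist(lapply(seq_len(nrow(seg)),
                           function(i) seg$start[i]:seg$end[i])))
}

oracle_wgd_fraction <- function(profile, build) {
  bp <- bp_expand(profile, build)
  mean((bp$total - bp$minor) >= 2)
}

oracle_altered_fraction <- function(profile, build) {
  bp <- bp_expand(profile, build)
  mean(bp$total >= 6 | bp$total <= 1 | (bp$total == 2 & bp$minor == 0))
}

oracle_arm_calls <- function(profile, build, threshold = 0.8) {
  bp <- bp_expand(profile, build)
  arms <- counted_arms(build)
  out <- character(nrow(arms))
  for (i in seq_len(nrow(arms))) {
    sel <- bp$chrom == arms$chrom[i] & bp$pos >= arms$start[i] &
      bp$pos <= arms$end[i]
    fg <- mean(bp$total[sel] > profile$ploidy)
    fl <- mean(bp$total[sel] < profile$ploidy)
    out[i] <- if (fg > threshold) "gain" else if (fl > threshold) "loss"
    else "neutral"
  }
  out
}

oracle_gene_status <- function(profile, genes) {
  iv <- genes$intervals
  amp <- logical(nrow(iv)); hd <- logical(nrow(iv))
  seg <- profile$segments
  for (g in seq_len(nrow(iv))) {
    for (p in seq(iv$start[g], iv$end[g])) {
      s <- seg[seg$chrom == iv$chrom[g] & seg$start <= p & seg$end >= p, ]
      if (nrow(s) == 1) {
        if (s$total_cn >= 6) amp[g] <- TRUE
        if (s$total_cn == 0) hd[g] <- TRUE
      }
    }
  }
  data.frame(gene = iv$label, amplified = amp, homdel = hd)
}

# exhaustive optimal segmentation by enumerating all boundary subsets
oracle_pcf <- function(y, gamma) {
  n <- length(y)
  best_cost <- Inf; best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    bounds <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, bounds + 1)
    ends <- c(bounds, n)
    cost <- gamma * length(starts)
    for (s in seq_along(starts)) {
      yy <- y[starts[s]:ends[s]]
      cost <- cost + sum((yy - mean(yy))^2)
    }
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- data.frame(start = starts, end = ends)
    }
  }
  list(cost = best_cost, segments = best)
}

oracle_kataegis <- function(pos, gamma, min_mut = 6, max_mean = 1000) {
  imd <- diff(sort(pos))
  segs <- oracle_pcf(log10(pmax(imd, 1)), gamma)$segments
  out <- list()
  for (s in seq_len(nrow(segs))) {
    i <- segs$start[s]; j <- segs$end[s]
    if (j - i + 2 >= min_mut && mean(imd[i:j]) <= max_mean) {
      out[[length(out) + 1]] <- data.frame(
        start = sort(pos)[i], end = sort(pos)[j + 1],
        n_mutations = j - i + 2, mean_imd = mean(imd[i:j]))
    }
  }
  if (length(out) == 0) return(data.frame(start = numeric(), end = numeric(),
                                          n_mutations = integer(),
                                          mean_imd = numeric()))
  do.call(rbind, out)
}

# independent single-linkage clustering of breakpoint ends on one chromosome
oracle_clustered_ends <- function(pos, d, min_size) {
  o <- order(pos)
  cl <- cumsum(c(1, !(diff(pos[o]) < d)))
  big <- as.integer(names(table(cl))[table(cl) >= min_size])
  flagged <- logical(length(pos))
  flagged[o] <- cl %in% big
  flagged
}

# grid-search NNLS on the 2-simplex for two-signature mixtures
oracle_nnls2 <- function(v, W, step = 1e-3) {
  grid <- seq(0, 1, by = step)
  best <- c(0, 0); best_err <- Inf
  for (a in grid) for (b in grid) {
    if (a + b > 1 + 1e-9) next
    err <- sum((v - W[, 1] * a - W[, 2] * b)^2)
    if (err < best_err) { best_err <- err; best <- c(a, b) }
  }
  best
}

empty_reference <- function() stats::setNames(character(0), character(0))

write_sample_fixture <- function(dir) {
  seg <- file.path(dir, "s1.segments.tsv")
  writeLines(c("#ploidy=2", "#purity=0.8",
               "sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "s1\t1\t1\t1000000\t2\t1"), seg)
  bedpe <- file.path(dir, "s1.bedpe")
  writeLines("1\t99\t100\t1\t1999\t2000\tsv1\t.\t+\t-\tDEL", bedpe)
  vcf <- file.path(dir, "s1.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t500\t.\tC\tT\t.\tPASS\t."), vcf)
  list(segments = seg, bedpe = bedpe, vcf = vcf)
}
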