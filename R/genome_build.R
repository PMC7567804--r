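#' @keywords internal
"_PACKAGE"

ACROCENTRIC <- c("13", "14", "15", "21", "22")
AUTOSOMES <- as.character(1:22)

#' Normalize chromosome names
#'
#' Accepts `"chr1"` or `"1"` style names and strips any `"chr"` prefix so
#' mixed-dialect inputs compare equal. Case of the prefix is ignored.
#'
#' @param x character vector of chromosome names.
#' @return character vector without `"chr"` prefixes.
#' @export
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Load a genome build from an arm table
#'
#' Reads a tab-separated table with columns `chrom`, `length`, `cen_start`
#' and `cen_end` (1-based, inclusive) and derives chromosome arms:
#' p spans `[1, cen_start]` and q spans `[cen_end, length]`. The short arms
#' of the acrocentric chromosomes (13, 14, 15, 21, 22) are flagged as not
#' counted for aneuploidy scoring; sex chromosomes are retained but never
#' counted.
#'
#' @param path path to the arm table TSV, or one of the shorthand names
#'   `"grch37"` (packaged GRCh37 table) and `"mini"` (the same table with
#'   all coordinates scaled 1:10, roughly 310 Mb of genome, used as the
#'   default simulation genome).
#' @return an object of class `GenomeBuild`: a list with `chroms`
#'   (data.frame `chrom`, `length`, `cen_start`, `cen_end`) and `arms`
#'   (data.frame `chrom`, `arm`, `start`, `end`, `counted`).
#' @examples
#' build <- load_genome_build("grch37")
#' sum(build$arms$counted)  # 39 counted autosomal arms
#' @export
load_genome_build <- function(path) {
  if (identical(path, "grch37") || identical(path, "mini")) {
    tab <- utils::read.table(
      system.file("extdata", "grch37_arms.tsv", package = "genomplexity"),
      header = TRUE, sep = "\t", colClasses = c("character", rep("numeric", 3))
    )
    if (identical(path, "mini")) {
      tab$length <- floor(tab$length / 10)
      tab$cen_start <- floor(tab$cen_start / 10)
      tab$cen_end <- floor(tab$cen_end / 10)
    }
  } else {
    if (!file.exists(path)) stop("arm table not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "length", "cen_start", "cen_end")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols) > 0) {
      stop("arm table format error: missing column(s) ",
           paste(missing_cols, collapse = ", "))
    }
    tab <- tab[, need]
    tab$chrom <- as.character(tab$chrom)
  }
  genome_build(tab)
}

#' Construct a genome build from a chromosome table
#'
#' @param chroms data.frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end` (1-based inclusive centromere interval).
#' @return a `GenomeBuild` object; see [load_genome_build()].
#' @export
genome_build <- function(chroms) {
  chroms$chrom <- normalize_chrom(chroms$chrom)
  if (any(duplicated(chroms$chrom))) stop("duplicated chromosome names")
  if (any(chroms$length <= 0)) stop("validation error: chromosome length <= 0")
  bad <- chroms$cen_start < 1 | chroms$cen_end > chroms$length |
    chroms$cen_start > chroms$cen_end
  if (any(bad)) {
    stop("validation error: centromere outside chromosome for ",
         paste(chroms$chrom[bad], collapse = ", "))
  }
  arms <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    ch <- chroms$chrom[i]
    data.frame(
      chrom = ch, arm = c("p", "q"),
      start = c(1, chroms$cen_end[i]),
      end = c(chroms$cen_start[i], chroms$length[i]),
      stringsAsFactors = FALSE
    )
  }))
  arms$counted <- arms$chrom %in% AUTOSOMES &
    !(arms$arm == "p" & arms$chrom %in% ACROCENTRIC)
  structure(list(chroms = chroms, arms = arms), class = "GenomeBuild")
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat("GenomeBuild:", nrow(x$chroms), "chromosomes,",
      sum(x$arms$counted), "counted autosomal arms,",
      format(sum(x$chroms$length), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Counted autosomal arms of a build
#'
#' Arms entering the aneuploidy score: both arms of every autosome except
#' the short arms of the acrocentric chromosomes.
#'
#' @param build a `GenomeBuild`.
#' @return data.frame of counted arms (`chrom`, `arm`, `start`, `end`).
#' @export
counted_arms <- function(build) {
  stopifnot(inherits(build, "GenomeBuild"))
  build$arms[build$arms$counted, c("chrom", "arm", "start", "end")]
}

#' Total autosomal genome length of a build
#' @param build a `GenomeBuild`.
#' @return total length in bp of chromosomes 1-22.
#' @export
autosome_length <- function(build) {
  sum(build$chroms$length[build$chroms$chrom %in% AUTOSOMES])
}

chrom_length <- function(build, chrom) {
  i <- match(normalize_chrom(chrom), build$chroms$chrom)
  if (any(is.na(i))) stop("unknown chromosome: ",
                          paste(chrom[is.na(i)], collapse = ", "))
  build$chroms$length[i]
}
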