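# Read-depth binning and subgenome dosage inference, plus the exact
# coverage/size reporting arithmetic.

#' Place error-free reads on a genome and compute per-position depth
#'
#' Each read is placed at every exact-match position on either strand; a
#' read matching n positions contributes 1/n depth at each covered site, so
#' total depth mass equals total mapped read length regardless of repeat
#' copy number.
#'
#' @param reads A `read_set` from [simulate_reads()] or a named character
#'   vector of read sequences.
#' @param genome A `synthetic_genome` or named character vector of
#'   chromosome sequences.
#' @return A `depth_profile`: `depth` (list of per-chromosome numeric
#'   vectors), `n_unmapped`, `n_hits` (per read).
#' @export
map_reads <- function(reads, genome) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  seqs <- if (inherits(genome, "synthetic_genome")) genome$sequences
          else genome
  res <- map_reads_cpp(seqs, reads)
  class(res) <- "depth_profile"
  res
}

#' Bin per-position depth and compute the genome-wide median
#'
#' Non-overlapping bins of `bin` sites; a trailing short bin is averaged
#' over its true length. The genome median is the median depth over every
#' position of every chromosome (the order of concatenation does not affect
#' it).
#'
#' @param profile A `depth_profile` from [map_reads()], or a list of
#'   per-chromosome numeric depth vectors.
#' @param bin Bin size in sites (>= 1).
#' @return List with `bins` (data frame: chrom, start, end, mean_depth) and
#'   `genome_median`.
#' @export
bin_depth <- function(profile, bin = 1000L) {
  depth <- if (inherits(profile, "depth_profile")) profile$depth else profile
  if (length(depth) == 0 || sum(lengths(depth)) == 0)
    stop("empty depth profile")
  if (bin < 1) stop("bin must be >= 1")
  rows <- lapply(names(depth), function(chrom) {
    d <- depth[[chrom]]
    starts <- seq(0L, length(d) - 1L, by = bin)
    ends <- pmin(starts + bin, length(d))
    means <- vapply(seq_along(starts),
                    function(i) mean(d[(starts[i] + 1L):ends[i]]), 0)
    data.frame(chrom = chrom, start = starts, end = ends,
               mean_depth = means, stringsAsFactors = FALSE)
  })
  list(bins = do.call(rbind, rows),
       genome_median = stats::median(unlist(depth, use.names = FALSE)))
}

#' Infer per-subgenome dosage from binned depth
#'
#' Each subgenome's depth is summarized as the median of its bin means
#' (robust to repeat-driven pileups); ratios are taken against the
#' shallowest subgenome and rounded to the smallest integer copy-number
#' vector.
#'
#' @param binned Output of [bin_depth()].
#' @param subgenome_map Named vector chromosome -> subgenome label.
#' @return A `dosage_report` list: `depth` (per-subgenome), `ratios`
#'   (pairwise matrix), `copy_number` (named integer vector, min 1).
#' @export
dosage_ratios <- function(binned, subgenome_map) {
  bins <- binned$bins
  sub <- subgenome_map[bins$chrom]
  if (any(is.na(sub))) stop("chromosome missing from subgenome map")
  if (length(unique(sub)) < 2) stop("need at least 2 subgenomes")
  med <- vapply(split(bins$mean_depth, sub), stats::median, 0)
  if (any(!is.finite(med)) || any(med <= 0))
    stop("a subgenome has no usable bins")
  ratios <- outer(med, med, "/")
  rel <- med / min(med)
  copy <- pmax(1L, as.integer(round(rel)))
  structure(list(depth = med, ratios = ratios,
                 copy_number = stats::setNames(copy, names(med))),
            class = "dosage_report")
}

#' @export
print.dosage_report <- function(x, ...) {
  cat("dosage_report\n  median binned depth:\n")
  print(round(x$depth, 2))
  cat("  inferred copy number:\n")
  print(x$copy_number)
  invisible(x)
}

#' Sequencing coverage fold
#'
#' `total_bases / genome_size`, rounded half away from zero at `digits`
#' decimals (the convention of printed coverage reports, e.g. 48.13 Gb over
#' a 532 Mb genome is 90.5x).
#'
#' @param total_bases Total sequenced bases.
#' @param genome_size Estimated genome size in bases (> 0).
#' @param digits Decimals to report.
#' @return Coverage fold.
#' @export
coverage_fold <- function(total_bases, genome_size, digits = 1) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  round_half_away(total_bases / genome_size, digits)
}

#' Assembly size as a percentage of a genome-size estimate
#'
#' @param size Assembly size in bases.
#' @param estimate Estimated genome size in bases (> 0).
#' @param digits Decimals to report (printed reports use integers).
#' @return Percentage.
#' @export
percent_of_estimate <- function(size, estimate, digits = 0) {
  if (estimate <= 0) stop("estimate must be > 0")
  round_half_away(100 * size / estimate, digits)
}
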