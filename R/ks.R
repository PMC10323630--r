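# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction, the
# standard filters for Ks distributions, and histogram peak detection used
# to diagnose allo- vs autopolyploidy (two Ks peaks = homologous plus
# homoeologous pair populations).

GENETIC_CODE_STD <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(64)
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"),
    "")[[1]]
  i <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# synonymous site fraction of each codon: per position, the fraction of the
# three alternative bases giving a synonymous change (changes to stop codons
# contribute to neither class)
codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_STD[[codon]]
  s <- 0
  bases <- c("A", "C", "G", "T")
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      alt_aa <- GENETIC_CODE_STD[[alt]]
      if (alt_aa == "*") next
      if (alt_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

perms_of <- function(n) {
  if (n == 1) return(list(1L))
  if (n == 2) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair; pathways through stop codons are excluded (all pathways used as a
# fallback when every ordering hits a stop)
codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- perms_of(length(pos))
  score_path <- function(ord, allow_stop) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in pos[ord]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && GENETIC_CODE_STD[[nxt]] == "*") return(NULL)
      if (GENETIC_CODE_STD[[nxt]] == GENETIC_CODE_STD[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, score_path, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(paths, score_path, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

#' Nei-Gojobori Ka and Ks for one codon-aligned pair
#'
#' Synonymous and nonsynonymous site counts are averaged over the two
#' sequences; differences are averaged over all single-step mutational
#' pathways (excluding those through stop codons); proportions are corrected
#' for multiple substitutions with the Jukes-Cantor formula
#' `K = -(3/4) log(1 - (4/3) p)`. A pair is flagged invalid (saturated)
#' when `p >= 3/4`. Codon pairs containing an ambiguous base, a gap, or a
#' stop codon are dropped pairwise.
#'
#' @param seq1,seq2 Coding sequences of equal length, a multiple of 3.
#' @return A `ks_record` list: `ka`, `ks`, `S`, `N`, `Sd`, `Nd`, `ps`,
#'   `pn`, `valid`.
#' @export
ng86 <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be the same length")
  if (nchar(seq1) %% 3 != 0) stop("length must be a multiple of 3")
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2) &
    GENETIC_CODE_STD[c1] != "*" & GENETIC_CODE_STD[c2] != "*"
  c1 <- c1[clean]; c2 <- c2[clean]
  if (length(c1) == 0) stop("no usable codons in the pair")

  S <- (sum(vapply(c1, codon_syn_sites, 0)) +
        sum(vapply(c2, codon_syn_sites, 0))) / 2
  N <- 3 * length(c1) - S
  d <- colSums(do.call(rbind, Map(codon_diffs, c1, c2)))
  Sd <- d[["sd"]]; Nd <- d[["nd"]]
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  structure(list(ka = ka, ks = ks, S = S, N = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, valid = !is.na(ks) && !is.na(ka)),
            class = "ks_record")
}

#' Filter a Ks record table
#'
#' Removes self-comparisons (identical gene ids when `gene1`/`gene2`
#' columns are present, otherwise records with Ks exactly 0) and records
#' with Ka or Ks strictly above `max_value` (saturated estimates).
#'
#' @param records Data frame with `ka` and `ks` columns (optionally
#'   `gene1`, `gene2`).
#' @param max_value Upper bound; the rule is strict `>`, so records at the
#'   bound are kept.
#' @param drop_self Drop self-comparisons.
#' @return The filtered subset of `records`.
#' @export
filter_ks <- function(records, max_value = 3, drop_self = TRUE) {
  keep <- rep(TRUE, nrow(records))
  if (drop_self) {
    keep <- if (!is.null(records$gene1) && !is.null(records$gene2))
      keep & (records$gene1 != records$gene2)
    else keep & (records$ks != 0)
  }
  keep <- keep & !(records$ks > max_value) & !(records$ka > max_value)
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Detect peaks in a Ks histogram
#'
#' Histograms Ks at fixed bin width and reports strict local maxima above a
#' prominence floor; the pattern of peaks diagnoses ploidy history (one
#' peak: a single pair population, e.g. an autopolyploid's homologs; two
#' peaks: homologous plus homoeologous populations of an allopolyploid).
#'
#' @param records Numeric Ks values, or a data frame with a `ks` column.
#' @param bin_width Histogram bin width (default 0.002, suited to low-Ks
#'   comparisons within and between young subgenomes).
#' @param min_prominence Minimum bin count, as a fraction of the tallest
#'   bin, for a local maximum to count as a peak.
#' @return A `peak_report` list: `breaks`, `mids`, `counts`, `peaks` (data
#'   frame ks/count, tallest first), `label` ("one-peak"/"two-peak").
#' @export
ks_peaks <- function(records, bin_width = 0.002, min_prominence = 0.05) {
  ks <- if (is.data.frame(records)) records$ks else records
  ks <- ks[!is.na(ks)]
  if (length(ks) == 0) stop("no Ks records")
  breaks <- seq(0, (floor(max(ks) / bin_width) + 1) * bin_width,
                by = bin_width)
  idx <- findInterval(ks, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  mids <- breaks[-length(breaks)] + bin_width / 2
  n <- length(counts)
  left <- c(-Inf, counts[-n])
  right <- c(counts[-1], -Inf)
  is_peak <- counts > left & counts > right &
    counts >= min_prominence * max(counts)
  peaks <- data.frame(ks = mids[is_peak], count = counts[is_peak])
  peaks <- peaks[order(-peaks$count), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(breaks = breaks, mids = mids, counts = counts,
                 peaks = peaks,
                 label = if (nrow(peaks) >= 2) "two-peak" else "one-peak"),
            class = "peak_report")
}
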