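# Differential k-mer subgenome phasing.
#
# Chromosomes enriched for the same repetitive k-mers share a recent origin,
# so hierarchical clustering of chromosomes on differentially abundant
# k-mers separates the subgenomes of an allopolyploid, and the density of
# the discriminating k-mer groups along chromosomes marks the satellite
# arrays (centromeres) that drive the signal.

#' Count k-mers per chromosome
#'
#' Exact sliding-window counting (every overlapping occurrence counts);
#' windows containing an ambiguous base are skipped, and with
#' `canonical = TRUE` each k-mer is folded onto the lexicographic minimum of
#' itself and its reverse complement.
#'
#' @param sequences Named character vector of chromosome sequences (or a
#'   Biostrings DNAStringSet).
#' @param k K-mer length (1-31; the phasing analysis uses 25).
#' @param canonical Fold reverse complements together.
#' @param min_count Drop k-mers whose count is below this on any chromosome
#'   (0 keeps everything). Applying the per-chromosome occurrence floor here
#'   keeps the matrix small on megabase genomes.
#' @return A `kmer_count_matrix`: integer matrix (k-mer x chromosome) in
#'   `$counts`, plus `$k` and `$canonical`.
#' @export
count_kmers <- function(sequences, k = 25L, canonical = TRUE,
                        min_count = 0L) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  if (length(sequences) == 0) stop("no sequences supplied")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (k < 1) stop("k must be >= 1")
  if (k > min(nchar(sequences)))
    warning("k exceeds the shortest sequence; its column will be empty")
  m <- count_kmers_cpp(sequences, as.integer(k), canonical,
                       as.integer(min_count))$counts
  structure(list(counts = m, k = as.integer(k), canonical = canonical),
            class = "kmer_count_matrix")
}

#' @export
print.kmer_count_matrix <- function(x, ...) {
  cat("kmer_count_matrix: ", nrow(x$counts), " ", x$k, "-mers x ",
      ncol(x$counts), " chromosomes",
      if (x$canonical) " (canonical)", "\n", sep = "")
  invisible(x)
}

# normalize a homoeolog group map to a named vector chrom -> set id
as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stats::setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  } else if (is.list(groups)) {
    stats::setNames(rep(names(groups), lengths(groups)),
                    unlist(groups, use.names = FALSE))
  } else groups
}

#' Filter for differential k-mers between homoeologs
#'
#' Retains k-mers that (1) occur at least `min_count` times on every
#' chromosome (when `require_all`), and (2) on some homoeolog reach at least
#' `fold` times their abundance on a sister chromosome (on at least one
#' sister, or on all sisters with `all_sisters = TRUE`).
#'
#' @param m A `kmer_count_matrix`.
#' @param groups Homoeolog map: data frame (chromosome, homoeolog_set),
#'   named list set -> chromosomes, or named vector chromosome -> set.
#' @param min_count Per-chromosome occurrence floor.
#' @param fold Abundance ratio defining "differential".
#' @param require_all Require the floor on all chromosomes.
#' @param all_sisters Require the fold change against every sister rather
#'   than at least one.
#' @return A filtered `kmer_count_matrix` (rows are a subset of the input).
#' @export
differential_filter <- function(m, groups, min_count = 10L, fold = 2,
                                require_all = TRUE, all_sisters = FALSE) {
  stopifnot(inherits(m, "kmer_count_matrix"))
  gm <- as_group_map(groups)
  chroms <- colnames(m$counts)
  missing <- setdiff(chroms, names(gm))
  if (length(missing))
    stop("chromosomes missing from the homoeolog map: ",
         paste(missing, collapse = ", "))
  counts <- m$counts
  keep <- rep(TRUE, nrow(counts))
  if (require_all && nrow(counts))
    keep <- apply(counts, 1, min) >= min_count

  sets <- split(chroms, gm[chroms])
  diff_ok <- rep(FALSE, nrow(counts))
  for (set in sets) {
    if (length(set) < 2) next
    for (focal in set) {
      sisters <- setdiff(set, focal)
      ok <- counts[, focal, drop = TRUE] >=
        fold * counts[, sisters, drop = FALSE]
      hit <- if (all_sisters) rowSums(ok) == length(sisters)
             else rowSums(ok) > 0
      diff_ok <- diff_ok | hit
    }
  }
  m$counts <- counts[keep & diff_ok, , drop = FALSE]
  m
}

# Euclidean distance on optionally log2(x+1)-scaled columns of `mat`
kmer_dist <- function(mat, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  if (transform == "log2") mat <- log2(mat + 1)
  stats::dist(mat, method = "euclidean")
}

#' Hierarchically cluster chromosomes by k-mer abundance
#'
#' Complete-linkage agglomerative clustering of chromosome columns, the
#' standard approach for grouping allopolyploid chromosomes into subgenomes
#' by shared repeat content. Distances are Euclidean on log2(count + 1)
#' columns by default (`transform = "raw"` for raw counts).
#'
#' @param m A `kmer_count_matrix`.
#' @param n_groups Optional flat cut; must not exceed the chromosome count.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param transform Column scaling before Euclidean distance.
#' @return List with `hclust` (dendrogram), `labels` (named cluster ids at
#'   the cut, or NULL), and `silhouette` (mean silhouette width at the cut).
#' @export
cluster_chromosomes <- function(m, n_groups = NULL, linkage = "complete",
                                transform = c("log2", "raw")) {
  stopifnot(inherits(m, "kmer_count_matrix"))
  if (ncol(m$counts) < 2) stop("need at least 2 chromosomes")
  if (nrow(m$counts) < 1) stop("need at least 1 k-mer")
  d <- kmer_dist(t(m$counts), transform)
  hc <- stats::hclust(d, method = linkage)
  labels <- NULL
  sil <- NULL
  if (!is.null(n_groups)) {
    if (n_groups > ncol(m$counts))
      stop("requested more groups than chromosomes")
    labels <- stats::cutree(hc, k = n_groups)
    sil <- mean_silhouette(as.matrix(d), labels)
  }
  list(hclust = hc, labels = labels, silhouette = sil)
}

# mean silhouette width of a flat clustering given a distance matrix
mean_silhouette <- function(dmat, labels) {
  n <- length(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(dmat[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dmat[i, labels == g]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster k-mers into abundance-profile groups
#'
#' Rows (k-mers) are clustered with the same linkage and distance as
#' [cluster_chromosomes()]; the resulting groups are the discriminating
#' repeat families whose densities can be profiled along chromosomes.
#'
#' @inheritParams cluster_chromosomes
#' @param n_groups Number of k-mer groups to cut.
#' @return List with `groups` (named list of k-mer character vectors, sizes
#'   in names), `assignment` (named integer vector), `hclust`.
#' @export
cluster_kmers <- function(m, n_groups, linkage = "complete",
                          transform = c("log2", "raw")) {
  stopifnot(inherits(m, "kmer_count_matrix"))
  if (nrow(m$counts) < 1) stop("need at least 1 k-mer")
  if (nrow(m$counts) == 1 || n_groups == 1) {
    assignment <- stats::setNames(rep(1L, nrow(m$counts)),
                                  rownames(m$counts))
    return(list(groups = list(group1 = rownames(m$counts)),
                assignment = assignment, hclust = NULL))
  }
  if (n_groups > nrow(m$counts)) stop("requested more groups than k-mers")
  d <- kmer_dist(m$counts, transform)
  hc <- stats::hclust(d, method = linkage)
  assignment <- stats::cutree(hc, k = n_groups)
  groups <- split(rownames(m$counts), assignment)
  names(groups) <- paste0("group", names(groups))
  list(groups = groups, assignment = assignment, hclust = hc)
}

#' Windowed density of a k-mer group along a chromosome
#'
#' The value in a window is `occurrences * k / window_length`: the
#' proportion of window bases occupied by group k-mers (occurrences are
#' assigned to the window containing their start; the trailing short window
#' is normalized by its true length).
#'
#' @param kmers Character vector of group member k-mers (may be empty).
#' @param sequence Single chromosome sequence string.
#' @param chrom Chromosome id recorded in the track.
#' @param window Window size in bases (>= k).
#' @param canonical Match both strands.
#' @return A `density_track` data frame: chrom, start, end, n, value.
#' @export
density_profile <- function(kmers, sequence, chrom = "chr", window = 1e6,
                            canonical = TRUE) {
  L <- nchar(sequence)
  k <- if (length(kmers)) nchar(kmers[1]) else 1L
  if (window < k) stop("window must be at least k")
  starts <- seq(0, L - 1, by = window)
  ends <- pmin(starts + window, L)
  n <- integer(length(starts))
  if (length(kmers)) {
    pos <- kmer_positions_cpp(sequence, kmers, canonical)
    if (length(pos)) {
      tab <- table(findInterval(pos, starts))
      n[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  track <- data.frame(chrom = chrom, start = starts, end = ends, n = n,
                      value = n * k / (ends - starts),
                      stringsAsFactors = FALSE)
  attr(track, "k") <- k
  attr(track, "window") <- window
  class(track) <- c("density_track", "data.frame")
  track
}

#' Windowed coverage density of annotated intervals
#'
#' Companion to [density_profile()] for gene and transposable-element
#' tracks: the value per window is the fraction of its bases covered by the
#' given intervals (0-based half-open, assumed non-overlapping).
#'
#' @param intervals Data frame with `start`, `end` (optionally filtered to
#'   one chromosome by the caller).
#' @param chrom_length Chromosome length.
#' @param chrom Chromosome id recorded in the track.
#' @param window Window size in bases.
#' @return A `density_track` data frame.
#' @export
interval_density <- function(intervals, chrom_length, chrom = "chr",
                             window = 1e6) {
  starts <- seq(0, chrom_length - 1, by = window)
  ends <- pmin(starts + window, chrom_length)
  cov <- vapply(seq_along(starts), function(i) {
    ov <- pmin(intervals$end, ends[i]) - pmax(intervals$start, starts[i])
    sum(ov[ov > 0])
  }, 0)
  track <- data.frame(chrom = chrom, start = starts, end = ends, n = NA,
                      value = cov / (ends - starts), stringsAsFactors = FALSE)
  attr(track, "window") <- window
  class(track) <- c("density_track", "data.frame")
  track
}

#' Estimate a centromere from gene and TE density tracks
#'
#' Centromeric and pericentromeric regions show depressed gene density and
#' elevated transposable-element density, so windows are scored as
#' `z(TE) - z(gene)` and the maximal-scoring contiguous run of windows is
#' reported.
#'
#' @param gene_track,te_track `density_track`s on the same window grid.
#' @return List with `chrom`, `start`, `end`, `score`, and `undefined`
#'   (TRUE when either track is constant, in which case the interval is NA).
#' @export
estimate_centromere <- function(gene_track, te_track) {
  if (nrow(gene_track) != nrow(te_track) ||
      any(gene_track$start != te_track$start))
    stop("tracks must share one window grid")
  if (stats::sd(gene_track$value) == 0 || stats::sd(te_track$value) == 0)
    return(list(chrom = gene_track$chrom[1], start = NA, end = NA,
                score = NA, undefined = TRUE))
  z <- function(x) (x - mean(x)) / stats::sd(x)
  s <- z(te_track$value) - z(gene_track$value)
  # maximal-sum contiguous run (Kadane)
  best <- -Inf; best_i <- 1L; best_j <- 1L
  cur <- 0; cur_i <- 1L
  for (j in seq_along(s)) {
    if (cur <= 0) { cur <- s[j]; cur_i <- j } else cur <- cur + s[j]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- j }
  }
  list(chrom = gene_track$chrom[1], start = gene_track$start[best_i],
       end = gene_track$end[best_j], score = best, undefined = FALSE)
}
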