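# Rule-based annotation and marker QC: fused gene-model candidates,
# genetic-marker filtering with per-subgenome mapping statistics, and
# S-locus (S-RNase + SFB) linkage calls.

#' Flag putatively fused gene models
#'
#' A gene model from the combined (transcript + protein) prediction run is
#' a fusion candidate when at least `min_overlappers` distinct models from
#' the proteins-only run overlap it (>= 1 bp, same chromosome,
#' strand-agnostic): multiple independent protein alignments across one
#' model suggest it spans more than one real locus.
#'
#' @param protein_only Data frame of proteins-only models: `model_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param combined Data frame of combined-run models, same columns.
#' @param min_overlappers Distinct overlapping proteins-only models needed
#'   to flag.
#' @return `combined` with added columns `n_overlappers`, `overlapper_ids`
#'   (";"-joined) and `flagged`.
#' @export
fusion_candidates <- function(protein_only, combined, min_overlappers = 2L) {
  n_ov <- integer(nrow(combined))
  ids <- character(nrow(combined))
  for (i in seq_len(nrow(combined))) {
    same <- protein_only$chrom == combined$chrom[i]
    hit <- same & protein_only$start < combined$end[i] &
      protein_only$end > combined$start[i]
    n_ov[i] <- length(unique(protein_only$model_id[hit]))
    ids[i] <- paste(unique(protein_only$model_id[hit]), collapse = ";")
  }
  combined$n_overlappers <- n_ov
  combined$overlapper_ids <- ids
  combined$flagged <- n_ov >= min_overlappers
  combined
}

#' Filter genetic-marker mapping hits
#'
#' Removes every hit of any marker mapping more than `max_hits` times, then
#' removes individual hits covering less than `min_fraction` of the marker
#' length ("below 80%" is strict, so hits at exactly the floor are kept),
#' and recounts hits per marker.
#'
#' @param hits Data frame: `marker_id`, `chrom`, `start`, `end`,
#'   `aligned_fraction` (of marker length, in (0, 1\]).
#' @param max_hits Maximum total mappings per marker.
#' @param min_fraction Minimum aligned fraction per hit.
#' @return List with `hits` (filtered) and `summary` (per-marker hit counts
#'   after filtering).
#' @export
filter_markers <- function(hits, max_hits = 4L, min_fraction = 0.8) {
  n_per <- table(hits$marker_id)
  multi <- names(n_per)[n_per > max_hits]
  out <- hits[!(hits$marker_id %in% multi), , drop = FALSE]
  out <- out[out$aligned_fraction >= min_fraction, , drop = FALSE]
  counts <- table(out$marker_id)
  summary <- data.frame(marker_id = names(counts),
                        n_hits = as.integer(counts),
                        stringsAsFactors = FALSE)
  list(hits = out, summary = summary)
}

#' Per-subgenome marker mapping statistics
#'
#' Counts markers that map exactly once to every subgenome (the signature
#' of a well-phased polyploid assembly) and, when genetic-map positions are
#' supplied, reports the per-chromosome Spearman rank correlation between
#' map order and physical order.
#'
#' @param hits Filtered marker hits (see [filter_markers()]).
#' @param subgenome_of Named vector chromosome -> subgenome label.
#' @param genetic_map Optional data frame: `marker_id`, `position` (cM).
#' @return List with `n_markers`, `n_exact_once_per_subgenome`, `percent`
#'   (integer), `per_subgenome_counts`, and `collinearity` (per-chromosome
#'   rank correlations, when a genetic map is given).
#' @export
marker_stats <- function(hits, subgenome_of, genetic_map = NULL) {
  if (nrow(hits) == 0) stop("no marker hits")
  sub <- subgenome_of[hits$chrom]
  if (any(is.na(sub))) stop("chromosome missing from subgenome map")
  subs <- sort(unique(subgenome_of))
  markers <- unique(hits$marker_id)
  tab <- table(factor(hits$marker_id, levels = markers),
               factor(sub, levels = subs))
  exact_once <- rowSums(tab == 1) == length(subs) &
    rowSums(tab) == length(subs)
  per_sub <- colSums(tab > 0)
  if (any(per_sub == 0))
    message("subgenome(s) without any marker: ",
            paste(names(per_sub)[per_sub == 0], collapse = ", "))
  res <- list(n_markers = length(markers),
              n_exact_once_per_subgenome = sum(exact_once),
              percent = round_half_away(100 * sum(exact_once) /
                                          length(markers), 0),
              per_subgenome_counts = per_sub)
  if (!is.null(genetic_map)) {
    cm <- stats::setNames(genetic_map$position, genetic_map$marker_id)
    h <- hits[hits$marker_id %in% names(cm), , drop = FALSE]
    res$collinearity <- vapply(split(h, h$chrom), function(hc) {
      if (nrow(hc) < 3) return(NA_real_)
      stats::cor(cm[hc$marker_id], hc$start, method = "spearman")
    }, 0)
  }
  res
}

#' Call S-locus haplotypes from S-RNase and SFB hits
#'
#' Each S-RNase hit is paired with the nearest SFB hit on its chromosome
#' (separation measured between nearest feature edges, 0 when overlapping).
#' The pair is a "full" S-allele call only when both identities are
#' strictly above `min_identity` and the separation is strictly below
#' `max_separation` (tight linkage); otherwise "partial".
#'
#' @param rnase_hits,sfb_hits Data frames: `chrom`, `start`, `end`,
#'   `identity` (fraction in \[0, 1\]), `allele` (query allele name).
#' @param min_identity Identity floor (strict `>`).
#' @param max_separation Linkage distance ceiling in bases (strict `<`).
#' @return Data frame of calls: chromosome, allele names, identities,
#'   separation, and `call` ("full"/"partial").
#' @export
s_locus_call <- function(rnase_hits, sfb_hits, min_identity = 0.90,
                         max_separation = 1e5) {
  rows <- lapply(seq_len(nrow(rnase_hits)), function(i) {
    r <- rnase_hits[i, ]
    s <- sfb_hits[sfb_hits$chrom == r$chrom, , drop = FALSE]
    if (nrow(s) == 0)
      return(data.frame(chrom = r$chrom, rnase_allele = r$allele,
                        rnase_identity = r$identity,
                        sfb_allele = NA_character_,
                        sfb_identity = NA_real_, separation = NA_real_,
                        call = "partial", stringsAsFactors = FALSE))
    gap <- pmax(0, pmax(s$start - r$end, r$start - s$end))
    j <- which.min(gap)
    full <- r$identity > min_identity && s$identity[j] > min_identity &&
      gap[j] < max_separation
    data.frame(chrom = r$chrom, rnase_allele = r$allele,
               rnase_identity = r$identity, sfb_allele = s$allele[j],
               sfb_identity = s$identity[j], separation = gap[j],
               call = if (full) "full" else "partial",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
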