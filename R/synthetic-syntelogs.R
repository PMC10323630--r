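# Gene trees and homology hits for a synthetic genome, so the syntelog
# assignment pipeline (anchor chaining + sister extraction + intersection +
# per-chromosome summary) can run end to end against planted truth.

#' True progenitor origin of every gene copy in a synthetic genome
#'
#' Each subgenome descends from one progenitor (by default A and A' from the
#' fruticosa-like progenitor F, B from the avium-like progenitor V); genes
#' inside an exchanged segment carry the donor subgenome's origin instead.
#'
#' @param genome A `synthetic_genome`.
#' @param progenitor_of Named vector subgenome -> progenitor species code.
#' @return Character vector of progenitor codes, one per `gene_catalog` row.
#' @export
gene_origins <- function(genome, progenitor_of = c(A = "F", Ap = "F",
                                                   B = "V")) {
  cat_ <- genome$gene_catalog
  origin <- progenitor_of[cat_$subgenome]
  ex <- genome$truth_exchanges
  if (!is.null(ex)) {
    for (i in seq_len(nrow(ex))) {
      hit <- cat_$chrom == ex$chrom[i] & cat_$start >= ex$start[i] &
        cat_$end <= ex$end[i]
      origin[hit] <- progenitor_of[[ex$donor[i]]]
    }
  }
  unname(origin)
}

#' Simulate syntelog-pipeline inputs for a synthetic genome
#'
#' For every homoeologous gene group, emits (a) a rooted gene tree in which
#' each subgenome copy is a bootstrap-supported cherry with a copy of its
#' true progenitor's gene (apple outgroup M, peach P outside), and (b) 1:1
#' collinear homology hits between the tetraploid genes and every
#' progenitor gene copy (progenitor copies live on per-copy pseudo
#' chromosomes, rank = gene rank). Exchanged genes pair with the donor's
#' progenitor, so label flips are planted exactly where the exchange is.
#'
#' @param genome A `synthetic_genome`.
#' @param bootstrap Support value on the cherry nodes.
#' @param progenitor_of Named vector subgenome -> progenitor species code.
#' @return List with `trees` (ape multiPhylo), `newick`, `hits` (data
#'   frame for [find_anchors()]), `origin` (per gene), `chrom_of` (named
#'   vector gene -> chromosome).
#' @export
simulate_syntelog_inputs <- function(genome, bootstrap = 95,
                                     progenitor_of = c(A = "F", Ap = "F",
                                                       B = "V")) {
  cat_ <- genome$gene_catalog
  cat_$origin <- gene_origins(genome, progenitor_of)
  newick <- character(0)
  hit_rows <- vector("list", nrow(cat_))
  hi <- 0L

  for (grp in split(cat_, cat_$group_id)) {
    # one progenitor partner copy per focal gene, labeled a, b, c ...
    copy_ix <- stats::ave(seq_len(nrow(grp)), grp$origin, FUN = seq_along)
    ci <- sub("^grp([0-9]+)_.*$", "\\1", grp$group_id[1])
    rank <- grp$rank[1]
    partner <- sprintf("%s_c%s_g%03d%s", grp$origin, ci, rank,
                       letters[copy_ix])
    cherries <- sprintf("(%s:0.01,%s:0.01)%g:0.01", grp$gene_id, partner,
                        bootstrap)
    inner <- cherries[1]
    for (j in seq_along(cherries)[-1])
      inner <- sprintf("(%s,%s)%g:0.01", inner, cherries[j], bootstrap)
    newick <- c(newick, sprintf(
      "(M_c%s_g%03d:0.08,(P_c%s_g%03d:0.04,%s)%g:0.02);",
      ci, rank, ci, rank, inner, bootstrap))

    # collinear 1:1 hits: each focal gene vs every progenitor copy in the
    # group, on per-copy progenitor pseudo-chromosomes
    for (i in seq_len(nrow(grp)))
      for (j in seq_len(nrow(grp))) {
        hi <- hi + 1L
        hit_rows[[hi]] <- data.frame(
          query = grp$gene_id[i], subject = partner[j],
          q_chrom = grp$chrom[i], q_rank = grp$rank[i],
          s_chrom = sprintf("%s_c%s%s", grp$origin[j], ci,
                            letters[copy_ix[j]]),
          s_rank = grp$rank[j], stringsAsFactors = FALSE)
      }
  }
  hits <- do.call(rbind, hit_rows[seq_len(hi)])
  trees <- ape::read.tree(text = newick)
  if (inherits(trees, "phylo"))
    trees <- structure(list(trees), class = "multiPhylo")
  list(trees = trees, newick = newick, hits = hits,
       origin = stats::setNames(cat_$origin, cat_$gene_id),
       chrom_of = stats::setNames(cat_$chrom, cat_$gene_id))
}
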