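# Gene-tree topology classification and census.

#' Classify the sister topology of a focal subgenome in one gene tree
#'
#' After rooting on the outgroup, the focal subgenome tip's sibling clade is
#' inspected: when all sibling tips belong to one species the class is
#' `"<focal>_sister_<species>"` (with the A/A' pair canonicalized to
#' `A_sister_Ap`), otherwise `"other"`.
#'
#' @param tree An ape phylo tree with species-coded tip labels
#'   (`<species>_<gene>`).
#' @param focal Focal subgenome species code (e.g. "A", "Ap", "B").
#' @param outgroup Outgroup species code for rooting unrooted trees.
#' @param subgenome_labels Codes treated as subgenomes when canonicalizing
#'   subgenome-subgenome cherries.
#' @return A class string, or "other" (with a warning when the focal tip is
#'   absent).
#' @export
classify_topology <- function(tree, focal, outgroup = "M",
                              subgenome_labels = c("A", "Ap", "B")) {
  sp <- species_of(tree$tip.label)
  if (!ape::is.rooted(tree)) {
    og <- which(sp == outgroup)
    if (length(og)) {
      tree <- ape::root(tree, outgroup = og[1], resolve.root = TRUE)
      sp <- species_of(tree$tip.label)
    }
  }
  i <- which(sp == focal)
  if (length(i) != 1) {
    warning("focal tip '", focal, "' absent or duplicated; classed as other")
    return("other")
  }
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  sibs <- setdiff(tips_by_node(tree)[[parent[i]]], i)
  sib_sp <- unique(sp[sibs])
  if (length(sib_sp) != 1) return("other")
  pair <- c(focal, sib_sp)
  if (all(pair %in% subgenome_labels))
    pair <- pair[order(match(pair, subgenome_labels))]
  paste0(pair[1], "_sister_", pair[2])
}

#' Census of sister-topology classes over a tree set
#'
#' Counts, per focal subgenome, how often each sister class occurs across
#' the trees. Percentages are 100 x count / n_trees, formatted to the
#' integer except below 10 percent where one decimal is kept (both rounded
#' half away from zero).
#'
#' @param trees A `gene_tree_set`, multiPhylo, or list of phylo trees.
#' @param focal_subgenomes Focal species codes to census.
#' @param outgroup Outgroup species code.
#' @return A `census_table` data frame: focal, class, count, percent
#'   (numeric), percent_formatted (character), n_trees.
#' @export
census <- function(trees, focal_subgenomes = c("A", "Ap", "B"),
                   outgroup = "M") {
  tree_list <- as_tree_list(trees)
  n <- length(tree_list)
  if (n < 1) stop("need at least 1 tree")
  rows <- list()
  for (focal in focal_subgenomes) {
    cls <- vapply(tree_list, classify_topology, "", focal = focal,
                  outgroup = outgroup)
    tab <- table(cls)
    counts <- stats::setNames(as.integer(tab), names(tab))
    for (cl in names(counts)) {
      pct <- 100 * counts[[cl]] / n
      rows[[length(rows) + 1L]] <- data.frame(
        focal = focal, class = cl, count = counts[[cl]],
        percent = if (pct < 10) round_half_away(pct, 1)
                  else round_half_away(pct, 0),
        percent_formatted = if (pct < 10)
          sprintf("%.1f", round_half_away(pct, 1))
        else sprintf("%d", as.integer(round_half_away(pct, 0))),
        n_trees = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("census_table", "data.frame")
  out
}
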