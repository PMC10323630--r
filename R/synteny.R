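# Collinear anchor chaining, bootstrap-supported sister extraction from gene
# trees, and syntelog-based progenitor assignment.

#' Species code of a gene id
#'
#' Tip labels follow `<species>_<gene>`; the species code is the prefix
#' before the first underscore.
#'
#' @param x Character vector of gene ids / tip labels.
#' @return Character vector of species codes.
#' @export
species_of <- function(x) sub("_.*$", "", x)

#' Chain homology hits into collinear anchor runs
#'
#' Maximal-scoring collinear chains are found per chromosome pair by dynamic
#' programming in rank space: within a chain query ranks increase strictly
#' and subject ranks are strictly monotone (increasing for orientation "+",
#' decreasing for "-"), consecutive anchors may be at most `max_gap` ranks
#' apart on either genome, and each gene joins at most one chain per
#' chromosome pair. Chains are extracted best-first until none with
#' `min_anchors` anchors remains.
#'
#' @param hits Data frame with columns `query`, `subject`, `q_chrom`,
#'   `q_rank`, `s_chrom`, `s_rank`, and optionally `score` (default 1 per
#'   hit).
#' @param min_anchors Minimum anchors per reported chain.
#' @param max_gap Maximum rank gap between consecutive anchors.
#' @return List of chains, each a list with `chain_id`, `q_chrom`,
#'   `s_chrom`, `orientation`, `score`, `n_anchors`, `anchors` (data frame).
#' @export
find_anchors <- function(hits, min_anchors = 4L, max_gap = 20L) {
  if (is.null(hits) || nrow(hits) == 0) return(list())
  if (is.null(hits$score)) hits$score <- 1
  chains <- list()
  for (key in unique(paste(hits$q_chrom, hits$s_chrom, sep = "\r"))) {
    part <- strsplit(key, "\r", fixed = TRUE)[[1]]
    h <- hits[hits$q_chrom == part[1] & hits$s_chrom == part[2], ,
              drop = FALSE]
    repeat {
      best <- NULL
      for (orient in c("+", "-")) {
        ch <- best_chain(h, orient, max_gap)
        if (!is.null(ch) && (is.null(best) || ch$score > best$score))
          best <- ch
      }
      if (is.null(best) || nrow(best$anchors) < min_anchors) break
      chains[[length(chains) + 1L]] <- list(
        chain_id = length(chains) + 1L, q_chrom = part[1],
        s_chrom = part[2], orientation = best$orientation,
        score = best$score, n_anchors = nrow(best$anchors),
        anchors = best$anchors)
      used <- h$query %in% best$anchors$query |
        h$subject %in% best$anchors$subject
      h <- h[!used, , drop = FALSE]
      if (nrow(h) == 0) break
    }
  }
  chains
}

# single best collinear chain on one chromosome pair and orientation
best_chain <- function(h, orientation, max_gap) {
  n <- nrow(h)
  if (n == 0) return(NULL)
  ord <- order(h$q_rank, h$s_rank)
  h <- h[ord, , drop = FALSE]
  s_rank <- if (orientation == "+") h$s_rank else -h$s_rank
  dp <- h$score
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (h$q_rank[j] < h$q_rank[i] && s_rank[j] < s_rank[i] &&
          h$q_rank[i] - h$q_rank[j] <= max_gap &&
          s_rank[i] - s_rank[j] <= max_gap &&
          dp[j] + h$score[i] > dp[i]) {
        dp[i] <- dp[j] + h$score[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(dp)
  path <- integer(0)
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  list(orientation = orientation, score = max(dp),
       anchors = h[path, c("query", "subject", "q_rank", "s_rank"),
                   drop = FALSE])
}

#' Extract bootstrap-supported sister relations from gene trees
#'
#' For each focal-subgenome tip, its sibling clade is examined: when every
#' sibling tip belongs to one single progenitor species (a two-tip cherry,
#' or a multi-copy clade of one progenitor) and the joining node's bootstrap
#' support reaches `bsv_min`, a (focal gene, partner gene) relation is
#' emitted per partner tip.
#'
#' @param trees A `gene_tree_set`, ape multiPhylo, or list of phylo trees.
#' @param focal_labels Species codes treated as focal subgenomes.
#' @param progenitor_labels Species codes treated as progenitors.
#' @param bsv_min Minimum bootstrap support (percent).
#' @param outgroup Species code used to root unrooted trees.
#' @return Data frame: tree_id, focal, partner, focal_species,
#'   partner_species, support.
#' @export
extract_sisters <- function(trees, focal_labels = c("A", "Ap", "B"),
                            progenitor_labels = c("F", "V"), bsv_min = 80,
                            outgroup = "M") {
  tree_list <- as_tree_list(trees)
  rows <- list()
  for (ti in seq_along(tree_list)) {
    tr <- tree_list[[ti]]
    if (any(is.na(tr$tip.label)) || any(tr$tip.label == "")) {
      warning("tree ", ti, " has unlabeled tips; skipped")
      next
    }
    sp <- species_of(tr$tip.label)
    if (!ape::is.rooted(tr)) {
      og <- which(sp == outgroup)
      if (length(og) == 0) {
        warning("tree ", ti, " is unrooted and lacks the outgroup; skipped")
        next
      }
      tr <- ape::root(tr, outgroup = og[1], resolve.root = TRUE)
      sp <- species_of(tr$tip.label)
    }
    ntip <- length(tr$tip.label)
    parent <- integer(ntip + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    clade_tips <- tips_by_node(tr)
    for (i in which(sp %in% focal_labels)) {
      pa <- parent[i]
      if (pa == 0L) next
      sibs <- setdiff(clade_tips[[pa]], i)
      sib_sp <- unique(sp[sibs])
      if (length(sibs) == 0 || length(sib_sp) != 1 ||
          !(sib_sp %in% progenitor_labels)) next
      sup <- suppressWarnings(as.numeric(tr$node.label[pa - ntip]))
      if (is.na(sup) || sup < bsv_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = ti, focal = tr$tip.label[i],
        partner = tr$tip.label[sibs],
        focal_species = sp[i], partner_species = sib_sp,
        support = sup, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(tree_id = integer(0), focal = character(0),
                      partner = character(0), focal_species = character(0),
                      partner_species = character(0), support = numeric(0)))
  do.call(rbind, rows)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "gene_tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees
}

# tip sets per node (tips: themselves; internal: via postorder accumulation)
tips_by_node <- function(tr) {
  ntip <- length(tr$tip.label)
  out <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  edges <- tr$edge[ape::postorder(tr), , drop = FALSE]
  for (e in seq_len(nrow(edges)))
    out[[edges[e, 1]]] <- c(out[[edges[e, 1]]], out[[edges[e, 2]]])
  out
}

#' Keep sister relations confirmed by synteny
#'
#' A relation survives when its (focal, partner) gene pair appears as an
#' anchor in some collinear chain (in either orientation of the pair).
#'
#' @param relations Output of [extract_sisters()].
#' @param chains Output of [find_anchors()].
#' @return The syntelog subset of `relations`.
#' @export
intersect_syntelogs <- function(relations, chains) {
  if (nrow(relations) == 0 || length(chains) == 0)
    return(relations[0, , drop = FALSE])
  keys <- unlist(lapply(chains, function(ch)
    c(paste(ch$anchors$query, ch$anchors$subject, sep = "\r"),
      paste(ch$anchors$subject, ch$anchors$query, sep = "\r"))))
  keep <- paste(relations$focal, relations$partner, sep = "\r") %in% keys
  relations[keep, , drop = FALSE]
}

#' Summarize progenitor support per chromosome and subgenome
#'
#' Tallies relations by progenitor label, makes a majority call per
#' chromosome (and per subgenome when a map is supplied), and reports
#' support as a percentage at one decimal. Chromosomes requested but
#' without relations are reported as explicit no-calls.
#'
#' @param relations Data frame from [extract_sisters()] /
#'   [intersect_syntelogs()].
#' @param chrom_of Named vector focal gene id -> chromosome.
#' @param subgenome_of Optional named vector chromosome -> subgenome.
#' @param progenitor_of Named vector partner species code -> progenitor
#'   label.
#' @param chromosomes Optional chromosomes that must appear in the summary
#'   (no-call when without relations).
#' @param gene_positions Optional data frame (`gene_id`, `start`) enabling a
#'   windowed label track.
#' @param window Window size for the label track.
#' @return A `syntelog_assignment` list: `genes`, `per_chromosome`,
#'   `per_subgenome`, `window_track`.
#' @export
assign_and_summarize <- function(relations, chrom_of, subgenome_of = NULL,
                                 progenitor_of = c(F = "fruticosa-like",
                                                   V = "avium-like"),
                                 chromosomes = NULL, gene_positions = NULL,
                                 window = 1e6) {
  genes <- relations
  genes$label <- progenitor_of[genes$partner_species]
  genes$chrom <- chrom_of[genes$focal]
  if (any(is.na(genes$chrom)))
    stop("focal gene missing from the chromosome map")

  summarize <- function(df, unit) {
    tab <- table(df[[unit]], df$label)
    out <- data.frame(unit = rownames(tab), stringsAsFactors = FALSE)
    names(out) <- unit
    out$n <- rowSums(tab)
    out$call <- colnames(tab)[max.col(tab, ties.method = "first")]
    out$n_majority <- apply(tab, 1, max)
    out$support_pct <- round_half_away(100 * out$n_majority / out$n, 1)
    for (lab in colnames(tab)) out[[paste0("n_", lab)]] <- tab[, lab]
    rownames(out) <- NULL
    out
  }

  per_chrom <- summarize(genes, "chrom")
  if (!is.null(chromosomes)) {
    missing <- setdiff(chromosomes, per_chrom$chrom)
    if (length(missing)) {
      pad <- per_chrom[rep(NA_integer_, length(missing)), , drop = FALSE]
      pad$chrom <- missing
      pad$n <- 0L
      pad$call <- "no-call"
      per_chrom <- rbind(per_chrom, pad)
    }
  }

  per_sub <- NULL
  if (!is.null(subgenome_of)) {
    genes$subgenome <- subgenome_of[genes$chrom]
    per_sub <- summarize(genes, "subgenome")
  }

  track <- NULL
  if (!is.null(gene_positions)) {
    pos <- stats::setNames(gene_positions$start, gene_positions$gene_id)
    genes$pos <- pos[genes$focal]
    genes$win <- floor(genes$pos / window)
    track <- summarize(transform(genes,
                                 chrom_win = paste0(chrom, ":", win * window,
                                                    "-", (win + 1) * window)),
                       "chrom_win")
  }

  structure(list(genes = genes, per_chromosome = per_chrom,
                 per_subgenome = per_sub, window_track = track),
            class = "syntelog_assignment")
}
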