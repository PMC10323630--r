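# Synthetic gene-tree sets with planted sister-topology classes, and
# bimodal Ks pair sets.
#
# Species codes used in tip labels (prefix before "_"): M outgroup (apple),
# P peach, V avium-like progenitor, F fruticosa-like progenitor, and the
# three tetraploid subgenomes A, Ap (A') and B.

#' Specification for a synthetic gene-tree set
#'
#' `class_counts` plants exact per-focal-subgenome sister classes; classes
#' for different focal subgenomes are scored independently on the same tree,
#' so e.g. `A_sister_F` and `B_sister_V` counts may overlap (as they do in
#' real single-copy orthogroup censuses).
#'
#' @param n_trees Number of trees.
#' @param class_counts Named counts over
#'   `c("A_sister_F", "Ap_sister_F", "A_sister_Ap", "B_sister_V")`.
#'   The A-side classes must sum to at most `n_trees`; `B_sister_V` must be
#'   at most `n_trees`. Remaining trees realize "other" topologies.
#' @param bootstrap_high Support value placed on internal nodes.
#' @param bootstrap_low Support placed on focal nodes of the first
#'   `low_support_trees` trees.
#' @param low_support_trees Number of trees whose focal nodes get
#'   `bootstrap_low` instead of `bootstrap_high`.
#' @param seed Integer seed (branch-length jitter).
#' @return A `tree_set_spec` list.
#' @export
tree_set_spec <- function(n_trees,
                          class_counts,
                          bootstrap_high = 95,
                          bootstrap_low = 50,
                          low_support_trees = 0L,
                          seed = 1L) {
  known <- c("A_sister_F", "Ap_sister_F", "A_sister_Ap", "B_sister_V")
  if (!all(names(class_counts) %in% known))
    stop("unknown topology class: ",
         paste(setdiff(names(class_counts), known), collapse = ", "))
  cc <- stats::setNames(rep(0L, length(known)), known)
  cc[names(class_counts)] <- as.integer(class_counts)
  a_total <- cc[["A_sister_F"]] + cc[["Ap_sister_F"]] + cc[["A_sister_Ap"]]
  if (a_total > n_trees || cc[["B_sister_V"]] > n_trees)
    stop("class counts exceed n_trees")
  if (bootstrap_high < 0 || bootstrap_high > 100 ||
      bootstrap_low < 0 || bootstrap_low > 100)
    stop("bootstrap values must be in [0, 100]")
  structure(list(n_trees = as.integer(n_trees), class_counts = cc,
                 bootstrap_high = bootstrap_high,
                 bootstrap_low = bootstrap_low,
                 low_support_trees = as.integer(low_support_trees),
                 seed = as.integer(seed)),
            class = "tree_set_spec")
}

#' Simulate gene trees realizing planted sister-topology classes
#'
#' Each tree is a rooted 7-taxon Newick string with bootstrap node labels:
#' apple (M) outgroup, peach (P) sister to the cherry clade, and the cherry
#' clade arranged so the planted A-side class (which of A/A' pairs with F,
#' or A with A') and B-side class (B with V or not) hold exactly.
#'
#' @param spec A [tree_set_spec()].
#' @return A `gene_tree_set`: `trees` (ape multiPhylo), `newick` (character),
#'   `truth` (data frame: tree_id, a_class, b_class).
#' @export
simulate_gene_trees <- function(spec) {
  stopifnot(inherits(spec, "tree_set_spec"))
  n <- spec$n_trees
  cc <- spec$class_counts
  a_seq <- rep(c("A_sister_F", "Ap_sister_F", "A_sister_Ap", "none"),
               c(cc[["A_sister_F"]], cc[["Ap_sister_F"]],
                 cc[["A_sister_Ap"]],
                 n - sum(cc[c("A_sister_F", "Ap_sister_F", "A_sister_Ap")])))
  b_seq <- rep(c("B_sister_V", "none"),
               c(cc[["B_sister_V"]], n - cc[["B_sister_V"]]))

  with_seed(spec$seed, {
    newick <- character(n)
    for (i in seq_len(n)) {
      sup <- if (i <= spec$low_support_trees) spec$bootstrap_low
             else spec$bootstrap_high
      hi <- spec$bootstrap_high
      tip <- function(sp) sprintf("%s_g%d:%.4f", sp, i,
                                  0.01 + stats::runif(1, 0, 0.01))
      cl <- function(x, y, s) sprintf("(%s,%s)%g:%.4f", x, y, s,
                                      0.004 + stats::runif(1, 0, 0.004))
      apart <- switch(a_seq[i],
        A_sister_F  = cl(cl(tip("A"), tip("F"), sup), tip("Ap"), hi),
        Ap_sister_F = cl(cl(tip("Ap"), tip("F"), sup), tip("A"), hi),
        A_sister_Ap = cl(cl(tip("A"), tip("Ap"), sup), tip("F"), hi),
        none = NA)
      if (b_seq[i] == "B_sister_V") {
        bpart <- cl(tip("B"), tip("V"), sup)
        inner <- if (!is.na(apart)) cl(bpart, apart, hi)
                 else cl(cl(cl(bpart, tip("A"), hi), tip("Ap"), hi),
                         tip("F"), hi)
        newick[i] <- sprintf("(%s,(%s,%s)%g:0.02);",
                             tip("M"), tip("P"), inner, hi)
      } else {
        inner <- if (!is.na(apart)) cl(apart, tip("B"), hi)
                 else cl(cl(cl(tip("B"), tip("A"), hi), tip("Ap"), hi),
                         tip("F"), hi)
        newick[i] <- sprintf("(%s,(%s,(%s,%s)%g:0.01)%g:0.02);",
                             tip("M"), tip("P"), tip("V"), inner, hi, hi)
      }
    }
    trees <- ape::read.tree(text = newick)
    if (inherits(trees, "phylo"))
      trees <- structure(list(trees), class = "multiPhylo")
    res <- list(trees = trees, newick = newick,
                truth = data.frame(tree_id = seq_len(n), a_class = a_seq,
                                   b_class = b_seq, stringsAsFactors = FALSE))
    class(res) <- "gene_tree_set"
    res
  })
}

#' Specification for a bimodal Ks pair set
#'
#' Emulates the Ks signature of an allotetraploid: a low-Ks mode from
#' homologous (within-subgenome) pairs and a higher mode from homoeologous
#' pairs. Components are lognormal with the stated modes.
#'
#' @param n_pairs Number of gene pairs.
#' @param mode_1,mode_2 Ks at the two component modes.
#' @param dispersions Lognormal sdlog per component (length 2, positive).
#' @param weight_1 Mixture weight of component 1, in \[0, 1\].
#' @param seed Integer seed.
#' @return A `ks_mixture_spec` list.
#' @export
ks_mixture_spec <- function(n_pairs, mode_1 = 0.003, mode_2 = 0.022,
                            dispersions = c(0.35, 0.35), weight_1 = 0.5,
                            seed = 1L) {
  stopifnot(mode_1 >= 0, mode_2 >= 0, weight_1 >= 0, weight_1 <= 1,
            all(dispersions > 0), length(dispersions) == 2)
  structure(list(n_pairs = as.integer(n_pairs), mode_1 = mode_1,
                 mode_2 = mode_2, dispersions = dispersions,
                 weight_1 = weight_1, seed = as.integer(seed)),
            class = "ks_mixture_spec")
}

#' Simulate Ks records from a two-component positive mixture
#'
#' A lognormal with mode m and sdlog s has meanlog `log(m) + s^2`, so each
#' component's density peaks at its stated mode.
#'
#' @param spec A [ks_mixture_spec()].
#' @return Data frame with columns `pair_id`, `component`, `ka`, `ks`.
#' @export
simulate_ks_pairs <- function(spec) {
  stopifnot(inherits(spec, "ks_mixture_spec"))
  n <- spec$n_pairs
  if (n == 0)
    return(data.frame(pair_id = character(0), component = integer(0),
                      ka = numeric(0), ks = numeric(0)))
  n1 <- round(spec$weight_1 * n)
  with_seed(spec$seed, {
    s <- spec$dispersions
    ks <- c(stats::rlnorm(n1, log(spec$mode_1) + s[1]^2, s[1]),
            stats::rlnorm(n - n1, log(spec$mode_2) + s[2]^2, s[2]))
    data.frame(pair_id = sprintf("pair_%06d", seq_len(n)),
               component = rep(c(1L, 2L), c(n1, n - n1)),
               ka = ks * stats::runif(n, 0.2, 0.5), ks = ks,
               stringsAsFactors = FALSE)
  })
}
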