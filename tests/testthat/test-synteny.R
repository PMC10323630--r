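# Anchor chaining, sister extraction, syntelog intersection, summaries.

perfect_hits <- function(n = 12) {
  data.frame(query = sprintf("A_g%02d", 1:n), subject = sprintf("F_g%02d", 1:n),
             q_chrom = "qc", q_rank = 1:n, s_chrom = "sc", s_rank = 1:n,
             stringsAsFactors = FALSE)
}

test_that("perfectly collinear hits chain into one forward run", {
  ch <- find_anchors(perfect_hits())
  expect_length(ch, 1)
  expect_equal(ch[[1]]$orientation, "+")
  expect_equal(ch[[1]]$n_anchors, 12)
  expect_length(find_anchors(perfect_hits()[0, ]), 0)
})

test_that("a central inversion yields an extra reversed chain", {
  h <- perfect_hits(30)
  inv <- 11:20
  h$s_rank[inv] <- rev(h$s_rank[inv])
  ch <- find_anchors(h, min_anchors = 4, max_gap = 20)
  expect_gte(length(ch), 2)
  expect_true("-" %in% vapply(ch, `[[`, "", "orientation"))
  # every anchor of the reversed chain comes from the inverted block
  rev_ch <- ch[[which(vapply(ch, `[[`, "", "orientation") == "-")[1]]]
  expect_true(all(rev_ch$anchors$q_rank %in% inv))
})

test_that("chain scores match the exhaustive oracle on small instances", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(6:12, 1)
    h <- data.frame(query = paste0("q", 1:n), subject = paste0("s", 1:n),
                    q_chrom = "qc", q_rank = sample(30, n),
                    s_chrom = "sc", s_rank = sample(30, n),
                    score = sample(1:3, n, replace = TRUE),
                    stringsAsFactors = FALSE)
    ch <- find_anchors(h, min_anchors = 1, max_gap = 10)
    got <- max(vapply(ch, `[[`, 0, "score"))
    expect_equal(got, oracle_best_chain_score(h, max_gap = 10))
  }
})

test_that("chaining is invariant to shuffling the input hits", {
  set.seed(23)
  h <- perfect_hits(20)
  h$s_rank[6:9] <- rev(h$s_rank[6:9])
  ch1 <- find_anchors(h)
  ch2 <- find_anchors(h[sample(nrow(h)), ])
  key <- function(ch) sort(vapply(ch, function(x)
    paste(sort(paste(x$anchors$query, x$anchors$subject)), collapse = ";"),
    ""))
  expect_identical(key(ch1), key(ch2))
})

test_that("sister extraction reads cherries at the bootstrap threshold", {
  nw <- paste0("((A_g1:0.01,F_g1:0.01)95:0.01,",
               "((B_g1:0.01,V_g1:0.01)99:0.01,P_g1:0.03)90:0.01);")
  tr <- ape::read.tree(text = nw)
  rel <- extract_sisters(list(tr), focal_labels = c("A", "Ap", "B"),
                         progenitor_labels = c("F", "V"))
  expect_equal(nrow(rel), 2)
  expect_setequal(paste(rel$focal, rel$partner, rel$support),
                  c("A_g1 F_g1 95", "B_g1 V_g1 99"))
  # support 79 on the cherry: excluded at the default threshold 80
  tr79 <- ape::read.tree(text = sub("95", "79", nw, fixed = TRUE))
  rel79 <- extract_sisters(list(tr79), focal_labels = c("A", "Ap", "B"),
                           progenitor_labels = c("F", "V"))
  expect_false("A_g1" %in% rel79$focal)
  # raising the threshold shrinks output monotonically
  rel90 <- extract_sisters(list(tr), focal_labels = c("A", "Ap", "B"),
                           progenitor_labels = c("F", "V"), bsv_min = 96)
  expect_true(all(rel90$focal %in% rel$focal))
  expect_true(all(rel90$support >= 96))
})

test_that("sister extraction agrees with the MRCA-matrix oracle", {
  set.seed(41)
  species <- c("M", "P", "V", "F", "A", "Ap", "B")
  for (rep in 1:25) {
    tr <- ape::rtree(7, tip.label = paste0(sample(species), "_g1"))
    tr$node.label <- as.character(sample(50:100, tr$Nnode))
    rel <- extract_sisters(list(tr), focal_labels = c("A", "Ap", "B"),
                           progenitor_labels = c("F", "V"), bsv_min = 0)
    for (focal in c("A", "Ap", "B")) {
      tip <- paste0(focal, "_g1")
      o <- oracle_sisters_of_tip(tr, tip)
      osp <- unique(species_of(o$siblings))
      expected <- length(osp) == 1 && osp %in% c("F", "V")
      got <- rel[rel$focal == tip, , drop = FALSE]
      expect_equal(nrow(got) > 0, expected, label = ape::write.tree(tr))
      if (expected && nrow(got))
        expect_setequal(got$partner, o$siblings)
    }
  }
})

test_that("syntelog intersection equals set intersection of pair keys", {
  rel <- data.frame(tree_id = 1:4,
                    focal = c("A_g1", "A_g2", "B_g1", "B_g2"),
                    partner = c("F_g1", "F_g2", "V_g1", "V_g2"),
                    focal_species = c("A", "A", "B", "B"),
                    partner_species = c("F", "F", "V", "V"),
                    support = 95, stringsAsFactors = FALSE)
  chains <- list(list(anchors = data.frame(
    query = c("A_g1", "V_g2"), subject = c("F_g1", "B_g2"),
    q_rank = 1:2, s_rank = 1:2)))
  out <- intersect_syntelogs(rel, chains)
  # kept: directly present, and present with roles swapped
  expect_setequal(out$focal, c("A_g1", "B_g2"))
  expect_equal(nrow(intersect_syntelogs(rel, list())), 0)

  set.seed(19)
  for (rep in 1:10) {
    keep <- sample(4, sample(0:4, 1))
    chains <- list(list(anchors = data.frame(
      query = rel$focal[keep], subject = rel$partner[keep],
      q_rank = seq_along(keep), s_rank = seq_along(keep))))
    expect_setequal(intersect_syntelogs(rel, chains)$focal, rel$focal[keep])
  }
})

test_that("progenitor summaries reproduce printed support percentages", {
  mk_rel <- function(n_f, n_v, chrom) data.frame(
    tree_id = seq_len(n_f + n_v),
    focal = sprintf("%s_g%05d", chrom, seq_len(n_f + n_v)),
    partner = "x", focal_species = "A",
    partner_species = rep(c("F", "V"), c(n_f, n_v)),
    support = 95, stringsAsFactors = FALSE)
  relA <- mk_rel(6664, 6739 - 6664, "cA")
  relAp <- mk_rel(6957, 6984 - 6957, "cAp")
  relB <- mk_rel(10370 - 10245, 10245, "cB")
  rel <- rbind(relA, relAp, relB)
  chrom_of <- stats::setNames(sub("_g.*", "", rel$focal), rel$focal)
  asg <- assign_and_summarize(rel, chrom_of)
  pc <- asg$per_chromosome
  expect_equal(pc$support_pct[pc$chrom == "cA"], 98.9)
  expect_equal(pc$call[pc$chrom == "cA"], "fruticosa-like")
  expect_equal(pc$support_pct[pc$chrom == "cAp"], 99.6)
  expect_equal(pc$support_pct[pc$chrom == "cB"], 98.8)
  expect_equal(pc$call[pc$chrom == "cB"], "avium-like")

  uni <- assign_and_summarize(relA[1:50, ], chrom_of)
  expect_equal(uni$per_chromosome$support_pct, 100)
  # requested chromosome without relations: explicit no-call
  nc <- assign_and_summarize(relA, chrom_of, chromosomes = c("cA", "cZ"))
  expect_equal(nc$per_chromosome$call[nc$per_chromosome$chrom == "cZ"],
               "no-call")
})
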