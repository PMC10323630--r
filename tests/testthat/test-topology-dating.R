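# Topology classification, census arithmetic, penalized-likelihood dating.

test_that("topology classes read off the focal tip's sibling clade", {
  t1 <- ape::read.tree(text =
    "(M_1:1,(P_1:1,((B_1:1,V_1:1):1,((A_1:1,F_1:1):1,Ap_1:1):1):1):1);")
  expect_equal(classify_topology(t1, "A"), "A_sister_F")
  expect_equal(classify_topology(t1, "B"), "B_sister_V")
  expect_equal(classify_topology(t1, "Ap"), "other")
  t2 <- ape::read.tree(text =
    "(M_1:1,(P_1:1,((B_1:1,V_1:1):1,((A_1:1,Ap_1:1):1,F_1:1):1):1):1);")
  expect_equal(classify_topology(t2, "A"), "A_sister_Ap")
  expect_equal(classify_topology(t2, "Ap"), "A_sister_Ap")
  expect_warning(got <- classify_topology(t2, "Z"), "absent")
  expect_equal(got, "other")
})

test_that("classification agrees with the MRCA-matrix oracle on random trees", {
  set.seed(13)
  species <- c("M", "P", "V", "F", "A", "Ap", "B")
  subg <- c("A", "Ap", "B")
  for (rep in 1:40) {
    tr <- ape::rtree(7, tip.label = paste0(sample(species), "_1"))
    for (focal in subg) {
      o <- oracle_sisters_of_tip(tr, paste0(focal, "_1"))
      osp <- unique(species_of(o$siblings))
      expected <- if (length(osp) == 1) {
        pair <- c(focal, osp)
        if (all(pair %in% subg)) pair <- pair[order(match(pair, subg))]
        paste0(pair[1], "_sister_", pair[2])
      } else "other"
      expect_equal(classify_topology(tr, focal), expected,
                   label = ape::write.tree(tr))
    }
  }
})

test_that("census percentages follow the <10% one-decimal formatting rule", {
  gt <- simulate_gene_trees(tree_set_spec(
    336, c(A_sister_F = 142, Ap_sister_F = 165, A_sister_Ap = 6,
           B_sister_V = 310)))
  cen <- census(gt)
  pick <- function(f, cl) cen[cen$focal == f & cen$class == cl, ]
  expect_equal(pick("A", "A_sister_F")$percent_formatted, "42")
  expect_equal(pick("Ap", "Ap_sister_F")$percent_formatted, "49")
  expect_equal(pick("A", "A_sister_Ap")$percent_formatted, "1.8")
  expect_equal(pick("B", "B_sister_V")$percent_formatted, "92")
  # per-focal counts are exhaustive
  for (f in c("A", "Ap", "B"))
    expect_equal(sum(cen$count[cen$focal == f]), 336)

  one_class <- simulate_gene_trees(tree_set_spec(5, c(B_sister_V = 5)))
  cb <- census(one_class, focal_subgenomes = "B")
  expect_equal(cb$percent[cb$class == "B_sister_V"], 100)
})

test_that("strict-clock ages are recovered exactly at any smoothing", {
  tr <- clock_tree()
  cal <- clock_calibration()
  for (lam in c(0.1, 1, 10)) {
    d <- pl_date(tr, n_sites = 1e5, cal, lambda = lam, n_starts = 3,
                 seed = 1)
    ages <- sort(unname(d$ages))
    expect_lt(max(abs(ages - c(2, 10, 30, 95))), 1e-6 * 95)
    # clock limit: all rates equal
    expect_lt(max(d$rates) / min(d$rates), 1 + 1e-4)
  }
})

test_that("huge smoothing drives all rates to a common value", {
  tr <- clock_tree()
  # perturb lengths so the data are not clock-like
  set.seed(3)
  tr$edge.length <- tr$edge.length * exp(stats::rnorm(length(tr$edge.length),
                                                      0, 0.3))
  d <- pl_date(tr, 1e5, clock_calibration(), lambda = 1e6, n_starts = 3,
               seed = 1)
  expect_lt(max(d$rates) / min(d$rates), 1.01)
})

test_that("two-rate trees are dated within 10% given bracketing calibrations", {
  nw <- "(((((A_1:2,B_1:2):2,C_1:4):4,D_1:8):12,E_1:20):75,F_1:95);"
  tr <- ape::read.tree(text = nw)
  mrca <- ape::getMRCA(tr, c("A_1", "B_1", "C_1", "D_1"))
  # fast clade: the MRCA's stem edge and everything below it
  below <- function(node) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    c(kids, unlist(lapply(kids, below)))
  }
  fast_nodes <- c(mrca, below(mrca))
  tr$edge.length <- tr$edge.length *
    ifelse(tr$edge[, 2] %in% fast_nodes, 3 * 0.002, 0.002)
  cal <- calibration_set(list(tr$tip.label, c("A_1", "B_1", "C_1", "D_1"),
                              c("A_1", "B_1", "C_1", "D_1", "E_1")),
                         c("fixed", "fixed", "fixed"), c(95, 8, 20))
  d <- pl_date(tr, 1e5, cal, lambda = 1, n_starts = 5, seed = 1)
  est <- d$ages[c("A_1|B_1", "A_1|B_1|C_1")]
  expect_lt(max(abs(est - c(2, 4)) / c(2, 4)), 0.10)
  expect_equal(max(d$rates) / min(d$rates), 3, tolerance = 0.05)
})

test_that("the optimizer matches a grid-search oracle on a 4-tip tree", {
  tr <- ape::read.tree(text = "(((A_1:2,B_1:2):8,C_1:10):85,D_1:95);")
  # two-rate: cherry tip edges 3x
  cherry_tips <- match(c("A_1", "B_1"), tr$tip.label)
  tr$edge.length <- tr$edge.length *
    ifelse(tr$edge[, 2] %in% cherry_tips, 3 * 0.002, 0.002)
  cal <- calibration_set(list(tr$tip.label), "fixed", 95)
  d <- pl_date(tr, 1e4, cal, lambda = 1, n_starts = 5, seed = 1)

  ntip <- 4L
  grid1 <- seq(0.5, 20, by = 0.5)
  grid2 <- seq(1, 90, by = 1)
  best <- c(NA, NA); best_val <- Inf
  for (t2 in grid2) for (t1 in grid1[grid1 < t2]) {
    ages <- numeric(ntip + tr$Nnode)
    ages[ntip + 1L] <- 95
    ages[ape::getMRCA(tr, c("A_1", "B_1", "C_1"))] <- t2
    ages[ape::getMRCA(tr, c("A_1", "B_1"))] <- t1
    v <- oracle_pl_objective(tr, 1e4, lambda = 1, ages)
    if (v < best_val) { best_val <- v; best <- c(t1, t2) }
  }
  expect_lt(abs(d$ages[["A_1|B_1"]] - best[1]), 0.5)
  expect_lt(abs(d$ages[["A_1|B_1|C_1"]] - best[2]), 1)
  # the fitted ages score at least as well as the grid's best under the
  # oracle's own objective evaluation
  fit_ages <- numeric(ntip + tr$Nnode)
  fit_ages[ntip + 1L] <- 95
  fit_ages[ape::getMRCA(tr, c("A_1", "B_1", "C_1"))] <-
    d$ages[["A_1|B_1|C_1"]]
  fit_ages[ape::getMRCA(tr, c("A_1", "B_1"))] <- d$ages[["A_1|B_1"]]
  expect_lte(oracle_pl_objective(tr, 1e4, lambda = 1, fit_ages),
             best_val + 1e-6)
})

test_that("age estimates are invariant to consistent rescaling of sites", {
  tr <- clock_tree()
  set.seed(9)
  tr$edge.length <- tr$edge.length * exp(stats::rnorm(8, 0, 0.2))
  cal <- clock_calibration()
  d1 <- pl_date(tr, 1e5, cal, lambda = 1, n_starts = 3, seed = 1)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length / 10
  d2 <- pl_date(tr2, 1e6, cal, lambda = 1, n_starts = 3, seed = 1)
  expect_equal(unname(d1$ages), unname(d2$ages), tolerance = 1e-3)
})

test_that("calibration handling rejects infeasible sets and honors minima", {
  tr <- clock_tree()
  bad <- calibration_set(list(tr$tip.label, c("A_1", "B_1")),
                         c("fixed", "min"), c(95, 200))
  expect_error(pl_date(tr, 1e5, bad), "infeasible")
  no_root <- calibration_set(list(c("A_1", "B_1")), "min", 5)
  expect_error(pl_date(tr, 1e5, no_root), "root")
  # a binding minimum holds the node at the bound
  cal <- calibration_set(list(tr$tip.label, c("A_1", "B_1")),
                         c("fixed", "min"), c(95, 5))
  d <- pl_date(tr, 1e5, cal, lambda = 1, n_starts = 3, seed = 1)
  expect_gte(d$ages[["A_1|B_1"]], 5 - 1e-9)
})

test_that("bootstrap age summaries behave on identical and noisy replicates", {
  tr <- clock_tree()
  cal <- clock_calibration()
  same <- list(tr, tr, tr)
  bs <- bootstrap_ages(same, cal, n_sites = 1e5, lambda = 1, n_starts = 1)
  expect_equal(bs$summary$upper - bs$summary$lower, rep(0, 4),
               tolerance = 1e-4)
  expect_equal(bs$summary$mean, unname(colMeans(bs$ages)))
  expect_equal(bs$n_failed, 0)
  expect_error(bootstrap_ages(list(tr), cal, 1e5), "fewer than 2")
})
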