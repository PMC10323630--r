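# Differential k-mer phasing: counting, filtering, clustering, densities.

test_that("k-mer counting matches its definition and a brute-force oracle", {
  m <- count_kmers(c(chr1 = "AAAA"), k = 3, canonical = TRUE)
  expect_equal(unname(m$counts["AAA", "chr1"]), 2)

  set.seed(42)
  s <- random_dna(500)
  both <- count_kmers(c(fwd = s, rev = as.character(revcomp(s))), k = 7,
                      canonical = TRUE)
  expect_equal(unname(both$counts[, "fwd"]), unname(both$counts[, "rev"]))

  seqs <- c(a = random_dna(1000), b = random_dna(800))
  m <- count_kmers(seqs, k = 9, canonical = TRUE)
  om <- oracle_count_kmers(seqs, k = 9, canonical = TRUE)
  expect_identical(m$counts[order(rownames(m$counts)), , drop = FALSE],
                   om[order(rownames(om)), , drop = FALSE])

  # N breaks the window
  m <- count_kmers(c(x = "AANAA"), k = 2, canonical = FALSE)
  expect_equal(sum(m$counts), 2)
  expect_warning(count_kmers(c(x = "ACGT"), k = 10), "shortest")
})

test_that("differential filter applies floor and fold rules exactly", {
  mk <- function(counts) {
    m <- matrix(counts, nrow = 1,
                dimnames = list("A", c("c1A", "c1Ap", "c1B")))
    structure(list(counts = m, k = 1L, canonical = TRUE),
              class = "kmer_count_matrix")
  }
  gm <- c(c1A = "s1", c1Ap = "s1", c1B = "s1")
  # count 9 somewhere: removed even if differential elsewhere
  expect_equal(nrow(differential_filter(mk(c(9, 40, 80)), gm)$counts), 0)
  # equal on all sisters: fold condition unsatisfiable
  expect_equal(nrow(differential_filter(mk(c(40, 40, 40)), gm)$counts), 0)
  # (40, 40, 15): all >= 10 and 40 >= 2 x 15 on at least one sister
  expect_equal(nrow(differential_filter(mk(c(40, 40, 15)), gm)$counts), 1)
  # all-sisters mode is stricter: 40 vs sisters (40, 15) fails
  expect_equal(nrow(differential_filter(mk(c(40, 40, 15)), gm,
                                        all_sisters = TRUE)$counts), 0)
  expect_error(differential_filter(mk(c(40, 40, 15)), c(c1A = "s1")),
               "missing")
})

test_that("differential filter output is a monotone subset of its input", {
  m <- small_kmer_matrix()
  gm <- homoeolog_map_of(small_genome())
  f1 <- differential_filter(m, gm, min_count = 10, fold = 2)
  expect_true(all(rownames(f1$counts) %in% rownames(m$counts)))
  f2 <- differential_filter(m, gm, min_count = 20, fold = 2)
  f3 <- differential_filter(m, gm, min_count = 10, fold = 3)
  expect_true(all(rownames(f2$counts) %in% rownames(f1$counts)))
  expect_true(all(rownames(f3$counts) %in% rownames(f1$counts)))
})

test_that("chromosome clustering recovers planted subgenomes (ARI = 1)", {
  g <- small_genome()
  mf <- differential_filter(small_kmer_matrix(), homoeolog_map_of(g))
  cl <- cluster_chromosomes(mf, n_groups = 3)
  expect_equal(adjusted_rand_index(cl$labels,
                                   g$truth_subgenome[names(cl$labels)]), 1)
  # identical columns merge at height 0
  m2 <- structure(list(counts = cbind(a = c(5L, 9L), b = c(5L, 9L),
                                      c = c(50L, 2L)),
                       k = 1L, canonical = TRUE),
                  class = "kmer_count_matrix")
  rownames(m2$counts) <- c("A", "C")
  hc <- cluster_chromosomes(m2)$hclust
  expect_equal(hc$height[1], 0)
  expect_error(cluster_chromosomes(mf, n_groups = 10), "more groups")
})

test_that("excluding chimeric chromosomes sharpens the 3-way separation", {
  g <- small_genome()
  # chimeras: halves of an A and a B chromosome glued together
  half <- nchar(g$sequences[["chr1A"]]) %/% 2
  chim1 <- paste0(substr(g$sequences[["chr1A"]], 1, half),
                  substr(g$sequences[["chr1B"]], half + 1, 3e5))
  chim2 <- paste0(substr(g$sequences[["chr2B"]], 1, half),
                  substr(g$sequences[["chr2A"]], half + 1, 3e5))
  seqs <- c(g$sequences, chim1 = chim1, chim2 = chim2)
  m <- count_kmers(seqs, k = 25, min_count = 10)
  gm <- c(homoeolog_map_of(g), chim1 = "set1", chim2 = "set2")
  mf <- differential_filter(m, gm)
  with_chim <- cluster_chromosomes(mf, n_groups = 3)$silhouette
  keep <- setdiff(colnames(mf$counts), c("chim1", "chim2"))
  mf2 <- mf
  mf2$counts <- mf2$counts[, keep]
  without <- cluster_chromosomes(mf2, n_groups = 3)$silhouette
  expect_gt(without, with_chim)
})

test_that("k-mer groups partition planted repeat families", {
  g <- small_genome()
  mf <- differential_filter(small_kmer_matrix(), homoeolog_map_of(g))
  cl <- cluster_kmers(mf, n_groups = 3)
  # family of origin of each differential k-mer, from the monomers
  fam_of <- function(kmer) {
    hits <- vapply(g$monomers[c("A", "Ap", "B")], function(mono) {
      dimer <- paste0(mono, mono)  # tandem context wraps around
      grepl(kmer, dimer, fixed = TRUE) ||
        grepl(as.character(revcomp(kmer)), dimer, fixed = TRUE)
    }, TRUE)
    if (sum(hits) == 1) names(hits)[hits] else NA_character_
  }
  fams <- vapply(rownames(mf$counts), fam_of, "")
  grp <- cl$assignment[!is.na(fams)]
  expect_equal(adjusted_rand_index(grp, fams[!is.na(fams)]), 1)

  # permutation invariance up to relabeling
  perm <- sample(nrow(mf$counts))
  mfp <- mf
  mfp$counts <- mfp$counts[perm, ]
  clp <- cluster_kmers(mfp, n_groups = 3)
  expect_equal(adjusted_rand_index(cl$assignment[rownames(mf$counts)],
                                   clp$assignment[rownames(mf$counts)]), 1)

  single <- structure(list(counts = matrix(5L, 1, 2,
                                           dimnames = list("A", c("x", "y"))),
                           k = 1L, canonical = TRUE),
                      class = "kmer_count_matrix")
  expect_length(cluster_kmers(single, 1)$groups, 1)
})

test_that("density profiles follow the occupancy formula and conserve mass", {
  # 400 planted 25-mer occurrences in one 1 Mb window -> 0.01
  set.seed(7)
  kmer <- "ACGTACGTTGCAACGTACGTTGCAG"
  expect_equal(nchar(kmer), 25)
  bases <- sample(c("A", "C"), 1.2e6, replace = TRUE)  # no G/T: no false hits
  starts <- (0:399) * 2000
  for (st in starts)
    bases[(st + 1):(st + 25)] <- strsplit(kmer, "")[[1]]
  seqv <- paste(bases, collapse = "")
  tr <- density_profile(kmer, seqv, chrom = "c", window = 1e6)
  expect_equal(tr$value[1], 400 * 25 / 1e6)
  # conservation: sum(value x window length) = k x occurrences
  expect_equal(sum(tr$value * (tr$end - tr$start)), 25 * 400)
  # trailing short window normalized by its true length
  expect_equal(tr$end[nrow(tr)] - tr$start[nrow(tr)], 2e5)
  expect_true(all(tr$value >= 0 & tr$value <= 1))
  # empty group: all-zero track
  tr0 <- density_profile(character(0), seqv, window = 1e6)
  expect_true(all(tr0$value == 0))
})

test_that("centromeres are recovered from gene/TE density contrast", {
  g <- small_genome()
  chrom <- "chr1A"
  L <- nchar(g$sequences[[chrom]])
  win <- 1e4
  genes <- g$gene_catalog[g$gene_catalog$chrom == chrom, ]
  reps <- g$repeat_catalog[g$repeat_catalog$chrom == chrom, ]
  gt <- interval_density(genes, L, chrom, window = win)
  tt <- interval_density(reps, L, chrom, window = win)
  est <- estimate_centromere(gt, tt)
  expect_false(est$undefined)
  cen <- g$truth_centromere[g$truth_centromere$chrom == chrom, ]
  inter <- max(0, min(est$end, cen$end) - max(est$start, cen$start))
  union <- (est$end - est$start) + (cen$end - cen$start) - inter
  expect_gte(inter / union, 0.5)

  # the differential k-mer density peak lies inside the estimated run
  mf <- differential_filter(small_kmer_matrix(), homoeolog_map_of(g))
  cl <- cluster_kmers(mf, n_groups = 3)
  own <- which.max(vapply(cl$groups, function(ks)
    mean(mf$counts[ks, chrom]), 0))
  dens <- density_profile(cl$groups[[own]], g$sequences[[chrom]],
                          chrom, window = win)
  peak_win <- dens[which.max(dens$value), ]
  expect_gte(peak_win$start, est$start)
  expect_lte(peak_win$end, est$end)

  flat <- gt
  flat$value <- rep(0.5, nrow(flat))
  expect_true(estimate_centromere(flat, flat)$undefined)
})
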