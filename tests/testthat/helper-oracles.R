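# Independent brute-force oracles. Each is written from the operation's
# definition with a different algorithmic route than the implementation it
# checks, and is only run on small instances.

# --- k-mer counting: naive sliding-window dictionary ---------------------
oracle_count_kmers <- function(sequences, k, canonical = TRUE) {
  tabs <- lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    words <- substring(s, 1:(n - k + 1), k:n)
    words <- words[grepl("^[ACGT]+$", words)]
    if (canonical) words <- canonical_kmer(words)
    table(words)
  })
  kmers <- sort(unique(unlist(lapply(tabs, names))))
  m <- sapply(tabs, function(tb) {
    v <- stats::setNames(rep(0L, length(kmers)), kmers)
    v[names(tb)] <- as.integer(tb)
    v
  })
  matrix(m, nrow = length(kmers), ncol = length(sequences),
         dimnames = list(kmers, names(sequences)))
}

# --- read pileup: regex search over every position -----------------------
oracle_pileup <- function(chroms, reads) {
  depth <- lapply(chroms, function(s) numeric(nchar(s)))
  find_all <- function(pat, s) {
    hits <- integer(0)
    from <- 1
    repeat {
      p <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
      if (p < 0) break
      hits <- c(hits, from + p - 1)
      from <- from + p
    }
    hits
  }
  for (r in reads) {
    pats <- unique(c(r, as.character(revcomp(r))))
    matches <- list()
    for (cn in names(chroms))
      for (pat in pats)
        for (st in find_all(pat, chroms[[cn]]))
          matches[[length(matches) + 1]] <- c(cn, st)
    if (length(matches) == 0) next
    w <- 1 / length(matches)
    for (m in matches) {
      st <- as.integer(m[2])
      depth[[m[1]]][st:(st + nchar(r) - 1)] <-
        depth[[m[1]]][st:(st + nchar(r) - 1)] + w
    }
  }
  depth
}

# --- collinear chaining: exhaustive subset search (n <= 15) --------------
oracle_best_chain_score <- function(hits, max_gap) {
  if (is.null(hits$score)) hits$score <- 1
  n <- nrow(hits)
  best <- 0
  extend <- function(idx, score) {
    best <<- max(best, score)
    last <- idx[length(idx)]
    for (j in seq_len(n)) {
      ok_plus <- hits$q_rank[j] > hits$q_rank[last] &&
        hits$s_rank[j] > hits$s_rank[last] &&
        hits$q_rank[j] - hits$q_rank[last] <= max_gap &&
        hits$s_rank[j] - hits$s_rank[last] <= max_gap
      if (ok_plus) extend(c(idx, j), score + hits$score[j])
    }
  }
  for (i in seq_len(n)) extend(i, hits$score[i])
  # orientation "-": flip subject ranks and rerun
  hits2 <- hits
  hits2$s_rank <- -hits2$s_rank
  best_minus <- 0
  extend2 <- function(idx, score) {
    best_minus <<- max(best_minus, score)
    last <- idx[length(idx)]
    for (j in seq_len(n)) {
      if (hits2$q_rank[j] > hits2$q_rank[last] &&
          hits2$s_rank[j] > hits2$s_rank[last] &&
          hits2$q_rank[j] - hits2$q_rank[last] <= max_gap &&
          hits2$s_rank[j] - hits2$s_rank[last] <= max_gap)
        extend2(c(idx, j), score + hits2$score[j])
    }
  }
  for (i in seq_len(n)) extend2(i, hits2$score[i])
  max(best, best_minus)
}

# --- sister clades: via the MRCA matrix ----------------------------------
# sibling tips of tip i = the tips j whose MRCA with i is deepest
oracle_sisters_of_tip <- function(tree, tip_label) {
  i <- match(tip_label, tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree)
  others <- setdiff(seq_along(tree$tip.label), i)
  d <- depths[mr[i, others]]
  sib <- others[d == max(d)]
  node <- mr[i, sib[1]]
  sup <- suppressWarnings(
    as.numeric(tree$node.label[node - length(tree$tip.label)]))
  list(siblings = tree$tip.label[sib], node = node, support = sup)
}

# --- NG86: independent implementation on Biostrings' codon table ---------
.oracle_ng86_env <- new.env(parent = emptyenv())

oracle_codon_table <- function() {
  if (!exists("tab", envir = .oracle_ng86_env)) {
    stopifnot(requireNamespace("Biostrings", quietly = TRUE))
    assign("tab", Biostrings::GENETIC_CODE, envir = .oracle_ng86_env)
  }
  get("tab", envir = .oracle_ng86_env)
}

oracle_syn_sites_seq <- function(seq) {
  tab <- oracle_codon_table()
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  total <- 0
  for (codon in codons) {
    for (p in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(codon, p, p)) next
        alt <- paste0(substr(codon, 1, p - 1), b, substr(codon, p + 1, 3))
        if (tab[[alt]] == "*") next
        if (tab[[alt]] == tab[[codon]]) total <- total + 1 / 3
      }
    }
  }
  total
}

# all permutations of 1..n, generated recursively
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1))
    for (k in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
  out
}

oracle_ng86 <- function(seq1, seq2) {
  tab <- oracle_codon_table()
  c1 <- substring(seq1, seq(1, nchar(seq1), 3), seq(3, nchar(seq1), 3))
  c2 <- substring(seq2, seq(1, nchar(seq2), 3), seq(3, nchar(seq2), 3))
  ok <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2) &
    tab[c1] != "*" & tab[c2] != "*"
  c1 <- c1[ok]; c2 <- c2[ok]
  S <- (oracle_syn_sites_seq(paste(c1, collapse = "")) +
        oracle_syn_sites_seq(paste(c2, collapse = ""))) / 2
  N <- 3 * length(c1) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    pos <- which(strsplit(c1[i], "")[[1]] != strsplit(c2[i], "")[[1]])
    if (length(pos) == 0) next
    walk <- function(order_idx, allow_stop) {
      cur <- c1[i]; sd <- 0; nd <- 0
      for (p in pos[order_idx]) {
        nxt <- paste0(substr(cur, 1, p - 1), substr(c2[i], p, p),
                      substr(cur, p + 1, 3))
        if (!allow_stop && tab[[nxt]] == "*") return(NULL)
        if (tab[[nxt]] == tab[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null),
                  lapply(oracle_perms(length(pos)), walk, allow_stop = FALSE))
    if (length(res) == 0)
      res <- lapply(oracle_perms(length(pos)), walk, allow_stop = TRUE)
    avg <- Reduce(`+`, res) / length(res)
    Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
  }
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       ks = jc(ps), ka = jc(pn))
}

# random coding-like pair: ancestor plus a mutated copy
random_codon_pair <- function(n_codons, rate) {
  anc <- random_dna(3 * n_codons)
  bases <- strsplit(anc, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (h in hit)
    bases[h] <- sample(setdiff(c("A", "C", "G", "T"), bases[h]), 1)
  list(anc, paste(bases, collapse = ""))
}

# --- interval QC: all-pairs overlap scans --------------------------------
oracle_fusion_flags <- function(protein_only, combined, min_overlappers) {
  vapply(seq_len(nrow(combined)), function(i) {
    cnt <- 0L
    for (j in seq_len(nrow(protein_only))) {
      if (protein_only$chrom[j] != combined$chrom[i]) next
      if (min(protein_only$end[j], combined$end[i]) -
          max(protein_only$start[j], combined$start[i]) >= 1)
        cnt <- cnt + 1L
    }
    cnt >= min_overlappers
  }, TRUE)
}

oracle_filter_markers <- function(hits, max_hits, min_fraction) {
  keep <- rep(TRUE, nrow(hits))
  for (m in unique(hits$marker_id))
    if (sum(hits$marker_id == m) > max_hits)
      keep[hits$marker_id == m] <- FALSE
  keep & hits$aligned_fraction >= min_fraction
}

oracle_s_locus <- function(rnase, sfb, min_identity, max_separation) {
  calls <- character(nrow(rnase))
  for (i in seq_len(nrow(rnase))) {
    cand <- which(sfb$chrom == rnase$chrom[i])
    if (length(cand) == 0) { calls[i] <- "partial"; next }
    seps <- vapply(cand, function(j) {
      if (sfb$start[j] < rnase$end[i] && sfb$end[j] > rnase$start[i]) 0
      else min(abs(sfb$start[j] - rnase$end[i]),
               abs(rnase$start[i] - sfb$end[j]))
    }, 0)
    j <- cand[which.min(seps)]
    calls[i] <- if (rnase$identity[i] > min_identity &&
                    sfb$identity[j] > min_identity &&
                    min(seps) < max_separation) "full" else "partial"
  }
  calls
}

# --- PL dating: grid search over ages with inner rate optimization -------
# independent evaluation of the dating objective on a 4-tip rooted tree
# with free node ages (t1, t2) and fixed root age
oracle_pl_objective <- function(tree, n_sites, lambda, ages) {
  edge <- tree$edge
  x <- round(tree$edge.length * n_sites)
  dur <- ages[edge[, 1]] - ages[edge[, 2]]
  stopifnot(all(dur > 0))
  ntip <- length(tree$tip.label)
  fn <- function(lr) {
    mu <- exp(lr) * dur * n_sites
    ll <- sum(x * log(mu) - mu)
    pen <- 0
    for (b in seq_len(nrow(edge))) {
      v <- edge[b, 2]
      if (v > ntip) {
        kid_edges <- which(edge[, 1] == v)
        pen <- pen + sum((lr[b] - lr[kid_edges])^2)
      }
    }
    rr <- lr[edge[, 1] == ntip + 1]
    pen <- pen + sum((rr - mean(rr))^2)
    -(ll - lambda * pen)
  }
  lr0 <- log(pmax(x, 0.5) / (dur * n_sites))
  opt <- stats::optim(lr0, fn, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$value
}
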