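# Shared helpers: seeded RNG scoping, sequence utilities, rounding/formatting.

# Run `expr` under a temporary RNG state so generators are pure in (spec, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of ACGT(N) strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) revcomp_cpp(as.character(x))

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement, the convention used throughout the k-mer phasing
#' pipeline so both strands collapse onto one key.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Round half away from zero at `digits` decimals (printed-report convention;
# base round() is round-half-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Adjusted Rand Index between two partitions
#'
#' Used to score recovery of planted subgenome labels by clustering.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# random ACGT string
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each position independently with probability `rate`
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit],
                         function(b) sample(setdiff(alt, b), 1), "")
  }
  paste(bases, collapse = "")
}
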