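# Synthetic allotetraploid genomes with planted truth.
#
# The generator emulates the genome organisation that drives subgenome
# phasing in a trigenomic AA'BB tetraploid: every subgenome carries a private
# centromeric satellite monomer tandem-arrayed at its centromeres, all
# monomer families are additionally scattered at low copy number across every
# chromosome (so differential k-mers exist on all chromosomes, merely at
# contrasting abundance), homoeologous gene copies share a group id and
# diverge at controllable per-subgenome rates, and subgenome B is carried at
# dosage 2 (two indistinguishable copies collapsed in the assembly).

#' Specification for a synthetic allotetraploid genome
#'
#' Defaults describe a compact AA'BB-like genome: 3 subgenomes (A, A' coded
#' `"Ap"`, and B at dosage 2) of 2 chromosomes x 2 Mb each, a 200 kb
#' centromere per chromosome carrying a tandem array of a subgenome-private
#' 100 bp satellite monomer, low-copy scatter of every monomer family on
#' every chromosome, a shared background repeat, and 300 genes per
#' chromosome in collinear homoeologous groups.
#'
#' @param subgenomes Character vector of subgenome labels.
#' @param chromosomes_per_subgenome Chromosomes per subgenome.
#' @param chromosome_length Chromosome length in bases.
#' @param centromere_span Centromere width in bases (must fit the tandem
#'   array and be smaller than the chromosome).
#' @param repeat_monomer_length Satellite monomer length in bases.
#' @param monomers_per_family Tandem copies of the private monomer in each
#'   own-subgenome centromere.
#' @param scattered_copies Dispersed copies of every monomer family placed
#'   outside the centromere on every chromosome.
#' @param background_repeat_fraction Fraction of each chromosome covered by
#'   a genome-wide shared repeat, in \[0, 1\].
#' @param gene_count_per_chromosome Genes per chromosome.
#' @param gene_length Gene length in bases.
#' @param subgenome_divergence Named per-subgenome substitution rate
#'   (substitutions/site) from the common ancestor of a homoeologous group;
#'   a pair's divergence is the sum of its two rates.
#' @param dosage Named integer copy number per subgenome (AA'BB is
#'   `c(A = 1, Ap = 1, B = 2)`).
#' @param exchanged_segments Optional data frame of homoeologous exchanges
#'   with columns `donor`, `recipient` (subgenome labels), `chromosome`
#'   (index), `start`, `end` (0-based half-open).
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return A `genome_spec` list, validated.
#' @export
genome_spec <- function(subgenomes = c("A", "Ap", "B"),
                        chromosomes_per_subgenome = 2L,
                        chromosome_length = 2e6,
                        centromere_span = 2e5,
                        repeat_monomer_length = 100L,
                        monomers_per_family = 400L,
                        scattered_copies = 15L,
                        background_repeat_fraction = 0.02,
                        gene_count_per_chromosome = 300L,
                        gene_length = 1000L,
                        subgenome_divergence = c(A = 0.005, Ap = 0.005, B = 0.02),
                        dosage = c(A = 1L, Ap = 1L, B = 2L),
                        exchanged_segments = NULL,
                        seed = 1L) {
  spec <- list(subgenomes = subgenomes,
               chromosomes_per_subgenome = as.integer(chromosomes_per_subgenome),
               chromosome_length = as.integer(chromosome_length),
               centromere_span = as.integer(centromere_span),
               repeat_monomer_length = as.integer(repeat_monomer_length),
               monomers_per_family = as.integer(monomers_per_family),
               scattered_copies = as.integer(scattered_copies),
               background_repeat_fraction = background_repeat_fraction,
               gene_count_per_chromosome = as.integer(gene_count_per_chromosome),
               gene_length = as.integer(gene_length),
               subgenome_divergence = subgenome_divergence,
               dosage = dosage,
               exchanged_segments = exchanged_segments,
               seed = as.integer(seed))
  validate_genome_spec(spec)
  class(spec) <- "genome_spec"
  spec
}

validate_genome_spec <- function(spec) {
  stopifnot(length(spec$subgenomes) >= 1,
            spec$chromosome_length > 0,
            spec$chromosomes_per_subgenome >= 1,
            spec$centromere_span > 0,
            spec$centromere_span < spec$chromosome_length,
            spec$repeat_monomer_length >= 1,
            spec$background_repeat_fraction >= 0,
            spec$background_repeat_fraction <= 1,
            spec$gene_length > 0)
  if (!all(spec$subgenomes %in% names(spec$dosage)))
    stop("every subgenome needs a dosage entry")
  if (any(spec$dosage[spec$subgenomes] < 1))
    stop("dosage values must be >= 1")
  if (!all(spec$subgenomes %in% names(spec$subgenome_divergence)))
    stop("every subgenome needs a divergence entry")
  if (spec$monomers_per_family * spec$repeat_monomer_length >
      spec$centromere_span)
    stop("centromere_span too small for the tandem monomer array")
  invisible(spec)
}

# sample `n` non-overlapping [pos, pos+len) intervals avoiding `occupied`
# (a data.frame with start/end); returns starts
scatter_positions <- function(n, len, chrom_len, occupied) {
  starts <- integer(0)
  occ_s <- occupied$start
  occ_e <- occupied$end
  tries <- 0L
  while (length(starts) < n && tries < n * 200L) {
    tries <- tries + 1L
    p <- sample.int(chrom_len - len + 1L, 1L) - 1L
    if (any(p < occ_e & (p + len) > occ_s)) next
    occ_s <- c(occ_s, p)
    occ_e <- c(occ_e, p + len)
    starts <- c(starts, p)
  }
  if (length(starts) < n)
    stop("could not place repeats without overlap; reduce copy numbers")
  starts
}

#' Build a synthetic allotetraploid genome with planted truth
#'
#' @param spec A [genome_spec()].
#' @return A `synthetic_genome` list: `sequences` (named character),
#'   `truth_subgenome`, `truth_centromere`, `gene_catalog`, `repeat_catalog`,
#'   `monomers`, `truth_exchanges`, and the `spec`.
#' @export
build_genome <- function(spec) {
  validate_genome_spec(spec)
  with_seed(spec$seed, build_genome_impl(spec))
}

build_genome_impl <- function(spec) {
  L <- spec$chromosome_length
  mlen <- spec$repeat_monomer_length
  cen_start <- (L - spec$centromere_span) %/% 2L
  cen_end <- cen_start + spec$centromere_span

  # private monomer per subgenome + one shared background monomer
  monomers <- c(stats::setNames(
    vapply(spec$subgenomes, function(s) random_seq(mlen), ""),
    spec$subgenomes), background = random_seq(mlen))

  # deterministic, arm-proportional gene placement shared by all homoeologs
  glen <- spec$gene_length
  ngene <- spec$gene_count_per_chromosome
  arm_lens <- c(cen_start, L - cen_end)
  n1 <- round(ngene * arm_lens[1] / sum(arm_lens))
  gene_starts <- function(arm_start, arm_len, n) {
    if (n == 0) return(integer(0))
    sp <- arm_len / n
    if (sp < glen + 2) stop("too many genes for the chromosome length")
    as.integer(arm_start + floor((seq_len(n) - 0.5) * sp - glen / 2))
  }
  gstarts <- c(gene_starts(0L, arm_lens[1], n1),
               gene_starts(cen_end, arm_lens[2], ngene - n1))

  # ancestral gene sequences and strands, shared across subgenomes
  n_chr <- spec$chromosomes_per_subgenome
  anc <- vector("list", n_chr)
  strands <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    anc[[ci]] <- vapply(seq_len(ngene), function(i) random_seq(glen), "")
    strands[[ci]] <- sample(c("+", "-"), ngene, replace = TRUE)
  }

  sequences <- character(0)
  truth_subgenome <- character(0)
  cen_rows <- list()
  gene_rows <- list()
  rep_rows <- list()

  for (s in spec$subgenomes) {
    for (ci in seq_len(n_chr)) {
      chrom <- paste0("chr", ci, s)
      bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

      insert <- function(pos, seqstr) {  # pos 0-based
        bases[(pos + 1L):(pos + nchar(seqstr))] <<- strsplit(seqstr, "")[[1]]
      }

      # centromeric tandem array of the subgenome's private monomer
      array_start <- cen_start +
        (spec$centromere_span - spec$monomers_per_family * mlen) %/% 2L
      insert(array_start, strrep(monomers[[s]], spec$monomers_per_family))
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        chrom = chrom, start = array_start,
        end = array_start + spec$monomers_per_family * mlen,
        family = s, stringsAsFactors = FALSE)

      occupied <- data.frame(start = c(cen_start, gstarts),
                             end = c(cen_end, gstarts + glen))

      # low-copy scatter of every private family outside the centromere
      for (fam in spec$subgenomes) {
        if (spec$scattered_copies == 0) next
        pos <- scatter_positions(spec$scattered_copies, mlen, L, occupied)
        occupied <- rbind(occupied,
                          data.frame(start = pos, end = pos + mlen))
        for (p in pos) insert(p, monomers[[fam]])
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + mlen, family = fam,
          stringsAsFactors = FALSE)
      }

      # shared background repeat
      n_bg <- as.integer(floor(spec$background_repeat_fraction * L / mlen))
      if (n_bg > 0) {
        pos <- scatter_positions(n_bg, mlen, L, occupied)
        for (p in pos) insert(p, monomers[["background"]])
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + mlen,
          family = "background", stringsAsFactors = FALSE)
      }

      # homoeologous gene copies, mutated at the subgenome's rate
      rate <- spec$subgenome_divergence[[s]]
      for (gi in seq_len(ngene)) {
        gseq <- mutate_seq(anc[[ci]][gi], rate)
        if (strands[[ci]][gi] == "-") gseq <- revcomp(gseq)
        insert(gstarts[gi], gseq)
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = sprintf("%s_g%03d", chrom, seq_len(ngene)),
        chrom = chrom, start = gstarts, end = gstarts + glen,
        strand = strands[[ci]], rank = seq_len(ngene),
        group_id = sprintf("grp%d_%03d", ci, seq_len(ngene)),
        subgenome = s, stringsAsFactors = FALSE)

      sequences[chrom] <- paste(bases, collapse = "")
      truth_subgenome[chrom] <- s
      cen_rows[[length(cen_rows) + 1L]] <- data.frame(
        chrom = chrom, start = cen_start, end = cen_end,
        stringsAsFactors = FALSE)
    }
  }

  genome <- list(sequences = sequences,
                 truth_subgenome = truth_subgenome,
                 truth_centromere = do.call(rbind, cen_rows),
                 gene_catalog = do.call(rbind, gene_rows),
                 repeat_catalog = do.call(rbind, rep_rows),
                 monomers = monomers,
                 truth_exchanges = NULL,
                 spec = spec)

  # homoeologous exchanges: copy donor sequence (and hence gene content)
  # into the recipient over the stated interval
  ex <- spec$exchanged_segments
  if (!is.null(ex) && nrow(ex) > 0) {
    for (i in seq_len(nrow(ex))) {
      st <- ex$start[i]; en <- ex$end[i]
      if (st < cen_end && en > cen_start)
        stop("exchanged segment overlaps the centromere; choose an arm interval")
      from <- paste0("chr", ex$chromosome[i], ex$donor[i])
      to <- paste0("chr", ex$chromosome[i], ex$recipient[i])
      substr(genome$sequences[[to]], st + 1L, en) <-
        substr(genome$sequences[[from]], st + 1L, en)
    }
    genome$truth_exchanges <- data.frame(
      donor = ex$donor, recipient = ex$recipient,
      chrom = paste0("chr", ex$chromosome, ex$recipient),
      start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  }

  class(genome) <- "synthetic_genome"
  genome
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", length(x$sequences), "chromosomes,",
      length(unique(x$truth_subgenome)), "subgenomes,",
      nrow(x$gene_catalog), "genes\n")
  invisible(x)
}

#' Simulate error-free short reads at per-subgenome dosage
#'
#' Reads are uniform, error-free substrings of the chromosome sequences with
#' strand chosen uniformly; the number of reads per chromosome is
#' `base_coverage * dosage(subgenome) * length / read_length`, so expected
#' per-base depth equals base coverage times subgenome dosage.
#'
#' @param genome A `synthetic_genome`.
#' @param base_coverage Fold coverage of a dosage-1 subgenome (> 0).
#' @param read_length Read length in bases.
#' @param seed Integer seed.
#' @return A `read_set`: `reads` (named character vector) and `truth`
#'   (data frame of chrom, start, strand).
#' @export
simulate_reads <- function(genome, base_coverage, read_length = 100L,
                           seed = 1L) {
  if (base_coverage <= 0) stop("base_coverage must be > 0")
  lens <- nchar(genome$sequences)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest chromosome")
  dosage <- genome$spec$dosage
  with_seed(seed, {
    out <- lapply(names(genome$sequences), function(chrom) {
      L <- lens[[chrom]]
      d <- dosage[[genome$truth_subgenome[[chrom]]]]
      n <- as.integer(round(base_coverage * d * L / read_length))
      start <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
      strand <- sample(c("+", "-"), n, replace = TRUE)
      seqs <- substring(genome$sequences[[chrom]], start + 1L,
                        start + read_length)
      seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
      names(seqs) <- sprintf("%s_r%06d", chrom, seq_len(n))
      list(reads = seqs,
           truth = data.frame(chrom = chrom, start = start, strand = strand,
                              stringsAsFactors = FALSE))
    })
    res <- list(reads = do.call(c, lapply(out, `[[`, "reads")),
                truth = do.call(rbind, lapply(out, `[[`, "truth")))
    class(res) <- "read_set"
    res
  })
}
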