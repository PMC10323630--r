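# Plain-text interchange: FASTA/FASTQ/GFF3/TSV writers and readers.
# Sequences travel through the package as named character vectors; Biostrings
# handles FASTA parsing when available.

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of nucleotide strings.
#' @param path Output file path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(sequences, path, width = 80L) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  lines <- readLines(path)
  idx <- grepl("^>", lines)
  id <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  grp <- cumsum(idx)
  seqs <- vapply(split(lines[!idx], grp[!idx]),
                 paste, "", collapse = "")
  names(seqs) <- id
  seqs
}

#' Write simulated reads to a FASTQ file
#'
#' Synthetic reads are error-free, so every base gets the maximum Phred
#' quality character.
#'
#' @param reads A `read_set` from [simulate_reads()] or a named character
#'   vector of read sequences.
#' @param path Output file path.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  stopifnot(!is.null(names(reads)))
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  writeLines(rbind(paste0("@", names(reads)), reads, "+", qual), con)
  invisible(path)
}

#' Write a gene catalog as GFF3
#'
#' Coordinates in the catalog are 0-based half-open; GFF3 is 1-based closed,
#' so starts are shifted by one on output.
#'
#' @param gene_catalog Data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (and optionally `group_id`).
#' @param path Output file path.
#' @export
write_gff3 <- function(gene_catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- paste0("ID=", gene_catalog$gene_id,
                  if (!is.null(gene_catalog$group_id))
                    paste0(";homoeolog_group=", gene_catalog$group_id) else "")
  writeLines(paste(gene_catalog$chrom, "polyphase", "gene",
                   gene_catalog$start + 1L, gene_catalog$end, ".",
                   gene_catalog$strand, ".", attrs, sep = "\t"), con)
  invisible(path)
}

#' Write a density track as a BEDGRAPH-style TSV
#'
#' @param track A `density_track` data frame (chrom, start, end, value).
#' @param path Output file path.
#' @export
write_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
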