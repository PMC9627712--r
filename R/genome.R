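#' Genome descriptor
#'
#' A minimal description of the reference genome: an ordered table of contig
#' names and lengths. The total size is the denominator of every genome
#' fraction computed downstream (F_ROH, length-class fractions).
#'
#' @param names character vector of contig names (unique).
#' @param lengths integer/numeric vector of contig lengths in bp (> 0).
#' @return A `genome_descriptor`: a data frame with columns `name` and
#'   `length`, and attribute `total_size` (sum of lengths in bp).
#' @examples
#' g <- genome_descriptor(c("chr1", "chr2"), c(12e6, 8e6))
#' total_size(g)
#' @export
genome_descriptor <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths))
    stop("contig names and lengths differ in length")
  if (anyDuplicated(names))
    stop("contig names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("contig lengths must be positive")
  out <- data.frame(name = names, length = lengths, stringsAsFactors = FALSE)
  attr(out, "total_size") <- sum(lengths)
  class(out) <- c("genome_descriptor", "data.frame")
  out
}

#' Total genome size
#'
#' @param genome a [genome_descriptor()].
#' @return Total genome size in bp.
#' @export
total_size <- function(genome) {
  stopifnot(inherits(genome, "genome_descriptor"))
  sum(genome$length)
}

#' Read a contig-length table
#'
#' Two-column TSV (`contig`, `length`), with or without a header row.
#'
#' @param path file path.
#' @return A [genome_descriptor()].
#' @export
read_contig_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\S+\t[0-9]+\\s*$", first)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("contig table must have two columns: name, length")
  genome_descriptor(tab[[1]], tab[[2]])
}

#' Read a reference genome FASTA
#'
#' @param path FASTA file.
#' @return A named character vector of contig sequences, with a
#'   `genome_descriptor` attached as attribute `"genome"`.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  attr(seqs, "genome") <- genome_descriptor(names(seqs), nchar(seqs))
  seqs
}

#' @export
print.genome_descriptor <- function(x, ...) {
  cat(sprintf("Genome: %d contigs, %.0f bp total\n", nrow(x), total_size(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more contigs\n", nrow(x) - 10))
  invisible(x)
}

# shared genotype codes: 0 = hom-ref (ancestral), 1 = het, 2 = hom-alt
# (derived), NA = missing. Used for both raw and polarized matrices.
GT_LEVELS <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)
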