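#' Genotype matrix container
#'
#' Holds biallelic SNP sites and an integer genotype matrix (sites x samples)
#' coded 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing.
#'
#' @param sites data frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` and optionally `info`.
#' @param gt integer matrix, one row per site, one column per sample
#'   (column names are sample ids).
#' @param sample_table optional data frame mapping `sample_id` to `group`
#'   (and optionally `year`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, gt, sample_table = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(gt), nrow(sites) == nrow(gt))
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("sites must have columns contig, pos, ref, alt")
  if (is.null(colnames(gt)))
    stop("gt must have sample ids as column names")
  bad <- !(gt %in% c(0L, 1L, 2L)) & !is.na(gt)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  storage.mode(gt) <- "integer"
  if (!is.null(sample_table)) check_sample_table(sample_table, colnames(gt))
  structure(list(sites = sites, gt = gt, sample_table = sample_table),
            class = "genotype_matrix")
}

check_sample_table <- function(sample_table, sample_ids) {
  if (!all(c("sample_id", "group") %in% names(sample_table)))
    stop("sample table needs columns sample_id, group")
  if (anyDuplicated(sample_table$sample_id))
    stop("duplicate sample ids in sample table")
  missing <- setdiff(sample_ids, sample_table$sample_id)
  if (length(missing))
    stop("samples absent from sample table: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNPs x %d samples\n",
              nrow(x$gt), ncol(x$gt)))
  cat("  contigs:", paste(unique(x$sites$contig), collapse = ", "), "\n")
  n_miss <- sum(is.na(x$gt))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * n_miss / length(x$gt)))
  invisible(x)
}

#' Sample ids of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @export
sample_ids <- function(gm) colnames(gm$gt)

# GT string -> integer code; phased and unphased identical
.gt_code <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  out <- rep(NA_integer_, length(g))
  out[g %in% c("0/0", "0")] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% c("1/1", "1")] <- 2L
  out
}

#' Read a multi-sample SNP VCF
#'
#' Parses a VCF 4.x file (via vcfR) into a [genotype_matrix()]. Only
#' biallelic SNP records are retained; multiallelic records, indels and
#' spanning deletions are skipped and the skip count is reported with a
#' message and stored in attribute `"n_skipped"`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_table optional sample metadata; every VCF sample must be
#'   present or an error is raised.
#' @param keep_info keep the raw INFO string per retained site (needed for
#'   [parse_snpeff_ann()]).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_table = NULL, keep_info = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt
  keep[is.na(keep)] <- FALSE
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(n_skipped, " non-SNP or multiallelic record(s) skipped")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  gt_raw <- gt_raw[keep, , drop = FALSE]
  gt <- matrix(.gt_code(gt_raw), nrow = nrow(gt_raw),
               dimnames = list(NULL, colnames(gt_raw)))
  sites <- data.frame(contig = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  if (keep_info) {
    info <- v@fix[, "INFO"]
    sites$info <- if (is.null(info)) NA_character_ else as.character(info)[keep]
  }
  if (!is.null(sample_table)) check_sample_table(sample_table, colnames(gt))
  out <- genotype_matrix(sites, gt, sample_table)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Sites-plus-GT writer; emits contig header lines when a genome descriptor
#' is supplied. Round-trips losslessly through [read_vcf()].
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param genome optional [genome_descriptor()] for `##contig` headers.
#' @export
write_vcf <- function(gm, path, genome = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohload",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%.0f>",
                          genome$name, genome$length))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(gm$gt)),
                      collapse = "\t"))
  gstr <- c("0/0", "0/1", "1/1")
  body_gt <- matrix("./.", nrow = nrow(gm$gt), ncol = ncol(gm$gt))
  ok <- !is.na(gm$gt)
  body_gt[ok] <- gstr[gm$gt[ok] + 1L]
  info <- if (!is.null(gm$sites$info)) {
    ifelse(is.na(gm$sites$info) | gm$sites$info == "", ".", gm$sites$info)
  } else rep(".", nrow(gm$gt))
  lines <- paste(gm$sites$contig, gm$sites$pos, ".", gm$sites$ref,
                 gm$sites$alt, ".", "PASS", info, "GT",
                 apply(body_gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(gm$gt) == 0) lines <- character(0)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Extracts CDS features (via rtracklayer), keeping the single longest
#' transcript per gene. GFF3 1-based closed coordinates are converted to the
#' internal 0-based half-open convention at this boundary; CDS intervals are
#' ordered in transcription direction (minus-strand genes run 3'->5'
#' genomically). Genes whose coding length (after removing the first exon's
#' phase offset) is not divisible by 3 are flagged unusable for effect
#' classification, with a warning.
#'
#' @param path GFF3 file.
#' @return A `gene_annotation`: a list of gene records, each with fields
#'   `gene_id`, `contig`, `strand`, `usable` and `cds` (data frame with
#'   0-based half-open `start`, `end` and `phase`, in transcription order).
#' @export
read_gff3 <- function(path) {
  if (file.size(path) == 0)
    return(structure(list(), class = "gene_annotation"))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0)
    return(structure(list(), class = "gene_annotation"))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  cds_idx <- which(type == "CDS")
  if (!length(cds_idx))
    return(structure(list(), class = "gene_annotation"))
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) x[[1]] else NA_character_, "")
  }
  # transcript -> gene map from mRNA/transcript features (may be absent)
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  tx2gene <- character(0)
  if (length(tx_idx)) {
    tx2gene <- first_parent(md$Parent[tx_idx])
    names(tx2gene) <- as.character(md$ID[tx_idx])
  }
  cds_parent <- first_parent(md$Parent[cds_idx])
  cds_tab <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr))[cds_idx],
    start = GenomicRanges::start(gr)[cds_idx] - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)[cds_idx],
    strand = as.character(GenomicRanges::strand(gr))[cds_idx],
    phase = as.integer(md$phase[cds_idx]),
    tx = cds_parent, stringsAsFactors = FALSE)
  cds_tab$phase[is.na(cds_tab$phase)] <- 0L
  cds_tab$gene <- ifelse(cds_tab$tx %in% names(tx2gene) &
                           !is.na(tx2gene[cds_tab$tx]),
                         tx2gene[cds_tab$tx], cds_tab$tx)
  # longest transcript per gene
  tx_len <- tapply(cds_tab$end - cds_tab$start, cds_tab$tx, sum)
  genes <- split(cds_tab, cds_tab$gene)
  out <- lapply(names(genes), function(gid) {
    g <- genes[[gid]]
    txs <- unique(g$tx)
    best <- txs[which.max(tx_len[txs])]
    g <- g[g$tx == best, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (g$strand[1] == "-") g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
    clen <- sum(g$end - g$start) - g$phase[1]
    usable <- clen %% 3 == 0 && clen > 0
    if (!usable)
      warning("gene ", gid, ": CDS length not divisible by 3; ",
              "flagged unusable for effect classification", call. = FALSE)
    list(gene_id = gid, contig = g$contig[1], strand = g$strand[1],
         usable = usable,
         cds = data.frame(start = g$start, end = g$end, phase = g$phase))
  })
  names(out) <- names(genes)
  structure(out, class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes (%d usable)\n", length(x),
              sum(vapply(x, `[[`, TRUE, "usable"))))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()] for the internal representation: emits
#' gene/mRNA/CDS lines with 1-based closed coordinates.
#'
#' @param annotation a `gene_annotation`.
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  lines <- "##gff-version 3"
  for (g in annotation) {
    lo <- min(g$cds$start) + 1L
    hi <- max(g$cds$end)
    lines <- c(lines,
      sprintf("%s\trohload\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$contig, lo, hi, g$strand, g$gene_id),
      sprintf("%s\trohload\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$contig, lo, hi, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\trohload\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
              g$contig, g$cds$start + 1L, g$cds$end, g$strand, g$cds$phase,
              g$gene_id, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED uses 0-based half-open coordinates, matching the internal convention,
#' so no conversion happens here. Output is sorted by genome contig order
#' (or alphabetically when no genome is given) then start.
#'
#' @param intervals data frame with `contig`, `start`, `end` and optionally a
#'   `name` column (e.g. the sample of an ROH segment).
#' @param path output path.
#' @param genome optional [genome_descriptor()]; used for contig ordering and
#'   bounds checking.
#' @export
write_bed <- function(intervals, path, genome = NULL) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  iv <- intervals
  if (!is.null(genome)) {
    bad <- !(iv$contig %in% genome$name)
    len <- genome$length[match(iv$contig, genome$name)]
    oob <- bad | iv$start < 0 | iv$end > len
    if (any(oob)) {
      i <- which(oob)[1]
      stop(sprintf("interval outside contig: %s:%.0f-%.0f",
                   iv$contig[i], iv$start[i], iv$end[i]))
    }
    ord <- order(match(iv$contig, genome$name), iv$start)
  } else {
    ord <- order(iv$contig, iv$start)
  }
  iv <- iv[ord, , drop = FALSE]
  name <- if ("name" %in% names(iv)) iv$name else rep(".", nrow(iv))
  lines <- sprintf("%s\t%.0f\t%.0f\t%s", iv$contig, iv$start, iv$end, name)
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV (header row, no quoting)
#' @param table a data frame.
#' @param path output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a seasonal census table
#'
#' TSV with header `year season count`; seasons are `spring`/`autumn`.
#'
#' @param path file path.
#' @return Data frame of class `census_series`.
#' @export
read_census <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  census_series(tab$year, tab$season, tab$count)
}

#' Construct a census series
#' @param year integer years.
#' @param season `"spring"` or `"autumn"`.
#' @param count positive integer census counts.
#' @export
census_series <- function(year, season, count) {
  if (is.null(year) || is.null(season) || is.null(count))
    stop("census needs year, season and count")
  season <- tolower(as.character(season))
  if (!all(season %in% c("spring", "autumn")))
    stop("season must be spring or autumn")
  if (any(count < 1)) stop("census counts must be >= 1")
  if (anyDuplicated(paste(year, season)))
    stop("duplicate (year, season) records")
  structure(data.frame(year = as.integer(year), season = season,
                       count = as.numeric(count)),
            class = c("census_series", "data.frame"))
}

#' Read a sample metadata table (TSV: sample_id, group[, year])
#' @param path file path.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop("sample table needs columns sample_id, group")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids")
  tab
}

#' Read deletion calls from a BED-with-carriers file
#'
#' Five columns: contig, start, end, id, comma-separated carrier sample ids
#' (`.` for none). This is the flat-text dialect the simulator emits; see
#' [read_sv_vcf()] for the SV-VCF dialect.
#'
#' @param path file path.
#' @return Data frame of class `deletion_calls` with a `carriers` list
#'   column.
#' @export
read_deletions_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("deletion BED needs 5 columns")
  names(tab)[1:5] <- c("contig", "start", "end", "id", "carrier_str")
  carriers <- strsplit(tab$carrier_str, ",", fixed = TRUE)
  carriers <- lapply(carriers, function(x) setdiff(x, "."))
  deletion_calls(tab$contig, tab$start, tab$end, tab$id, carriers)
}

#' Construct a deletion-call table
#' @param contig,start,end interval (0-based half-open).
#' @param id call identifier.
#' @param carriers list of character vectors of carrier sample ids (any
#'   non-reference SV genotype counts as carriage).
#' @export
deletion_calls <- function(contig, start, end, id, carriers) {
  if (any(end <= start)) stop("deletion end must exceed start")
  out <- data.frame(contig = contig, start = start, end = end, id = id,
                    stringsAsFactors = FALSE)
  out$carriers <- carriers
  class(out) <- c("deletion_calls", "data.frame")
  out
}

#' Read deletion calls from an SV VCF
#'
#' Records with `SVTYPE=DEL` are converted to intervals `[POS, END)` (0-based
#' half-open); a sample carries the deletion if its GT contains a non-reference
#' allele.
#'
#' @param path SV VCF file.
#' @return A `deletion_calls` data frame.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- as.character(v@fix[, "INFO"])
  is_del <- grepl("(^|;)SVTYPE=DEL(;|$)", info)
  if (!any(is_del)) {
    return(deletion_calls(character(0), numeric(0), numeric(0),
                          character(0), list()))
  }
  endv <- vapply(info, function(s) {
    m <- regmatches(s, regexpr("(?:^|;)END=[0-9]+", s, perl = TRUE))
    if (length(m)) as.numeric(sub(".*=", "", m)) else NA_real_
  }, 0)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  idx <- which(is_del)
  carriers <- lapply(idx, function(i) {
    g <- gsub("|", "/", gt_raw[i, ], fixed = TRUE)
    samples[!is.na(g) & g %in% c("0/1", "1/0", "1/1", "1")]
  })
  deletion_calls(fix$CHROM[idx], as.numeric(fix$POS[idx]) - 1, endv[idx],
                 ifelse(is.na(fix$ID[idx]) | fix$ID[idx] == ".",
                        paste0("DEL", seq_along(idx)), fix$ID[idx]),
                 carriers)
}
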