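#' @title Coding-effect classification and genotype polarization
#' @description Mutation classes follow the conservative scheme used in
#'   mutation-load studies: `SYN` (amino acid unchanged), `NSYN` (changed,
#'   no stop gained) and `LOF` strictly defined as stop-gained (a premature
#'   stop codon introduced by the SNP). Stop-loss and splice variants are
#'   not LOF here; stop-retained changes are SYN.
#' @name effects
NULL

MUTATION_CLASSES <- c("SYN", "NSYN", "LOF")
.severity <- c(NONCODING = 0L, SYN = 1L, NSYN = 2L, LOF = 3L)

.revcomp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# transcript (spliced CDS) sequence of a gene, 5'->3'
.gene_transcript <- function(gene, sequences) {
  ctg <- sequences[[gene$contig]]
  chunks <- substring(ctg, gene$cds$start + 1L, gene$cds$end)
  if (gene$strand == "-") {
    chunks <- vapply(chunks, function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, "")
  }
  paste(chunks, collapse = "")
}

# 1-based transcript coordinate of genomic position pos within gene, or NA
.transcript_coord <- function(gene, pos) {
  off <- 0L
  for (i in seq_len(nrow(gene$cds))) {
    st <- gene$cds$start[i]
    en <- gene$cds$end[i]
    w <- en - st
    if (pos > st && pos <= en) {
      within <- if (gene$strand == "+") pos - st else en - pos + 1L
      return(off + within)
    }
    off <- off + w
  }
  NA_integer_
}

.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify a SNP's coding effect against one gene
#'
#' Locates the codon containing the site (strand- and phase-aware, across
#' exon junctions), substitutes the alternate allele and compares the
#' translated amino acids under the standard nuclear code.
#'
#' @param contig,pos,ref,alt the variant (1-based position, single
#'   nucleotides; `ref` must match the reference sequence).
#' @param gene one gene record from [read_gff3()].
#' @param sequences named character vector of contig sequences (e.g. from
#'   [read_genome_fasta()]).
#' @return `"SYN"`, `"NSYN"`, `"LOF"` or `"NONCODING"`.
#' @export
classify_snp_effect <- function(contig, pos, ref, alt, gene, sequences) {
  if (contig != gene$contig) return("NONCODING")
  if (!isTRUE(gene$usable)) {
    warning("gene ", gene$gene_id, " unusable; site treated as NONCODING",
            call. = FALSE)
    return("NONCODING")
  }
  tpos <- .transcript_coord(gene, pos)
  if (is.na(tpos)) return("NONCODING")
  tx <- .gene_transcript(gene, sequences)
  ref_t <- if (gene$strand == "+") ref else .revcomp1(ref)
  alt_t <- if (gene$strand == "+") alt else .revcomp1(alt)
  if (substr(tx, tpos, tpos) != ref_t)
    stop(sprintf("reference mismatch at %s:%d (gene %s)", contig, pos,
                 gene$gene_id))
  trim <- gene$cds$phase[1]
  if (tpos <= trim) return("NONCODING")  # upstream of first full codon
  codon_idx <- (tpos - trim - 1L) %/% 3L
  c_start <- trim + codon_idx * 3L + 1L
  if (c_start + 2L > nchar(tx)) return("NONCODING")  # trailing partial codon
  ref_codon <- substr(tx, c_start, c_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, tpos - c_start + 1L, tpos - c_start + 1L) <- alt_t
  aa_ref <- .translate_codon(ref_codon)
  aa_alt <- .translate_codon(alt_codon)
  if (aa_ref == aa_alt) return("SYN")
  if (aa_alt == "*" && aa_ref != "*") return("LOF")
  "NSYN"
}

#' Classify every site of a genotype matrix
#'
#' Sites overlapping several genes take the most severe class
#' (LOF > NSYN > SYN), matching annotation-tool convention.
#'
#' @param gm a [genotype_matrix()].
#' @param annotation a `gene_annotation` from [read_gff3()].
#' @param sequences named character vector of contig sequences.
#' @return Character vector (length = number of sites) of classes, with the
#'   assigned `gene_id` as attribute `"gene_id"` (NA for NONCODING).
#' @export
classify_effects <- function(gm, annotation, sequences) {
  n <- nrow(gm$sites)
  classes <- rep("NONCODING", n)
  gene_ids <- rep(NA_character_, n)
  if (!length(annotation)) {
    attr(classes, "gene_id") <- gene_ids
    return(classes)
  }
  # interval index of CDS pieces -> gene
  cds_ctg <- unlist(lapply(annotation, function(g)
    rep(g$contig, nrow(g$cds))))
  cds_gene <- unlist(lapply(annotation, function(g)
    rep(g$gene_id, nrow(g$cds))))
  cds_start <- unlist(lapply(annotation, function(g) g$cds$start))
  cds_end <- unlist(lapply(annotation, function(g) g$cds$end))
  site_gr <- GenomicRanges::GRanges(gm$sites$contig,
                                    IRanges::IRanges(gm$sites$pos,
                                                     gm$sites$pos))
  cds_gr <- GenomicRanges::GRanges(cds_ctg,
                                   IRanges::IRanges(cds_start + 1L, cds_end))
  hits <- GenomicRanges::findOverlaps(site_gr, cds_gr)
  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]
    g <- annotation[[cds_gene[S4Vectors::subjectHits(hits)[h]]]]
    cl <- suppressWarnings(
      classify_snp_effect(gm$sites$contig[i], gm$sites$pos[i],
                          gm$sites$ref[i], gm$sites$alt[i], g, sequences))
    if (.severity[cl] > .severity[classes[i]]) {
      classes[i] <- cl
      gene_ids[i] <- g$gene_id
    }
  }
  attr(classes, "gene_id") <- gene_ids
  classes
}

#' Parse a SnpEff ANN field into a mutation class
#'
#' Compatibility path for pre-annotated VCFs: `stop_gained` maps to LOF,
#' `missense_variant` to NSYN, `synonymous_variant` to SYN, anything else to
#' NONCODING. With several ANN entries (or `&`-joined terms) the most severe
#' class wins.
#'
#' @param info INFO string(s) or bare `ANN=` value(s).
#' @return Character vector of classes (`NA` with a warning for malformed
#'   entries).
#' @export
parse_snpeff_ann <- function(info) {
  vapply(info, function(s) {
    if (is.na(s)) return(NA_character_)
    m <- regmatches(s, regexpr("(?:^|;)ANN=[^;]+", s, perl = TRUE))
    ann <- if (length(m)) sub("^;?ANN=", "", m) else
      if (!grepl("=", s) || startsWith(s, "ANN=")) sub("^ANN=", "", s) else ""
    if (ann == "") {
      warning("no ANN field found; site skipped", call. = FALSE)
      return(NA_character_)
    }
    best <- 0L
    for (entry in strsplit(ann, ",", fixed = TRUE)[[1]]) {
      fields <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(fields) < 2) {
        warning("malformed ANN entry; skipped", call. = FALSE)
        next
      }
      for (term in strsplit(fields[2], "&", fixed = TRUE)[[1]]) {
        cl <- switch(term,
                     stop_gained = "LOF",
                     missense_variant = "NSYN",
                     synonymous_variant = "SYN",
                     "NONCODING")
        if (.severity[cl] > best) best <- .severity[cl]
      }
    }
    names(.severity)[match(best, .severity)]
  }, "", USE.NAMES = FALSE)
}

#' Polarize genotypes into ancestral/derived classes
#'
#' With the reference genome standing in for the ancestral state (the
#' operational definition used when the reference is an outgroup), hom-ref
#' is hom-ancestral and hom-alt is hom-derived, so the integer codes carry
#' over unchanged (0 = HOM_ANC, 1 = HET, 2 = HOM_DER, NA = MISSING). An
#' ancestral-allele table can override the proxy: sites whose ancestral
#' allele is the alternate allele have their codes flipped, and sites whose
#' stated ancestral allele matches neither allele become missing.
#'
#' @param gm a [genotype_matrix()].
#' @param ancestral optional data frame `contig`, `pos`, `allele`.
#' @return Integer matrix of polarized codes with attribute
#'   `"polarized" = TRUE`.
#' @export
polarize <- function(gm, ancestral = NULL) {
  out <- gm$gt
  if (!is.null(ancestral)) {
    key <- paste(gm$sites$contig, gm$sites$pos)
    akey <- paste(ancestral$contig, ancestral$pos)
    m <- match(key, akey)
    has <- !is.na(m)
    aa <- ancestral$allele[m[has]]
    flip <- which(has)[aa == gm$sites$alt[has]]
    drop <- which(has)[aa != gm$sites$alt[has] & aa != gm$sites$ref[has]]
    out[flip, ] <- 2L - out[flip, , drop = FALSE]
    out[drop, ] <- NA_integer_
  }
  attr(out, "polarized") <- TRUE
  out
}
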