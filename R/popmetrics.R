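#' Fixed loss-of-function variants private to a focal group
#'
#' Retains LOF sites where every non-missing focal sample is
#' homozygous-derived (missing focal genotypes are ignored but at least one
#' non-missing call is required) and every non-missing background sample
#' carries zero derived alleles. Output is invariant to sample ordering.
#'
#' @param pol polarized genotype matrix.
#' @param lof_idx row indices of LOF sites.
#' @param focal,background disjoint, non-empty character vectors of sample
#'   ids.
#' @return Integer vector of retained site indices, with attribute
#'   `"n_all_focal_missing"` counting sites excluded because no focal sample
#'   was genotyped.
#' @export
unique_fixed_lof <- function(pol, lof_idx, focal, background) {
  if (!length(focal) || !length(background))
    stop("focal and background sample sets must be non-empty")
  if (length(intersect(focal, background)))
    stop("focal and background sample sets must be disjoint")
  stopifnot(all(c(focal, background) %in% colnames(pol)))
  fg <- pol[lof_idx, focal, drop = FALSE]
  bg <- pol[lof_idx, background, drop = FALSE]
  n_focal_ok <- rowSums(!is.na(fg))
  focal_all_der <- rowSums(fg == 2L, na.rm = TRUE) == n_focal_ok
  bg_no_der <- rowSums(bg > 0L, na.rm = TRUE) == 0
  keep <- n_focal_ok >= 1 & focal_all_der & bg_no_der
  out <- lof_idx[keep]
  attr(out, "n_all_focal_missing") <- sum(n_focal_ok == 0)
  out
}

#' Deletions private to a focal sample set, with gene proximity
#'
#' Retains deletion calls carried by every focal sample and by no background
#' sample, annotates the distance to the nearest gene (0 when overlapping),
#' and flags calls within `window` bp of a gene and calls longer than
#' `max_length` (likely caller artefacts; flagged, never silently dropped).
#'
#' @param dels a `deletion_calls` table ([read_deletions_bed()] /
#'   [read_sv_vcf()]).
#' @param focal character vector of (high-quality) focal sample ids.
#' @param background character vector of background sample ids.
#' @param annotation a `gene_annotation`; gene extent is the span of its
#'   CDS.
#' @param window gene-proximity window in bp (default 2000).
#' @param max_length length above which a call is flagged `oversized`
#'   (default 1e6).
#' @return The retained calls with columns `gene_distance`, `nearest_gene`,
#'   `proximal` (distance <= window) and `oversized` appended.
#' @export
unique_deletions <- function(dels, focal, background, annotation,
                             window = 2000, max_length = 1e6) {
  if (!length(focal)) stop("focal sample list must be explicit")
  carried <- function(by) vapply(dels$carriers, function(cs) by %in% cs, TRUE)
  in_all_focal <- Reduce(`&`, lapply(focal, carried),
                         rep(TRUE, nrow(dels)))
  in_any_bg <- Reduce(`|`, lapply(background, carried),
                      rep(FALSE, nrow(dels)))
  keep <- dels[in_all_focal & !in_any_bg, , drop = FALSE]
  keep$gene_distance <- NA_real_
  keep$nearest_gene <- NA_character_
  if (nrow(keep) && length(annotation)) {
    gene_ctg <- vapply(annotation, `[[`, "", "contig")
    gene_lo <- vapply(annotation, function(g) min(g$cds$start), 0)
    gene_hi <- vapply(annotation, function(g) max(g$cds$end), 0)
    gene_id <- vapply(annotation, `[[`, "", "gene_id")
    del_gr <- GenomicRanges::GRanges(keep$contig,
      IRanges::IRanges(keep$start + 1, keep$end))
    gene_gr <- GenomicRanges::GRanges(gene_ctg,
      IRanges::IRanges(gene_lo + 1, gene_hi))
    hits <- GenomicRanges::distanceToNearest(del_gr, gene_gr)
    qi <- S4Vectors::queryHits(hits)
    keep$gene_distance[qi] <- S4Vectors::mcols(hits)$distance
    keep$nearest_gene[qi] <- gene_id[S4Vectors::subjectHits(hits)]
  }
  keep$proximal <- !is.na(keep$gene_distance) & keep$gene_distance <= window
  keep$oversized <- (keep$end - keep$start) > max_length
  rownames(keep) <- NULL
  keep
}

#' Harmonic-mean effective population size from census counts
#'
#' The variance effective size of a fluctuating population is approximated
#' by the harmonic mean of the census counts over time, computed separately
#' for the spring and autumn count series; it is dominated by the bottleneck
#' minima and never exceeds the arithmetic mean.
#'
#' @param census a [census_series()].
#' @return Data frame of class `ne_estimate`: `season`, `ne` (full
#'   precision), `ne_rounded`, `n_years`.
#' @export
harmonic_mean_ne <- function(census) {
  stopifnot(inherits(census, "census_series"))
  if (any(census$count <= 0))
    stop("harmonic mean undefined for non-positive counts")
  out <- do.call(rbind, lapply(split(census, census$season), function(d) {
    ne <- nrow(d) / sum(1 / d$count)
    data.frame(season = d$season[1], ne = ne,
               ne_rounded = .round_half_up(ne), n_years = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ne_estimate", "data.frame")
  out
}

#' Weir-Cockerham F_st between two groups
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) of Weir & Cockerham
#' (1984), computed from genotype counts (using observed heterozygosity).
#' The genome-wide headline estimate is the ratio of sums `sum(a) /
#' sum(a+b+c)` (the "weighted" convention of vcftools); the mean of
#' per-site ratios is also reported. Monomorphic sites and sites with fewer
#' than two genotyped individuals in either group are skipped and counted.
#'
#' @param gm a [genotype_matrix()] (raw codes; polarization is irrelevant
#'   to F_st).
#' @param groups named character vector mapping sample id to group; exactly
#'   two groups must be present among the matrix samples.
#' @return List of class `fst_estimate`: `fst_weighted`, `fst_mean`,
#'   `n_sites_used`, `n_skipped`, and the per-site component matrix
#'   `components` (columns a, b, c).
#' @export
weir_cockerham_fst <- function(gm, groups) {
  groups <- groups[names(groups) %in% colnames(gm$gt)]
  groups <- groups[!is.na(groups)]
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  g1 <- gm$gt[, names(groups)[groups == gl[1]], drop = FALSE]
  g2 <- gm$gt[, names(groups)[groups == gl[2]], drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- ifelse(n1 > 0, rowSums(g1, na.rm = TRUE) / (2 * n1), NA)
  p2 <- ifelse(n2 > 0, rowSums(g2, na.rm = TRUE) / (2 * n2), NA)
  h1 <- ifelse(n1 > 0, rowSums(g1 == 1L, na.rm = TRUE) / n1, NA)
  h2 <- ifelse(n2 > 0, rowSums(g2 == 1L, na.rm = TRUE) / n2, NA)
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 >= 2 & n2 >= 2 & nbar > 1
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  poly <- ok & pbar > 0 & pbar < 1
  n_skipped <- sum(!poly)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!poly] <- NA; b[!poly] <- NA; cc[!poly] <- NA
  denom <- a + b + cc
  use <- poly & is.finite(denom) & denom != 0
  structure(list(
    fst_weighted = sum(a[use]) / sum(denom[use]),
    fst_mean = mean((a / denom)[use]),
    n_sites_used = sum(use), n_skipped = n_skipped,
    groups = gl,
    components = cbind(a = a, b = b, c = cc)),
    class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_st (%s vs %s): %.4f (ratio of sums, %d sites; mean of ratios %.4f)\n",
              x$groups[1], x$groups[2], x$fst_weighted, x$n_sites_used,
              x$fst_mean))
  invisible(x)
}
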