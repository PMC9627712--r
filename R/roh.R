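#' Parameters of the ROH hidden Markov model
#'
#' The detector is a two-state HMM over the ordered SNP sites of one sample
#' on one contig. The hidden state is autozygous vs non-autozygous; the
#' observation at each non-missing site is collapsed to heterozygous vs
#' homozygous (hom-ref and hom-alt are equivalent evidence for autozygosity).
#'
#' Emissions: inside an autozygous tract a site is heterozygous with
#' probability `het_emission` (genotyping error / gene conversion); outside,
#' the heterozygote probability is `2p(1-p)` under Hardy-Weinberg at the
#' site's alternate-allele frequency `p` when frequencies are supplied,
#' otherwise `1 - hom_outside` as a constant. Transitions between states are
#' distance-dependent: over a gap of `d` bp the switch probability is
#' `(1 - exp(-2 r d)) / 2` with `r = transition_rate / 1e6` per bp, the
#' two-state continuous-time symmetric chain; for small `r d` this is
#' approximately `r d`, i.e. `transition_rate` expected switches per Mb.
#' Missing genotypes are skipped but still contribute distance.
#'
#' @param het_emission probability of observing HET inside an autozygous
#'   tract (default 0.005).
#' @param hom_outside constant probability of observing HOM outside tracts
#'   when no allele frequencies are available (default 0.7).
#' @param transition_rate expected state switches per Mb (default 0.1).
#' @param min_sites minimum number of informative (non-missing) SNPs a
#'   reported segment must span (default 10).
#' @param min_report_length bp threshold used by the F_ROH summary, not by
#'   detection; segments of any length are returned (default 1e5).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(het_emission = 0.005, hom_outside = 0.7,
                       transition_rate = 0.1, min_sites = 10,
                       min_report_length = 1e5) {
  stopifnot(het_emission > 0, het_emission < 1,
            hom_outside > 0, hom_outside < 1,
            transition_rate > 0, min_sites >= 1, min_report_length > 0)
  structure(list(het_emission = het_emission, hom_outside = hom_outside,
                 transition_rate = transition_rate, min_sites = min_sites,
                 min_report_length = min_report_length),
            class = "roh_params")
}

# log emission matrix: rows = sites (non-missing), cols = (auto, outside)
.roh_emissions <- function(het, params, freqs = NULL) {
  eps <- params$het_emission
  if (is.null(freqs)) {
    p_het_out <- rep(1 - params$hom_outside, length(het))
  } else {
    p <- pmin(pmax(freqs, 0), 1)
    p_het_out <- pmin(pmax(2 * p * (1 - p), 1e-4), 0.5)
  }
  cbind(auto = ifelse(het, log(eps), log1p(-eps)),
        out = ifelse(het, log(p_het_out), log1p(-p_het_out)))
}

# per-gap log transition probabilities; d in bp
.roh_switch_prob <- function(d, params) {
  r <- params$transition_rate / 1e6
  (1 - exp(-2 * r * d)) / 2
}

# Viterbi decoding; returns integer state vector (1 = autozygous, 2 = outside)
.roh_viterbi <- function(emissions, log_switch, log_stay) {
  n <- nrow(emissions)
  if (n == 0) return(integer(0))
  delta <- matrix(-Inf, n, 2)
  psi <- matrix(1L, n, 2)
  delta[1, ] <- log(0.5) + emissions[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in 1:2) {
        cand <- delta[t - 1, ] +
          c(if (s == 1) log_stay[t - 1] else log_switch[t - 1],
            if (s == 2) log_stay[t - 1] else log_switch[t - 1])
        psi[t, s] <- which.max(cand)
        delta[t, s] <- cand[psi[t, s]] + emissions[t, s]
      }
    }
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  states
}

# full decode for one sample on one contig; exposes the state path at the
# informative sites (used by tests to compare against exhaustive enumeration)
.roh_decode <- function(gt, pos, params, freqs = NULL) {
  if (is.unsorted(pos, strictly = TRUE))
    stop("site positions must be strictly increasing")
  ok <- !is.na(gt)
  gt <- gt[ok]
  pos <- pos[ok]
  if (!is.null(freqs)) freqs <- freqs[ok]
  if (length(gt) == 0)
    return(list(pos = pos, states = integer(0)))
  em <- .roh_emissions(gt == 1L, params, freqs)
  d <- diff(pos)
  psw <- .roh_switch_prob(d, params)
  list(pos = pos,
       states = .roh_viterbi(em, log(psw), log1p(-psw)))
}

#' Detect runs of homozygosity on one contig of one sample
#'
#' Decodes the two-state HMM described in [roh_params()] with the Viterbi
#' algorithm and reports maximal runs of the autozygous state, trimmed to
#' the first and last supporting SNP. Segments are reported regardless of
#' length (the 100 kb threshold is applied by [compute_froh()]); runs
#' spanning fewer than `min_sites` informative SNPs are dropped.
#'
#' @param gt integer genotype codes (0/1/2/NA) for one sample, ordered along
#'   the contig.
#' @param pos 1-based positions, strictly increasing.
#' @param params an [roh_params()] object.
#' @param freqs optional alternate-allele frequencies per site.
#' @param contig contig name stored in the output (default "contig").
#' @return Data frame with `contig`, `start`, `end` (0-based half-open),
#'   `n_sites`.
#' @export
detect_roh <- function(gt, pos, params = roh_params(), freqs = NULL,
                       contig = "contig") {
  dec <- .roh_decode(gt, pos, params, freqs)
  empty <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), n_sites = integer(0))
  if (length(dec$states) == 0) return(empty)
  r <- rle(dec$states == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_sites
  if (!any(keep)) return(empty)
  data.frame(contig = contig,
             start = dec$pos[starts[keep]] - 1,   # 0-based half-open
             end = as.numeric(dec$pos[ends[keep]]),
             n_sites = r$lengths[keep])
}

#' Scan a whole cohort for ROHs
#'
#' Runs [detect_roh()] for every sample x contig in a genotype matrix.
#' Allele frequencies for the outside-state emission are estimated from the
#' cohort itself (alternate-allele frequency over non-missing genotypes) by
#' default, mirroring how likelihood-based ROH callers use population allele
#' frequencies.
#'
#' @param gm a [genotype_matrix()].
#' @param genome a [genome_descriptor()].
#' @param params an [roh_params()].
#' @param freq_mode `"estimate"` (from the cohort), `"constant"` (use
#'   `hom_outside`), or a numeric vector of per-site frequencies.
#' @return Object of class `roh_scan`: list with `segments` (sample, contig,
#'   start, end, n_sites, length), `genome`, `params`.
#' @export
roh_scan <- function(gm, genome, params = roh_params(),
                     freq_mode = "estimate") {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(genome, "genome_descriptor"))
  freqs <- NULL
  if (is.numeric(freq_mode)) {
    stopifnot(length(freq_mode) == nrow(gm$gt))
    freqs <- freq_mode
  } else if (identical(freq_mode, "estimate")) {
    n_ok <- rowSums(!is.na(gm$gt))
    freqs <- ifelse(n_ok > 0, rowSums(gm$gt, na.rm = TRUE) / (2 * n_ok), 0)
  } else if (!identical(freq_mode, "constant")) {
    stop("freq_mode must be 'estimate', 'constant' or a numeric vector")
  }
  pieces <- list()
  for (ctg in unique(gm$sites$contig)) {
    idx <- which(gm$sites$contig == ctg)
    idx <- idx[order(gm$sites$pos[idx])]
    pos <- gm$sites$pos[idx]
    f <- if (!is.null(freqs)) freqs[idx] else NULL
    for (smp in colnames(gm$gt)) {
      seg <- detect_roh(gm$gt[idx, smp], pos, params, f, contig = ctg)
      if (nrow(seg)) {
        seg$sample <- smp
        pieces[[length(pieces) + 1L]] <- seg
      }
    }
  }
  segments <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               n_sites = integer(0), sample = character(0))
  segments <- segments[, c("sample", "contig", "start", "end", "n_sites")]
  segments$length <- segments$end - segments$start
  rownames(segments) <- NULL
  structure(list(segments = segments, genome = genome, params = params,
                 samples = colnames(gm$gt)),
            class = "roh_scan")
}

#' @export
print.roh_scan <- function(x, ...) {
  cat(sprintf("roh_scan: %d segments across %d samples (genome %.0f bp)\n",
              nrow(x$segments), length(x$samples), total_size(x$genome)))
  invisible(x)
}

#' @describeIn roh_scan per-sample F_ROH and length-class genome fractions.
#' @param object,x an `roh_scan`.
#' @param ... unused.
#' @export
summary.roh_scan <- function(object, ...) {
  fr <- compute_froh(object$segments, object$genome,
                     samples = object$samples)
  cls <- bin_roh_lengths(object$segments, object$genome,
                         samples = object$samples)
  out <- merge(fr, cls, by = "sample", sort = FALSE)
  class(out) <- c("inbreeding_summary", "data.frame")
  out
}

#' @export
print.inbreeding_summary <- function(x, ...) {
  cat("Per-sample inbreeding (F_ROH over tracts >= 100 kb by default):\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.roh_scan <- function(x, ...) {
  s <- summary(x)
  m <- t(as.matrix(s[, c("f_0.1_1Mb", "f_1_10Mb", "f_10Mb_plus")]))
  colnames(m) <- s$sample
  graphics::barplot(m, las = 2, col = c("grey75", "grey45", "grey15"),
                    ylab = "genome fraction in ROHs",
                    legend.text = c("0.1-1 Mb", "1-10 Mb", ">10 Mb"), ...)
  invisible(x)
}

# merge overlapping segments of one sample, per contig; returns df
.merge_segments <- function(seg) {
  if (nrow(seg) == 0) return(seg[, c("contig", "start", "end")])
  pieces <- lapply(split(seg, seg$contig), function(s) {
    ir <- IRanges::reduce(IRanges::IRanges(start = s$start + 1,
                                           end = s$end))
    data.frame(contig = s$contig[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.split_by_sample <- function(segments, samples = NULL) {
  if (!"sample" %in% names(segments))
    segments$sample <- rep("sample", length.out = nrow(segments))
  if (is.null(samples)) samples <- unique(segments$sample)
  lapply(stats::setNames(samples, samples),
         function(s) segments[segments$sample == s, , drop = FALSE])
}

#' F_ROH: genome fraction in runs of homozygosity
#'
#' The inbreeding coefficient F_ROH is the summed length of ROHs at least
#' `min_length` bp long (after merging overlaps within a sample) divided by
#' the total genome size.
#'
#' @param segments data frame of segments with `contig`, `start`, `end` and
#'   optionally `sample`.
#' @param genome a [genome_descriptor()].
#' @param min_length minimum tract length in bp (default 1e5, i.e. 100 kb).
#' @param samples optional sample universe, so samples with no segments get
#'   F_ROH = 0 rows.
#' @return Data frame with `sample` and `froh`.
#' @export
compute_froh <- function(segments, genome, min_length = 1e5,
                         samples = NULL) {
  G <- total_size(genome)
  per <- .split_by_sample(segments, samples)
  out <- data.frame(sample = names(per), froh = vapply(per, function(s) {
    m <- .merge_segments(s)
    len <- m$end - m$start
    sum(len[len >= min_length]) / G
  }, 0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genome fraction per ROH length class
#'
#' Tracts at least 100 kb long are partitioned into half-open length bins
#' \[0.1, 1), \[1, 10) and \[10, Inf) Mb; the per-class genome fractions sum
#' to F_ROH at the default threshold.
#'
#' @inheritParams compute_froh
#' @return Data frame with `sample`, `f_0.1_1Mb`, `f_1_10Mb`, `f_10Mb_plus`.
#' @export
bin_roh_lengths <- function(segments, genome, samples = NULL) {
  G <- total_size(genome)
  per <- .split_by_sample(segments, samples)
  rows <- lapply(per, function(s) {
    m <- .merge_segments(s)
    len <- m$end - m$start
    c(sum(len[len >= 1e5 & len < 1e6]),
      sum(len[len >= 1e6 & len < 1e7]),
      sum(len[len >= 1e7])) / G
  })
  out <- data.frame(sample = names(per),
                    do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out)[2:4] <- c("f_0.1_1Mb", "f_1_10Mb", "f_10Mb_plus")
  rownames(out) <- NULL
  out
}

#' Mean recombination rate from map length and genome size
#'
#' @param map_length_cM total genetic map length in centimorgans.
#' @param genome_bp physical genome size in bp.
#' @return Rate in cM/Mb.
#' @examples
#' recombination_rate(5330, 1.16e9)  # ~4.6 cM/Mb
#' @export
recombination_rate <- function(map_length_cM, genome_bp) {
  if (map_length_cM <= 0 || genome_bp <= 0)
    stop("map length and genome size must be positive")
  map_length_cM / (genome_bp / 1e6)
}

#' Age of an ROH in generations
#'
#' The expected length of an autozygous tract whose haplotypes coalesce `g`
#' generations ago is `100 / (2 g)` cM, so the tract length dates the shared
#' ancestor as `g = 100 / (2 L_cM)` with `L_cM = length_bp * rate / 1e6`.
#' A 1 Mb tract at ~4.6 cM/Mb dates to ~11 generations; a 0.1 Mb tract to
#' ~109 generations.
#'
#' @param length_bp tract length(s) in bp.
#' @param rate_cM_per_Mb mean recombination rate.
#' @return Generations to the most recent common ancestor (unrounded;
#'   see [roh_age_table()] for display rounding).
#' @export
date_roh <- function(length_bp, rate_cM_per_Mb) {
  if (any(length_bp <= 0) || rate_cM_per_Mb <= 0)
    stop("length and rate must be positive")
  length_cM <- length_bp * rate_cM_per_Mb / 1e6
  100 / (2 * length_cM)
}

# round-half-up, for display only
.round_half_up <- function(x) floor(x + 0.5)

#' Tract ages for a segment table
#'
#' @param segments data frame with `length` (or `start`/`end`).
#' @param rate_cM_per_Mb mean recombination rate in cM/Mb.
#' @return The segment table with `g` (full precision) and `g_rounded`
#'   (nearest integer, half-up) columns appended.
#' @export
roh_age_table <- function(segments, rate_cM_per_Mb) {
  len <- if ("length" %in% names(segments)) segments$length else
    segments$end - segments$start
  segments$g <- date_roh(len, rate_cM_per_Mb)
  segments$g_rounded <- .round_half_up(segments$g)
  segments
}
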