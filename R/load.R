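#' Sites segregating across the analysed cohort
#'
#' A site is segregating when its non-missing polarized genotypes show both
#' alleles (derived-allele frequency strictly between 0 and 1). Recomputed
#' after any sample subsetting, this defines the site universe of the load
#' profiles.
#'
#' @param pol polarized genotype matrix (see [polarize()]).
#' @return Logical vector over sites.
#' @export
segregating_sites <- function(pol) {
  n_ok <- rowSums(!is.na(pol))
  der <- rowSums(pol, na.rm = TRUE)
  n_ok > 0 & der > 0 & der < 2 * n_ok
}

#' Genotype-class proportions per sample and mutation class
#'
#' The per-sample mutation-load profile: at each class's segregating sites,
#' the proportions of the sample's non-missing genotypes that are
#' homozygous-ancestral, heterozygous and homozygous-derived. Proportions
#' are used instead of raw counts because they are robust to differences in
#' coverage and missingness between samples.
#'
#' @param pol polarized genotype matrix.
#' @param classes character vector of site classes (`SYN`/`NSYN`/`LOF`/
#'   `NONCODING`), length = number of sites.
#' @param restrict_segregating restrict to sites segregating across the
#'   cohort (default TRUE).
#' @return Long data frame of class `load_profile`: `sample`, `class`,
#'   `n_sites`, `p_anc`, `p_het`, `p_der`. Classes with no non-missing site
#'   for a sample are reported with `n_sites = 0` and NA proportions.
#' @export
genotype_class_proportions <- function(pol, classes,
                                       restrict_segregating = TRUE) {
  stopifnot(length(classes) == nrow(pol))
  use <- classes %in% MUTATION_CLASSES
  if (restrict_segregating) use <- use & segregating_sites(pol)
  rows <- list()
  for (cl in MUTATION_CLASSES) {
    sub <- pol[use & classes == cl, , drop = FALSE]
    for (smp in colnames(pol)) {
      g <- sub[, smp]
      n <- sum(!is.na(g))
      if (n == 0) {
        p <- c(NA_real_, NA_real_, NA_real_)
      } else {
        p <- c(sum(g == 0L, na.rm = TRUE),
               sum(g == 1L, na.rm = TRUE),
               sum(g == 2L, na.rm = TRUE)) / n
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, class = cl, n_sites = n,
        p_anc = p[1], p_het = p[2], p_der = p[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$n_sites > 0
  stopifnot(all(abs(out$p_anc[ok] + out$p_het[ok] + out$p_der[ok] - 1)
                < 1e-12))
  class(out) <- c("load_profile", "data.frame")
  out
}

#' Group (species) means and 2-SE intervals of load proportions
#'
#' @param profile a `load_profile`.
#' @param groups named character vector mapping sample id to group.
#' @return Long data frame: group, class, category, n, mean, se, lo, hi
#'   (mean +/- 2 SE over member samples).
#' @export
load_group_summary <- function(profile, groups) {
  long <- .profile_long(profile)
  long$group <- groups[long$sample]
  agg <- do.call(rbind, lapply(
    split(long, list(long$group, long$class, long$category), drop = TRUE),
    function(d) {
      v <- d$value[!is.na(d$value)]
      se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
      data.frame(group = d$group[1], class = d$class[1],
                 category = d$category[1], n = length(v),
                 mean = mean(v), se = se,
                 lo = mean(v) - 2 * se, hi = mean(v) + 2 * se,
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  agg
}

# wide profile -> long (sample, class, category, value)
.profile_long <- function(profile) {
  do.call(rbind, lapply(c(anc = "p_anc", het = "p_het", der = "p_der"),
    function(col) data.frame(sample = profile$sample, class = profile$class,
                             category = sub("p_", "", col),
                             value = profile[[col]],
                             stringsAsFactors = FALSE)))
}

#' Compare load proportions among groups (ANOVA + Tukey HSD)
#'
#' One-way fixed-effects ANOVA of the per-sample proportions for every
#' (mutation class, genotype category) cell, followed by Tukey HSD pairwise
#' comparisons (Tukey-Kramer under unequal n). Pairwise contrasts involving
#' a single-sample group are kept but flagged low-power.
#'
#' @param profile a `load_profile`.
#' @param groups named character vector mapping sample id to group.
#' @return List with `anova` (class, category, df1, df2, F, p) and `tukey`
#'   (class, category, contrast, diff, lo, hi, p_adj, low_power).
#' @export
compare_load_groups <- function(profile, groups) {
  long <- .profile_long(profile)
  long$group <- groups[long$sample]
  if (length(unique(long$group)) < 2)
    stop("need at least two groups")
  an <- list(); tk <- list()
  for (cl in unique(long$class)) for (cat in c("anc", "het", "der")) {
    d <- long[long$class == cl & long$category == cat & !is.na(long$value), ]
    if (!nrow(d) || length(unique(d$group)) < 2) next
    d$group <- factor(d$group)
    fit <- stats::aov(value ~ group, data = d)
    s <- summary(fit)[[1]]
    an[[length(an) + 1L]] <- data.frame(
      class = cl, category = cat, df1 = s$Df[1], df2 = s$Df[2],
      F = s$`F value`[1], p = s$`Pr(>F)`[1], stringsAsFactors = FALSE)
    th <- stats::TukeyHSD(fit)$group
    sizes <- table(d$group)
    pair_groups <- strsplit(rownames(th), "-", fixed = TRUE)
    low <- vapply(pair_groups, function(g2) any(sizes[g2] < 2), TRUE)
    tk[[length(tk) + 1L]] <- data.frame(
      class = cl, category = cat, contrast = rownames(th),
      diff = th[, "diff"], lo = th[, "lwr"], hi = th[, "upr"],
      p_adj = th[, "p adj"], low_power = low, stringsAsFactors = FALSE)
  }
  list(anova = {x <- do.call(rbind, an); rownames(x) <- NULL; x},
       tukey = {x <- do.call(rbind, tk); rownames(x) <- NULL; x})
}

#' Filtered LOF allele-frequency table across three focal species
#'
#' To compare loss-of-function allele frequencies on an equal sampling
#' footing, a variant is retained only when (i) every focal species has at
#' least `min_genotyped` non-missing individuals and (ii) the derived allele
#' is present (frequency > 0) in at least `min_species_present` of the focal
#' species. Per-species frequency is the derived-allele count divided by
#' twice the number of non-missing individuals. A one-way ANOVA of
#' frequency ~ species over the retained variants is attached.
#'
#' @param pol polarized genotype matrix restricted (by `lof_idx`) to LOF
#'   sites.
#' @param lof_idx integer indices of LOF sites within `pol` rows.
#' @param species named character vector mapping sample id to species; the
#'   focal species are `focal_species`.
#' @param focal_species exactly three species names.
#' @param min_genotyped minimum non-missing individuals per species
#'   (default 4).
#' @param min_species_present minimum species carrying the derived allele
#'   (default 2).
#' @return List of class `lof_frequency_table`: `table` (variant x species
#'   long data frame with `n_genotyped` and `freq`), `kept` (indices into
#'   `lof_idx`), `anova` (list with F and p), `means` (per-species mean
#'   frequency).
#' @export
lof_frequency_filter <- function(pol, lof_idx, species, focal_species,
                                 min_genotyped = 4, min_species_present = 2) {
  if (length(focal_species) != 3)
    stop("exactly three focal species must be designated")
  rows <- list(); kept <- integer(0)
  for (i in lof_idx) {
    g <- pol[i, ]
    stats_sp <- lapply(focal_species, function(sp) {
      gs <- g[names(g) %in% names(species)[species == sp]]
      n <- sum(!is.na(gs))
      der <- sum(gs, na.rm = TRUE)
      c(n = n, freq = if (n > 0) der / (2 * n) else NA_real_)
    })
    n_ok <- vapply(stats_sp, `[[`, 0, "n")
    fr <- vapply(stats_sp, `[[`, 0, "freq")
    if (all(n_ok >= min_genotyped) &&
        sum(fr > 0, na.rm = TRUE) >= min_species_present) {
      kept <- c(kept, i)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = i, species = focal_species, n_genotyped = n_ok,
        freq = fr, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = integer(0), species = character(0),
               n_genotyped = integer(0), freq = numeric(0))
  rownames(tab) <- NULL
  anova_res <- NULL; means <- NULL
  if (length(kept) >= 2) {
    fit <- stats::aov(freq ~ species, data = tab)
    s <- summary(fit)[[1]]
    anova_res <- list(F = s$`F value`[1], p = s$`Pr(>F)`[1])
    means <- tapply(tab$freq, tab$species, mean)
  }
  structure(list(table = tab, kept = kept, anova = anova_res,
                 means = means),
            class = "lof_frequency_table")
}

#' @export
print.lof_frequency_table <- function(x, ...) {
  cat(sprintf("lof_frequency_table: %d variants retained\n",
              length(x$kept)))
  if (!is.null(x$means)) {
    cat("mean derived-allele frequency per species:\n")
    print(round(x$means, 3))
    cat(sprintf("ANOVA p = %.3g\n", x$anova$p))
  }
  invisible(x)
}

#' Exact two-sided binomial p-value (minimum-likelihood rule)
#'
#' Sums the probabilities of all outcomes at most as likely as the observed
#' count under Binomial(n, p0) — the same two-sided rule as
#' [stats::binom.test()], with the conventional `1 + 1e-7` relative slack on
#' the pmf comparison. Switch `alternative` for one-sided tests.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return p-value.
#' @export
exact_binom_p <- function(k, n, p0, alternative = "two.sided") {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  if (alternative == "greater")
    return(stats::pbinom(k - 1, n, p0, lower.tail = FALSE))
  if (alternative == "less")
    return(stats::pbinom(k, n, p0))
  pmf <- stats::dbinom(0:n, n, p0)
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

#' Per-individual enrichment of LOF variants inside ROHs
#'
#' Binomial test of whether an individual's LOF variant positions fall
#' inside its ROHs more (or less) often than expected from its F_ROH: the
#' number of successes is the count of LOF positions (with a non-missing
#' genotype) inside merged ROH segments at least `min_length` bp long, the
#' number of trials is the total count of non-missing LOF positions, and
#' the null success probability is the individual's F_ROH.
#'
#' @param segments this sample's ROH segments (`contig`, `start`, `end`).
#' @param lof_sites data frame `contig`, `pos` of LOF variant positions.
#' @param genotyped logical vector: which LOF sites have a non-missing
#'   genotype in this sample.
#' @param froh the sample's F_ROH (in (0,1); 0 or 1 makes the test
#'   undefined and returns NA with a reason).
#' @param min_length ROH length threshold (default 1e5, matching F_ROH).
#' @param alternative passed to [exact_binom_p()].
#' @return One-row data frame: `k`, `n`, `p0`, `p_value`, `direction`,
#'   `reason`.
#' @export
roh_lof_enrichment <- function(segments, lof_sites, genotyped, froh,
                               min_length = 1e5,
                               alternative = "two.sided") {
  stopifnot(nrow(lof_sites) == length(genotyped))
  use <- lof_sites[genotyped, , drop = FALSE]
  n <- nrow(use)
  m <- .merge_segments(segments)
  m <- m[m$end - m$start >= min_length, , drop = FALSE]
  k <- 0L
  if (n > 0 && nrow(m) > 0) {
    for (ctg in unique(use$contig)) {
      p <- use$pos[use$contig == ctg]
      s <- m[m$contig == ctg, , drop = FALSE]
      if (!nrow(s)) next
      ix <- findInterval(p - 1, sort(s$start))
      so <- s[order(s$start), , drop = FALSE]
      inside <- ix > 0 & (p - 1) < so$end[pmax(ix, 1L)]
      k <- k + sum(inside)
    }
  }
  if (n == 0 || froh <= 0 || froh >= 1) {
    reason <- if (n == 0) "no genotyped LOF sites" else
      "F_ROH of 0 or 1 leaves the null degenerate"
    return(data.frame(k = k, n = n, p0 = froh, p_value = NA_real_,
                      direction = NA_character_, reason = reason,
                      stringsAsFactors = FALSE))
  }
  data.frame(k = k, n = n, p0 = froh,
             p_value = exact_binom_p(k, n, froh, alternative),
             direction = if (k / n > froh) "enriched" else "depleted",
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Cohort-wide LOF-in-ROH enrichment
#'
#' @param scan an [roh_scan()] result.
#' @param gm the [genotype_matrix()] the scan was run on.
#' @param classes site classes from [classify_effects()] (or
#'   [parse_snpeff_ann()]).
#' @param min_length ROH/F_ROH length threshold.
#' @param alternative test sidedness.
#' @return Data frame, one row per sample, as in [roh_lof_enrichment()].
#' @export
cohort_lof_enrichment <- function(scan, gm, classes, min_length = 1e5,
                                  alternative = "two.sided") {
  lof <- which(classes == "LOF")
  lof_sites <- gm$sites[lof, c("contig", "pos")]
  fr <- compute_froh(scan$segments, scan$genome, min_length,
                     samples = scan$samples)
  out <- do.call(rbind, lapply(scan$samples, function(smp) {
    seg <- scan$segments[scan$segments$sample == smp, , drop = FALSE]
    r <- roh_lof_enrichment(seg, lof_sites, !is.na(gm$gt[lof, smp]),
                            fr$froh[fr$sample == smp], min_length,
                            alternative)
    cbind(sample = smp, r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
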