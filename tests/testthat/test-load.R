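test_that("genotype-class proportions are simple tallies that sum to one", {
  pol <- matrix(c(0L, 0L, 1L, 2L,   # s1 over 4 LOF sites
                  2L, 2L, 2L, 2L,   # s2
                  0L, NA, NA, NA),  # s3: one informative site
                nrow = 4, dimnames = list(NULL, NULL))
  colnames(pol) <- c("s1", "s2", "s3")
  classes <- rep("LOF", 4)
  prof <- genotype_class_proportions(pol, classes,
                                     restrict_segregating = FALSE)
  p1 <- prof[prof$sample == "s1" & prof$class == "LOF", ]
  expect_equal(c(p1$p_anc, p1$p_het, p1$p_der), c(0.5, 0.25, 0.25))
  ok <- prof$n_sites > 0
  expect_true(all(abs(prof$p_anc[ok] + prof$p_het[ok] + prof$p_der[ok] - 1)
                  < 1e-12))
  # class with zero informative sites: absent (NA), not zero
  p_syn <- prof[prof$sample == "s1" & prof$class == "SYN", ]
  expect_equal(p_syn$n_sites, 0)
  expect_true(is.na(p_syn$p_anc))
})

test_that("a fully inbred error-free sample has zero heterozygosity", {
  cfg <- sim_config(seed = 13,
                    samples = data.frame(
                      sample_id = c("in1", "out1", "out2", "out3"),
                      group = c("gin", "gout", "gout", "gout"),
                      target_F = c(0.995, 0, 0, 0),
                      tract_age_g = c(5, 10, 10, 10)),
                    het_error_inside_roh = 0, missing_rate = 0,
                    contigs = c(a = 3e6), snp_density = 300,
                    genes = list(n = 6, codons = c(100, 150),
                                 exons = c(1, 2), intron = c(100, 300)),
                    planted = list(SYN = c(shared = 6),
                                   NSYN = c(shared = 6),
                                   LOF = c(shared = 6)),
                    deletions = list(n_private = 0, n_other = 0,
                                     length = c(500, 600),
                                     near_gene_fraction = 0))
  sim <- simulate_cohort(cfg)
  pol <- polarize(sim$gm)
  cl <- classify_effects(sim$gm, sim$annotation, sim$sequences)
  prof <- genotype_class_proportions(pol, cl)
  inbred <- prof[prof$sample == "in1" & prof$n_sites > 0, ]
  expect_true(all(inbred$p_het == 0))
  # genome-wide heterozygosity of the inbred sample is near zero too
  expect_lte(mean(pol[, "in1"] == 1L, na.rm = TRUE), 0.01)
})

test_that("profile output matches a naive per-site tally oracle exactly", {
  sim <- fixture_cohort()
  pol <- polarize(sim$gm)
  cl <- fixture_classes()
  prof <- genotype_class_proportions(pol, cl)
  seg <- segregating_sites(pol)
  for (smp in sample_ids(sim$gm)) for (mcl in c("SYN", "NSYN", "LOF")) {
    counts <- c(0, 0, 0); n <- 0
    for (i in which(cl == mcl & seg)) {
      g <- pol[i, smp]
      if (!is.na(g)) { n <- n + 1; counts[g + 1] <- counts[g + 1] + 1 }
    }
    row <- prof[prof$sample == smp & prof$class == mcl, ]
    expect_equal(row$n_sites, n)
    if (n > 0)
      expect_equal(c(row$p_anc, row$p_het, row$p_der), counts / n)
  }
})

test_that("group comparison reduces to the textbook one-way ANOVA", {
  # identical group means -> F = 0, p = 1
  prof <- data.frame(sample = paste0("s", 1:6),
                     class = "SYN", n_sites = 10,
                     p_anc = rep(c(0.2, 0.5, 0.8), 2),
                     p_het = rep(c(0.1, 0.2, 0.1), 2),
                     p_der = rep(c(0.7, 0.3, 0.1), 2))
  class(prof) <- c("load_profile", "data.frame")
  groups <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  res <- compare_load_groups(prof, groups)
  a <- res$anova[res$anova$category == "anc", ]
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # hand-computed 3-group toy: values 1,2,3 / 2,3,4 / 6,7,8 (as proportions)
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8) / 10
  prof2 <- data.frame(sample = paste0("t", 1:9), class = "LOF",
                      n_sites = 10, p_anc = vals, p_het = 0, p_der = 0)
  class(prof2) <- c("load_profile", "data.frame")
  g2 <- setNames(rep(c("A", "B", "C"), each = 3), paste0("t", 1:9))
  res2 <- compare_load_groups(prof2, g2)
  # closed form: group means 2,3,7 (x0.1), grand 4; SSB=3*(4+1+9)/100,
  # SSW=6*1/100; F = (SSB/2)/(SSW/6)
  ssb <- 3 * ((2 - 4)^2 + (3 - 4)^2 + (7 - 4)^2) / 100
  ssw <- 6 * 1 / 100
  expect_equal(res2$anova$F[res2$anova$category == "anc"],
               (ssb / 2) / (ssw / 6))
  tk <- res2$tukey[res2$tukey$category == "anc", ]
  expect_equal(nrow(tk), 3)
  expect_false(any(tk$low_power))
})

test_that("single-sample groups are flagged low power, not suppressed", {
  prof <- data.frame(sample = paste0("s", 1:5), class = "SYN", n_sites = 5,
                     p_anc = c(0.1, 0.2, 0.3, 0.2, 0.9),
                     p_het = 0.05, p_der = 0.0)
  class(prof) <- c("load_profile", "data.frame")
  groups <- setNames(c("A", "A", "B", "B", "C"), paste0("s", 1:5))
  res <- compare_load_groups(prof, groups)
  tk <- res$tukey[res$tukey$category == "anc", ]
  expect_equal(sum(grepl("C", tk$contrast) & tk$low_power), 2)
  expect_false(tk$low_power[tk$contrast == "B-A"])
})

test_that("Tukey HSD family-wise error stays near its nominal level", {
  # null: all three groups share one distribution of load proportions
  set.seed(501)
  n_rep <- 1000
  groups <- setNames(rep(c("A", "B", "C"), each = 5), paste0("s", 1:15))
  any_rej <- 0L
  for (r in seq_len(n_rep)) {
    prof <- data.frame(sample = names(groups), class = "LOF", n_sites = 50,
                       p_anc = pmin(pmax(rnorm(15, 0.5, 0.1), 0), 1),
                       p_het = NA_real_, p_der = NA_real_)
    class(prof) <- c("load_profile", "data.frame")
    res <- compare_load_groups(prof, groups)
    p <- res$tukey$p_adj[res$tukey$category == "anc"]
    if (any(p <= 0.05)) any_rej <- any_rej + 1L
  }
  expect_lte(any_rej / n_rep, 0.07)
})

test_that("LOF frequency filter applies both sampling and presence rules", {
  # 12 samples, 3 species x 4; site 1: only 3 genotyped in spB -> excluded;
  # site 2: derived allele present in one species only -> excluded;
  # site 3: passes
  pol <- rbind(
    c(2L, 2L, 2L, 2L,  1L, 1L, 0L, NA,  0L, 0L, 1L, 0L),
    c(0L, 0L, 0L, 0L,  0L, 0L, 0L, 0L,  2L, 1L, 1L, 0L),
    c(2L, 1L, 0L, 0L,  1L, 0L, 0L, 0L,  0L, 0L, 0L, 1L))
  colnames(pol) <- paste0(rep(c("a", "b", "c"), each = 4), 1:4)
  species <- setNames(rep(c("spA", "spB", "spC"), each = 4), colnames(pol))
  res <- lof_frequency_filter(pol, 1:3, species, c("spA", "spB", "spC"))
  expect_equal(res$kept, 3L)
  tab <- res$table
  expect_equal(tab$freq[tab$species == "spA"], 3 / 8)
  expect_equal(tab$freq[tab$species == "spB"], 1 / 8)
  expect_equal(tab$freq[tab$species == "spC"], 1 / 8)
  expect_error(lof_frequency_filter(pol, 1:3, species, c("spA", "spB")),
               "three focal species")
})

test_that("frequency filter recovers an independent per-variant recount", {
  sim <- fixture_cohort()
  pol <- polarize(sim$gm)
  cl <- fixture_classes()
  species <- fixture_groups()
  lofi <- which(cl == "LOF")
  res <- lof_frequency_filter(pol, lofi, species, c("spA", "spB", "spC"))
  # brute recount: loop over LOF sites and species
  for (i in lofi) {
    keep <- TRUE; freqs <- c()
    for (sp in c("spA", "spB", "spC")) {
      g <- pol[i, names(species)[species == sp]]
      n <- sum(!is.na(g))
      if (n < 4) keep <- FALSE
      freqs <- c(freqs, if (n > 0) sum(g, na.rm = TRUE) / (2 * n) else NA)
    }
    if (sum(freqs > 0, na.rm = TRUE) < 2) keep <- FALSE
    expect_equal(i %in% res$kept, keep, label = paste("site", i))
    if (keep)
      expect_equal(res$table$freq[res$table$variant == i], freqs)
  }
  expect_gt(length(res$kept), 0)
})

test_that("exact binomial matches closed forms and brute-force pmf sums", {
  expect_equal(exact_binom_p(10, 10, 0.5), 2 * 0.5^10)
  expect_equal(exact_binom_p(5, 10, 0.5), 1)       # k/n == p0, symmetric
  # brute-force pmf-summation oracle
  pmf <- dbinom(0:10, 10, 0.3)
  expect_equal(exact_binom_p(9, 10, 0.3),
               sum(pmf[pmf <= dbinom(9, 10, 0.3) * (1 + 1e-7)]))
  # agreement with the independent C implementation
  set.seed(6)
  for (rep_i in 1:50) {
    n <- sample(1:40, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(exact_binom_p(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-12)
  }
  expect_error(exact_binom_p(3, 2, 0.5))
})

test_that("ROH-LOF enrichment counts and degenerate cases behave", {
  seg <- data.frame(contig = "c1", start = c(0, 5e5), end = c(2e5, 9e5))
  lof <- data.frame(contig = "c1", pos = c(100, 150000, 300000, 600000,
                                           950000))
  r <- roh_lof_enrichment(seg, lof, rep(TRUE, 5), froh = 0.4)
  expect_equal(r$k, 3)   # 100, 150000, 600000 inside
  expect_equal(r$n, 5)
  expect_equal(r$p_value, exact_binom_p(3, 5, 0.4))
  expect_equal(r$direction, "enriched")
  # missing genotypes drop out of both k and n
  r2 <- roh_lof_enrichment(seg, lof, c(TRUE, FALSE, TRUE, TRUE, TRUE), 0.4)
  expect_equal(r2$k, 2)
  expect_equal(r2$n, 4)
  # segments below the length threshold do not count
  r3 <- roh_lof_enrichment(data.frame(contig = "c1", start = 0, end = 5e4),
                           lof, rep(TRUE, 5), 0.4)
  expect_equal(r3$k, 0)
  # F_ROH of 0 or 1: undefined, NA with reason
  r4 <- roh_lof_enrichment(seg, lof, rep(TRUE, 5), 0)
  expect_true(is.na(r4$p_value))
  expect_match(r4$reason, "degenerate")
})

test_that("binomial null calibration and power against planted enrichment", {
  # type-I error under the null (true inside-rate = F_ROH)
  n <- 200; p0 <- 0.3
  pv_by_k <- vapply(0:n, exact_binom_p, 0, n = n, p0 = p0)
  set.seed(902)
  k_null <- rbinom(2000, n, p0)
  rate <- mean(pv_by_k[k_null + 1] <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # power when LOF sites land in ROHs at twice the F_ROH rate
  k_alt <- rbinom(500, n, 2 * p0)
  expect_gte(mean(pv_by_k[k_alt + 1] <= 0.05), 0.8)
})

test_that("load proportions shift little when missingness doubles", {
  base <- function(seed, miss) {
    cfg <- sim_config(seed = seed, missing_rate = miss,
                      contigs = c(a = 4e6, b = 2e6), snp_density = 300)
    sim <- simulate_cohort(cfg)
    pol <- polarize(sim$gm)
    cl <- classify_effects(sim$gm, sim$annotation, sim$sequences)
    prof <- genotype_class_proportions(pol, cl)
    prof[prof$class == "SYN" & prof$n_sites > 0, ]
  }
  p1 <- base(301, 0.03)
  p2 <- base(302, 0.06)
  se <- function(x) sd(x) / sqrt(length(x))
  for (cat in c("p_anc", "p_het", "p_der")) {
    diff <- abs(mean(p1[[cat]]) - mean(p2[[cat]]))
    expect_lte(diff, 2 * sqrt(se(p1[[cat]])^2 + se(p2[[cat]])^2) + 1e-8)
  }
})
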