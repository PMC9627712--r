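test_that("unique fixed LOF rule handles missingness, hets and ordering", {
  pol <- rbind(
    c(2L, 2L, NA, 0L, 0L, 0L),   # retained: missing focal ignored
    c(2L, 2L, 2L, 0L, 1L, 0L),   # one background het -> excluded
    c(2L, 1L, 2L, 0L, 0L, 0L),   # focal het -> excluded
    c(NA, NA, NA, 0L, 0L, 0L),   # all focal missing -> excluded + logged
    c(2L, 2L, 2L, NA, 0L, 0L))   # missing background ignored -> retained
  colnames(pol) <- c("f1", "f2", "f3", "b1", "b2", "b3")
  got <- unique_fixed_lof(pol, 1:5, c("f1", "f2", "f3"),
                          c("b1", "b2", "b3"))
  expect_equal(as.integer(got), c(1L, 5L))
  expect_equal(attr(got, "n_all_focal_missing"), 1)
  # invariant to sample ordering
  perm <- c("b2", "f3", "b1", "f1", "b3", "f2")
  got2 <- unique_fixed_lof(pol[, perm], 1:5, c("f1", "f2", "f3"),
                           c("b1", "b2", "b3"))
  expect_equal(as.integer(got2), as.integer(got))
  expect_error(unique_fixed_lof(pol, 1:5, character(0), "b1"), "non-empty")
  expect_error(unique_fixed_lof(pol, 1:5, c("f1", "b1"), c("b1", "b2")),
               "disjoint")
})

test_that("fixture cohort: unique fixed LOF equals the planted truth", {
  sim <- fixture_cohort()
  pol <- polarize(sim$gm)
  cl <- fixture_classes()
  grp <- fixture_groups()
  focal <- names(grp)[grp == sim$config$focal_group]
  lofi <- which(cl == "LOF")
  got <- unique_fixed_lof(pol, lofi, focal, setdiff(names(grp), focal))
  key <- paste(sim$gm$sites$contig, sim$gm$sites$pos)
  tv <- sim$truth$variants
  want <- paste(tv$contig, tv$pos)[tv$class == "LOF" &
                                     tv$pattern == "fixed_in_group"]
  expect_setequal(key[got], want)
  expect_equal(length(got), 3)
})

test_that("unique deletions: carrier logic, distance window and size flag", {
  gff_gene <- list(gene_id = "g1", contig = "c1", strand = "+",
                   usable = TRUE,
                   cds = data.frame(start = 100, end = 200, phase = 0L))
  ann <- structure(list(g1 = gff_gene), class = "gene_annotation")
  dels <- deletion_calls(
    contig = rep("c1", 5),
    start = c(150, 2200, 2201, 5e4, 1e5),
    end = c(180, 2300, 2400, 5e4 + 2e6, 1e5 + 100),
    id = paste0("D", 1:5),
    carriers = list(c("f1", "f2"), c("f1", "f2"), c("f1", "f2"),
                    c("f1", "f2"), c("f1", "f2", "b1")))
  got <- unique_deletions(dels, c("f1", "f2"), c("b1", "b2"), ann)
  expect_setequal(got$id, c("D1", "D2", "D3", "D4"))  # D5 has a bg carrier
  expect_equal(got$gene_distance[got$id == "D1"], 0)   # overlaps the gene
  expect_true(got$proximal[got$id == "D1"])
  # distance exactly 2000 -> proximal; 2001 -> not
  expect_equal(got$gene_distance[got$id == "D2"], 2000)
  expect_true(got$proximal[got$id == "D2"])
  expect_equal(got$gene_distance[got$id == "D3"], 2001)
  expect_false(got$proximal[got$id == "D3"])
  expect_true(got$oversized[got$id == "D4"])
  expect_false(any(got$oversized[got$id != "D4"]))
  # a deletion absent from one focal sample is not unique
  dels2 <- dels
  dels2$carriers[[1]] <- "f1"
  got2 <- unique_deletions(dels2, c("f1", "f2"), c("b1", "b2"), ann)
  expect_false("D1" %in% got2$id)
})

test_that("fixture cohort: unique deletions equal the planted truth", {
  sim <- fixture_cohort()
  grp <- fixture_groups()
  focal <- names(grp)[grp == sim$config$focal_group]
  got <- unique_deletions(sim$deletions, focal, setdiff(names(grp), focal),
                          sim$annotation)
  want <- sim$truth$deletions$id[sim$truth$deletions$pattern ==
                                   "focal_private"]
  expect_setequal(got$id, want)
  # order invariance in the carrier lists
  shuf <- sim$deletions
  shuf$carriers <- lapply(shuf$carriers, rev)
  got2 <- unique_deletions(shuf, rev(focal), setdiff(names(grp), focal),
                           sim$annotation)
  expect_setequal(got2$id, want)
})

test_that("harmonic-mean Ne matches closed forms and its inequality", {
  cs <- census_series(c(2000, 2001, 2000, 2001),
                      c("spring", "spring", "autumn", "autumn"),
                      c(38, 38, 100, 50))
  ne <- harmonic_mean_ne(cs)
  expect_equal(ne$ne[ne$season == "spring"], 38)        # equal counts
  expect_equal(round(ne$ne[ne$season == "autumn"], 2), 66.67)
  expect_equal(ne$n_years, c(2, 2))
  # harmonic <= arithmetic on random inputs, invariant to ordering
  set.seed(8)
  for (r in 1:20) {
    counts <- sample(20:500, 12)
    cs2 <- census_series(1:12, rep("spring", 12), counts)
    ne2 <- harmonic_mean_ne(cs2)
    expect_lte(ne2$ne, mean(counts))
    cs3 <- census_series(1:12, rep("spring", 12), rev(counts))
    expect_equal(harmonic_mean_ne(cs3)$ne, ne2$ne)
  }
})

test_that("Weir-Cockerham components match a from-scratch hand computation", {
  # two sites, two populations (n = 5 and 4 genotyped at both sites)
  g1 <- rbind(c(0L, 0L, 1L, 1L, 2L), c(0L, 0L, 0L, 1L, 1L))
  g2 <- rbind(c(2L, 2L, 2L, 1L, NA), c(1L, 1L, 2L, 2L, NA))
  gt <- cbind(g1, g2)
  colnames(gt) <- c(paste0("a", 1:5), paste0("b", 1:5))
  gm <- genotype_matrix(data.frame(contig = "c", pos = 1:2,
                                   ref = "A", alt = "C"), gt)
  f <- weir_cockerham_fst(gm, setNames(rep(c("A", "B"), each = 5),
                                       colnames(gt)))
  # frozen values from an independent transcription of the 1984 estimator
  expect_equal(unname(f$components[, "a"]), c(0.08428571, 0.13357143),
               tolerance = 1e-7)
  expect_equal(unname(f$components[, "b"]), c(0.04345238, -0.03253968),
               tolerance = 1e-7)
  expect_equal(unname(f$components[, "c"]), c(1 / 6, 2 / 9),
               tolerance = 1e-7)
  expect_equal(f$fst_weighted, 0.352714423386, tolerance = 1e-10)
  expect_equal(f$n_sites_used, 2)
})

test_that("F_st hits the boundary cases: fixed difference and null", {
  gt <- cbind(matrix(0L, 5, 10), matrix(2L, 5, 10))
  colnames(gt) <- paste0("s", 1:20)
  gm <- genotype_matrix(data.frame(contig = "c", pos = 1:5,
                                   ref = "A", alt = "C"), gt)
  grp <- setNames(rep(c("x", "y"), each = 10), paste0("s", 1:20))
  expect_equal(weir_cockerham_fst(gm, grp)$fst_weighted, 1)
  # identical groups: genome-wide estimate within 0.01 of zero (10k sites)
  set.seed(17)
  n <- 10000
  p <- runif(n, 0.05, 0.95)
  gt2 <- matrix(rbinom(n * 20, 2, rep(p, 20)), nrow = n,
                dimnames = list(NULL, paste0("s", 1:20)))
  gm2 <- genotype_matrix(data.frame(contig = "c", pos = 1:n,
                                    ref = "A", alt = "C"), gt2)
  expect_lte(abs(weir_cockerham_fst(gm2, grp)$fst_weighted), 0.01)
  # monomorphic and single-group-only sites are skipped
  gt3 <- rbind(rep(0L, 20), c(rep(0L, 10), rep(NA, 10)),
               c(rep(c(0L, 1L), 5), rep(1L, 10)))
  colnames(gt3) <- paste0("s", 1:20)
  gm3 <- genotype_matrix(data.frame(contig = "c", pos = 1:3,
                                    ref = "A", alt = "C"), gt3)
  f3 <- weir_cockerham_fst(gm3, grp)
  expect_equal(f3$n_sites_used, 1)
  expect_equal(f3$n_skipped, 2)
})
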