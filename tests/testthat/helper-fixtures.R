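# Shared fixtures and independent oracles. The fixture cohort is built once
# per test run from the default simulator configuration at a fixed seed.

.fix_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fix_env$sim))
    .fix_env$sim <- simulate_cohort(sim_config(seed = 42))
  .fix_env$sim
}

fixture_scan <- function() {
  if (is.null(.fix_env$scan))
    .fix_env$scan <- roh_scan(fixture_cohort()$gm, fixture_cohort()$genome)
  .fix_env$scan
}

fixture_classes <- function() {
  if (is.null(.fix_env$classes)) {
    sim <- fixture_cohort()
    .fix_env$classes <- classify_effects(sim$gm, sim$annotation,
                                         sim$sequences)
  }
  .fix_env$classes
}

fixture_groups <- function() {
  sim <- fixture_cohort()
  stats::setNames(sim$gm$sample_table$group, sim$gm$sample_table$sample_id)
}

# base-level Jaccard index between two interval sets (data frames with
# contig/start/end, 0-based half-open)
interval_jaccard <- function(a, b) {
  ov <- 0; un <- 0
  for (ctg in unique(c(a$contig, b$contig))) {
    ia <- IRanges::reduce(IRanges::IRanges(
      a$start[a$contig == ctg] + 1, a$end[a$contig == ctg]))
    ib <- IRanges::reduce(IRanges::IRanges(
      b$start[b$contig == ctg] + 1, b$end[b$contig == ctg]))
    ov <- ov + sum(IRanges::width(IRanges::intersect(ia, ib)))
    un <- un + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (un == 0) return(NA_real_)
  ov / un
}

# ---- independent translate-and-compare effect oracle -------------------
# Rebuilds the whole spliced CDS from sequence + gene model, applies the
# substitution at the genomic level, translates both sequences in full and
# compares the proteins. LOF iff the first stop moves earlier.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_transcript <- function(gene, seqs) {
  chunks <- substring(seqs[[gene$contig]], gene$cds$start + 1, gene$cds$end)
  if (gene$strand == "-") chunks <- vapply(chunks, oracle_revcomp, "")
  paste(chunks, collapse = "")
}

oracle_translate <- function(dna) {
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(dna),
                          if.fuzzy.codon = "X")))
}

oracle_classify <- function(contig, pos, ref, alt, gene, seqs) {
  # mutate the genome, then rebuild and translate the full CDS
  ctg <- seqs[[gene$contig]]
  stopifnot(substr(ctg, pos, pos) == ref)
  mut <- seqs
  substr(ctg, pos, pos) <- alt
  mut[[gene$contig]] <- ctg
  tx_ref <- oracle_transcript(gene, seqs)
  tx_alt <- oracle_transcript(gene, mut)
  trim <- gene$cds$phase[1]
  usable_len <- (nchar(tx_ref) - trim) %/% 3 * 3
  p_ref <- oracle_translate(substr(tx_ref, trim + 1, trim + usable_len))
  p_alt <- oracle_translate(substr(tx_alt, trim + 1, trim + usable_len))
  if (identical(p_ref, p_alt)) return("SYN")
  first_stop <- function(p) {
    i <- regexpr("*", p, fixed = TRUE)
    if (i < 0) nchar(p) + 1L else as.integer(i)
  }
  if (first_stop(p_alt) < first_stop(p_ref)) return("LOF")
  "NSYN"
}

# ---- codon-test gene builders ------------------------------------------
# A 4-codon gene (ATG | CCT | <test codon> | TAA) on either strand, with
# the CDS either contiguous or split across two exons so that the test
# codon straddles the junction. Returns the gene record, the sequences,
# and a mapper from (codon position 1:3, transcript-strand base) to the
# genomic (pos, ref, alt).
make_codon_gene <- function(test_codon, strand = "+", split = FALSE,
                            pad = 10L) {
  tx <- paste0("ATG", "CCT", test_codon, "TAA")   # 12 bases
  n <- nchar(tx)
  if (!split) {
    widths <- n
  } else {
    widths <- c(7L, 5L)   # codon 3 spans the junction (base 7 | bases 8-9)
  }
  intron <- if (split) 20L else integer(0)
  span <- n + sum(intron)
  g_w <- if (strand == "+") widths else rev(widths)
  g_introns <- if (strand == "+") intron else rev(intron)
  starts <- pad + cumsum(c(0L, head(g_w, -1L) + g_introns))
  cds <- data.frame(start = starts, end = starts + g_w)
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  tx_w <- cds$end - cds$start
  before <- cumsum(c(0, head(tx_w, -1)))
  cds$phase <- as.integer((3 - before %% 3) %% 3)
  rownames(cds) <- NULL
  gene <- list(gene_id = "g1", contig = "ctg", strand = strand,
               usable = TRUE, cds = cds)
  # embed the transcript into a random-free deterministic background
  total <- pad + span + pad
  base <- strsplit(paste(rep("ACGT", ceiling(total / 4)), collapse = ""),
                   "")[[1]][seq_len(total)]
  off <- 0L
  for (i in seq_len(nrow(cds))) {
    w <- cds$end[i] - cds$start[i]
    chunk <- substr(tx, off + 1L, off + w)
    if (strand == "-") chunk <- oracle_revcomp(chunk)
    base[(cds$start[i] + 1L):cds$end[i]] <- strsplit(chunk, "")[[1]]
    off <- off + w
  }
  seqs <- c(ctg = paste(base, collapse = ""))
  tx2genomic <- function(tpos) {
    off <- 0L
    for (i in seq_len(nrow(cds))) {
      w <- cds$end[i] - cds$start[i]
      if (tpos <= off + w) {
        within <- tpos - off
        return(if (strand == "+") cds$start[i] + within
               else cds$end[i] - within + 1L)
      }
      off <- off + w
    }
    stop("outside CDS")
  }
  variant_at <- function(codon_pos, alt_base_tx) {
    tpos <- 6L + codon_pos
    gp <- tx2genomic(tpos)
    ref_tx <- substr(tx, tpos, tpos)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    list(pos = gp,
         ref = if (strand == "+") ref_tx else comp[[ref_tx]],
         alt = if (strand == "+") alt_base_tx else comp[[alt_base_tx]])
  }
  list(gene = gene, seqs = seqs, variant_at = variant_at)
}

# ---- exhaustive HMM path enumeration -----------------------------------
# Joint log-probability of a state path under the two-state ROH model,
# recomputed from first principles (1 = autozygous, 2 = outside).
path_logprob <- function(states, het, d, eps, p_het_out) {
  em <- function(t, s) {
    if (s == 1) { if (het[t]) log(eps) else log1p(-eps) }
    else { if (het[t]) log(p_het_out[t]) else log1p(-p_het_out[t]) }
  }
  lp <- log(0.5) + em(1, states[1])
  if (length(states) > 1) for (t in 2:length(states)) {
    psw <- d[t - 1]
    lp <- lp + (if (states[t] != states[t - 1]) log(psw) else log1p(-psw)) +
      em(t, states[t])
  }
  lp
}

# all 2^n paths; returns list(best_states, best_lp, n_ties)
brute_force_decode <- function(het, d, eps, p_het_out) {
  n <- length(het)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  lp <- apply(paths, 1, path_logprob, het = het, d = d, eps = eps,
              p_het_out = p_het_out)
  best <- max(lp)
  ties <- which(lp > best - 1e-12)
  list(states = as.integer(paths[which.max(lp), ]), lp = best,
       n_ties = length(ties))
}
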