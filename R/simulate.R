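#' Configuration of the synthetic cohort simulator
#'
#' The simulator emulates resequenced desert-pupfish-like cohorts: diploid
#' genotypes carrying per-individual autozygous tract mosaics, a Beta
#' allele-frequency spectrum outside tracts, coding genes with planted
#' synonymous/missense/stop-gain variants of guaranteed class, per-genotype
#' missingness and error, and group-private deletions. All randomness flows
#' from the single seed: identical config + seed give byte-identical output
#' files.
#'
#' Defaults describe a small three-species cohort (four samples each): one
#' severely inbred focal group (target F = 0.6, tracts of recent ancestry,
#' g = 10), one mildly inbred group (F = 0.12, g = 18) and one intermediate
#' group (F = 0.3, g = 12), on a 20 Mb two-contig genome at 500 SNPs/Mb
#' with a recombination rate of 4.6 cM/Mb (site density scaled down from
#' the several-thousand-per-Mb density of real whole-genome SNP sets).
#'
#' @param seed integer RNG seed.
#' @param contigs named numeric vector of contig lengths in bp.
#' @param snp_density background SNP sites per Mb.
#' @param samples data frame `sample_id`, `group`, `target_F` (in \[0,1)),
#'   `tract_age_g` (generations; tract lengths are exponential with mean
#'   `100/(2 g)` cM).
#' @param allele_freq_beta Beta(a, b) parameters of the alternate-allele
#'   frequency at non-autozygous sites.
#' @param het_error_inside_roh probability a site inside an autozygous
#'   tract is flipped to HET (genotyping error).
#' @param missing_rate per-genotype missingness probability.
#' @param mispolarize_rate fraction of background sites whose REF/ALT roles
#'   are deliberately swapped, to probe robustness of the
#'   reference-as-ancestral assumption (default 0).
#' @param recomb_rate_cM_per_Mb recombination rate used to convert tract
#'   lengths from cM to bp.
#' @param genes list: `n`, `codons` (min, max codons incl. the terminal
#'   stop), `exons` (min, max CDS chunks), `intron` (min, max intron bp).
#' @param planted named list per class (`SYN`, `NSYN`, `LOF`) of counts per
#'   privacy pattern `c(shared=, group_private=, fixed_in_group=)`.
#' @param deletions list: `n_private` (carried by exactly the focal group),
#'   `n_other`, `length` (min, max bp), `near_gene_fraction`.
#' @param focal_group group receiving the fixed-private variants and
#'   private deletions (default: first group in `samples`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       contigs = c(chr1 = 12e6, chr2 = 8e6),
                       snp_density = 500,
                       samples = NULL,
                       allele_freq_beta = c(0.5, 3),
                       het_error_inside_roh = 0.002,
                       missing_rate = 0.03,
                       mispolarize_rate = 0,
                       recomb_rate_cM_per_Mb = 4.6,
                       genes = list(n = 24, codons = c(120, 240),
                                    exons = c(1, 3), intron = c(100, 500)),
                       planted = list(
                         SYN = c(shared = 6, group_private = 3,
                                 fixed_in_group = 2),
                         NSYN = c(shared = 6, group_private = 3,
                                  fixed_in_group = 2),
                         LOF = c(shared = 6, group_private = 3,
                                 fixed_in_group = 3)),
                       deletions = list(n_private = 4, n_other = 6,
                                        length = c(500, 5000),
                                        near_gene_fraction = 0.5),
                       focal_group = NULL) {
  if (is.null(samples)) {
    grp <- rep(c("spA", "spB", "spC"), each = 4)
    samples <- data.frame(
      sample_id = paste0(grp, "_", rep(1:4, times = 3)),
      group = grp,
      target_F = rep(c(0.6, 0.12, 0.3), each = 4),
      tract_age_g = rep(c(10, 18, 12), each = 4),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(samples$target_F >= 0), all(samples$target_F < 1),
            all(samples$tract_age_g >= 1),
            het_error_inside_roh >= 0, het_error_inside_roh <= 1,
            missing_rate >= 0, missing_rate <= 1,
            mispolarize_rate >= 0, mispolarize_rate <= 1)
  if (is.null(focal_group)) focal_group <- samples$group[1]
  structure(list(seed = seed, contigs = contigs, snp_density = snp_density,
                 samples = samples, allele_freq_beta = allele_freq_beta,
                 het_error_inside_roh = het_error_inside_roh,
                 missing_rate = missing_rate,
                 mispolarize_rate = mispolarize_rate,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 genes = genes, planted = planted, deletions = deletions,
                 focal_group = focal_group),
            class = "sim_config")
}

# ---- interval arithmetic on 2-column [start, end) matrices -------------

.iv_merge <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) out[j, 2] <- max(out[j, 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}

# parts of [s, e) not covered by merged interval set cur
.iv_novel <- function(s, e, cur) {
  keep <- matrix(numeric(0), ncol = 2)
  pos <- s
  if (nrow(cur)) {
    ov <- cur[cur[, 1] < e & cur[, 2] > s, , drop = FALSE]
    if (nrow(ov)) ov <- ov[order(ov[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(ov))) {
      if (ov[i, 1] > pos) keep <- rbind(keep, c(pos, min(ov[i, 1], e)))
      pos <- max(pos, ov[i, 2])
      if (pos >= e) break
    }
  }
  if (pos < e) keep <- rbind(keep, c(pos, e))
  keep
}

# lay autozygous tracts on [0, G) until exactly target_bp bases are covered
.lay_tracts <- function(G, target_bp, mean_bp) {
  cur <- matrix(numeric(0), ncol = 2)
  if (target_bp <= 0) return(cur)
  if (mean_bp >= G)
    stop("infeasible config: mean tract length exceeds the genome")
  total <- 0
  max_iter <- ceiling(20 * target_bp / mean_bp) + 2000
  for (iter in seq_len(max_iter)) {
    if (total >= target_bp) break
    s <- floor(stats::runif(1, 0, G))
    L <- max(1, round(stats::rexp(1, 1 / mean_bp)))
    e <- min(s + L, G)
    if (e <= s) next
    nov <- .iv_novel(s, e, cur)
    if (!nrow(nov)) next
    novlen <- sum(nov[, 2] - nov[, 1])
    if (total + novlen >= target_bp) {
      need <- target_bp - total
      kept <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(nrow(nov))) {
        w <- nov[i, 2] - nov[i, 1]
        if (need <= 0) break
        if (w <= need) { kept <- rbind(kept, nov[i, ]); need <- need - w }
        else { kept <- rbind(kept, c(nov[i, 1], nov[i, 1] + need)); need <- 0 }
      }
      cur <- .iv_merge(rbind(cur, kept))
      total <- target_bp
    } else {
      cur <- .iv_merge(rbind(cur, nov))
      total <- total + novlen
    }
  }
  if (total < target_bp)
    stop("infeasible config: could not reach target autozygous fraction")
  cur
}

# split genome-coordinate intervals onto contigs
.iv_to_contigs <- function(m, contigs) {
  offs <- c(0, cumsum(as.numeric(contigs)))
  rows <- list()
  for (k in seq_along(contigs)) {
    lo <- offs[k]; hi <- offs[k + 1]
    ov <- m[m[, 1] < hi & m[, 2] > lo, , drop = FALSE]
    if (nrow(ov))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = names(contigs)[k],
        start = pmax(ov[, 1], lo) - lo, end = pmin(ov[, 2], hi) - lo)
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- gene and codon machinery ------------------------------------------

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"), paste0),
                               c("A", "C", "G", "T"), paste0))
.NONSTOP_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

# (ref codon, substituted base on transcript strand, position in codon)
.PLANT_TEMPLATES <- list(
  SYN = list(c("GAA", "G", "3"), c("CTG", "A", "3"), c("GGT", "C", "3")),
  NSYN = list(c("GAA", "T", "2"), c("CTT", "A", "2"), c("AAA", "G", "1")),
  LOF = list(c("TGG", "A", "3"), c("TAC", "A", "3"), c("TCA", "G", "2")))

.make_gene_skeletons <- function(config, genome) {
  gcfg <- config$genes
  if (is.null(gcfg) || gcfg$n == 0) return(list())
  occupied <- lapply(genome$name, function(x) matrix(numeric(0), ncol = 2))
  names(occupied) <- genome$name
  out <- list()
  for (i in seq_len(gcfg$n)) {
    n_cod <- sample(gcfg$codons[1]:gcfg$codons[2], 1)
    n_ex <- sample(gcfg$exons[1]:gcfg$exons[2], 1)
    coding <- 3L * n_cod
    if (n_ex == 1) widths <- coding else {
      repeat {
        cuts <- sort(sample(seq_len(coding - 1), n_ex - 1))
        widths <- diff(c(0, cuts, coding))
        if (all(widths >= 30)) break
      }
    }
    introns <- if (n_ex > 1)
      sample(gcfg$intron[1]:gcfg$intron[2], n_ex - 1, replace = TRUE)
    else integer(0)
    span <- coding + sum(introns)
    strand <- sample(c("+", "-"), 1)
    placed <- FALSE
    for (try in 1:200) {
      k <- sample(seq_len(nrow(genome)), 1, prob = genome$length)
      clen <- genome$length[k]
      if (clen < span + 8000) next
      st <- floor(stats::runif(1, 2000, clen - span - 2000))
      occ <- occupied[[genome$name[k]]]
      if (nrow(occ) && any(occ[, 1] < st + span + 3000 &
                           occ[, 2] > st - 3000)) next
      occupied[[genome$name[k]]] <- rbind(occ, c(st, st + span))
      # genomic chunk widths left to right
      g_w <- if (strand == "+") widths else rev(widths)
      starts <- st + cumsum(c(0, utils::head(g_w, -1) +
                                if (n_ex > 1) {
                                  if (strand == "+") introns else rev(introns)
                                } else integer(0)))
      cds <- data.frame(start = starts, end = starts + g_w)
      if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
      tx_w <- cds$end - cds$start
      before <- cumsum(c(0, utils::head(tx_w, -1)))
      cds$phase <- as.integer((3 - before %% 3) %% 3)
      rownames(cds) <- NULL
      out[[length(out) + 1L]] <- list(
        gene_id = sprintf("gene%02d", i), contig = genome$name[k],
        strand = strand, usable = TRUE, cds = cds, n_cod = n_cod)
      placed <- TRUE
      break
    }
    if (!placed)
      warning("could not place gene ", i, "; genome too crowded",
              call. = FALSE)
  }
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

# transcript coordinate -> genomic 1-based position
.genomic_pos <- function(gene, tpos) {
  off <- 0L
  for (i in seq_len(nrow(gene$cds))) {
    w <- gene$cds$end[i] - gene$cds$start[i]
    if (tpos <= off + w) {
      within <- tpos - off
      return(if (gene$strand == "+") gene$cds$start[i] + within
             else gene$cds$end[i] - within + 1L)
    }
    off <- off + w
  }
  stop("transcript coordinate outside CDS")
}

#' Simulate a cohort with known truth
#'
#' Generates, from a single seed, a complete synthetic dataset: reference
#' contig sequences, gene models, a multi-sample SNP genotype matrix built
#' on per-sample autozygous tract mosaics, planted coding variants whose
#' SYN/NSYN/LOF class is guaranteed by construction against the standard
#' codon table, planted deletions, and truth tables for all of it.
#'
#' Tracts are laid down as a Poisson process of exponential lengths (mean
#' `100/(2 g)` cM converted to bp) with overlaps merged, until the realized
#' autozygous fraction reaches `target_F` exactly (the last tract is
#' truncated); tracts are truncated at contig ends. Inside tracts
#' genotypes are homozygous for a single drawn allele (flipped to HET with
#' probability `het_error_inside_roh`); outside they are Hardy-Weinberg
#' draws at Beta-distributed frequencies; genotypes go missing
#' independently at `missing_rate`. Background SNPs are placed uniformly
#' outside CDS so that coding variation is exactly the planted set.
#' Shared-pattern planted genotypes follow the sample's autozygosity
#' mosaic and see the same missingness as background sites;
#' group-private and fixed-private planted genotypes are fully observed
#' and exempt from error, so the privacy truth tables are exact.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes `cohort.vcf`,
#'   `genome.fa`, `genes.gff3`, `deletions.bed`, `sample_table.tsv` and
#'   `truth_*.tsv` files.
#' @return List of class `sim_cohort`: `genome`, `sequences` (named
#'   character, or NULL when no genes and no `dir`), `gm`
#'   ([genotype_matrix()]), `annotation`, `deletions`, `truth` (list:
#'   `roh`, `variants`, `deletions`, `samples`), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- genome_descriptor(names(config$contigs), config$contigs)
  G <- total_size(genome)
  samples <- config$samples
  n_smp <- nrow(samples)

  genes <- .make_gene_skeletons(config, genome)

  # reference sequences (base vectors), needed when genes exist or writing
  need_seq <- length(genes) > 0 || !is.null(dir)
  seqs <- NULL
  if (need_seq) {
    seqs <- lapply(stats::setNames(genome$length, genome$name),
                   function(L) sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE))
  }

  # planted variant assignment and transcripts
  plant <- list()
  if (length(genes)) {
    used <- lapply(genes, function(g) integer(0))
    for (cl in names(config$planted)) {
      counts <- config$planted[[cl]]
      for (pat in names(counts)) {
        for (rep_i in seq_len(counts[[pat]])) {
          for (try in 1:500) {
            gi <- sample(seq_along(genes), 1)
            g <- genes[[gi]]
            free <- setdiff(2:(g$n_cod - 1), used[[gi]])
            if (!length(free)) next
            idx <- if (length(free) == 1) free else sample(free, 1)
            used[[gi]] <- c(used[[gi]], idx)
            tpl <- .PLANT_TEMPLATES[[cl]][[
              sample(length(.PLANT_TEMPLATES[[cl]]), 1)]]
            plant[[length(plant) + 1L]] <- list(
              class = cl, pattern = pat, gene = names(genes)[gi],
              codon_idx = idx, ref_codon = tpl[1], alt_base = tpl[2],
              codon_pos = as.integer(tpl[3]))
            break
          }
        }
      }
    }
    # build transcripts (ATG ... TAA) with planted codons, write into genome
    for (gn in names(genes)) {
      g <- genes[[gn]]
      codons <- c("ATG",
                  sample(.NONSTOP_CODONS, g$n_cod - 2, replace = TRUE),
                  "TAA")
      for (p in plant) if (p$gene == gn) codons[p$codon_idx] <- p$ref_codon
      tx <- paste(codons, collapse = "")
      off <- 0L
      for (i in seq_len(nrow(g$cds))) {
        w <- g$cds$end[i] - g$cds$start[i]
        chunk <- substr(tx, off + 1L, off + w)
        if (g$strand == "-")
          chunk <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(chunk)))
        seqs[[g$contig]][(g$cds$start[i] + 1L):g$cds$end[i]] <-
          strsplit(chunk, "")[[1]]
        off <- off + w
      }
      genes[[gn]]$transcript <- tx
    }
  }

  # CDS exclusion zones per contig, for background SNP placement
  cds_by_ctg <- lapply(stats::setNames(genome$name, genome$name),
                       function(ctg) {
    rows <- lapply(genes, function(g)
      if (g$contig == ctg) as.matrix(g$cds[, c("start", "end")]) else NULL)
    m <- do.call(rbind, rows)
    if (is.null(m)) matrix(numeric(0), ncol = 2) else .iv_merge(m)
  })

  # background SNP sites
  site_rows <- list()
  freqs <- list()
  ab <- config$allele_freq_beta
  for (k in seq_len(nrow(genome))) {
    ctg <- genome$name[k]
    m <- round(genome$length[k] * config$snp_density / 1e6)
    if (m == 0) next
    cand <- sample.int(genome$length[k], min(genome$length[k],
                                             ceiling(1.3 * m) + 50))
    excl <- cds_by_ctg[[ctg]]
    if (nrow(excl)) {
      ix <- findInterval(cand - 1, excl[, 1])
      inside <- ix > 0 & (cand - 1) < excl[pmax(ix, 1L), 2]
      cand <- cand[!inside]
    }
    pos <- sort(cand[seq_len(min(m, length(cand)))])
    p <- pmin(pmax(stats::rbeta(length(pos), ab[1], ab[2]), 0.005), 0.995)
    base_ref <- if (!is.null(seqs)) seqs[[ctg]][pos] else
      sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    alt <- vapply(base_ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    site_rows[[ctg]] <- data.frame(contig = ctg, pos = pos, ref = base_ref,
                                   alt = unname(alt),
                                   stringsAsFactors = FALSE)
    freqs[[ctg]] <- p
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  p_all <- unlist(freqs, use.names = FALSE)
  if (config$mispolarize_rate > 0 && nrow(sites)) {
    swap <- stats::runif(nrow(sites)) < config$mispolarize_rate
    tmp <- sites$ref[swap]
    sites$ref[swap] <- sites$alt[swap]
    sites$alt[swap] <- tmp
    p_all[swap] <- 1 - p_all[swap]
    # keep the reference sequence in step with the swapped REF allele
    if (!is.null(seqs)) for (ctg in unique(sites$contig[swap])) {
      i <- swap & sites$contig == ctg
      seqs[[ctg]][sites$pos[i]] <- sites$ref[i]
    }
    attr(sites, "mispolarized") <- sum(swap)
  }

  # autozygous mosaics and background genotypes
  offs <- c(0, cumsum(as.numeric(genome$length)))
  names(offs) <- c(genome$name, "END")
  roh_truth <- list()
  tracts_list <- vector("list", n_smp)
  gt <- matrix(NA_integer_, nrow = nrow(sites), ncol = n_smp,
               dimnames = list(NULL, samples$sample_id))
  gpos <- sites$pos + offs[sites$contig]   # genome-wide coordinate
  for (j in seq_len(n_smp)) {
    mean_cM <- 100 / (2 * samples$tract_age_g[j])
    mean_bp <- mean_cM / config$recomb_rate_cM_per_Mb * 1e6
    target_bp <- round(samples$target_F[j] * G)
    tr <- .lay_tracts(G, target_bp, mean_bp)
    tracts_list[[j]] <- tr
    if (nrow(tr)) {
      td <- .iv_to_contigs(tr, config$contigs)
      td$sample <- samples$sample_id[j]
      roh_truth[[length(roh_truth) + 1L]] <-
        td[, c("sample", "contig", "start", "end")]
    }
    inside <- rep(FALSE, nrow(sites))
    if (nrow(tr)) {
      ix <- findInterval(gpos - 1, tr[, 1])
      inside <- ix > 0 & (gpos - 1) < tr[pmax(ix, 1L), 2]
    }
    g <- integer(nrow(sites))
    n_in <- sum(inside)
    if (n_in) {
      g[inside] <- 2L * stats::rbinom(n_in, 1, p_all[inside])
      err <- stats::runif(n_in) < config$het_error_inside_roh
      g[inside][err] <- 1L
    }
    n_out <- sum(!inside)
    if (n_out) g[!inside] <- stats::rbinom(n_out, 2, p_all[!inside])
    miss <- stats::runif(nrow(sites)) < config$missing_rate
    g[miss] <- NA_integer_
    gt[, j] <- g
  }
  roh_truth <- if (length(roh_truth)) do.call(rbind, roh_truth) else
    data.frame(sample = character(0), contig = character(0),
               start = numeric(0), end = numeric(0))
  rownames(roh_truth) <- NULL

  # planted variant sites + genotypes
  var_truth <- data.frame(contig = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          class = character(0), pattern = character(0),
                          group = character(0), gene_id = character(0),
                          stringsAsFactors = FALSE)
  if (length(plant)) {
    groups <- unique(samples$group)
    focal <- config$focal_group
    priv_cycle <- 0L
    prows <- list()
    pgt <- matrix(NA_integer_, nrow = 0, ncol = n_smp)
    for (p in plant) {
      g <- genes[[p$gene]]
      tpos <- 3L * (p$codon_idx - 1L) + p$codon_pos
      gp <- .genomic_pos(g, tpos)
      ref_t <- substr(p$ref_codon, p$codon_pos, p$codon_pos)
      alt_t <- p$alt_base
      ref_g <- if (g$strand == "+") ref_t else .revcomp1(ref_t)
      alt_g <- if (g$strand == "+") alt_t else .revcomp1(alt_t)
      stopifnot(seqs[[g$contig]][gp] == ref_g)
      if (p$pattern == "fixed_in_group") {
        grp <- focal
        gvec <- ifelse(samples$group == grp, 2L, 0L)
      } else if (p$pattern == "group_private") {
        grp <- groups[priv_cycle %% length(groups) + 1L]
        priv_cycle <- priv_cycle + 1L
        members <- which(samples$group == grp)
        gvec <- rep(0L, n_smp)
        gvec[members] <- c(1L, sample(1:2, length(members) - 1,
                                      replace = TRUE))
      } else {
        # shared variants respect each sample's autozygosity mosaic:
        # inside a tract the genotype is homozygous for the single drawn
        # haplotype allele, outside it is a Hardy-Weinberg draw
        grp <- NA_character_
        q <- stats::runif(1, 0.15, 0.6)
        gp_global <- gp + offs[[g$contig]]
        gvec <- integer(n_smp)
        for (j in seq_len(n_smp)) {
          tr <- tracts_list[[j]]
          inside <- nrow(tr) > 0 &&
            any(tr[, 1] <= gp_global - 1 & gp_global - 1 < tr[, 2])
          gvec[j] <- if (inside) 2L * stats::rbinom(1, 1, q)
          else stats::rbinom(1, 2, q)
        }
        # keep the site segregating; the forced heterozygote goes into
        # the least inbred sample
        if (all(gvec == 0L) || all(gvec == 2L))
          gvec[which.min(samples$target_F)] <- 1L
        # shared sites see missingness like any other genotype call;
        # privacy-pattern sites stay fully observed so truth is exact
        gvec[stats::runif(n_smp) < config$missing_rate] <- NA_integer_
      }
      # a non-fixed pattern must never mimic the fixed-private signature
      if (p$pattern != "fixed_in_group") {
        fmask <- samples$group == focal
        fv <- gvec[fmask]
        if (sum(!is.na(fv)) >= 1 && all(fv == 2L, na.rm = TRUE) &&
            all(gvec[!fmask] == 0L, na.rm = TRUE))
          gvec[which(fmask)[1]] <- 1L
      }
      prows[[length(prows) + 1L]] <- data.frame(
        contig = g$contig, pos = gp, ref = ref_g, alt = alt_g,
        class = p$class, pattern = p$pattern, group = grp,
        gene_id = p$gene, stringsAsFactors = FALSE)
      pgt <- rbind(pgt, gvec)
    }
    var_truth <- do.call(rbind, prows)
    rownames(var_truth) <- NULL
    sites <- rbind(sites, var_truth[, c("contig", "pos", "ref", "alt")])
    gt <- rbind(gt, pgt)
  }

  # order sites by genome contig order then position
  ord <- order(match(sites$contig, genome$name), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sample_table <- samples[, c("sample_id", "group")]
  gm <- genotype_matrix(sites, gt, sample_table)

  # deletions
  dcfg <- config$deletions
  del_rows <- list()
  focal_samples <- samples$sample_id[samples$group == config$focal_group]
  bg_samples <- setdiff(samples$sample_id, focal_samples)
  gene_spans <- lapply(genes, function(g)
    list(contig = g$contig, lo = min(g$cds$start), hi = max(g$cds$end)))
  n_del <- dcfg$n_private + dcfg$n_other
  for (i in seq_len(n_del)) {
    len <- sample(dcfg$length[1]:dcfg$length[2], 1)
    near <- length(gene_spans) > 0 &&
      stats::runif(1) < dcfg$near_gene_fraction
    placed <- FALSE
    for (try in 1:200) {
      if (near) {
        gs <- gene_spans[[sample(length(gene_spans), 1)]]
        st <- gs$hi + sample(0:1500, 1)
        ctg <- gs$contig
      } else {
        k <- sample(seq_len(nrow(genome)), 1, prob = genome$length)
        ctg <- genome$name[k]
        st <- floor(stats::runif(1, 0, genome$length[k] - len))
        if (length(gene_spans)) {
          far <- all(vapply(gene_spans, function(gs)
            gs$contig != ctg || st > gs$hi + 10000 ||
              st + len < gs$lo - 10000, TRUE))
          if (!far) next
        }
      }
      if (st + len > genome$length[genome$name == ctg]) next
      placed <- TRUE
      break
    }
    if (!placed) next
    if (i <= dcfg$n_private) {
      carriers <- focal_samples
      pattern <- "focal_private"
    } else {
      # always include at least one background carrier
      nb <- sample(seq_along(bg_samples), 1)
      carriers <- sort(c(sample(bg_samples, nb),
                         if (stats::runif(1) < 0.5 && length(focal_samples))
                           sample(focal_samples,
                                  sample(seq_along(focal_samples), 1))))
      pattern <- "mixed"
    }
    del_rows[[length(del_rows) + 1L]] <- list(
      contig = ctg, start = st, end = st + len,
      id = sprintf("DEL%02d", i), carriers = carriers, pattern = pattern)
  }
  dels <- deletion_calls(
    vapply(del_rows, `[[`, "", "contig"),
    vapply(del_rows, `[[`, 0, "start"),
    vapply(del_rows, `[[`, 0, "end"),
    vapply(del_rows, `[[`, "", "id"),
    lapply(del_rows, `[[`, "carriers"))
  del_truth <- as.data.frame(dels[, c("contig", "start", "end", "id")])
  del_truth$pattern <- vapply(del_rows, `[[`, "", "pattern")
  del_truth$carriers <- vapply(del_rows, function(d)
    paste(d$carriers, collapse = ","), "")

  # per-sample realized truth
  tr_len <- tapply(roh_truth$end - roh_truth$start, roh_truth$sample, sum)
  smp_truth <- data.frame(
    sample = samples$sample_id, group = samples$group,
    true_F = as.numeric(ifelse(samples$sample_id %in% names(tr_len),
                               tr_len[samples$sample_id], 0)) / G,
    n_tracts = as.integer(table(
      factor(roh_truth$sample, levels = samples$sample_id))),
    stringsAsFactors = FALSE)

  annotation <- structure(lapply(genes, function(g)
    g[c("gene_id", "contig", "strand", "usable", "cds")]),
    class = "gene_annotation")
  seq_chr <- if (!is.null(seqs))
    vapply(seqs, paste, "", collapse = "") else NULL

  out <- structure(list(
    genome = genome, sequences = seq_chr, gm = gm,
    annotation = annotation, deletions = dels,
    truth = list(roh = roh_truth, variants = var_truth,
                 deletions = del_truth, samples = smp_truth),
    config = config), class = "sim_cohort")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(gm, file.path(dir, "cohort.vcf"), genome)
    ss <- Biostrings::DNAStringSet(seq_chr)
    Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
    write_gff3(annotation, file.path(dir, "genes.gff3"))
    bed <- data.frame(contig = dels$contig, start = dels$start,
                      end = dels$end, id = dels$id,
                      carriers = vapply(dels$carriers, function(x)
                        if (length(x)) paste(x, collapse = ",") else ".",
                        ""))
    utils::write.table(bed, file.path(dir, "deletions.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_tsv(sample_table, file.path(dir, "sample_table.tsv"))
    write_tsv(roh_truth, file.path(dir, "truth_roh.tsv"))
    write_tsv(var_truth, file.path(dir, "truth_variants.tsv"))
    write_tsv(del_truth, file.path(dir, "truth_deletions.tsv"))
    write_tsv(smp_truth, file.path(dir, "truth_samples.tsv"))
  }
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d samples, %d SNPs, %d genes, %d deletions (seed %d)\n",
    ncol(x$gm$gt), nrow(x$gm$gt), length(x$annotation),
    nrow(x$deletions), x$config$seed))
  invisible(x)
}

#' Exact bookkeeping of a simulated cohort's truth
#'
#' Pure tabulation, no estimation: per-sample realized autozygous fraction
#' and tract count, and cohort totals of planted variants per class and
#' pattern.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @return List: `samples` (sample, group, true_F, n_tracts),
#'   `variant_counts` (class x pattern table), `n_deletions`.
#' @export
realized_truth_summary <- function(sim) {
  stopifnot(inherits(sim, "sim_cohort"))
  vc <- if (nrow(sim$truth$variants))
    table(sim$truth$variants$class, sim$truth$variants$pattern)
  else table(character(0), character(0))
  list(samples = sim$truth$samples, variant_counts = vc,
       n_deletions = nrow(sim$truth$deletions))
}
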