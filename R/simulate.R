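#' Configuration for the two-population divergence simulator
#'
#' Defaults mirror the study design the package targets: two broiler lines
#' divergently selected for abdominal fat content (203 lean + 272 fat males),
#' ~2,000 chip SNPs on the ~83 Mb Z chromosome. Allele frequencies follow a
#' Balding-Nichols model: per SNP an ancestral frequency is drawn uniformly in
#' `ancestral_maf_range` and each population's frequency is drawn from a Beta
#' distribution with differentiation parameter `fst_target`.
#'
#' @param n_pop_A,n_pop_B diploid sample counts for the two lines.
#' @param n_snps number of biallelic SNPs.
#' @param chrom_length_bp chromosome length in bp.
#' @param fst_target differentiation parameter in `[0, 1)`; 0 gives a single
#'   panmictic population.
#' @param ancestral_maf_range range the ancestral counted-allele frequency is
#'   drawn from.
#' @param missing_rate per-entry genotype missingness rate.
#' @param labels population labels, `c(pop_A, pop_B)`.
#' @param seed integer seed; together with the other fields it fully
#'   determines the output.
#' @return a `pop_sim_config` list.
#' @export
pop_sim_config <- function(n_pop_A = 203, n_pop_B = 272, n_snps = 2000,
                           chrom_length_bp = 83e6, fst_target = 0.2,
                           ancestral_maf_range = c(0.05, 0.5),
                           missing_rate = 0.02,
                           labels = c("lean", "fat"), seed = 1) {
  stopifnot(fst_target >= 0, fst_target < 1,
            n_pop_A >= 1, n_pop_B >= 1, n_snps >= 1,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1, length(labels) == 2)
  structure(list(n_pop_A = n_pop_A, n_pop_B = n_pop_B, n_snps = n_snps,
                 chrom_length_bp = chrom_length_bp, fst_target = fst_target,
                 ancestral_maf_range = ancestral_maf_range,
                 missing_rate = missing_rate, labels = labels,
                 seed = as.integer(seed)),
            class = "pop_sim_config")
}

#' Simulate two diverged populations
#'
#' Draws Balding-Nichols population allele frequencies around uniform
#' ancestral frequencies, samples haplotypes independently per site (the
#' baseline is LD-free; haplotype structure is added by [inject_sweep()]),
#' sums haplotype pairs into genotypes and applies missingness to the dosage
#' matrix only (phased haplotypes stay complete).
#'
#' @param cfg a [pop_sim_config()].
#' @return list with `geno` ([geno_matrix()]), `haps` ([haplotype_set()]) and
#'   `truth` (ancestral and per-population frequencies, positions,
#'   `fst_target`).
#' @export
simulate_divergent_pops <- function(cfg) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  withr::with_seed(cfg$seed, {
    pos <- sim_positions(cfg$n_snps, cfg$chrom_length_bp)
    p_anc <- runif(cfg$n_snps, cfg$ancestral_maf_range[1],
                   cfg$ancestral_maf_range[2])
    F <- cfg$fst_target
    draw_pop_freq <- function(p) {
      if (F == 0) return(p)
      rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }
    p_A <- draw_pop_freq(p_anc)
    p_B <- draw_pop_freq(p_anc)

    hap_A <- matrix(rbinom(2L * cfg$n_pop_A * cfg$n_snps, 1L,
                           rep(p_A, each = 2L * cfg$n_pop_A)),
                    nrow = 2L * cfg$n_pop_A)
    hap_B <- matrix(rbinom(2L * cfg$n_pop_B * cfg$n_snps, 1L,
                           rep(p_B, each = 2L * cfg$n_pop_B)),
                    nrow = 2L * cfg$n_pop_B)
    ids <- c(paste0(cfg$labels[1], "_", seq_len(cfg$n_pop_A)),
             paste0(cfg$labels[2], "_", seq_len(cfg$n_pop_B)))
    haps <- haplotype_set(
      hap = rbind(hap_A, hap_B),
      positions_bp = pos,
      sample_id = rep(ids, each = 2L),
      population = rep(rep(cfg$labels, c(cfg$n_pop_A, cfg$n_pop_B)), each = 2L),
      snp_id = paste0("snp", seq_len(cfg$n_snps))
    )
    haps$chrom_length_bp <- cfg$chrom_length_bp

    geno <- haplotypes_to_geno(haps)
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(length(geno$dosage)) < cfg$missing_rate,
                     nrow = nrow(geno$dosage))
      geno$dosage[miss] <- NA_integer_
    }
    truth <- list(fst_target = F, p_anc = p_anc, p_A = p_A, p_B = p_B,
                  positions_bp = pos, labels = cfg$labels)
    list(geno = geno, haps = haps, truth = truth)
  })
}

# uniform positions, sorted; duplicate positions resolved by +1 bp shifts
sim_positions <- function(n, len) {
  pos <- sort(as.integer(ceiling(runif(n, 0, len))))
  while (anyDuplicated(pos)) {
    dup <- duplicated(pos)
    pos[dup] <- pos[dup] + 1L
    pos <- sort(pos)
  }
  pos
}

#' Configuration for a localized selective sweep
#'
#' @param target_pop population label whose haplotypes carry the sweep.
#' @param center_bp sweep centre, bp.
#' @param span_bp sweep width, bp (the affected interval is
#'   `center_bp +/- span_bp/2`).
#' @param carrier_fraction fraction of the target population's haplotypes
#'   replaced by one core haplotype across the span, in `(0, 1]` (0 is a
#'   no-op).
#' @param seed integer seed for carrier/core selection.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(target_pop, center_bp, span_bp,
                         carrier_fraction = 0.9, seed = 1) {
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1, span_bp > 0)
  structure(list(target_pop = target_pop, center_bp = center_bp,
                 span_bp = span_bp, carrier_fraction = carrier_fraction,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Inject a selective sweep into a haplotype set
#'
#' Within the sweep span, a `carrier_fraction` of the target population's
#' haplotype rows is overwritten by one randomly chosen core haplotype,
#' producing the long shared haplotypes (extended homozygosity) and the
#' allele-frequency shift that a recent sweep leaves. Sites outside the span
#' are untouched.
#'
#' @param h a [haplotype_set()].
#' @param cfg a [sweep_config()].
#' @return the modified [haplotype_set()].
#' @export
inject_sweep <- function(h, cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  if (!any(h$population == cfg$target_pop)) {
    abort("target population absent from haplotype set", class = "zsweep_invalid")
  }
  lo <- cfg$center_bp - cfg$span_bp / 2
  hi <- cfg$center_bp + cfg$span_bp / 2
  chrom_len <- h$chrom_length_bp %||% max(h$positions_bp)
  if (lo < 1 || hi > chrom_len) {
    abort("sweep span falls outside the chromosome", class = "zsweep_invalid")
  }
  if (cfg$carrier_fraction == 0) return(h)
  span_cols <- which(h$positions_bp >= lo & h$positions_bp <= hi)
  if (!length(span_cols)) return(h)
  rows <- which(h$population == cfg$target_pop)
  withr::with_seed(cfg$seed, {
    core <- sample(rows, 1L)
    n_carrier <- round(cfg$carrier_fraction * length(rows))
    carriers <- sample(rows, n_carrier)
    h$hap[carriers, span_cols] <-
      matrix(h$hap[core, span_cols], nrow = n_carrier,
             ncol = length(span_cols), byrow = TRUE)
  })
  h
}

#' Configuration for the microarray expression simulator
#'
#' Defaults mirror the study's expression contrast: 5 fat-line vs 5 lean-line
#' abdominal-adipose arrays on the log2 scale, with truly differential genes
#' shifted by `log2_fold_change` (fold change `2^lfc`) and per-cell detection
#' failures emulating absent calls.
#'
#' @param n_genes number of genes (probes).
#' @param n_per_line arrays per line.
#' @param de_fraction fraction of genes that are truly differential.
#' @param log2_fold_change true absolute log2 fold change of DE genes.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param detection_fail_rate per-cell probability a detection flag is FALSE.
#' @param labels line labels, `c(line_A, line_B)`.
#' @param seed integer seed.
#' @return an `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 200, n_per_line = 5, de_fraction = 0.08,
                            log2_fold_change = 2, noise_sd = 0.25,
                            detection_fail_rate = 0.1,
                            labels = c("lean", "fat"), seed = 1) {
  stopifnot(n_genes >= 1, n_per_line >= 2, de_fraction >= 0, de_fraction <= 1,
            log2_fold_change >= 0, noise_sd >= 0,
            detection_fail_rate >= 0, detection_fail_rate < 1)
  structure(list(n_genes = n_genes, n_per_line = n_per_line,
                 de_fraction = de_fraction,
                 log2_fold_change = log2_fold_change, noise_sd = noise_sd,
                 detection_fail_rate = detection_fail_rate, labels = labels,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate a two-line expression matrix with known DE genes
#'
#' Log2 expression is baseline + line effect + Gaussian noise; a recorded
#' subset of genes carries a true log2 shift of `log2_fold_change` (random
#' direction). Detection flags fail independently per cell.
#'
#' @param cfg an [expr_sim_config()].
#' @return list with `expr` (an [expr_matrix()]) and `truth` (tibble with
#'   `gene`, `is_de`, signed `true_log2_fc`, first line minus second).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    n_de <- round(cfg$de_fraction * cfg$n_genes)
    de_idx <- if (n_de > 0) sample(cfg$n_genes, n_de) else integer(0)
    delta <- numeric(cfg$n_genes)
    if (n_de > 0) {
      delta[de_idx] <- cfg$log2_fold_change *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    base <- runif(cfg$n_genes, 6, 12)
    n <- cfg$n_per_line
    line <- rep(cfg$labels, each = n)
    ids <- paste0(line, "_", rep(seq_len(n), 2))
    mu <- cbind(matrix(rep(base + delta / 2, n), ncol = n),
                matrix(rep(base - delta / 2, n), ncol = n))
    log2m <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                         nrow = nrow(mu))
    detm <- matrix(runif(length(mu)) >= cfg$detection_fail_rate,
                   nrow = nrow(mu))
    rownames(log2m) <- rownames(detm) <- genes
    colnames(log2m) <- colnames(detm) <- ids
    truth <- tibble(gene = genes,
                    is_de = seq_len(cfg$n_genes) %in% de_idx,
                    true_log2_fc = delta)
    list(expr = expr_matrix(log2m, detected = detm, line = line),
         truth = truth)
  })
}
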