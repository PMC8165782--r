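# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles (literal enumeration, explicit sums of squares) and
# share no code with the implementation they check.

# Weir-Cockerham F_ST from a 2x2 gamete count table via the literal one-way
# ANOVA on the individual gamete values (0/1 allele indicators).
oracle_fst <- function(n1, c1, n2, c2) {
  g1 <- c(rep(1, c1), rep(0, n1 - c1))
  g2 <- c(rep(1, c2), rep(0, n2 - c2))
  all <- c(g1, g2)
  grand <- mean(all)
  ss_between <- n1 * (mean(g1) - grand)^2 + n2 * (mean(g2) - grand)^2
  msp <- ss_between / (2 - 1)
  ss_within <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  msg <- ss_within / (n1 + n2 - 2)
  n <- n1 + n2
  n_c <- (n - (n1^2 + n2^2) / n) / (2 - 1)
  fst <- (msp - msg) / (msp + (n_c - 1) * msg)
  list(fst = fst, msp = msp, msg = msg, n_c = n_c)
}

# EHH by enumerating every haplotype pair and checking identity over the
# SNP columns from the core through column j.
oracle_ehh <- function(hapm, core, j) {
  cols <- seq(min(core, j), max(core, j))
  n <- nrow(hapm)
  same <- 0
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      if (all(hapm[a, cols] == hapm[b, cols])) same <- same + 1
    }
  }
  same / (n * (n - 1) / 2)
}

# full EHH curve (one direction) from the pair-enumeration oracle
oracle_ehh_curve <- function(hapm, pos, core, direction) {
  idx <- if (direction == "left") seq(core, 1L) else seq(core, length(pos))
  vapply(idx, function(j) oracle_ehh(hapm, core, j), numeric(1))
}

# iHH by straight-line (trapezoid) integration of the oracle EHH curves,
# truncating after the first point below the cutoff and capping gap widths.
oracle_ihh <- function(hapm, pos, core, cutoff = 0.05, max_gap = 200000) {
  area_side <- function(direction) {
    idx <- if (direction == "left") seq(core, 1L) else seq(core, length(pos))
    e <- oracle_ehh_curve(hapm, pos, core, direction)
    stop_at <- which(e < cutoff)[1]
    if (!is.na(stop_at) && stop_at == 1) return(NA_real_)
    last <- if (is.na(stop_at)) length(e) else stop_at
    a <- 0
    for (k in seq_len(last - 1)) {
      w <- min(abs(pos[idx[k + 1]] - pos[idx[k]]), max_gap)
      a <- a + w * (e[k] + e[k + 1]) / 2
    }
    a
  }
  l <- area_side("left"); r <- area_side("right")
  if (is.na(l) || is.na(r)) NA_real_ else l + r
}

# one-way two-group ANOVA F and p via explicit sums of squares
oracle_anova_f <- function(values, groups) {
  lv <- unique(groups)
  g1 <- values[groups == lv[1]]
  g2 <- values[groups == lv[2]]
  grand <- mean(values)
  ssb <- length(g1) * (mean(g1) - grand)^2 + length(g2) * (mean(g2) - grand)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  df1 <- 1
  df2 <- length(values) - 2
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# all-pairs inclusive interval overlap
oracle_overlaps <- function(regions, track) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- character(0)
    for (j in seq_len(nrow(track))) {
      if (track$start_bp[j] <= regions$end_bp[i] &&
          track$end_bp[j] >= regions$start_bp[i]) {
        hit <- c(hit, track$label[j])
      }
    }
    out[[i]] <- hit
  }
  out
}

# small diverged-population fixture shared across files
small_sim <- function(seed = 42, fst = 0.2, n_a = 30, n_b = 30, m = 120,
                      miss = 0.02) {
  simulate_divergent_pops(pop_sim_config(
    n_pop_A = n_a, n_pop_B = n_b, n_snps = m, chrom_length_bp = 5e6,
    fst_target = fst, missing_rate = miss, seed = seed))
}
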