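#' Expression matrix container
#'
#' Log2 expression values (genes x samples) with per-cell detection flags
#' and a line label per sample. Detection flags encode the array's
#' present/absent calls; the package consumes them as supplied (or as
#' simulated) rather than recomputing them from raw probe intensities.
#'
#' @param log2 numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param detected logical matrix, same shape: TRUE where the probe was
#'   detected in that sample.
#' @param line character, line label per sample (exactly two levels for the
#'   DE stage).
#' @param probe_gene optional probe-to-gene map (tibble `probe`, `gene`),
#'   many-to-one allowed; kept as metadata.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(log2, detected = NULL, line, probe_gene = NULL) {
  log2 <- as.matrix(log2)
  if (is.null(rownames(log2))) {
    rownames(log2) <- paste0("gene", seq_len(nrow(log2)))
  }
  if (!is.null(detected)) {
    detected <- as.matrix(detected)
    mode(detected) <- "logical"
    stopifnot(identical(dim(detected), dim(log2)))
  }
  if (length(line) != ncol(log2)) {
    abort("one line label per sample column", class = "zsweep_invalid")
  }
  structure(
    list(log2 = log2, detected = detected, line = as.character(line),
         probe_gene = probe_gene),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$log2), " genes x ", ncol(x$log2),
      " samples; lines: ",
      paste(names(table(x$line)), table(x$line), sep = "=", collapse = ", "),
      "\n  detection flags: ", if (is.null(x$detected)) "absent" else
        sprintf("%.1f%% detected", 100 * mean(x$detected)), "\n", sep = "")
  invisible(x)
}

#' Per-line expressed calls from detection flags
#'
#' A gene counts as expressed in a line when a strict majority of that
#' line's samples carry a detection flag.
#'
#' @param e an [expr_matrix()] with detection flags.
#' @param line line label.
#' @return named logical vector, one entry per gene.
#' @export
expressed_call <- function(e, line) {
  if (is.null(e$detected)) {
    abort(paste("detection flags are required for expressed calls;",
                "supply them with the expression matrix"),
          class = "zsweep_invalid")
  }
  cols <- e$line == line
  if (!any(cols)) abort(paste0("no samples in line '", line, "'"),
                        class = "zsweep_invalid")
  rowMeans(e$detected[, cols, drop = FALSE]) > 0.5
}

#' Two-line differential expression
#'
#' Per gene, a one-way ANOVA across the two lines on log2 values (with two
#' groups and pooled variance this is the classical equal-variance F-test,
#' `F = t^2`). The fold change is `2^|mean_A - mean_B|` of the log2 line
#' means, with the direction given by the higher line. A gene is a DEG iff
#' `p < alpha` and `fold_change > fc_threshold`, both strict (a fold change
#' of exactly 2 does not pass). No multiple-testing correction is applied;
#' the thresholds are the conventional microarray screen.
#'
#' @param e an [expr_matrix()] with exactly two line labels and at least 2
#'   samples per line.
#' @param fc_threshold linear-scale fold-change threshold (strict `>`).
#' @param alpha p-value threshold (strict `<`).
#' @return object of class `de_result`: tibble with `gene`, `mean_a`,
#'   `mean_b` (log2 line means; `a` = first line label), `log2_fc`
#'   (`mean_a - mean_b`), `fold_change` (`>= 1`), `direction` (higher
#'   line), `p_value`, `expressed_a`, `expressed_b` (when flags are
#'   available) and `is_deg`. Line labels and thresholds are attached as
#'   attributes.
#' @export
de_test <- function(e, fc_threshold = 2, alpha = 0.05) {
  lines <- unique(e$line)
  if (length(lines) != 2) {
    abort("de_test needs exactly two lines", class = "zsweep_invalid")
  }
  ca <- e$line == lines[1]
  cb <- e$line == lines[2]
  if (sum(ca) < 2 || sum(cb) < 2) {
    abort("need >= 2 samples per line", class = "zsweep_invalid")
  }
  grp <- factor(e$line, levels = lines)
  mean_a <- unname(rowMeans(e$log2[, ca, drop = FALSE]))
  mean_b <- unname(rowMeans(e$log2[, cb, drop = FALSE]))
  p <- unname(apply(e$log2, 1, function(v) {
    if (stats::sd(v) == 0) return(1)  # flat gene: no evidence either way
    res <- oneway.test(v ~ grp, var.equal = TRUE)
    p1 <- unname(res$p.value)
    if (is.nan(p1)) 1 else p1  # zero variance within both groups, equal means
  }))
  out <- tibble(
    gene = rownames(e$log2),
    mean_a = mean_a, mean_b = mean_b,
    log2_fc = mean_a - mean_b,
    fold_change = 2^abs(mean_a - mean_b),
    direction = ifelse(mean_a >= mean_b, lines[1], lines[2]),
    p_value = p
  )
  if (!is.null(e$detected)) {
    out$expressed_a <- unname(expressed_call(e, lines[1]))
    out$expressed_b <- unname(expressed_call(e, lines[2]))
  }
  out <- mutate(out,
                is_deg = .data$p_value < alpha & .data$fold_change > fc_threshold)
  structure(out, class = c("de_result", class(out)),
            lines = lines, fc_threshold = fc_threshold, alpha = alpha)
}

#' @export
glance.de_result <- function(x, ...) {
  lines <- attr(x, "lines")
  tibble(n_genes = nrow(x), n_deg = sum(x$is_deg),
         n_up_a = sum(x$is_deg & x$direction == lines[1]),
         n_up_b = sum(x$is_deg & x$direction == lines[2]),
         fc_threshold = attr(x, "fc_threshold"), alpha = attr(x, "alpha"))
}

#' Expressed / not-expressed contingency across the two lines
#'
#' The 2x2 cross-classification of genes by per-line expressed calls
#' (expressed in both, in one line only, in neither).
#'
#' @param e an [expr_matrix()] with detection flags and two lines.
#' @return tibble `expressed_a`, `expressed_b`, `n`.
#' @export
expressed_contingency <- function(e) {
  lines <- unique(e$line)
  stopifnot(length(lines) == 2)
  a <- expressed_call(e, lines[1])
  b <- expressed_call(e, lines[2])
  tibble(expressed_a = c(TRUE, TRUE, FALSE, FALSE),
         expressed_b = c(TRUE, FALSE, TRUE, FALSE),
         n = c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)))
}
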