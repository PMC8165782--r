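#' Plot methods for scan results
#'
#' Each scan object has an [ggplot2::autoplot()] method producing the
#' field's customary view: window-mean F_ST along the chromosome with the
#' Tukey fence, standardised XPEHH with the +/-2 band, the EigenGWAS
#' Manhattan plot with its Bonferroni line, a PCA scatter for the
#' eigendecomposition, and a volcano plot for the expression stage.
#'
#' @param object the result object.
#' @param ... unused.
#' @name zsweep-plots
NULL

mb <- function(x) x / 1e6

#' @rdname zsweep-plots
#' @export
autoplot.fst_scan <- function(object, ...) {
  w <- as_tibble(object$windows)
  ggplot2::ggplot(w, ggplot2::aes(x = mb((.data$start_bp + .data$end_bp) / 2),
                                  y = .data$mean_fst,
                                  colour = .data$is_outlier)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Position (Mb)", y = "Window mean F_ST",
                  title = "Windowed F_ST differentiation scan") +
    ggplot2::theme_minimal()
}

#' @rdname zsweep-plots
#' @export
autoplot.xpehh_scan <- function(object, ...) {
  s <- filter(object$scores, !is.na(.data$standardized))
  ggplot2::ggplot(s, ggplot2::aes(x = mb(.data$pos_bp),
                                  y = .data$standardized,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-object$params$threshold,
                                       object$params$threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Position (Mb)", y = "Standardised XPEHH",
                  title = paste0("XPEHH: ", object$params$pop_a, " vs ",
                                 object$params$pop_b)) +
    ggplot2::theme_minimal()
}

#' @rdname zsweep-plots
#' @export
autoplot.eigengwas_scan <- function(object, ...) {
  r <- filter(object$results, !is.na(.data$p_value))
  ggplot2::ggplot(r, ggplot2::aes(x = mb(.data$pos_bp),
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Position (Mb)", y = "-log10 p (GC-corrected)",
                  title = paste0("EigenGWAS scan of PC",
                                 object$params$eigvec)) +
    ggplot2::theme_minimal()
}

#' @rdname zsweep-plots
#' @param colour_by optional vector (e.g. population labels) colouring the
#'   samples in the PCA scatter.
#' @export
autoplot.eigen_decomp <- function(object, colour_by = NULL, ...) {
  d <- tidy(object)
  if (!is.null(colour_by)) d$group <- colour_by
  ve <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$variance_explained[1:2])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (is.null(colour_by)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  p + ggplot2::labs(x = ve[1], y = ve[2], colour = NULL,
                    title = "Population structure (GRM eigenvectors)") +
    ggplot2::theme_minimal()
}

#' @rdname zsweep-plots
#' @export
autoplot.de_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$is_deg)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = c(-log2(attr(object, "fc_threshold")),
                                       log2(attr(object, "fc_threshold"))),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = "Fat vs lean differential expression") +
    ggplot2::theme_minimal()
}

#' @rdname zsweep-plots
#' @export
autoplot.candidate_regions <- function(object, ...) {
  members <- bind_rows(object$members) |>
    mutate(region = rep(object$region_id,
                        vapply(object$members, nrow, integer(1))))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = as_tibble(object),
      ggplot2::aes(x = mb(.data$start_bp), xend = mb(.data$end_bp),
                   y = "candidate", yend = "candidate"),
      linewidth = 4, colour = "grey70") +
    ggplot2::geom_segment(
      data = members,
      ggplot2::aes(x = mb(.data$start_bp), xend = mb(.data$end_bp),
                   y = .data$method, yend = .data$method,
                   colour = .data$method),
      linewidth = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Position (Mb)", y = NULL,
                  title = "Candidate selection regions and method support") +
    ggplot2::theme_minimal()
}
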