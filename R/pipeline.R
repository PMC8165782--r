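#' Significant items of a scan, ready for region building
#'
#' Extracts the significant output of each scan in the common item layout
#' consumed by [build_method_regions()]: outlier windows for the F_ST scan,
#' significant SNPs for XPEHH and EigenGWAS. The `stat` column is the
#' window mean F_ST, the standardised XPEHH score, or `-log10(p)` for
#' EigenGWAS, so that larger `|stat|` always means a stronger signal.
#'
#' @param scan an `fst_scan`, `xpehh_scan` or `eigengwas_scan` object.
#' @return tibble of items with a `method` column.
#' @export
significant_items <- function(scan) UseMethod("significant_items")

#' @export
significant_items.fst_scan <- function(scan) {
  scan$windows |>
    filter(.data$is_outlier) |>
    mutate(method = "FST", .before = 1) |>
    select("method", "start_bp", "end_bp", stat = "mean_fst")
}

#' @export
significant_items.xpehh_scan <- function(scan) {
  scan$scores |>
    filter(.data$significant) |>
    mutate(method = "XPEHH", .before = 1) |>
    select("method", "snp_id", "pos_bp", stat = "standardized")
}

#' @export
significant_items.eigengwas_scan <- function(scan) {
  scan$results |>
    filter(.data$significant) |>
    mutate(method = "EIGENGWAS", stat = -log10(.data$p_value), .before = 1) |>
    select("method", "snp_id", "pos_bp", "stat")
}

#' Run the whole selection-signature pipeline
#'
#' Orchestrates QC, the enabled scans (F_ST windows, XPEHH, EigenGWAS),
#' per-method region building, cross-method merging, optional annotation and
#' the optional expression stage, from a single declarative config. The
#' config is fully serialisable, every default is echoed into the returned
#' report (no silent defaults), and together with the input data (or the
#' simulation seeds) it reproduces the run exactly.
#'
#' @param config a nested list (or path to a YAML file with the same keys):
#' \describe{
#'   \item{simulate}{list with `pop` ([pop_sim_config()] args), optional
#'     `sweep` ([sweep_config()] args) and optional `expr`
#'     ([expr_sim_config()] args); used when no `input` block is given.}
#'   \item{input}{list with `genotypes` (path), `format`, optional
#'     `pop_map`, optional `haplotypes` (phased VCF path), optional
#'     `expression`/`flags`/`line_map` paths.}
#'   \item{qc}{[qc_filter()] thresholds.}
#'   \item{fst, xpehh, eigengwas}{per-scan parameter lists, each with an
#'     `enabled` flag (all enabled by default; XPEHH needs haplotypes).}
#'   \item{regions}{[build_method_regions()] / [merge_across_methods()]
#'     parameters.}
#'   \item{tracks}{named list of BED paths to annotate with.}
#'   \item{expression}{list with `fc_threshold`, `alpha`.}
#'   \item{out_dir}{optional directory; when given, every stage's TSV plus
#'     a `summary.json` report are written there.}
#'   \item{seed}{integer; reseeds the simulate block configs that do not set
#'     their own seed.}
#' }
#' @return an object of class `zsweep_run`: list with `report` (plain,
#'   JSON-serialisable summary), `geno`, `haps`, `scans`, `intervals`,
#'   `regions`, `de` and the expanded `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- expand_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "zsweep_stage_error")
    })
  }
  if (!cfg$fst$enabled && !cfg$xpehh$enabled && !cfg$eigengwas$enabled) {
    abort("all scans disabled: nothing to run", class = "zsweep_invalid")
  }

  haps <- NULL; expr <- NULL; truth <- NULL
  if (!is.null(cfg$input)) {
    geno <- stage("input", read_genotypes(cfg$input$genotypes,
                                          format = cfg$input$format %||% "vcf",
                                          pop_map = cfg$input$pop_map))
    if (!is.null(cfg$input$haplotypes)) {
      haps <- stage("input", read_haplotypes(cfg$input$haplotypes,
                                             pop_map = cfg$input$pop_map))
    }
    if (!is.null(cfg$input$expression)) {
      expr <- stage("input", read_expression(cfg$input$expression,
                                             cfg$input$flags,
                                             cfg$input$line_map))
    }
  } else {
    sim <- stage("simulate", {
      pop_cfg <- do.call(pop_sim_config, cfg$simulate$pop)
      out <- simulate_divergent_pops(pop_cfg)
      if (!is.null(cfg$simulate$sweep)) {
        sw <- do.call(sweep_config, cfg$simulate$sweep)
        out$haps <- inject_sweep(out$haps, sw)
        out$geno <- local({
          g <- haplotypes_to_geno(out$haps)
          g$dosage[is.na(out$geno$dosage)] <- NA_integer_
          g
        })
        out$truth$sweep <- cfg$simulate$sweep
      }
      out
    })
    geno <- sim$geno; haps <- sim$haps; truth <- sim$truth
    if (!is.null(cfg$simulate$expr)) {
      se <- stage("simulate",
                  simulate_expression(do.call(expr_sim_config,
                                              cfg$simulate$expr)))
      expr <- se$expr
      truth$expr <- se$truth
    }
  }

  qc <- stage("qc", qc_filter(geno, cfg$qc$snp_call_rate,
                              cfg$qc$sample_call_rate, cfg$qc$maf_min))
  g <- qc$geno

  scans <- list()
  if (cfg$fst$enabled) {
    scans$fst <- stage("fst_scan",
                       fst_scan(g, cfg$fst$window_bp, cfg$fst$step_bp))
  }
  if (cfg$xpehh$enabled && !is.null(haps)) {
    scans$xpehh <- stage("xpehh",
                         xpehh_scan(haps, ehh_cutoff = cfg$xpehh$ehh_cutoff,
                                    max_gap_bp = cfg$xpehh$max_gap_bp,
                                    threshold = cfg$xpehh$threshold))
  }
  if (cfg$eigengwas$enabled) {
    scans$eigengwas <- stage("eigengwas",
                             eigengwas_scan(g, eigvec = cfg$eigengwas$eigvec,
                                            k = cfg$eigengwas$k,
                                            gc = cfg$eigengwas$gc,
                                            alpha = cfg$eigengwas$alpha))
  }

  items <- bind_rows(purrr::map(scans, significant_items))
  intervals <- stage("regions",
                     build_method_regions(items, cfg$regions$flank_bp,
                                          cfg$regions$within_method_gap_bp))
  regions <- stage("regions",
                   merge_across_methods(intervals, cfg$regions$gap_bp,
                                        cfg$regions$rounding_tolerance_bp))
  for (nm in names(cfg$tracks %||% list())) {
    track <- stage("annotate", read_annotation_track(cfg$tracks[[nm]], nm))
    regions <- stage("annotate", annotate_regions(regions, track, nm))
  }
  de <- NULL
  if (!is.null(expr)) {
    de <- stage("expression_de",
                de_test(expr, cfg$expression$fc_threshold,
                        cfg$expression$alpha))
  }

  report <- build_report(cfg, qc, scans, regions, de)
  run <- structure(
    list(report = report, geno = g, haps = haps, scans = scans,
         intervals = intervals, regions = regions, de = de, truth = truth,
         config = cfg),
    class = "zsweep_run"
  )
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

expand_config <- function(config) {
  defaults <- list(
    simulate = list(pop = list(), sweep = NULL, expr = NULL),
    input = NULL,
    qc = list(snp_call_rate = 0.95, sample_call_rate = 0.95, maf_min = 0.01),
    fst = list(enabled = TRUE, window_bp = 100000, step_bp = 10000),
    xpehh = list(enabled = TRUE, ehh_cutoff = 0.05, max_gap_bp = 200000,
                 threshold = 2),
    eigengwas = list(enabled = TRUE, eigvec = 1, k = 10, gc = TRUE,
                     alpha = 0.05),
    regions = list(flank_bp = 200000, within_method_gap_bp = 1000000,
                   gap_bp = 1000000, rounding_tolerance_bp = 100000),
    tracks = list(),
    expression = list(fc_threshold = 2, alpha = 0.05),
    out_dir = NULL,
    seed = 1
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$input)) {
    if (is.null(cfg$simulate$pop$seed)) cfg$simulate$pop$seed <- cfg$seed
    if (!is.null(cfg$simulate$sweep) && is.null(cfg$simulate$sweep$seed)) {
      cfg$simulate$sweep$seed <- cfg$seed
    }
    if (!is.null(cfg$simulate$expr) && is.null(cfg$simulate$expr$seed)) {
      cfg$simulate$expr$seed <- cfg$seed
    }
  }
  cfg
}

build_report <- function(cfg, qc, scans, regions, de) {
  supp <- if (nrow(regions)) support_summary(regions) else
    list(n_regions = 0, patterns = tibble(), per_method = tibble())
  flat_regions <- regions |>
    as_tibble() |>
    mutate(support = purrr::map_chr(.data$support, paste, collapse = "+")) |>
    select(-dplyr::any_of("members")) |>
    (\(d) d[, !vapply(d, is.list, logical(1)), drop = FALSE])()
  rep <- list(
    config = cfg[c("qc", "fst", "xpehh", "eigengwas", "regions",
                   "expression", "seed")],
    qc = as.list(glance(qc$report)),
    scans = purrr::map(scans, ~ as.list(glance(.x))),
    regions = list(
      n_regions = supp$n_regions,
      patterns = as.data.frame(supp$patterns),
      per_method = as.data.frame(supp$per_method),
      table = as.data.frame(flat_regions)
    )
  )
  if (!is.null(de)) rep$expression <- as.list(glance(de))
  rep
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
  if (!is.null(run$scans$fst)) {
    w(run$scans$fst$snp, "fst_per_snp.tsv")
    w(as_tibble(run$scans$fst$windows), "fst_windows.tsv")
  }
  if (!is.null(run$scans$xpehh)) w(run$scans$xpehh$scores, "xpehh.tsv")
  if (!is.null(run$scans$eigengwas)) {
    w(run$scans$eigengwas$results, "eigengwas.tsv")
    w(tidy(run$scans$eigengwas$decomp), "eigenvectors.tsv")
  }
  w(run$intervals, "method_intervals.tsv")
  flat <- run$regions |>
    as_tibble() |>
    mutate(support = purrr::map_chr(.data$support, paste, collapse = "+"))
  flat <- flat[, !vapply(flat, is.list, logical(1)), drop = FALSE]
  w(flat, "candidate_regions.tsv")
  if (nrow(run$regions)) {
    write_intervals_bed(
      mutate(as_tibble(run$regions),
             label = purrr::map_chr(.data$support, paste, collapse = "+")),
      file.path(out_dir, "candidate_regions.bed"))
  }
  if (!is.null(run$de)) w(as_tibble(run$de), "de_results.tsv")
  jsonlite::write_json(run$report, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.zsweep_run <- function(x, ...) {
  cat("<zsweep_run>\n  scans: ", paste(names(x$scans), collapse = ", "),
      "\n  candidate regions: ", nrow(x$regions), "\n", sep = "")
  invisible(x)
}
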