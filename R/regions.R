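#' Build per-method significant intervals
#'
#' Turns a method's significant items into intervals: each significant SNP
#' expands to `pos +/- flank_bp`; outlier windows pass through unchanged.
#' Overlapping or nearby (gap `<= within_method_gap_bp`) intervals of the
#' same method are unioned (single linkage), and each union carries its top
#' item — the member with the largest `|stat|`.
#'
#' Coordinates are 1-based inclusive bp throughout.
#'
#' @param items tibble of significant items with a `method` column and
#'   either `pos_bp` (SNP items, optionally `snp_id`) or
#'   `start_bp`/`end_bp` (window items), plus a `stat` column.
#' @param flank_bp flank added on each side of a significant SNP.
#' @param within_method_gap_bp maximum gap joined within a method.
#' @return tibble of intervals: `method`, `start_bp`, `end_bp`, `n_items`,
#'   `top_id`, `top_stat`.
#' @export
build_method_regions <- function(items, flank_bp = 200000,
                                 within_method_gap_bp = 1000000) {
  items <- as_tibble(items)
  if (nrow(items) == 0) {
    return(tibble(method = character(), start_bp = integer(),
                  end_bp = integer(), n_items = integer(),
                  top_id = character(), top_stat = double()))
  }
  if (!"stat" %in% names(items)) items$stat <- NA_real_
  if (!"snp_id" %in% names(items)) items$snp_id <- NA_character_
  if ("pos_bp" %in% names(items) && !"start_bp" %in% names(items)) {
    items <- mutate(items, start_bp = pmax(1, .data$pos_bp - flank_bp),
                    end_bp = .data$pos_bp + flank_bp)
  } else if ("pos_bp" %in% names(items)) {
    snp <- is.na(items$start_bp) & !is.na(items$pos_bp)
    items$start_bp[snp] <- pmax(1, items$pos_bp[snp] - flank_bp)
    items$end_bp[snp] <- items$pos_bp[snp] + flank_bp
  }
  items |>
    group_by(.data$method) |>
    dplyr::group_modify(~ union_intervals(.x, within_method_gap_bp)) |>
    ungroup() |>
    arrange(.data$method, .data$start_bp)
}

# value of x at the item with the largest |stat|; NA when no stat is known
pick_top <- function(x, stat) {
  i <- which.max(abs(stat))
  if (length(i)) x[i] else x[NA_integer_]
}

# single-linkage union of intervals; merged iff start2 - end1 <= gap_bp
union_intervals <- function(df, gap_bp) {
  ir <- IRanges::IRanges(start = as.integer(df$start_bp),
                         end = as.integer(df$end_bp))
  red <- IRanges::reduce(ir, min.gapwidth = gap_bp)
  grp <- S4Vectors::subjectHits(
    IRanges::findOverlaps(ir, red, maxgap = gap_bp - 1L)
  )
  out <- df |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(
      start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
      n_items = n(),
      top_id = pick_top(.data$snp_id, .data$stat),
      top_stat = pick_top(.data$stat, .data$stat),
      .groups = "drop"
    ) |>
    select(-".grp")
  out
}

#' Merge per-method intervals into candidate regions
#'
#' Single-linkage union across methods: two intervals fall in the same
#' candidate region when their gap (`start2 - end1`, bp) is strictly smaller
#' than `gap_bp + rounding_tolerance_bp`. The tolerance absorbs the rounding
#' of endpoints printed at 0.01 Mb precision, where a true sub-1 Mb gap can
#' print as slightly more than 1 Mb. Candidate bounds are the min start /
#' max end of the members; the support set is the set of member methods.
#'
#' @param intervals per-method intervals (output of
#'   [build_method_regions()] or any tibble with `method`, `start_bp`,
#'   `end_bp`); one chromosome at a time.
#' @param gap_bp nominal maximum between-method gap.
#' @param rounding_tolerance_bp slack added to `gap_bp`.
#' @return object of class `candidate_regions`: a tibble with `region_id`,
#'   `start_bp`, `end_bp`, `length_mb` (end - start, 2 dp), `support`
#'   (list of methods), `n_methods`, `pattern` (methods pasted with `+`) and
#'   `members` (list of member-interval tibbles).
#' @export
merge_across_methods <- function(intervals, gap_bp = 1000000,
                                 rounding_tolerance_bp = 100000) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) == 0) {
    out <- tibble(region_id = integer(), start_bp = integer(),
                  end_bp = integer(), length_mb = double(),
                  support = list(), n_methods = integer(),
                  pattern = character(), members = list())
    return(structure(out, class = c("candidate_regions", class(out))))
  }
  thr <- gap_bp + rounding_tolerance_bp   # merge iff gap < thr (strict)
  ir <- IRanges::IRanges(start = as.integer(intervals$start_bp),
                         end = as.integer(intervals$end_bp))
  red <- IRanges::reduce(ir, min.gapwidth = thr - 1L)
  grp <- S4Vectors::subjectHits(
    IRanges::findOverlaps(ir, red, maxgap = thr - 2L)
  )
  out <- intervals |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    dplyr::group_modify(function(df, key) {
      tibble(
        start_bp = min(df$start_bp), end_bp = max(df$end_bp),
        support = list(sort(unique(df$method))),
        n_methods = length(unique(df$method)),
        pattern = paste(sort(unique(df$method)), collapse = "+"),
        members = list(select(df, -dplyr::any_of(".grp")))
      )
    }) |>
    ungroup() |>
    select(-".grp") |>
    arrange(.data$start_bp) |>
    mutate(region_id = row_number(),
           length_mb = round((.data$end_bp - .data$start_bp) / 1e6, 2),
           .before = 1) |>
    dplyr::relocate("length_mb", .after = "end_bp")
  structure(out, class = c("candidate_regions", class(out)),
            params = list(gap_bp = gap_bp,
                          rounding_tolerance_bp = rounding_tolerance_bp))
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat("<candidate_regions> ", nrow(x), " regions\n", sep = "")
  NextMethod()
}

#' Summarise candidate regions by method support
#'
#' Counts candidate regions per support pattern and summarises each method's
#' member intervals (count, total and mean length, Mb at 2 decimals,
#' `end - start` convention).
#'
#' @param regions a [merge_across_methods()] result.
#' @return list with `n_regions`, `patterns` (tibble `pattern`, `n`) and
#'   `per_method` (tibble `method`, `n_candidate_regions`, `n_intervals`,
#'   `total_length_mb`, `mean_length_mb`).
#' @export
support_summary <- function(regions) {
  members <- bind_rows(regions$members)
  patterns <- regions |>
    as_tibble() |>
    dplyr::count(.data$pattern, name = "n") |>
    arrange(desc(.data$n))
  per_method <- members |>
    group_by(.data$method) |>
    summarise(
      n_intervals = n(),
      total_length_mb = round(sum(.data$end_bp - .data$start_bp) / 1e6, 2),
      mean_length_mb = round(mean(.data$end_bp - .data$start_bp) / 1e6, 2),
      .groups = "drop"
    )
  support_counts <- tibble(
    method = unlist(regions$support)
  ) |>
    dplyr::count(.data$method, name = "n_candidate_regions")
  per_method <- left_join(support_counts, per_method, by = "method")
  stopifnot(sum(patterns$n) == nrow(regions))
  list(n_regions = nrow(regions), patterns = patterns,
       per_method = per_method)
}

#' Annotate candidate regions with an interval track
#'
#' Attaches every track label whose interval overlaps a region by at least
#' 1 bp (inclusive coordinates on both sides, so touching endpoints count).
#'
#' @param regions a [merge_across_methods()] result (or any tibble with
#'   `start_bp`, `end_bp`, optionally `chrom`).
#' @param track annotation track from [read_annotation_track()] (tibble with
#'   `chrom`, `start_bp`, `end_bp`, `label`).
#' @param name column name for the attached labels (defaults to the track's
#'   `track` attribute or `"genes"`).
#' @return `regions` with an added list-column of overlapping labels and an
#'   `n_<name>` count column.
#' @export
annotate_regions <- function(regions, track, name = NULL) {
  name <- name %||% attr(track, "track") %||% "genes"
  reg_chrom <- if ("chrom" %in% names(regions)) regions$chrom else
    rep("Z", nrow(regions))
  if (!any(reg_chrom %in% track$chrom)) {
    warn(paste0("no track intervals on the regions' chromosome(s); '",
                name, "' annotations are empty"))
  }
  labs <- vector("list", nrow(regions))
  for (ch in unique(reg_chrom)) {
    ri <- which(reg_chrom == ch)
    ti <- which(track$chrom == ch)
    if (!length(ti)) { labs[ri] <- list(character(0)); next }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(as.integer(regions$start_bp[ri]),
                       as.integer(regions$end_bp[ri])),
      IRanges::IRanges(as.integer(track$start_bp[ti]),
                       as.integer(track$end_bp[ti])),
      minoverlap = 1L
    )
    for (k in seq_along(ri)) {
      labs[[ri[k]]] <-
        track$label[ti][S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]]
    }
  }
  regions[[name]] <- labs
  regions[[paste0("n_", name)]] <- lengths(labs)
  regions
}

#' Published per-method selection intervals on the chicken Z chromosome
#'
#' The per-method selection-signature intervals (F_ST outlier windows,
#' EigenGWAS Bonferroni hits, XPEHH) reported on the Z chromosome of broiler
#' lines divergently selected for abdominal fat content, shipped as a worked
#' example for the cross-method merge. One printed F_ST interval had its end
#' before its start and is corrected here; the `note` column records the
#' correction.
#'
#' @return tibble: `method`, `start_bp`, `end_bp`, `snp_id` (top SNP),
#'   `stat` (F_ST value, regression p-value, or standardised XPEHH),
#'   `gene` (major gene printed for the interval, `NA` if none), `note`.
#' @export
chicken_z_intervals <- function() {
  path <- system.file("extdata", "chicken_z_method_intervals.tsv",
                      package = "zsweep")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  tab |>
    mutate(start_bp = as.integer(round(.data$start_mb * 1e6)),
           end_bp = as.integer(round(.data$end_mb * 1e6))) |>
    select("method", "start_bp", "end_bp", snp_id = "top_snp", "stat",
           "gene", "note")
}
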