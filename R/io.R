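#' Read genotypes from standard file formats
#'
#' Reads biallelic SNP genotypes into a [geno_matrix()]. Three dialects are
#' supported:
#'
#' * `vcf` — VCF v4.x with a GT field; the ALT allele is the counted allele.
#'   Multi-allelic records are rejected. Phase separators (`|`) are preserved
#'   on the way out by [write_genotypes()] when haplotypes are supplied.
#' * `plink_text` — whitespace `.ped` + `.map` pair (pass the `.ped` path;
#'   the `.map` is found alongside). Allele codes `A`/`B` with `B` counted;
#'   `0 0` is missing.
#' * `matrix_tsv` — dosage matrix TSV, first column `sample_id`, remaining
#'   columns one SNP each (header row = SNP ids), values 0/1/2/NA.
#'
#' Population labels come from `pop_map` (a two-column `sample_id`,
#' `population` table or a path to one as TSV); if absent, the prefix of the
#' sample id up to the first underscore is used.
#'
#' @param path input file path.
#' @param format one of `"vcf"`, `"plink_text"`, `"matrix_tsv"`.
#' @param pop_map optional sample-to-population table (data frame or TSV path).
#' @param variants for `matrix_tsv` only: variant table (`snp_id`, `chrom`,
#'   `pos_bp`) as data frame or TSV path. If `NULL`, SNP ids of the form
#'   `chrom:pos` are parsed.
#' @return a validated [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text", "matrix_tsv"),
                           pop_map = NULL, variants = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "zsweep_parse_error")
  }
  g <- switch(format,
    vcf = read_genotypes_vcf(path),
    plink_text = read_genotypes_plink(path),
    matrix_tsv = read_genotypes_tsv(path, variants)
  )
  g$samples$population <- resolve_populations(g$samples$sample_id, pop_map)
  validate_geno_matrix(g)
}

resolve_populations <- function(sample_id, pop_map) {
  if (is.null(pop_map)) {
    return(sub("_.*$", "", sample_id))
  }
  if (is.character(pop_map) && length(pop_map) == 1L) {
    pop_map <- readr::read_tsv(pop_map, show_col_types = FALSE)
  }
  pop_map <- as_tibble(pop_map)
  names(pop_map)[1:2] <- c("sample_id", "population")
  idx <- match(sample_id, pop_map$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples missing from population map: ",
                 paste(head(sample_id[is.na(idx)], 5), collapse = ", ")),
          class = "zsweep_invalid")
  }
  as.character(pop_map$population[idx])
}

read_genotypes_vcf <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)),
                              class = "zsweep_parse_error")
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    abort(paste0("multi-allelic site(s) not supported: ",
                 paste(head(fix$ID[multi], 5), collapse = ", ")),
          class = "zsweep_multiallelic")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[|/]", "", gt)
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    a <- alleles[j, ]
    ok <- !is.na(a) & grepl("^[01]+$", a)
    dos[ok, j] <- vapply(strsplit(a[ok], ""),
                         function(x) sum(x == "1"), integer(1))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  geno_unsorted(
    dosage = dos,
    samples = tibble(sample_id = colnames(gt), population = NA_character_),
    variants = tibble(snp_id = ids, chrom = fix$CHROM,
                      pos_bp = as.integer(fix$POS))
  )
}

read_genotypes_plink <- function(path) {
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path) || !file.exists(map_path)) {
    abort("plink_text needs a .ped path with a sibling .map file",
          class = "zsweep_parse_error")
  }
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp"),
                           stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- 6L + 2L * nrow(map)
  bad <- which(lengths(toks) != nfield)
  if (length(bad)) {
    abort(paste0("malformed .ped line ", bad[1], ": expected ", nfield,
                 " fields, got ", lengths(toks)[bad[1]]),
          class = "zsweep_parse_error")
  }
  dos <- matrix(NA_integer_, nrow = length(toks), ncol = nrow(map))
  ids <- character(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    ids[i] <- tk[2]
    a1 <- tk[seq(7L, nfield, by = 2L)]
    a2 <- tk[seq(8L, nfield, by = 2L)]
    called <- a1 != "0" & a2 != "0"
    dos[i, called] <- (a1[called] == "B") + (a2[called] == "B")
  }
  geno_unsorted(
    dosage = dos,
    samples = tibble(sample_id = ids, population = NA_character_),
    variants = tibble(snp_id = map$snp_id, chrom = as.character(map$chrom),
                      pos_bp = as.integer(map$pos_bp))
  )
}

read_genotypes_tsv <- function(path, variants) {
  tab <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("failed to parse TSV '", path, "': ",
                                     conditionMessage(e)),
          class = "zsweep_parse_error")
  )
  if (names(tab)[1] != "sample_id") {
    abort("matrix_tsv must have 'sample_id' as its first column",
          class = "zsweep_parse_error")
  }
  dos <- as.matrix(tab[, -1, drop = FALSE])
  snp_id <- colnames(dos)
  if (is.null(variants)) {
    if (!all(grepl("^[^:]+:[0-9]+$", snp_id))) {
      abort("matrix_tsv without a variant table needs 'chrom:pos' SNP ids",
            class = "zsweep_parse_error")
    }
    variants <- tibble(
      snp_id = snp_id,
      chrom = sub(":.*$", "", snp_id),
      pos_bp = as.integer(sub("^.*:", "", snp_id))
    )
  } else {
    if (is.character(variants) && length(variants) == 1L) {
      variants <- readr::read_tsv(variants, show_col_types = FALSE)
    }
    variants <- as_tibble(variants)
    variants$pos_bp <- as.integer(variants$pos_bp)
    variants$chrom <- as.character(variants$chrom)
    idx <- match(snp_id, variants$snp_id)
    if (anyNA(idx)) {
      abort("variant table does not cover all SNP columns",
            class = "zsweep_parse_error")
    }
    variants <- variants[idx, ]
  }
  geno_unsorted(
    dosage = dos,
    samples = tibble(sample_id = tab$sample_id, population = NA_character_),
    variants = variants
  )
}

# sort variants by (chrom, pos) before validation; readers may not be sorted
geno_unsorted <- function(dosage, samples, variants) {
  ord <- order(variants$chrom, variants$pos_bp)
  structure(
    list(dosage = {
      d <- as.matrix(dosage)[, ord, drop = FALSE]
      storage.mode(d) <- "integer"
      d
    },
    samples = as_tibble(samples), variants = as_tibble(variants)[ord, ]),
    class = "geno_matrix"
  )
}

#' Write genotypes to VCF or dosage TSV
#'
#' The VCF writer emits a minimal VCFv4.2 file with GT fields; when the
#' matching [haplotype_set()] is supplied, genotypes are written phased
#' (`0|1`), otherwise unphased (`0/1`). `NA` dosage becomes `./.`.
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @param format `"vcf"` or `"matrix_tsv"` or `"plink_text"` (writes
#'   `.ped` + `.map`; pass the `.ped` path).
#' @param haplotypes optional [haplotype_set()] used to phase the VCF GT field.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "matrix_tsv", "plink_text"),
                            haplotypes = NULL) {
  format <- match.arg(format)
  switch(format,
    vcf = write_genotypes_vcf(g, path, haplotypes),
    matrix_tsv = write_genotypes_tsv(g, path),
    plink_text = write_genotypes_plink(g, path)
  )
  invisible(path)
}

write_genotypes_vcf <- function(g, path, haplotypes) {
  n <- nrow(g$dosage)
  m <- ncol(g$dosage)
  gt <- matrix("./.", nrow = m, ncol = n)
  if (!is.null(haplotypes)) {
    for (i in seq_len(n)) {
      rows <- which(haplotypes$sample_id == g$samples$sample_id[i])
      gt[, i] <- paste(haplotypes$hap[rows[1], ], haplotypes$hap[rows[2], ],
                       sep = "|")
    }
  } else {
    code <- c("0/0", "0/1", "1/1")
    for (i in seq_len(n)) {
      d <- g$dosage[i, ]
      gt[!is.na(d), i] <- code[d[!is.na(d)] + 1L]
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  body <- paste(g$variants$chrom, g$variants$pos_bp, g$variants$snp_id,
                "A", "B", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

write_genotypes_tsv <- function(g, path) {
  tab <- as.data.frame(g$dosage)
  colnames(tab) <- g$variants$snp_id
  tab <- cbind(sample_id = g$samples$sample_id, tab)
  readr::write_tsv(as_tibble(tab), path)
  var_path <- paste0(path, ".variants.tsv")
  readr::write_tsv(g$variants, var_path)
}

write_genotypes_plink <- function(g, path) {
  map_path <- sub("\\.ped$", ".map", path)
  map <- data.frame(chrom = g$variants$chrom, snp_id = g$variants$snp_id,
                    cm = 0, pos_bp = g$variants$pos_bp)
  utils::write.table(map, map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  code <- c("A A", "A B", "B B")
  lines <- vapply(seq_len(nrow(g$dosage)), function(i) {
    d <- g$dosage[i, ]
    al <- ifelse(is.na(d), "0 0", code[d + 1L])
    paste(c(g$samples$population[i], g$samples$sample_id[i], "0", "0", "1",
            "-9", al), collapse = " ")
  }, character(1))
  writeLines(lines, path)
}

#' Read an annotation track from BED
#'
#' BED on disk is 0-based half-open; the returned track uses the package's
#' 1-based inclusive convention (`start_bp = bed_start + 1`,
#' `end_bp = bed_end`).
#'
#' @param path BED file (3+ columns; column 4, when present, is the label).
#' @param name track name (e.g. `"genes"`, `"qtl"`).
#' @return tibble with `chrom`, `start_bp`, `end_bp`, `label` and a `track`
#'   attribute.
#' @export
read_annotation_track <- function(path, name = "genes") {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) abort("BED needs at least 3 columns",
                           class = "zsweep_parse_error")
  lab <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    paste0(name, "_", seq_len(nrow(bed)))
  out <- tibble(chrom = as.character(bed[[1]]),
                start_bp = as.integer(bed[[2]]) + 1L,
                end_bp = as.integer(bed[[3]]),
                label = lab)
  out <- arrange(out, .data$chrom, .data$start_bp)
  attr(out, "track") <- name
  out
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive intervals back to BED's 0-based
#' half-open coordinates.
#'
#' @param intervals tibble with `chrom` (optional, default `"Z"`),
#'   `start_bp`, `end_bp` and optionally a `label`/`method` column written as
#'   the BED name field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  chrom <- if ("chrom" %in% names(intervals)) intervals$chrom else "Z"
  name <- if ("label" %in% names(intervals)) intervals$label
    else if ("method" %in% names(intervals)) as.character(intervals$method)
    else "."
  bed <- data.frame(chrom = chrom,
                    start = intervals$start_bp - 1L,
                    end = intervals$end_bp,
                    name = name)
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix with detection flags
#'
#' The TSV layout is genes in rows (`gene` first column), samples in columns,
#' log2 values; the companion flag table has the same layout with
#' TRUE/FALSE detection calls. Line labels come from a `sample_id`,`line`
#' map (TSV path or data frame).
#'
#' @param path expression TSV.
#' @param flags_path detection-flag TSV (same shape).
#' @param line_map two-column sample-to-line table or TSV path.
#' @return an `expr_matrix` object; see [expr_matrix()].
#' @export
read_expression <- function(path, flags_path, line_map) {
  ex <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  fl <- readr::read_tsv(flags_path, show_col_types = FALSE, progress = FALSE)
  if (!identical(dim(ex), dim(fl)) || !identical(names(ex), names(fl))) {
    abort("expression and flag tables must have identical layout",
          class = "zsweep_parse_error")
  }
  genes <- ex[[1]]
  log2m <- as.matrix(ex[, -1])
  detm <- as.matrix(fl[, -1])
  mode(detm) <- "logical"
  rownames(log2m) <- rownames(detm) <- genes
  if (is.character(line_map) && length(line_map) == 1L) {
    line_map <- readr::read_tsv(line_map, show_col_types = FALSE)
  }
  line_map <- as_tibble(line_map)
  names(line_map)[1:2] <- c("sample_id", "line")
  line <- line_map$line[match(colnames(log2m), line_map$sample_id)]
  expr_matrix(log2m, detected = detm, line = line)
}

#' @rdname read_expression
#' @param e an [expr_matrix()].
#' @export
write_expression <- function(e, path, flags_path) {
  ex <- cbind(tibble(gene = rownames(e$log2)), as_tibble(e$log2))
  fl <- cbind(tibble(gene = rownames(e$log2)), as_tibble(e$detected))
  readr::write_tsv(as_tibble(ex), path)
  readr::write_tsv(as_tibble(fl), flags_path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Requires every GT to be phased (`0|1` style); the two haplotypes of each
#' sample become two rows of the returned [haplotype_set()].
#'
#' @inheritParams read_genotypes
#' @param chrom restrict to one chromosome (default: the first seen).
#' @return a [haplotype_set()].
#' @export
read_haplotypes <- function(path, pop_map = NULL, chrom = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(chrom)) keep <- fix$CHROM == chrom else
    keep <- fix$CHROM == fix$CHROM[1]
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (any(grepl("/", gt))) {
    abort("unphased genotypes: haplotypes need '|'-phased GT fields",
          class = "zsweep_parse_error")
  }
  ord <- order(as.integer(fix$POS))
  fix <- fix[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  samples <- colnames(gt)
  a1 <- apply(gt, 2, function(x) as.integer(sub("\\|.*$", "", x)))
  a2 <- apply(gt, 2, function(x) as.integer(sub("^.*\\|", "", x)))
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(fix))
  hap[seq(1, nrow(hap), by = 2), ] <- t(a1)
  hap[seq(2, nrow(hap), by = 2), ] <- t(a2)
  pops <- resolve_populations(samples, pop_map)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  haplotype_set(hap, positions_bp = as.integer(fix$POS),
                sample_id = rep(samples, each = 2),
                population = rep(pops, each = 2),
                snp_id = ids, chrom = fix$CHROM[1])
}
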