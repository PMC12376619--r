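#' SV catalog and genotype containers
#'
#' The package represents a cohort of structural variants (SVs) with two
#' plain objects: a *catalog* tibble with one row per nonredundant SV, and a
#' *genotype matrix* of diploid dosages.  All user-facing functions take and
#' return these, so analyses chain with the pipe.
#'
#' A catalog tibble has columns
#' \describe{
#'   \item{sv_id}{unique SV identifier (character)}
#'   \item{chrom}{chromosome name}
#'   \item{start, end}{1-based inclusive coordinates; `end == start` for
#'     insertions (INS) and break-ends (BND), which are point events}
#'   \item{svtype}{one of `DEL`, `INS`, `DUP`, `INV`, `BND`}
#'   \item{svlen}{unsigned length in bp (>= 50 for non-BND types; the VCF
#'     sign convention for deletions is re-applied on write)}
#'   \item{mate_chrom, mate_pos}{mate breakpoint, BND only (`NA` otherwise)}
#' }
#'
#' The genotype matrix is an integer matrix (SV x sample, dimnames set) of
#' ALT-allele dosages: 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing.  Missing genotypes are a
#' first-class state and are excluded from every allele count.
#'
#' @param catalog data frame to validate as an SV catalog.
#' @return `sv_catalog()` returns the validated catalog as a tibble, with
#'   invariants checked (coordinates, types, lengths, BND mates).
#' @examples
#' sv_catalog(tibble::tibble(
#'   sv_id = "sv1", chrom = "chr1", start = 1000L, end = 1099L,
#'   svtype = "DEL", svlen = 100L
#' ))
#' @export
sv_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  needed <- c("sv_id", "chrom", "start", "end", "svtype", "svlen")
  missing_cols <- setdiff(needed, names(catalog))
  if (length(missing_cols) > 0) {
    abort(paste0("catalog is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"mate_chrom" %in% names(catalog)) catalog$mate_chrom <- NA_character_
  if (!"mate_pos" %in% names(catalog)) catalog$mate_pos <- NA_integer_
  catalog$start <- as.integer(catalog$start)
  catalog$end <- as.integer(catalog$end)
  catalog$svlen <- as.integer(catalog$svlen)
  catalog$mate_pos <- as.integer(catalog$mate_pos)

  if (anyDuplicated(catalog$sv_id)) {
    abort("catalog sv_id values must be unique")
  }
  bad_type <- setdiff(unique(catalog$svtype), sv_types())
  if (length(bad_type) > 0) {
    abort(paste0("unknown svtype: ", paste(bad_type, collapse = ", ")))
  }
  if (any(catalog$end < catalog$start)) {
    abort("catalog has records with end < start")
  }
  point <- catalog$svtype %in% c("INS", "BND")
  if (any(catalog$end[point] != catalog$start[point])) {
    abort("INS and BND records must have end == start (point events)")
  }
  non_bnd <- catalog$svtype != "BND"
  if (any(catalog$svlen[non_bnd] < 50L, na.rm = TRUE)) {
    abort("non-BND SVs must be at least 50 bp")
  }
  is_bnd <- catalog$svtype == "BND"
  if (any(is_bnd & (is.na(catalog$mate_chrom) | is.na(catalog$mate_pos)))) {
    abort("BND records require mate_chrom and mate_pos")
  }
  catalog[c(needed, "mate_chrom", "mate_pos",
            setdiff(names(catalog), c(needed, "mate_chrom", "mate_pos")))]
}

#' @rdname sv_catalog
#' @export
sv_types <- function() c("DEL", "INS", "DUP", "INV", "BND")

#' @param gt integer matrix of dosages in `{0, 1, 2, NA}`, SVs in rows and
#'   samples in columns, both dimnames set.
#' @param catalog optional catalog the matrix rows must match.
#' @return `genotype_matrix()` returns the validated matrix (invisibly
#'   unchanged apart from storage mode).
#' @rdname sv_catalog
#' @export
genotype_matrix <- function(gt, catalog = NULL) {
  if (!is.matrix(gt)) abort("gt must be a matrix")
  storage.mode(gt) <- "integer"
  ## R normalizes zero-length dimnames to NULL, so only require names on
  ## non-degenerate dimensions
  if ((nrow(gt) > 0 && is.null(rownames(gt))) ||
      (ncol(gt) > 0 && is.null(colnames(gt)))) {
    abort("gt must have SV ids as rownames and sample ids as colnames")
  }
  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad)) abort("genotype dosages must be 0, 1, 2 or NA")
  if (!is.null(catalog) &&
      !identical(rownames(gt) %||% character(), catalog$sv_id)) {
    abort("gt rownames do not match catalog sv_id (same order required)")
  }
  gt
}

#' Population manifest
#'
#' Samples are assigned to populations and to one of three analysis roles:
#' `target` (the focal, putatively adapted group), `control` (the reference
#' group the targets are contrasted against) and `donor` (the species that
#' may have contributed introgressed haplotypes).  `order_index` fixes the
#' sample order used for the cumulative catalog growth curve.
#'
#' @param manifest data frame with columns `sample_id`, `population`,
#'   `role` and optionally `order_index` (filled `1..n` when absent).
#' @return validated manifest tibble.
#' @export
population_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  needed <- c("sample_id", "population", "role")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated sample id(s) in manifest: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad_role <- setdiff(unique(manifest$role), c("target", "control", "donor"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s) in manifest: ",
                 paste(bad_role, collapse = ", "),
                 " (expected target/control/donor)"))
  }
  if (!"order_index" %in% names(manifest)) {
    manifest$order_index <- seq_len(nrow(manifest))
  }
  manifest$order_index <- as.integer(manifest$order_index)
  manifest[c(needed, "order_index")]
}

#' Interval tables
#'
#' Annotation tracks (repeats, genes, exons, conserved elements, hotspots)
#' are tibbles with columns `chrom`, `start`, `end` in the package-internal
#' 1-based inclusive convention, plus an optional `label`.  BED input is
#' converted at the boundary by [read_bed()].
#'
#' @param intervals data frame with `chrom`, `start`, `end` and optionally
#'   `label`.
#' @return validated interval tibble.
#' @export
interval_set <- function(intervals) {
  intervals <- as_tibble(intervals)
  needed <- c("chrom", "start", "end")
  missing_cols <- setdiff(needed, names(intervals))
  if (length(missing_cols) > 0) {
    abort(paste0("interval set is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  if (any(intervals$end < intervals$start)) {
    abort("interval set has records with end < start")
  }
  if (!"label" %in% names(intervals)) intervals$label <- NA_character_
  intervals[c(needed, "label",
              setdiff(names(intervals), c(needed, "label")))]
}

## GRanges view of an interval tibble or catalog span; internal coordinates
## are 1-based inclusive so no shift is needed.
as_granges <- function(df, point = NULL) {
  start <- df$start
  end <- df$end
  if (!is.null(point) && any(point)) end[point] <- start[point]
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = start, end = end)
  )
}

## dosage helpers ------------------------------------------------------------

gt_called <- function(gt) !is.na(gt)

gt_carrier <- function(gt) !is.na(gt) & gt > 0L

## map "0/0"-style strings to dosages; unknown strings -> NA (caller counts)
gt_parse_strings <- function(x) {
  x <- sub("\\|", "/", x)
  out <- rep(NA_integer_, length(x))
  out[x %in% c("0/0")] <- 0L
  out[x %in% c("0/1", "1/0")] <- 1L
  out[x %in% c("1/1")] <- 2L
  attr(out, "n_malformed") <-
    sum(!is.na(x) & !x %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  out
}

gt_format_strings <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}
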