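#' Read a multi-sample structural-variant VCF
#'
#' Parses a VCF 4.2 file whose records carry `SVTYPE`, `SVLEN` and `END`
#' INFO keys (as emitted by long-read SV callers and merge tools) into the
#' package's catalog + genotype-matrix pair.  Coordinates stay VCF-native
#' (1-based inclusive); insertions and break-ends become point events
#' (`end = start`); `SVLEN` is stored unsigned.  `GT` values outside
#' `0/0`, `0/1`, `1/0`, `1/1`, `./.` are set missing with a warning giving
#' the malformed-cell count.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return list with elements `catalog` (tibble, see [sv_catalog()]) and
#'   `gt` (integer dosage matrix, SV x sample).
#' @seealso [write_sv_vcf()] for the inverse operation.
#' @export
read_sv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(vcf@fix)
  sample_ids <- setdiff(colnames(vcf@gt), "FORMAT")
  if (n == 0) {
    catalog <- sv_catalog(tibble(
      sv_id = character(), chrom = character(), start = integer(),
      end = integer(), svtype = character(), svlen = integer(),
      mate_chrom = character(), mate_pos = integer()
    ))
    gt <- matrix(integer(), nrow = 0, ncol = length(sample_ids),
                 dimnames = list(character(), sample_ids))
    return(list(catalog = catalog, gt = gt))
  }

  fix <- vcf@fix
  svtype <- unname(vcfR::extract.info(vcf, "SVTYPE"))
  if (any(is.na(svtype))) {
    abort(paste0("records without SVTYPE at VCF row(s): ",
                 paste(which(is.na(svtype)), collapse = ", ")))
  }
  svlen <- suppressWarnings(
    abs(as.integer(vcfR::extract.info(vcf, "SVLEN")))
  )
  end <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "END")))
  start <- as.integer(fix[, "POS"])
  point <- svtype %in% c("INS", "BND")
  end[point] <- start[point]
  ## spans without an explicit END fall back to start + len - 1
  no_end <- !point & is.na(end)
  end[no_end] <- start[no_end] + svlen[no_end] - 1L

  mate_chrom <- unname(vcfR::extract.info(vcf, "CHR2"))
  mate_pos <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "POS2")))
  svlen[svtype == "BND" & is.na(svlen)] <- 0L

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("sv", which(is.na(ids) | ids == "."))

  catalog <- sv_catalog(tibble(
    sv_id = ids, chrom = fix[, "CHROM"], start = start, end = end,
    svtype = svtype, svlen = svlen,
    mate_chrom = mate_chrom, mate_pos = mate_pos
  ))

  gt_chr <- vcfR::extract.gt(vcf, "GT")
  parsed <- gt_parse_strings(as.vector(gt_chr))
  n_bad <- attr(parsed, "n_malformed")
  if (n_bad > 0) {
    warn(paste0(n_bad, " malformed GT value(s) set to missing"))
  }
  gt <- matrix(as.integer(parsed), nrow = n,
               dimnames = list(ids, sample_ids))
  list(catalog = catalog, gt = genotype_matrix(gt, catalog))
}

#' Write a catalog + genotype matrix as a VCF
#'
#' Emits plain-text VCF 4.2 with `SVTYPE`, `SVLEN`, `END` (and `CHR2`/`POS2`
#' for break-ends) INFO fields and per-sample `GT`.  Deletion `SVLEN` is
#' written negative per the VCF sign convention; all other types positive.
#' The output round-trips through [read_sv_vcf()] losslessly for every
#' field the data model stores.
#'
#' @param catalog SV catalog tibble.
#' @param gt dosage matrix whose rownames equal `catalog$sv_id`.
#' @param path output file path.
#' @param contigs optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(catalog, gt, path, contigs = NULL) {
  catalog <- sv_catalog(catalog)
  gt <- genotype_matrix(gt, catalog)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svaltiscan",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Mate chromosome for BND">',
    '##INFO=<ID=POS2,Number=1,Type=Integer,Description="Mate position for BND">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contigs)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contigs), as.integer(contigs)))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", colnames(gt)),
                            collapse = "\t"))
  if (nrow(catalog) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  svlen_out <- catalog$svlen
  svlen_out[catalog$svtype == "DEL"] <- -svlen_out[catalog$svtype == "DEL"]
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d",
                  catalog$svtype, catalog$end, svlen_out)
  is_bnd <- catalog$svtype == "BND"
  info[is_bnd] <- paste0(info[is_bnd], sprintf(";CHR2=%s;POS2=%d",
                                               catalog$mate_chrom[is_bnd],
                                               catalog$mate_pos[is_bnd]))
  gt_txt <- apply(gt, 1, function(g) paste(gt_format_strings(g),
                                           collapse = "\t"))
  body <- paste(catalog$chrom, catalog$start, catalog$sv_id, "N",
                paste0("<", catalog$svtype, ">"), ".", "PASS", info, "GT",
                gt_txt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED annotation track
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive, so
#' a line `chr1 0 100` becomes the interval `chr1:[1, 100]`.  Lines with
#' `start >= end` (empty in BED) are dropped with a warning naming them.
#' Overlapping intervals are preserved as-is, never merged.
#'
#' @param path BED3+ file; a 4th column, when present, is kept as `label`.
#' @return interval tibble (see [interval_set()]).
#' @export
read_bed <- function(path) {
  ## read.table tolerates a ragged optional-column tail (BED3 + BED4 mixed)
  bed <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                      colClasses = "character", comment.char = "#",
                      quote = ""),
    error = function(e) data.frame())
  bed[bed == ""] <- NA
  if (nrow(bed) == 0) {
    return(interval_set(tibble(chrom = character(), start = integer(),
                               end = integer())))
  }
  start0 <- as.integer(bed[[2]])
  end0 <- as.integer(bed[[3]])
  bad <- start0 >= end0
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " BED line(s) with start >= end: ",
                paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  out <- tibble(
    chrom = bed[[1]][!bad],
    start = start0[!bad] + 1L,
    end = end0[!bad],
    label = if (ncol(bed) >= 4) bed[[4]][!bad] else NA_character_
  )
  interval_set(out)
}

#' Write an interval tibble as BED
#'
#' Inverse boundary conversion of [read_bed()]: internal 1-based inclusive
#' back to 0-based half-open.
#'
#' @param intervals interval tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- interval_set(intervals)
  lines <- paste(intervals$chrom, intervals$start - 1L, intervals$end,
                 sep = "\t")
  if (!all(is.na(intervals$label))) {
    lab <- intervals$label
    lab[is.na(lab)] <- "."
    lines <- paste(lines, lab, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a population manifest TSV
#'
#' Expects a header line and columns `sample_id`, `population`, `role`
#' (`target`/`control`/`donor`) and optionally `order_index`.  With
#' `roles_optional = TRUE` a file without a `role` column is accepted and
#' every sample is assigned role `target`.
#'
#' @param path TSV file path.
#' @param roles_optional allow a missing `role` column (default `FALSE`).
#' @return manifest tibble (see [population_manifest()]).
#' @export
read_manifest <- function(path, roles_optional = FALSE) {
  man <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!"role" %in% names(man)) {
    if (!roles_optional) {
      abort("manifest has no 'role' column (use roles_optional = TRUE to default all samples to target)")
    }
    man$role <- "target"
  }
  population_manifest(man)
}

#' @rdname read_manifest
#' @param manifest manifest tibble to write.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- population_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' Read a biallelic SNP VCF into a dosage matrix
#'
#' Used for the flanking-haplotype validation of introgression candidates.
#' Only `GT` is consumed; sites and samples keep file order.
#'
#' @param path VCF path.
#' @return list with `sites` (tibble `chrom`, `pos`, `id`) and `gt`
#'   (integer dosage matrix, site x sample).
#' @export
read_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  sample_ids <- setdiff(colnames(vcf@gt), "FORMAT")
  n <- nrow(vcf@fix)
  if (n == 0) {
    return(list(sites = tibble(chrom = character(), pos = integer(),
                               id = character()),
                gt = matrix(integer(), 0, length(sample_ids),
                            dimnames = list(character(), sample_ids))))
  }
  ids <- vcf@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("snp", seq_len(n))[is.na(ids) | ids == "."]
  gt_chr <- vcfR::extract.gt(vcf, "GT")
  gt <- matrix(as.integer(gt_parse_strings(as.vector(gt_chr))), nrow = n,
               dimnames = list(ids, sample_ids))
  list(sites = tibble(chrom = vcf@fix[, "CHROM"],
                      pos = as.integer(vcf@fix[, "POS"]), id = ids),
       gt = gt)
}

#' Write a SNP dosage matrix as a minimal biallelic VCF
#'
#' @param sites tibble with `chrom`, `pos`, `id`.
#' @param gt site x sample dosage matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(sites, gt, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svaltiscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  )
  if (nrow(sites) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  gt_txt <- apply(gt, 1, function(g) paste(gt_format_strings(g),
                                           collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, sites$id, "A", "G", ".", "PASS",
                ".", "GT", gt_txt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
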