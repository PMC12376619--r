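## Independent oracles used across the suite.  Each deliberately takes a
## different computational route than the package implementation.

## Weir & Cockerham (1984) variance components via the ANOVA sum-of-squares
## decomposition over gametes (the package uses the closed-form moment
## expressions instead).  gts_by_pop: list of dosage vectors, NAs allowed.
wc_anova_oracle <- function(gts_by_pop) {
  gts_by_pop <- lapply(gts_by_pop, function(g) g[!is.na(g)])
  gts_by_pop <- gts_by_pop[lengths(gts_by_pop) > 0]
  r <- length(gts_by_pop)
  if (r < 2) return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                         theta = NA_real_))
  ni <- lengths(gts_by_pop)
  n_tot <- sum(ni)
  if (any(ni == n_tot)) return(list(a = NA, b = NA, c = NA, theta = NA))
  pi <- vapply(gts_by_pop, function(g) sum(g) / (2 * length(g)), 0)
  pbar <- sum(ni * pi) / n_tot
  SSP <- 2 * sum(ni * (pi - pbar)^2)
  SSI <- 2 * sum(unlist(Map(function(g, p) (g / 2 - p)^2, gts_by_pop, pi)))
  SSG <- sum(unlist(gts_by_pop) == 1) / 2
  if (n_tot - r == 0 || r - 1 == 0) {
    return(list(a = NA, b = NA, c = NA, theta = NA))
  }
  MSP <- SSP / (r - 1)
  MSI <- SSI / (n_tot - r)
  MSG <- SSG / n_tot
  nc <- (n_tot - sum(ni^2) / n_tot) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (denom > 0) a / denom else NA_real_)
}

## one-row dosage matrix helper
gt_row <- function(..., sv = "sv1") {
  g <- c(...)
  m <- matrix(as.integer(g), nrow = 1,
              dimnames = list(sv, paste0("s", seq_along(g))))
  m
}

## dosage matrix from per-sample vectors (SV x sample)
gt_mat <- function(rows, samples = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- if (is.null(names(rows))) {
    paste0("sv", seq_along(rows))
  } else {
    names(rows)
  }
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  storage.mode(m) <- "integer"
  m
}

## brute-force single-linkage clustering: all-pairs link test then
## transitive closure by fixed-point iteration
brute_cluster <- function(calls, max_dist) {
  n <- nrow(calls)
  link <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    calls$chrom[i] == calls$chrom[j] &&
      calls$svtype[i] == calls$svtype[j] &&
      abs(calls$start[i] - calls$start[j]) <= max_dist &&
      abs(calls$end[i] - calls$end[j]) <= max_dist
  }))
  repeat {
    link2 <- link | (link %*% link > 0)
    if (identical(link2, link)) break
    link <- link2
  }
  cl <- integer(n)
  nxt <- 0
  for (i in seq_len(n)) {
    if (cl[i] == 0) {
      nxt <- nxt + 1
      cl[which(link[i, ])] <- nxt
    }
  }
  cl
}

## brute-force reciprocal-overlap TE check for one SV span
brute_reciprocal_tagged <- function(sv_start, sv_end, repeats, min_recip) {
  any(vapply(seq_len(nrow(repeats)), function(k) {
    ov <- min(sv_end, repeats$end[k]) - max(sv_start, repeats$start[k]) + 1
    if (ov <= 0) return(FALSE)
    min(ov / (sv_end - sv_start + 1),
        ov / (repeats$end[k] - repeats$start[k] + 1)) >= min_recip
  }, logical(1)))
}

## random tree with strictly positive branch lengths; its cophenetic
## distances are exactly additive, so NJ must recover it
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
  tr
}

## toy hand-written SV VCF used by the io tests
toy_sv_vcf <- function(path, extra_records = character()) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="c2">',
    '##INFO=<ID=POS2,Number=1,Type=Integer,Description="p2">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sampleA", "sampleB"), collapse = "\t"),
    "chr1\t1000\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1100;SVLEN=-101\tGT\t0/1\t1/1",
    "chr1\t5000\tins1\tN\t<INS>\t.\tPASS\tSVTYPE=INS;END=5000;SVLEN=300\tGT\t0/0\t0/1",
    "chr2\t700\tbnd1\tN\t<BND>\t.\tPASS\tSVTYPE=BND;END=700;CHR2=chr3;POS2=42000\tGT\t./.\t0/1",
    extra_records
  )
  writeLines(lines, path)
  path
}
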