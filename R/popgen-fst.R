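#' Per-SV allele and carrier frequencies
#'
#' `allele_freq()` returns the ALT allele frequency
#' `(#het + 2 #hom_alt) / (2 #called)`; `carrier_freq()` the fraction of
#' called samples carrying at least one ALT allele.  Missing genotypes are
#' excluded from both numerator and denominator.  SVs with no called
#' genotype get `NA` and are flagged by `n_called = 0`.
#'
#' @param gt dosage matrix (SV x sample).
#' @param samples sample ids to use (default: all columns).
#' @param percent report carrier frequency as an integer percentage
#'   (`round(100 * f)`), the convention used for headline carrier rates.
#' @return tibble with `sv_id`, `n_called` and `af` (or `carrier_rate`).
#' @export
allele_freq <- function(gt, samples = colnames(gt)) {
  sub <- gt[, samples, drop = FALSE]
  n_called <- unname(rowSums(gt_called(sub)))
  af <- unname(rowSums(sub, na.rm = TRUE)) / (2 * n_called)
  af[n_called == 0] <- NA_real_
  tibble(sv_id = rownames(gt), n_called = as.integer(n_called), af = af)
}

#' @rdname allele_freq
#' @export
carrier_freq <- function(gt, samples = colnames(gt), percent = FALSE) {
  sub <- gt[, samples, drop = FALSE]
  n_called <- unname(rowSums(gt_called(sub)))
  f <- unname(rowSums(gt_carrier(sub))) / n_called
  f[n_called == 0] <- NA_real_
  if (percent) f <- round(100 * f)
  tibble(sv_id = rownames(gt), n_called = as.integer(n_called),
         carrier_rate = f)
}

#' Weir-Cockerham FST variance components per SV
#'
#' Computes, for every SV, the Weir & Cockerham (1984) variance components
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals) from per-population sample sizes, ALT allele
#' frequencies and observed heterozygosities, and the estimator
#' `theta = a / (a + b + c)`.  Negative estimates are retained (they are
#' part of the estimator's sampling distribution); SVs monomorphic across
#' all populations, or informative in fewer than two populations, are
#' returned with `theta = NA`.
#'
#' @param gt dosage matrix (SV x sample).
#' @param pops named list of sample-id vectors, one per population
#'   (at least two).
#' @return tibble with `sv_id`, `a`, `b`, `c`, `theta` and `n_pops` (number
#'   of populations with at least one called genotype).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst <- function(gt, pops) {
  if (length(pops) < 2) abort("need at least two populations")
  if (is.null(names(pops))) names(pops) <- paste0("pop", seq_along(pops))
  r_max <- length(pops)
  n_sv <- nrow(gt)

  N <- P <- H <- matrix(NA_real_, n_sv, r_max)
  for (k in seq_len(r_max)) {
    sub <- gt[, pops[[k]], drop = FALSE]
    nk <- rowSums(gt_called(sub))
    N[, k] <- nk
    P[, k] <- rowSums(sub, na.rm = TRUE) / (2 * nk)
    H[, k] <- rowSums(sub == 1L, na.rm = TRUE) / nk
  }
  valid <- N > 0
  r <- rowSums(valid)
  N[!valid] <- 0
  P[!valid] <- 0
  H[!valid] <- 0

  n_tot <- rowSums(N)
  nbar <- n_tot / r
  nc <- (n_tot - rowSums(N^2) / n_tot) / (r - 1)
  pbar <- rowSums(N * P) / n_tot
  s2 <- rowSums(N * (P - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(N * H) / n_tot

  inner <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
  a <- nbar / nc * (s2 - inner / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom > 0, a / denom, NA_real_)
  tibble(sv_id = rownames(gt), a = a, b = b, c = cc, theta = theta,
         n_pops = as.integer(r))
}

#' Windowed FST over sliding genomic windows
#'
#' Aggregates per-site Weir-Cockerham components into sliding windows using
#' the ratio-of-sums estimator `sum(a) / sum(a + b + c)` (not the mean of
#' per-site ratios).  Windows containing no informative site are omitted.
#'
#' @param components tibble with `chrom`, `pos`, `a`, `b`, `c` (e.g.
#'   [wc_fst()] output joined to SV midpoints).
#' @param window window size in bp (default 50000).
#' @param step window increment in bp (default 25000).
#' @return tibble with `chrom`, `start`, `end`, `n_sites`, `fst`.
#' @export
windowed_fst <- function(components, window = 50000, step = 25000) {
  if (window <= 0) abort("window must be > 0")
  if (step <= 0) abort("step must be > 0")
  ok <- stats::complete.cases(components[, c("a", "b", "c")])
  components <- components[ok, , drop = FALSE]
  per_chrom <- function(df) {
    starts <- seq(1, max(df$pos), by = step)
    purrr::map_dfr(starts, function(w) {
      inw <- df$pos >= w & df$pos <= w + window - 1
      if (!any(inw)) return(NULL)
      tibble(start = w, end = w + window - 1, n_sites = sum(inw),
             fst = sum(df$a[inw]) /
               sum(df$a[inw] + df$b[inw] + df$c[inw]))
    })
  }
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_sites = integer(), fst = numeric())
  if (nrow(components) == 0) return(empty)
  out <- components |>
    dplyr::group_split(.data$chrom) |>
    purrr::map_dfr(function(df) {
      res <- per_chrom(df)
      if (nrow(res) == 0) return(NULL)
      dplyr::mutate(res, chrom = df$chrom[1], .before = 1)
    })
  if (nrow(out) == 0) empty else out
}
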