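#' SV midpoints per chromosome
#'
#' Hotspot detection works on one point per SV: the midpoint
#' `floor((start + end) / 2)` for span types and the breakpoint itself for
#' insertions and break-ends.
#'
#' @param catalog SV catalog tibble.
#' @return tibble with `sv_id`, `chrom`, `pos`, sorted within chromosome.
#' @export
sv_midpoints <- function(catalog) {
  catalog <- sv_catalog(catalog)
  pos <- as.integer(floor((as.numeric(catalog$start) +
                             as.numeric(catalog$end)) / 2))
  point <- catalog$svtype %in% c("INS", "BND")
  pos[point] <- catalog$start[point]
  tibble(sv_id = catalog$sv_id, chrom = catalog$chrom, pos = pos) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Kernel-density SV hotspot detection with a permutation null
#'
#' Per chromosome, a Gaussian kernel density of SV midpoints (kernel sd =
#' `bandwidth`) is evaluated on a regular grid.  The null distribution is
#' obtained by `n_perm` uniform re-placements of the same number of
#' midpoints along the chromosome; each observed grid density gets an
#' empirical p-value against the pooled null densities of its chromosome,
#' with the +1 pseudo-count convention (so p is never 0 and never below
#' `1/(1 + n_perm * n_grid)`).  After Benjamini-Hochberg correction across
#' all grid points genome-wide, runs of significant points are merged,
#' extended by `bandwidth / 2` on each side, clipped to the chromosome and
#' reported with their SV count, peak density and minimum empirical p.
#'
#' @param midpoints tibble from [sv_midpoints()] (`chrom`, `pos`).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bandwidth Gaussian kernel sd in bp (default 5e5).
#' @param grid_step grid spacing in bp (default 1e4).
#' @param n_perm number of permutations (default 200, minimum 20).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param seed optional integer seed for the permutation RNG.
#' @return object of class `svalt_hotspots`: a tibble of hotspot intervals
#'   (`chrom`, `start`, `end`, `n_sv`, `peak_density`, `min_p`) with
#'   attributes `n_hotspots`, `total_bp` and the call parameters.
#' @export
call_hotspots <- function(midpoints, chrom_lengths, bandwidth = 5e5,
                          grid_step = 1e4, n_perm = 200, alpha = 0.05,
                          seed = NULL) {
  if (bandwidth <= 0) abort("bandwidth must be > 0")
  if (n_perm < 20) abort("n_perm must be >= 20")
  missing_chr <- setdiff(unique(midpoints$chrom), names(chrom_lengths))
  if (length(missing_chr) > 0) {
    abort(paste0("chrom_lengths missing: ",
                 paste(missing_chr, collapse = ", ")))
  }
  if (!is.null(seed)) withr::local_seed(seed)

  per_chrom <- purrr::map(names(chrom_lengths), function(chr) {
    x <- midpoints$pos[midpoints$chrom == chr]
    if (length(x) == 0) return(NULL)
    len <- chrom_lengths[[chr]]
    ngrid <- max(2L, as.integer(floor(len / grid_step)) + 1L)
    grid <- seq(1, len, length.out = ngrid)
    dens <- function(p) {
      density(p, bw = bandwidth, from = 1, to = len, n = ngrid)$y
    }
    obs <- dens(x)
    null_vals <- unlist(lapply(seq_len(n_perm), function(i) {
      dens(runif(length(x), 1, len))
    }), use.names = FALSE)
    null_sorted <- sort(null_vals)
    n_null <- length(null_sorted)
    ## #null >= obs: subtract the strictly-smaller count so exact ties
    ## (e.g. zero density in empty regions) stay conservative
    n_ge <- n_null - findInterval(obs, null_sorted, left.open = TRUE)
    p <- (1 + n_ge) / (1 + n_null)
    list(chrom = chr, grid = grid, obs = obs, p = p, x = x, len = len)
  })
  per_chrom <- purrr::compact(per_chrom)

  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_sv = integer(), peak_density = numeric(),
                  min_p = numeric())
  hotspots <- empty
  if (length(per_chrom) > 0) {
    all_p <- unlist(purrr::map(per_chrom, "p"), use.names = FALSE)
    p_adj <- p.adjust(all_p, method = "BH")
    offset <- 0
    hotspots <- purrr::map_dfr(per_chrom, function(pc) {
      k <- length(pc$p)
      sig <- p_adj[offset + seq_len(k)] < alpha
      offset <<- offset + k
      if (!any(sig)) return(NULL)
      runs <- rle(sig)
      ends_i <- cumsum(runs$lengths)
      starts_i <- ends_i - runs$lengths + 1
      keep <- which(runs$values)
      iv <- tibble(
        start = pmax(1, floor(pc$grid[starts_i[keep]] - bandwidth / 2)),
        end = pmin(pc$len, ceiling(pc$grid[ends_i[keep]] + bandwidth / 2))
      )
      ## merge intervals that touch after extension
      iv <- dplyr::arrange(iv, .data$start)
      grp <- cumsum(c(1, as.integer(iv$start[-1] >
                                      cummax(iv$end)[-nrow(iv)] + 1)))
      merged <- iv |>
        dplyr::mutate(grp = grp) |>
        dplyr::group_by(.data$grp) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         .groups = "drop")
      purrr::pmap_dfr(merged[c("start", "end")], function(start, end) {
        ing <- pc$grid >= start & pc$grid <= end
        tibble(chrom = pc$chrom, start = as.integer(start),
               end = as.integer(end),
               n_sv = sum(pc$x >= start & pc$x <= end),
               peak_density = max(pc$obs[ing]),
               min_p = min(pc$p[ing]))
      })
    })
    if (nrow(hotspots) == 0) hotspots <- empty
  }
  structure(hotspots,
            class = c("svalt_hotspots", class(hotspots)),
            n_hotspots = nrow(hotspots),
            total_bp = sum(as.numeric(hotspots$end) - hotspots$start + 1),
            bandwidth = bandwidth, grid_step = grid_step,
            n_perm = n_perm, alpha = alpha)
}

#' @export
print.svalt_hotspots <- function(x, ...) {
  cat("SV hotspots:", attr(x, "n_hotspots"), "interval(s),",
      format(attr(x, "total_bp"), big.mark = ","), "bp total\n")
  NextMethod()
}

#' @rdname call_hotspots
#' @param x,object an `svalt_hotspots` object.
#' @param ... unused.
#' @method glance svalt_hotspots
#' @export
glance.svalt_hotspots <- function(x, ...) {
  tibble(n_hotspots = attr(x, "n_hotspots"),
         total_bp = attr(x, "total_bp"),
         bandwidth = attr(x, "bandwidth"),
         n_perm = attr(x, "n_perm"),
         alpha = attr(x, "alpha"))
}

#' Random-relocation enrichment Z test of hotspots against an annotation
#'
#' Tests whether annotated points (e.g. midpoints of TE-derived SVs, or
#' conserved elements) fall inside hotspots more or less often than
#' expected.  The default null relocates the hotspot intervals `n_draws`
#' times — lengths and chromosome assignment preserved, uniform
#' non-overlapping placement — which keeps the annotation's own clustering
#' structure intact; `null = "permute_points"` instead redraws the same
#' number of annotation points uniformly per chromosome.  `Z = (observed -
#' null mean) / null sd`, with a one-sided normal p in the direction of the
#' deviation (enrichment for positive Z, depletion for negative).
#'
#' For annotations that are a *subset of the SV catalog itself* (e.g.
#' TE-derived SVs) the first two nulls confound the annotation with SV
#' density: hotspots hold many SVs by construction, so any SV subset is
#' "enriched" there.  `null = "permute_labels"` handles this by resampling
#' which members of `universe` (all SV midpoints) carry the label, holding
#' positions fixed — it tests whether the labelled *fraction* inside
#' hotspots exceeds the genome-wide fraction.
#'
#' @param hotspots `svalt_hotspots` object (or interval tibble).
#' @param points tibble with `chrom`, `pos` of annotated points.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_draws number of random draws (default 1000, minimum 100).
#' @param seed optional integer seed.
#' @param null `"relocate_hotspots"` (default), `"permute_points"`, or
#'   `"permute_labels"`.
#' @param universe tibble of all SV midpoints (`chrom`, `pos`); required
#'   for `null = "permute_labels"`, where `points` must be the labelled
#'   subset.
#' @return object of class `svalt_enrichment` (one-row tibble with
#'   `observed`, `null_mean`, `null_sd`, `z`, `p`, `direction`, `n_draws`).
#' @export
enrichment_z <- function(hotspots, points, chrom_lengths, n_draws = 1000,
                         seed = NULL,
                         null = c("relocate_hotspots", "permute_points",
                                  "permute_labels"),
                         universe = NULL) {
  null <- match.arg(null)
  if (n_draws < 100) abort("n_draws must be >= 100")
  if (nrow(points) == 0) abort("need at least one annotated point")
  if (nrow(hotspots) == 0) abort("hotspot set is empty")
  if (null == "permute_labels" && is.null(universe)) {
    abort("null = \"permute_labels\" requires the universe of SV midpoints")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  count_in <- function(iv, pts) {
    total <- 0L
    for (chr in unique(iv$chrom)) {
      p <- pts$pos[pts$chrom == chr]
      if (length(p) == 0) next
      sub <- iv[iv$chrom == chr, ]
      o <- order(sub$start)
      s <- sub$start[o]; e <- sub$end[o]
      k <- findInterval(p, s)
      inside <- k > 0
      total <- total + sum(p[inside] <= e[k[inside]])
    }
    total
  }
  observed <- count_in(hotspots, points)

  null_counts <- if (null == "relocate_hotspots") {
    lens_by_chr <- split(as.numeric(hotspots$end - hotspots$start + 1),
                         hotspots$chrom)
    vapply(seq_len(n_draws), function(i) {
      iv <- purrr::imap_dfr(lens_by_chr, function(lens, chr) {
        clen <- chrom_lengths[[chr]]
        free <- clen - sum(lens)
        if (free < 0) abort(paste0("hotspots exceed length of ", chr))
        ## sample() on a length-1 numeric would permute seq_len(lens)
        if (length(lens) > 1) lens <- sample(lens)
        gaps <- sort(runif(length(lens), 0, free))
        starts <- floor(gaps + cumsum(c(0, lens[-length(lens)]))) + 1
        tibble(chrom = chr, start = starts, end = starts + lens - 1)
      })
      count_in(iv, points)
    }, numeric(1))
  } else if (null == "permute_points") {
    n_by_chr <- table(points$chrom)
    vapply(seq_len(n_draws), function(i) {
      pts <- purrr::imap_dfr(as.list(n_by_chr), function(n, chr) {
        tibble(chrom = chr,
               pos = floor(runif(n, 1, chrom_lengths[[chr]])))
      })
      count_in(hotspots, pts)
    }, numeric(1))
  } else {
    ## resample which catalog midpoints are labelled, positions fixed
    in_hot <- vapply(seq_len(nrow(universe)), function(i) {
      sub <- hotspots[hotspots$chrom == universe$chrom[i], ]
      any(universe$pos[i] >= sub$start & universe$pos[i] <= sub$end)
    }, logical(1))
    k <- nrow(points)
    vapply(seq_len(n_draws), function(i) {
      sum(in_hot[sample.int(nrow(universe), k)])
    }, numeric(1))
  }

  mu <- mean(null_counts)
  s <- sd(null_counts)
  if (s == 0) {
    abort(paste0("null counts are constant (", mu,
                 "); annotation or hotspot set too small for a Z test"))
  }
  z <- (observed - mu) / s
  p <- pnorm(abs(z), lower.tail = FALSE)
  out <- tibble(observed = observed, null_mean = mu, null_sd = s, z = z,
                p = p,
                direction = ifelse(z >= 0, "enrichment", "depletion"),
                n_draws = as.integer(n_draws))
  structure(out, class = c("svalt_enrichment", class(out)))
}

#' @rdname enrichment_z
#' @param x an `svalt_enrichment` object.
#' @param ... unused.
#' @method tidy svalt_enrichment
#' @export
tidy.svalt_enrichment <- function(x, ...) as_tibble(unclass(x))
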