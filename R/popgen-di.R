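#' Pairwise FST tables for a di selection scan
#'
#' Computes per-SV Weir-Cockerham `theta` for the focal group against each
#' control population separately.  The focal unit is either the pooled
#' target group (`focal = "pooled"`, the default, matching the usual
#' highland-vs-each-lowland-breed contrast) or each target population in
#' turn (`focal = "per_population"`).
#'
#' @param gt dosage matrix.
#' @param manifest population manifest.
#' @param focal `"pooled"` or `"per_population"`.
#' @param control_pops control populations; default: all populations with
#'   role `control`.
#' @return long tibble with `sv_id`, `focal`, `control`, `pair`, `theta`.
#' @export
fst_pairs <- function(gt, manifest, focal = c("pooled", "per_population"),
                      control_pops = NULL) {
  focal <- match.arg(focal)
  manifest <- population_manifest(manifest)
  if (is.null(control_pops)) {
    control_pops <- unique(manifest$population[manifest$role == "control"])
  }
  if (length(control_pops) == 0) abort("no control populations")
  focal_groups <- if (focal == "pooled") {
    list(pooled_target = manifest$sample_id[manifest$role == "target"])
  } else {
    tgt <- manifest[manifest$role == "target", ]
    split(tgt$sample_id, tgt$population)
  }
  if (any(lengths(focal_groups) == 0)) abort("no target samples")

  purrr::imap_dfr(focal_groups, function(fs, fname) {
    purrr::map_dfr(control_pops, function(cp) {
      cs <- manifest$sample_id[manifest$population == cp]
      th <- wc_fst(gt, setNames(list(fs, cs), c(fname, cp)))
      tibble(sv_id = th$sv_id, focal = fname, control = cp,
             pair = paste0(fname, "~", cp), theta = th$theta)
    })
  })
}

#' The di population-differentiation statistic
#'
#' For SV `s` and focal group `i`, `d_i(s) = sum_j (theta_ij(s) - mu_ij) /
#' sigma_ij` over comparison populations `j`, where `mu_ij` and `sigma_ij`
#' are the mean and standard deviation of the pairwise FST across all SVs.
#' Large positive values mark loci unusually differentiated in the focal
#' group.  SV/pair combinations with undefined FST (monomorphic sites) are
#' excluded both from the genome-wide moments and from that SV's sum; the
#' number of pairs actually used is reported per SV.
#'
#' @param theta_long long tibble from [fst_pairs()] (columns `sv_id`,
#'   `pair`, `theta`; an optional `focal` column scopes moments within each
#'   focal group).
#' @return object of class `svalt_di` with elements `di` (tibble `sv_id`,
#'   `focal`, `di`, `n_pairs`) and `moments` (tibble `pair`, `mu`, `sigma`,
#'   `n_used`).  Use [tidy()] / [glance()] or [di_outliers()] downstream.
#' @export
di_statistic <- function(theta_long) {
  if (!"focal" %in% names(theta_long)) theta_long$focal <- "focal"
  moments <- theta_long |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(mu = mean(.data$theta, na.rm = TRUE),
                     sigma = sd(.data$theta, na.rm = TRUE),
                     n_used = sum(!is.na(.data$theta)), .groups = "drop")
  degenerate <- moments$pair[is.na(moments$sigma) | moments$sigma == 0]
  if (length(degenerate) > 0) {
    abort(paste0("zero or undefined FST dispersion for pair(s): ",
                 paste(degenerate, collapse = ", ")))
  }
  di <- theta_long |>
    dplyr::left_join(moments, by = "pair") |>
    dplyr::group_by(.data$sv_id, .data$focal) |>
    dplyr::summarise(
      di = sum((.data$theta - .data$mu) / .data$sigma, na.rm = TRUE),
      n_pairs = sum(!is.na(.data$theta)), .groups = "drop") |>
    dplyr::mutate(di = ifelse(.data$n_pairs == 0, NA_real_, .data$di))
  structure(list(di = di, moments = moments), class = "svalt_di")
}

#' @export
print.svalt_di <- function(x, ...) {
  cat("di selection scan:", nrow(x$di), "SV values over",
      nrow(x$moments), "population pair(s)\n")
  print(x$moments)
  invisible(x)
}

#' @rdname di_statistic
#' @param x,object an `svalt_di` object.
#' @param ... unused.
#' @method tidy svalt_di
#' @export
tidy.svalt_di <- function(x, ...) x$di

#' @rdname di_statistic
#' @method glance svalt_di
#' @export
glance.svalt_di <- function(x, ...) {
  tibble(n_sv = dplyr::n_distinct(x$di$sv_id),
         n_pairs = nrow(x$moments),
         mean_di = mean(x$di$di, na.rm = TRUE),
         sd_di = sd(x$di$di, na.rm = TRUE))
}

#' Z-test outlier calling on di values
#'
#' Standardizes the di values (`Z = (di - mean) / sd`) and flags SVs in the
#' one-sided upper tail at level `alpha`: `P = 1 - Phi(Z) < alpha`, i.e.
#' `Z > 3.09` for the default `alpha = 0.001`.  A selection scan looks for
#' elevated differentiation only, hence the one-sided test.
#'
#' @param di_res `svalt_di` object or a tibble with `sv_id` and `di`.
#' @param alpha one-sided significance level (default 0.001).
#' @return tibble with `sv_id`, `di`, `z`, `p`, `outlier`.
#' @export
di_outliers <- function(di_res, alpha = 0.001) {
  di <- if (inherits(di_res, "svalt_di")) di_res$di else as_tibble(di_res)
  if (!"focal" %in% names(di)) di$focal <- "focal"
  ## standardization is within each focal group's genome-wide distribution
  out <- di |>
    dplyr::group_by(.data$focal) |>
    dplyr::group_modify(function(df, key) {
      vals <- df$di
      if (sum(is.finite(vals)) < 2) {
        abort("need at least two finite di values")
      }
      s <- sd(vals, na.rm = TRUE)
      if (is.na(s) || s == 0) abort("di values have zero dispersion")
      z <- (vals - mean(vals, na.rm = TRUE)) / s
      p <- pnorm(z, lower.tail = FALSE)
      tibble(sv_id = df$sv_id, di = vals, z = z, p = p,
             outlier = !is.na(p) & p < alpha)
    }) |>
    dplyr::ungroup()
  out[c("sv_id", "focal", "di", "z", "p", "outlier")]
}
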