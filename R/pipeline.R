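#' Percentages with a fixed rounding convention
#'
#' `percent_of()` computes `100 * a / b` rounded half-even to 2 decimals —
#' the convention used for every proportion the pipeline reports, so that
#' e.g. 46028 of 222528 prints as 20.68.  `summarize_counts()` applies it
#' to a named count vector.
#'
#' @param a,b numerator and denominator counts (`b > 0`).
#' @return `percent_of()`: numeric percentage; `summarize_counts()`: tibble
#'   with `label`, `n`, `percent`.
#' @export
percent_of <- function(a, b) {
  if (any(b == 0)) abort("zero denominator in percentage")
  round(100 * a / b, 2)
}

#' @rdname percent_of
#' @param counts named integer vector.
#' @param total denominator (default `sum(counts)`).
#' @export
summarize_counts <- function(counts, total = sum(counts)) {
  tibble(label = names(counts), n = as.integer(counts),
         percent = percent_of(as.integer(counts), total))
}

pipeline_stages <- function() {
  c("sharing", "control_absent", "annotate", "te", "popgen", "hotspots",
    "enrichment", "introgression")
}

#' Run the SV population-genetics pipeline end-to-end
#'
#' Executes the toggled stages on either a simulated cohort (the default)
#' or files read from `inputs`, writes per-stage TSVs plus a machine-
#' readable `summary.json` / `summary.tsv` into `out_dir`, and returns the
#' stage results.  Every number in the summary is an aggregation of a
#' stage table written alongside it, and the whole run is a deterministic
#' function of `(inputs/config, parameters, seed)`.
#'
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] used when `inputs` is `NULL`.
#' @param inputs optional named list of file paths: `sv_vcf`, `manifest`,
#'   and optionally `genes`, `exons`, `repeats`, `conserved`, `ins_labels`,
#'   `chrom_lengths` (named vector, required for hotspot stages) and
#'   `snp_vcfs` (named `sv_id -> path` for introgression validation).
#' @param seed integer seed covering all stage randomness.
#' @param stages which stages to run, a subset of
#'   `sharing, control_absent, annotate, te, popgen, hotspots, enrichment,
#'   introgression` (the `enrichment` stage requires `hotspots` and `te`).
#' @param di_alpha one-sided level for di outlier calling.
#' @param hotspot_bandwidth,hotspot_grid_step,hotspot_n_perm,hotspot_alpha
#'   parameters of [call_hotspots()].
#' @param enrich_n_draws draws for [enrichment_z()].
#' @param donor_fixed_min,control_max,target_min_carriers,max_missing_frac
#'   policy of [candidate_introgressed()].
#' @param max_validate maximum number of candidates taken through
#'   haplotype-tree validation.
#' @return (invisibly) list with the stage tables and the `summary` list.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), inputs = NULL,
                         seed = 1, stages = pipeline_stages(),
                         di_alpha = 0.001,
                         hotspot_bandwidth = 5e5, hotspot_grid_step = 1e4,
                         hotspot_n_perm = 200, hotspot_alpha = 0.05,
                         enrich_n_draws = 1000,
                         donor_fixed_min = 1.0, control_max = 0.0,
                         target_min_carriers = 1, max_missing_frac = 0.2,
                         max_validate = 20) {
  unknown <- setdiff(stages, pipeline_stages())
  if (length(unknown) > 0) {
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  if ("enrichment" %in% stages &&
      !all(c("hotspots", "te") %in% stages)) {
    abort("the enrichment stage requires the hotspots and te stages")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  withr::local_seed(seed)

  if (is.null(inputs)) {
    cohort <- simulate_cohort(sim, seed = seed)
    chrom_lengths <- sim$chromosomes
  } else {
    sv <- read_sv_vcf(inputs$sv_vcf)
    cohort <- list(
      catalog = sv$catalog, gt = sv$gt,
      manifest = read_manifest(inputs$manifest),
      genes = if (!is.null(inputs$genes)) read_bed(inputs$genes),
      exons = if (!is.null(inputs$exons)) read_bed(inputs$exons),
      repeats = if (!is.null(inputs$repeats)) read_bed(inputs$repeats),
      conserved = if (!is.null(inputs$conserved)) read_bed(inputs$conserved),
      ins_labels = if (!is.null(inputs$ins_labels)) {
        readr::read_tsv(inputs$ins_labels, show_col_types = FALSE)
      },
      truth = NULL)
    chrom_lengths <- inputs$chrom_lengths
    if (any(c("hotspots", "enrichment") %in% stages) &&
        is.null(chrom_lengths)) {
      abort("inputs$chrom_lengths is required for the hotspot stages")
    }
  }
  catalog <- cohort$catalog
  gt <- cohort$gt
  manifest <- cohort$manifest
  res <- list(cohort = cohort)
  p <- function(f) file.path(out_dir, f)
  log_stage <- function(name, n_in, n_out) {
    message(sprintf("[%s] in=%d out=%d", name, n_in, n_out))
  }

  summary <- list(seed = seed,
                  n_sv = nrow(catalog),
                  n_samples = ncol(gt),
                  sv_type_counts = as.list(table(catalog$svtype)))

  if ("sharing" %in% stages) {
    sharing <- classify_sharing(gt)
    growth <- cumulative_growth(
      gt, manifest$sample_id[order(manifest$order_index)])
    readr::write_tsv(sharing, p("sharing.tsv"))
    readr::write_tsv(growth, p("growth_curve.tsv"))
    counts <- table(sharing$sharing_class)
    summary$sharing_counts <- as.list(counts)
    summary$sharing_percent <-
      as.list(setNames(percent_of(as.integer(counts), sum(counts)),
                       names(counts)))
    res$sharing <- sharing
    res$growth <- growth
    log_stage("sharing", nrow(catalog), nrow(sharing))
  }

  if ("control_absent" %in% stages) {
    ca <- control_absent(gt, manifest, catalog = catalog)
    readr::write_tsv(tibble(sv_id = ca$sv_ids), p("control_absent.tsv"))
    summary$control_absent_n <- length(ca$sv_ids)
    summary$control_absent_percent <-
      percent_of(length(ca$sv_ids), nrow(catalog))
    summary$control_absent_by_type <-
      as.list(setNames(ca$type_counts$n, ca$type_counts$svtype))
    res$control_absent <- ca
    log_stage("control_absent", nrow(catalog), length(ca$sv_ids))
  }

  if ("annotate" %in% stages) {
    regions <- annotate_regions(catalog, cohort$genes, cohort$exons)
    readr::write_tsv(regions, p("regions.tsv"))
    counts <- table(regions$region)
    summary$region_counts <- as.list(counts)
    summary$exonic_percent <-
      percent_of(sum(regions$region == "exonic"), nrow(catalog))
    res$regions <- regions
    log_stage("annotate", nrow(catalog), nrow(regions))
  }

  if ("te" %in% stages) {
    te <- tag_te(catalog, cohort$repeats, cohort$ins_labels)
    readr::write_tsv(te, p("te_tags.tsv"))
    summary$te_n <- sum(te$te)
    summary$te_percent <- percent_of(sum(te$te), nrow(catalog))
    res$te <- te
    log_stage("te", nrow(catalog), sum(te$te))
  }

  if ("popgen" %in% stages) {
    theta <- fst_pairs(gt, manifest)
    di <- di_statistic(theta)
    outliers <- di_outliers(di, alpha = di_alpha)
    readr::write_tsv(theta, p("fst_pairs.tsv"))
    readr::write_tsv(outliers, p("di.tsv"))
    mids <- sv_midpoints(catalog)
    ctrl_pops <- unique(manifest$population[manifest$role == "control"])
    comp <- wc_fst(gt, list(
      target = manifest$sample_id[manifest$role == "target"],
      control = manifest$sample_id[manifest$role == "control"]))
    wfst <- comp |>
      dplyr::inner_join(mids, by = "sv_id") |>
      windowed_fst()
    readr::write_tsv(wfst, p("windowed_fst.tsv"))
    summary$di_sv_n <- sum(outliers$outlier)
    summary$di_alpha <- di_alpha
    res$di <- di
    res$di_outliers <- outliers
    res$windowed_fst <- wfst
    log_stage("popgen", nrow(catalog), sum(outliers$outlier))
  }

  if ("hotspots" %in% stages) {
    mids <- sv_midpoints(catalog)
    hs <- call_hotspots(mids, chrom_lengths,
                        bandwidth = hotspot_bandwidth,
                        grid_step = hotspot_grid_step,
                        n_perm = hotspot_n_perm, alpha = hotspot_alpha)
    readr::write_tsv(as_tibble(hs), p("hotspots.tsv"))
    write_bed(dplyr::mutate(as_tibble(hs)[c("chrom", "start", "end")],
                            label = NA_character_),
              p("hotspots.bed"))
    summary$hotspot_n <- attr(hs, "n_hotspots")
    summary$hotspot_bp <- attr(hs, "total_bp")
    res$hotspots <- hs
    log_stage("hotspots", nrow(mids), nrow(hs))
  }

  if ("enrichment" %in% stages) {
    mids <- sv_midpoints(catalog)
    te_mids <- mids[mids$sv_id %in% res$te$sv_id[res$te$te], ]
    enr <- list()
    if (nrow(res$hotspots) > 0 && nrow(te_mids) > 0) {
      ## TE-SVs are a catalog subset: test their fraction, not density
      enr$te_sv <- enrichment_z(res$hotspots, te_mids, chrom_lengths,
                                n_draws = enrich_n_draws,
                                null = "permute_labels", universe = mids)
    }
    if (!is.null(cohort$conserved) && nrow(res$hotspots) > 0 &&
        nrow(cohort$conserved) > 0) {
      cons_pts <- tibble(
        chrom = cohort$conserved$chrom,
        pos = floor((cohort$conserved$start + cohort$conserved$end) / 2))
      enr$conserved <- enrichment_z(res$hotspots, cons_pts, chrom_lengths,
                                    n_draws = enrich_n_draws)
    }
    if (length(enr) > 0) {
      enr_tbl <- dplyr::bind_rows(purrr::map(enr, tidy), .id = "annotation")
      readr::write_tsv(enr_tbl, p("enrichment.tsv"))
      summary$enrichment <- purrr::map(enr, function(e) {
        list(z = e$z, p = e$p, observed = e$observed,
             direction = e$direction)
      })
      res$enrichment <- enr
      log_stage("enrichment", nrow(res$hotspots), length(enr))
    }
  }

  if ("introgression" %in% stages) {
    calls <- candidate_introgressed(
      gt, manifest, donor_fixed_min = donor_fixed_min,
      control_max = control_max,
      target_min_carriers = target_min_carriers,
      max_missing_frac = max_missing_frac)
    cand <- calls[calls$candidate, ]
    status <- rep(NA_character_, nrow(cand))
    donors <- manifest$sample_id[manifest$role == "donor"]
    to_validate <- head(seq_len(nrow(cand)), max_validate)
    for (i in to_validate) {
      id <- cand$sv_id[i]
      carriers <- colnames(gt)[gt_carrier(gt[id, ]) & colnames(gt) %in%
        manifest$sample_id[manifest$role == "target"]]
      if (length(carriers) == 0) next
      snp <- if (!is.null(inputs) && !is.null(inputs$snp_vcfs)) {
        path <- inputs$snp_vcfs[[id]]
        if (is.null(path)) next
        read_snp_vcf(path)$gt
      } else {
        truly <- !is.null(cohort$truth) &&
          cohort$truth$introgressed[match(id, cohort$truth$sv_id)]
        simulate_flanking_snps(manifest, carriers = carriers,
                               introgressed = isTRUE(truly),
                               divergence = sim$donor_divergence,
                               noise = sim$snp_noise)
      }
      tree <- nj_tree(allele_sharing_distance(snp))
      others <- setdiff(colnames(gt), c(carriers, donors))
      status[i] <- validate_candidate(tree, carriers, donors, others)
    }
    cand$status <- status
    freqs <- introgression_frequencies(cand, gt, manifest)
    readr::write_tsv(calls, p("introgression_calls.tsv"))
    readr::write_tsv(freqs, p("introgression_frequencies.tsv"))
    summary$introgression_candidates <- nrow(cand)
    summary$introgression_validated <-
      sum(status == "validated", na.rm = TRUE)
    summary$introgression_rejected <-
      sum(status == "rejected", na.rm = TRUE)
    res$introgression <- cand
    res$introgression_frequencies <- freqs
    log_stage("introgression", nrow(catalog), nrow(cand))
  }

  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  flat <- purrr::imap_dfr(summary, function(v, k) {
    if (is.list(v)) {
      purrr::imap_dfr(v, function(v2, k2) {
        tibble(key = paste0(k, ".", k2),
               value = paste(unlist(v2), collapse = ","))
      })
    } else {
      tibble(key = k, value = as.character(v))
    }
  })
  readr::write_tsv(flat, p("summary.tsv"))
  res$summary <- summary
  invisible(res)
}
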