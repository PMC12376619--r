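#' Candidate donor-introgressed SVs
#'
#' An SV is a *candidate* introgressed variant when, per policy, it is
#' fixed in the donor species (ALT allele frequency among called donors at
#' least `donor_fixed_min`), absent from controls (control ALT frequency at
#' most `control_max`; the default 0 means every called control genotype is
#' homozygous reference), carried by at least `target_min_carriers` target
#' samples, and sufficiently genotyped (called fraction at least
#' `1 - max_missing_frac` within each role group).  Candidates are then
#' passed to the haplotype-tree validation ([validate_candidate()]).
#'
#' @param gt dosage matrix.
#' @param manifest population manifest; all three roles must be present.
#' @param donor_fixed_min minimum donor ALT frequency (default 1.0).
#' @param control_max maximum control ALT frequency (default 0.0).
#' @param target_min_carriers minimum number of target carriers (default 1).
#' @param max_missing_frac maximum missing fraction per role group
#'   (default 0.2).
#' @return tibble with `sv_id`, `candidate`, `donor_af`, `control_af`,
#'   `target_af`, `target_carriers` and the per-role called fractions.
#' @export
candidate_introgressed <- function(gt, manifest, donor_fixed_min = 1.0,
                                   control_max = 0.0,
                                   target_min_carriers = 1,
                                   max_missing_frac = 0.2) {
  manifest <- population_manifest(manifest)
  roles <- c("target", "control", "donor")
  grp <- lapply(setNames(roles, roles), function(r) {
    ids <- intersect(manifest$sample_id[manifest$role == r], colnames(gt))
    if (length(ids) == 0) abort(paste0("no samples with role '", r, "'"))
    ids
  })
  af <- lapply(grp, function(ids) allele_freq(gt, ids))
  called_frac <- lapply(grp, function(ids) {
    unname(rowMeans(gt_called(gt[, ids, drop = FALSE])))
  })
  target_carriers <-
    unname(rowSums(gt_carrier(gt[, grp$target, drop = FALSE])))

  candidate <-
    !is.na(af$donor$af) & af$donor$af >= donor_fixed_min &
    !is.na(af$control$af) & af$control$af <= control_max &
    target_carriers >= target_min_carriers &
    called_frac$target >= 1 - max_missing_frac &
    called_frac$control >= 1 - max_missing_frac &
    called_frac$donor >= 1 - max_missing_frac

  tibble(sv_id = rownames(gt), candidate = candidate,
         donor_af = af$donor$af, control_af = af$control$af,
         target_af = af$target$af,
         target_carriers = as.integer(target_carriers),
         called_frac_target = called_frac$target,
         called_frac_control = called_frac$control,
         called_frac_donor = called_frac$donor)
}

#' Allele-sharing (IBS) distance matrix
#'
#' `d(x, y) = 1 - mean(IBS)` over sites called in both samples, where the
#' per-site identity-by-state score is the shared-allele fraction
#' (0, 0.5 or 1 for diploid dosages).  Equivalently
#' `d = mean(|g_x - g_y|) / 2`.  This is phase-free, so unphased genotype
#' calls can feed the haplotype tree directly.
#'
#' @param snp_gt dosage matrix, sites x samples.
#' @return symmetric distance matrix (values in `[0, 1]`, zero diagonal)
#'   with a `n_sites` attribute; errors if some pair shares no called site.
#' @export
allele_sharing_distance <- function(snp_gt) {
  samples <- colnames(snp_gt)
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(snp_gt[, i]) & !is.na(snp_gt[, j])
      if (!any(both)) {
        abort(paste0("no jointly called sites for pair ", samples[i],
                     " / ", samples[j]))
      }
      d <- mean(abs(snp_gt[both, i] - snp_gt[both, j])) / 2
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "n_sites") <- nrow(snp_gt)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}), which recovers the
#' generating tree exactly for additive distances.
#'
#' @param D symmetric distance matrix with at least 3 taxa.
#' @return unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) abort("neighbor joining needs at least 3 taxa")
  ape::nj(D)
}

## leaf sets on both sides of every edge of an unrooted phylo tree
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  n_node <- max(tree$edge)
  tipsets <- vector("list", n_node)
  for (i in seq_len(n_tip)) tipsets[[i]] <- tips[i]
  edges <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[child]])
  }
  purrr::map(seq_len(nrow(edges)), function(k) {
    side <- tipsets[[edges[k, 2]]]
    list(side, setdiff(tips, side))
  }) |> purrr::flatten()
}

#' Haplotype-tree validation of an introgression candidate
#'
#' A candidate is *validated* when, in the flanking-SNP tree, the carrier
#' haplotypes cluster with the donors: some edge of the unrooted tree must
#' bipartition the leaves into one side holding every donor and every
#' carrier but no non-carrier cattle sample, versus the rest.  Carriers of
#' a genuinely introgressed SV are heterozygous (one donor-derived
#' haplotype), which places them on the stem between the cattle mass and
#' the donor clade — inside the donor-side bipartition, though not inside
#' the donors' own minimal clade.
#'
#' @param tree unrooted `phylo` tree over the window's samples.
#' @param carriers target samples carrying the SV.
#' @param donors donor samples.
#' @param others all remaining cattle samples (non-carrier targets and
#'   controls).
#' @return `"validated"` or `"rejected"`.
#' @export
validate_candidate <- function(tree, carriers, donors, others) {
  tips <- tree$tip.label
  missing_leaf <- setdiff(c(carriers, donors, others), tips)
  if (length(missing_leaf) > 0) {
    abort(paste0("samples absent from tree: ",
                 paste(missing_leaf, collapse = ", ")))
  }
  splits <- tree_splits(tree)
  ok <- purrr::some(splits, function(s) {
    all(donors %in% s) && all(carriers %in% s) && !any(others %in% s)
  })
  if (ok) "validated" else "rejected"
}

#' Per-population frequency table for introgression calls
#'
#' Allele and carrier frequencies of each called SV in every population of
#' the manifest, the companion table to candidate/validated status.
#'
#' @param calls tibble with at least `sv_id` (e.g. candidates from
#'   [candidate_introgressed()]).
#' @param gt dosage matrix.
#' @param manifest population manifest.
#' @return long tibble with `sv_id`, `population`, `role`, `af`,
#'   `carrier_rate`, `n_called`.
#' @export
introgression_frequencies <- function(calls, gt, manifest) {
  manifest <- population_manifest(manifest)
  ids <- unique(calls$sv_id)
  sub <- gt[rownames(gt) %in% ids, , drop = FALSE]
  pops <- manifest |>
    dplyr::distinct(.data$population, .data$role)
  purrr::pmap_dfr(pops, function(population, role) {
    ids_pop <- manifest$sample_id[manifest$population == population]
    af_tbl <- allele_freq(sub, intersect(ids_pop, colnames(sub)))
    cf_tbl <- carrier_freq(sub, intersect(ids_pop, colnames(sub)))
    tibble(sv_id = af_tbl$sv_id, population = population, role = role,
           af = af_tbl$af, carrier_rate = cf_tbl$carrier_rate,
           n_called = af_tbl$n_called)
  })
}
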