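#' Simulation configuration for synthetic SV cohorts
#'
#' Builds the parameter set for [simulate_cohort()].  Defaults describe a
#' compact cohort with the statistical structure of a high-altitude
#' adaptation study: several differentiated populations in three roles
#' (target / control / donor), Balding-Nichols allele-frequency
#' differentiation, planted SV hotspots, planted frequency-shifted
#' (differentiated) SVs, planted donor-introgressed SVs, and
#' transposable-element labels enriched inside hotspots.  The SV type mix
#' defaults to the proportions observed in large long-read cattle cohorts
#' (DEL 0.403, INS 0.539, DUP 0.029, INV 0.012, BND 0.017).
#'
#' @param chromosomes named vector of chromosome lengths in bp.
#' @param n_sv_background number of background (uniformly placed) SVs;
#'   differentiated and introgressed SVs are drawn from these.
#' @param n_hotspots number of planted hotspot clusters.
#' @param sv_per_hotspot SVs per planted cluster.
#' @param hotspot_sd positional sd of cluster members around the center, bp.
#' @param svtype_props named proportions over DEL/INS/DUP/INV/BND
#'   (must sum to 1).
#' @param populations tibble with `name`, `role`, `n` defining the cohort.
#' @param fst Balding-Nichols differentiation parameter F in (0, 1).
#' @param n_differentiated number of SVs given a target-specific
#'   allele-frequency shift.
#' @param diff_shift the shift: target-side ancestral frequency becomes
#'   `min(1, p + diff_shift)`.
#' @param n_introgressed number of donor-introgressed SVs (donor-fixed,
#'   control-absent).
#' @param introgression_carrier_freq probability that a target sample
#'   carries an introgressed SV (carriers are heterozygous: one donor
#'   haplotype).
#' @param te_prob_hotspot,te_prob_background probability that a DEL, DUP or
#'   INS inside / outside a planted hotspot is TE-derived.
#' @param missing_rate per-genotype missingness probability.
#' @param error_rate per-genotype probability of being replaced by one of
#'   the other two states (uniformly); applied to all samples.
#' @param flank_bp one-sided flanking-window size for SNP haplotypes, bp.
#' @param snp_density SNPs per bp in flanking windows.
#' @param donor_divergence per-site probability of a fixed cattle/donor
#'   difference in flanking windows.
#' @param snp_noise per-site, per-haplotype mutation probability in
#'   flanking windows.
#' @param n_genes,n_repeats,n_conserved sizes of the simulated annotation
#'   tracks.
#' @param max_redraws redraw cap for SVs monomorphic across cattle.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chromosomes = c(chr1 = 50e6, chr2 = 50e6,
                                       chr3 = 50e6),
                       n_sv_background = 1500,
                       n_hotspots = 5, sv_per_hotspot = 150,
                       hotspot_sd = 1e5,
                       svtype_props = c(DEL = 0.403, INS = 0.539,
                                        DUP = 0.029, INV = 0.012,
                                        BND = 0.017),
                       populations = tibble(
                         name = c("target1", "target2", "target3",
                                  "control1", "control2", "donor"),
                         role = c("target", "target", "target",
                                  "control", "control", "donor"),
                         n = c(8L, 8L, 8L, 8L, 8L, 6L)
                       ),
                       fst = 0.1,
                       n_differentiated = 50, diff_shift = 0.6,
                       n_introgressed = 50,
                       introgression_carrier_freq = 0.3,
                       te_prob_hotspot = 0.6, te_prob_background = 0.2,
                       missing_rate = 0.02, error_rate = 0,
                       flank_bp = 5e4, snp_density = 1e-3,
                       donor_divergence = 0.3, snp_noise = 0.02,
                       n_genes = 300, n_repeats = 1000,
                       n_conserved = 2000,
                       max_redraws = 20) {
  if (abs(sum(svtype_props) - 1) > 1e-9) {
    abort("svtype_props must sum to 1")
  }
  if (fst <= 0 || fst >= 1) abort("fst must be in (0, 1)")
  if (donor_divergence <= 0 || donor_divergence >= 1) {
    abort("donor_divergence must be in (0, 1)")
  }
  populations <- as_tibble(populations)
  if (n_differentiated > 0 &&
      !any(populations$role == "target")) {
    abort("n_differentiated > 0 requires a target population")
  }
  if (n_introgressed > 0 &&
      !all(c("target", "control", "donor") %in% populations$role)) {
    abort("n_introgressed > 0 requires target, control and donor populations")
  }
  if (n_differentiated + n_introgressed > n_sv_background) {
    abort("n_differentiated + n_introgressed exceeds n_sv_background")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @param path YAML file whose top-level keys are `sim_config()` arguments.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$chromosomes)) {
    cfg$chromosomes <- unlist(cfg$chromosomes)
  }
  if (!is.null(cfg$svtype_props)) cfg$svtype_props <- unlist(cfg$svtype_props)
  if (!is.null(cfg$populations)) {
    cfg$populations <- dplyr::bind_rows(cfg$populations)
    ## YAML 1.1 reads a bare `n` key as boolean FALSE
    names(cfg$populations)[names(cfg$populations) %in% c("FALSE", "no")] <- "n"
  }
  do.call(sim_config, cfg)
}

## Balding-Nichols population frequency draw around ancestral p
bn_freq <- function(p, f) {
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a structural-variant cohort
#'
#' Generates a full synthetic cohort: an SV catalog whose positions mix a
#' uniform background with Gaussian hotspot clusters, diploid genotypes
#' under the Balding-Nichols model (ancestral frequency
#' `p ~ U(0.05, 0.95)`, per-population frequency
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, dosage `Binomial(2, p_pop)`),
#' target-shifted differentiated SVs, donor-fixed/control-absent
#' introgressed SVs, TE labels enriched inside hotspots, simulated gene /
#' repeat / conserved-element tracks consistent with those labels, and a
#' truth table for every planted feature.  Genotype error and missingness
#' are applied last.  Output is a deterministic function of
#' `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return list with `catalog`, `gt`, `manifest`, `truth`, `genes`,
#'   `exons`, `repeats`, `conserved`, `ins_labels`, `hotspot_centers` and
#'   the `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  chroms <- config$chromosomes

  ## --- manifest ------------------------------------------------------------
  manifest <- population_manifest(purrr::pmap_dfr(
    config$populations,
    function(name, role, n) {
      tibble(sample_id = sprintf("%s_%02d", name, seq_len(n)),
             population = name, role = role)
    }))

  ## --- positions -----------------------------------------------------------
  n_bg <- config$n_sv_background
  bg_chrom <- sample(names(chroms), n_bg, replace = TRUE,
                     prob = chroms / sum(chroms))
  bg_pos <- floor(runif(n_bg, 1, chroms[bg_chrom]))

  hot_centers <- NULL
  hot_chrom <- hot_pos <- hot_cluster <- NULL
  if (config$n_hotspots > 0) {
    ## centers kept off chromosome ends and apart from each other so the
    ## planted clusters are distinct detection problems
    centers <- tibble(chrom = character(), center = numeric())
    tries <- 0
    while (nrow(centers) < config$n_hotspots && tries < 1000) {
      tries <- tries + 1
      chr <- sample(names(chroms), 1)
      len <- chroms[[chr]]
      ctr <- runif(1, 0.05 * len, 0.95 * len)
      same <- centers$chrom == chr
      if (!any(same) || all(abs(centers$center[same] - ctr) > 5e6)) {
        centers <- dplyr::bind_rows(centers,
                                    tibble(chrom = chr, center = ctr))
      }
    }
    hot_centers <- dplyr::mutate(centers,
                                 cluster = seq_len(nrow(centers)))
    k <- config$sv_per_hotspot
    hot_cluster <- rep(hot_centers$cluster, each = k)
    hot_chrom <- rep(hot_centers$chrom, each = k)
    hot_pos <- floor(pmin(pmax(
      rnorm(length(hot_chrom), rep(hot_centers$center, each = k),
            config$hotspot_sd), 1), chroms[hot_chrom]))
  }

  chrom <- c(bg_chrom, hot_chrom)
  pos <- c(bg_pos, hot_pos)
  cluster <- c(rep(NA_integer_, n_bg), hot_cluster)
  n_sv <- length(pos)

  ## --- catalog -------------------------------------------------------------
  svtype <- sample(names(config$svtype_props), n_sv, replace = TRUE,
                   prob = config$svtype_props)
  svlen <- pmax(50L, as.integer(round(stats::rlnorm(n_sv, log(300), 1))))
  start <- as.integer(pos)
  end <- as.integer(pmin(pos + svlen - 1, chroms[chrom]))
  point <- svtype %in% c("INS", "BND")
  end[point] <- start[point]
  mate_chrom <- rep(NA_character_, n_sv)
  mate_pos <- rep(NA_integer_, n_sv)
  is_bnd <- svtype == "BND"
  if (any(is_bnd)) {
    mate_chrom[is_bnd] <- sample(names(chroms), sum(is_bnd), replace = TRUE)
    mate_pos[is_bnd] <- floor(runif(sum(is_bnd), 1, chroms[mate_chrom[is_bnd]]))
    svlen[is_bnd] <- 0L
  }
  ord <- order(chrom, start)
  sv_id <- sprintf("sv%05d", seq_len(n_sv))
  catalog <- sv_catalog(tibble(
    sv_id = sv_id, chrom = chrom[ord], start = start[ord], end = end[ord],
    svtype = svtype[ord], svlen = svlen[ord],
    mate_chrom = mate_chrom[ord], mate_pos = mate_pos[ord]
  ))
  cluster <- cluster[ord]
  was_background <- c(rep(TRUE, n_bg), rep(FALSE, n_sv - n_bg))[ord]

  ## --- planted flags -------------------------------------------------------
  bg_idx <- which(was_background)
  planted <- sample(bg_idx, config$n_differentiated + config$n_introgressed)
  diff_idx <- head(planted, config$n_differentiated)
  intro_idx <- tail(planted, config$n_introgressed)
  differentiated <- seq_len(n_sv) %in% diff_idx
  introgressed <- seq_len(n_sv) %in% intro_idx

  in_hotspot <- !is.na(cluster)
  te <- rep(FALSE, n_sv)
  taggable <- catalog$svtype %in% c("DEL", "DUP", "INS")
  te[taggable] <- runif(sum(taggable)) <
    ifelse(in_hotspot[taggable], config$te_prob_hotspot,
           config$te_prob_background)

  ## --- genotypes -----------------------------------------------------------
  pops <- config$populations
  cattle <- manifest$sample_id[manifest$role != "donor"]
  p_anc <- runif(n_sv, 0.05, 0.95)
  p_target <- pmin(1, p_anc + ifelse(differentiated, config$diff_shift, 0))

  draw_gt <- function(rows) {
    gt <- matrix(NA_integer_, length(rows), nrow(manifest),
                 dimnames = list(catalog$sv_id[rows], manifest$sample_id))
    for (k in seq_len(nrow(pops))) {
      ids <- manifest$sample_id[manifest$population == pops$name[k]]
      p0 <- if (pops$role[k] == "target") p_target[rows] else p_anc[rows]
      p_pop <- bn_freq(p0, config$fst)
      p_pop[p0 >= 1] <- 1
      gt[, ids] <- matrix(
        rbinom(length(rows) * length(ids), 2, rep(p_pop, length(ids))),
        nrow = length(rows))
    }
    gt
  }
  gt <- draw_gt(seq_len(n_sv))

  ## redraw SVs monomorphic across cattle so the catalog mimics a cohort
  ## call set (a variant exists because someone carries it)
  for (i in seq_len(config$max_redraws)) {
    sub <- gt[, cattle, drop = FALSE]
    mono <- which(!introgressed &
                    (rowSums(sub) == 0 | rowSums(sub) == 2 * ncol(sub)))
    if (length(mono) == 0) break
    p_anc[mono] <- runif(length(mono), 0.05, 0.95)
    p_target[mono] <- pmin(1, p_anc[mono] +
                             ifelse(differentiated[mono],
                                    config$diff_shift, 0))
    gt[mono, ] <- draw_gt(mono)
  }

  ## introgressed SVs: donor-fixed, control-absent, target carriers HET
  if (length(intro_idx) > 0) {
    donors <- manifest$sample_id[manifest$role == "donor"]
    controls <- manifest$sample_id[manifest$role == "control"]
    targets <- manifest$sample_id[manifest$role == "target"]
    gt[intro_idx, donors] <- 2L
    gt[intro_idx, controls] <- 0L
    carrier <- matrix(
      runif(length(intro_idx) * length(targets)) <
        config$introgression_carrier_freq,
      nrow = length(intro_idx))
    gt[intro_idx, targets] <- ifelse(carrier, 1L, 0L)
  }

  ## --- noise ---------------------------------------------------------------
  if (config$error_rate > 0) {
    flip <- runif(length(gt)) < config$error_rate
    shift <- sample(1:2, sum(flip), replace = TRUE)
    gt[flip] <- (gt[flip] + shift) %% 3L
  }
  if (config$missing_rate > 0) {
    gt[runif(length(gt)) < config$missing_rate] <- NA_integer_
  }
  storage.mode(gt) <- "integer"

  ## --- annotation tracks ---------------------------------------------------
  tracks <- simulate_tracks(catalog, te, config)

  truth <- tibble(sv_id = catalog$sv_id,
                  hotspot_cluster = cluster,
                  differentiated = differentiated,
                  introgressed = introgressed,
                  te = te,
                  p_ancestral = p_anc)

  list(catalog = catalog, gt = genotype_matrix(gt, catalog),
       manifest = manifest, truth = truth,
       genes = tracks$genes, exons = tracks$exons,
       repeats = tracks$repeats, conserved = tracks$conserved,
       ins_labels = tracks$ins_labels,
       hotspot_centers = hot_centers, config = config)
}

## repeat classes roughly in the proportions seen in cattle SV studies
te_classes <- function(n) {
  sample(c("LINE", "SINE", "LTR", "DNA"), n, replace = TRUE,
         prob = c(0.81, 0.107, 0.072, 0.011))
}

## gene/exon, repeat and conserved-element tracks consistent with the
## simulated TE truth labels (TE DEL/DUPs get a fully overlapping repeat;
## TE INSs get a sidecar label; extra repeats are scattered at random)
simulate_tracks <- function(catalog, te, config) {
  chroms <- config$chromosomes

  gene_chrom <- sample(names(chroms), config$n_genes, replace = TRUE,
                       prob = chroms / sum(chroms))
  gene_len <- floor(runif(config$n_genes, 5e3, 1e5))
  gene_start <- floor(runif(config$n_genes, 1, chroms[gene_chrom] - gene_len))
  genes <- interval_set(tibble(chrom = gene_chrom, start = gene_start,
                               end = gene_start + gene_len - 1,
                               label = sprintf("gene%04d",
                                               seq_len(config$n_genes))))
  exons <- purrr::pmap_dfr(genes[c("chrom", "start", "end", "label")],
                           function(chrom, start, end, label) {
    k <- sample(3:8, 1)
    es <- sort(floor(runif(k, start, end - 200)))
    tibble(chrom = chrom, start = es,
           end = pmin(es + floor(runif(k, 100, 1500)), end),
           label = label)
  })
  exons <- interval_set(exons)

  te_span <- which(te & catalog$svtype %in% c("DEL", "DUP"))
  rep_chrom <- sample(names(chroms), config$n_repeats, replace = TRUE,
                      prob = chroms / sum(chroms))
  rep_len <- floor(runif(config$n_repeats, 100, 5000))
  rep_start <- floor(runif(config$n_repeats, 1, chroms[rep_chrom] - rep_len))
  repeats <- interval_set(dplyr::bind_rows(
    tibble(chrom = catalog$chrom[te_span], start = catalog$start[te_span],
           end = catalog$end[te_span], label = te_classes(length(te_span))),
    tibble(chrom = rep_chrom, start = rep_start,
           end = rep_start + rep_len - 1, label = te_classes(config$n_repeats))
  ))

  te_ins <- which(te & catalog$svtype == "INS")
  ins_labels <- tibble(sv_id = catalog$sv_id[te_ins],
                       te_class = te_classes(length(te_ins)))

  cons_chrom <- sample(names(chroms), config$n_conserved, replace = TRUE,
                       prob = chroms / sum(chroms))
  cons_start <- floor(runif(config$n_conserved, 1, chroms[cons_chrom] - 200))
  conserved <- interval_set(tibble(chrom = cons_chrom, start = cons_start,
                                   end = cons_start + 199))

  list(genes = genes, exons = exons, repeats = repeats,
       conserved = conserved, ins_labels = ins_labels)
}

#' Simulate flanking-SNP genotypes for one SV window
#'
#' Two haplotype pools — cattle and donor — share a backbone but differ at
#' each site with probability `divergence`; every haplotype draw further
#' mutates each site with probability `noise`.  Donor samples get two donor
#' haplotypes; carriers of an introgressed SV get one donor and one cattle
#' haplotype; everyone else gets two cattle haplotypes.  For a
#' non-introgressed SV (`introgressed = FALSE`) carriers are
#' indistinguishable from other cattle, the null case for tree validation.
#'
#' @param manifest population manifest for the cohort.
#' @param carriers target samples carrying the SV.
#' @param introgressed is the SV truly donor-introgressed?
#' @param n_sites number of SNP sites in the window.
#' @param divergence per-site probability of a fixed cattle/donor
#'   difference, in (0, 1).
#' @param noise per-site, per-haplotype mutation probability.
#' @param seed optional integer seed.
#' @return site x sample dosage matrix.
#' @export
simulate_flanking_snps <- function(manifest, carriers = character(),
                                   introgressed = TRUE, n_sites = 100,
                                   divergence = 0.3, noise = 0.02,
                                   seed = NULL) {
  if (divergence <= 0 || divergence >= 1) {
    abort("divergence must be in (0, 1)")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  manifest <- population_manifest(manifest)
  donor_consensus <- as.integer(runif(n_sites) < divergence)
  cattle_consensus <- integer(n_sites)
  hap <- function(consensus) {
    mut <- runif(n_sites) < noise
    as.integer(xor(consensus == 1L, mut))
  }
  gt <- vapply(manifest$sample_id, function(s) {
    role <- manifest$role[manifest$sample_id == s]
    if (role == "donor") {
      hap(donor_consensus) + hap(donor_consensus)
    } else if (s %in% carriers && introgressed) {
      hap(donor_consensus) + hap(cattle_consensus)
    } else {
      hap(cattle_consensus) + hap(cattle_consensus)
    }
  }, integer(n_sites))
  rownames(gt) <- sprintf("site%04d", seq_len(n_sites))
  gt
}

#' Write a simulated cohort as re-readable fixture files
#'
#' Emits the multi-sample SV VCF, manifest TSV, truth TSV, annotation BEDs
#' (repeats, genes, exons, conserved), the insertion TE-label sidecar, and
#' flanking-window SNP VCFs for up to `n_snp_windows` introgressed SVs.
#' Everything round-trips through the package readers.
#'
#' @param cohort output of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param n_snp_windows number of introgressed SVs to emit SNP VCFs for.
#' @return tibble of written files (`what`, `path`), invisibly.
#' @export
write_fixtures <- function(cohort, out_dir, n_snp_windows = 3) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  p <- function(f) file.path(out_dir, f)
  write_sv_vcf(cohort$catalog, cohort$gt, p("cohort.sv.vcf"),
               contigs = cohort$config$chromosomes)
  write_manifest(cohort$manifest, p("manifest.tsv"))
  readr::write_tsv(cohort$truth, p("truth.tsv"))
  write_bed(cohort$repeats, p("repeats.bed"))
  write_bed(cohort$genes, p("genes.bed"))
  write_bed(cohort$exons, p("exons.bed"))
  write_bed(cohort$conserved, p("conserved.bed"))
  readr::write_tsv(cohort$ins_labels, p("ins_te_labels.tsv"))

  files <- tibble(what = c("sv_vcf", "manifest", "truth", "repeats",
                           "genes", "exons", "conserved", "ins_labels"),
                  path = c(p("cohort.sv.vcf"), p("manifest.tsv"),
                           p("truth.tsv"), p("repeats.bed"), p("genes.bed"),
                           p("exons.bed"), p("conserved.bed"),
                           p("ins_te_labels.tsv")))

  intro_ids <- cohort$truth$sv_id[cohort$truth$introgressed]
  for (id in head(intro_ids, n_snp_windows)) {
    carriers <- colnames(cohort$gt)[gt_carrier(cohort$gt[id, ]) &
      colnames(cohort$gt) %in%
        cohort$manifest$sample_id[cohort$manifest$role == "target"]]
    snp <- simulate_flanking_snps(
      cohort$manifest, carriers = carriers, introgressed = TRUE,
      n_sites = max(10L, as.integer(2 * cohort$config$flank_bp *
                                      cohort$config$snp_density)),
      divergence = cohort$config$donor_divergence,
      noise = cohort$config$snp_noise)
    row <- cohort$catalog[cohort$catalog$sv_id == id, ]
    sites <- tibble(chrom = row$chrom,
                    pos = pmax(1, row$start - cohort$config$flank_bp) +
                      seq_len(nrow(snp)) - 1,
                    id = rownames(snp))
    f <- p(paste0("flank_", id, ".snp.vcf"))
    write_snp_vcf(sites, snp, f)
    files <- dplyr::bind_rows(files, tibble(what = "snp_vcf", path = f))
  }
  invisible(files)
}
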