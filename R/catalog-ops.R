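#' Merge policy for breakpoint-distance SV clustering
#'
#' Two SV calls are considered the same event when they are on the same
#' chromosome, of the same type (unless `require_same_type = FALSE`) and
#' both breakpoints (start and end) lie within `max_breakpoint_dist` of
#' each other; clusters are formed by single linkage over these pairwise
#' links.  Break-ends additionally require the same mate chromosome.
#' Consensus filtering keeps clusters supported by at least
#' `min_caller_support` distinct callers.
#'
#' @param max_breakpoint_dist maximum breakpoint distance in bp
#'   (default 500).
#' @param require_same_type cluster only same-type calls (default `TRUE`).
#' @param min_caller_support minimum number of supporting callers for
#'   [consensus_filter()] (default 2).
#' @return a `merge_policy` list.
#' @export
merge_policy <- function(max_breakpoint_dist = 500, require_same_type = TRUE,
                         min_caller_support = 2) {
  if (max_breakpoint_dist < 0) abort("max_breakpoint_dist must be >= 0")
  if (min_caller_support < 1) abort("min_caller_support must be >= 1")
  structure(list(max_breakpoint_dist = as.numeric(max_breakpoint_dist),
                 require_same_type = isTRUE(require_same_type),
                 min_caller_support = as.integer(min_caller_support)),
            class = "merge_policy")
}

## single-linkage clustering of calls; returns integer cluster ids.
## Links: same group key, |start_i - start_j| <= d AND |end_i - end_j| <= d.
cluster_sv_calls <- function(calls, max_dist, require_same_type = TRUE) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  key <- calls$chrom
  if (require_same_type) key <- paste(key, calls$svtype)
  is_bnd <- calls$svtype == "BND"
  key[is_bnd] <- paste(key[is_bnd], calls$mate_chrom[is_bnd])

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }

  for (idx in split(seq_len(n), key)) {
    if (length(idx) < 2) next
    o <- idx[order(calls$start[idx], calls$end[idx])]
    s <- calls$start[o]; e <- calls$end[o]
    m <- length(o)
    for (i in seq_len(m - 1)) {
      j <- i + 1
      while (j <= m && s[j] - s[i] <= max_dist) {
        if (abs(e[j] - e[i]) <= max_dist) union_(o[i], o[j])
        j <- j + 1
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Consensus filter across SV callers for one sample
#'
#' Retains calls supported by at least `min_caller_support` callers: calls
#' from different callers are clustered by breakpoint distance (see
#' [merge_policy()]) and each sufficiently supported cluster is represented
#' by its call from the first caller in `priority`.
#'
#' @param callsets named list of per-caller catalog tibbles for one sample.
#' @param policy a [merge_policy()].
#' @param priority caller order used to choose the representative; defaults
#'   to `names(callsets)`.
#' @return catalog tibble of retained representatives with an `n_callers`
#'   support column.
#' @export
consensus_filter <- function(callsets, policy = merge_policy(),
                             priority = names(callsets)) {
  if (is.null(names(callsets)) || any(names(callsets) == "")) {
    abort("callsets must be a named list (one element per caller)")
  }
  if (length(callsets) < policy$min_caller_support) {
    abort(paste0("need at least ", policy$min_caller_support,
                 " callers for min_caller_support = ",
                 policy$min_caller_support))
  }
  calls <- dplyr::bind_rows(purrr::map(callsets, sv_catalog),
                            .id = "caller")
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, n_callers = integer(0)))
  }
  calls$.cluster <- cluster_sv_calls(calls, policy$max_breakpoint_dist,
                                     policy$require_same_type)
  calls$.prio <- match(calls$caller, priority)
  calls |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::mutate(n_callers = dplyr::n_distinct(.data$caller)) |>
    dplyr::filter(.data$n_callers >= policy$min_caller_support) |>
    dplyr::arrange(.data$.prio, .data$start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select(-".cluster", -".prio")
}

#' Merge per-sample call sets into a nonredundant cohort catalog
#'
#' Same-type, same-chromosome calls whose breakpoints both lie within
#' `max_breakpoint_dist` of a cluster member are merged by single linkage.
#' Each cluster is represented by the call from the earliest sample in the
#' input order, and a presence matrix records which samples contributed a
#' call to each cluster.  Cohort SV ids are `"<sample>:<id>"` of the
#' representative, so they are stable under the documented sample order.
#'
#' @param callsets named list of per-sample catalog tibbles, in merge order.
#' @param policy a [merge_policy()].
#' @return list with `catalog` (representatives, plus `n_samples` support)
#'   and `presence` (integer 0/1 matrix, SV x sample).
#' @export
merge_samples <- function(callsets, policy = merge_policy()) {
  samples <- names(callsets)
  if (length(callsets) > 0 &&
      (is.null(samples) || any(samples == ""))) {
    abort("callsets must be a named list (one element per sample)")
  }
  samples <- samples %||% character()
  calls <- dplyr::bind_rows(purrr::map(callsets, sv_catalog),
                            .id = "sample")
  if (nrow(calls) == 0) {
    catalog <- sv_catalog(tibble(
      sv_id = character(), chrom = character(), start = integer(),
      end = integer(), svtype = character(), svlen = integer()
    ))
    presence <- matrix(integer(), 0, length(samples),
                       dimnames = list(character(), samples))
    return(list(catalog = catalog, presence = presence))
  }
  cl <- cluster_sv_calls(calls, policy$max_breakpoint_dist,
                         policy$require_same_type)
  calls$.cluster <- cl
  calls$.sample_rank <- match(calls$sample, samples)
  reps <- calls |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::mutate(n_samples = dplyr::n_distinct(.data$sample)) |>
    dplyr::arrange(.data$.sample_rank, .data$start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start, .data$.cluster)
  reps$merged_id <- paste0(reps$sample, ":", reps$sv_id)

  presence <- matrix(0L, nrow(reps), length(samples),
                     dimnames = list(reps$merged_id, samples))
  idx <- cbind(match(calls$.cluster, reps$.cluster),
               calls$.sample_rank)
  presence[idx] <- 1L

  catalog <- reps |>
    dplyr::mutate(sv_id = .data$merged_id) |>
    dplyr::select("sv_id", "chrom", "start", "end", "svtype", "svlen",
                  "mate_chrom", "mate_pos", "n_samples")
  list(catalog = sv_catalog(catalog), presence = presence)
}

#' Cumulative nonredundant catalog growth curve
#'
#' Number of distinct cohort SVs discovered as samples are added one by one
#' in the given order.
#'
#' @param presence 0/1 presence matrix (SV x sample) from [merge_samples()],
#'   or a dosage matrix (any nonzero dosage counts as presence).
#' @param order character vector of sample ids; must only name columns of
#'   `presence` and defaults to column order.
#' @return tibble with `sample`, `n_new` and `cumulative` counts;
#'   `cumulative` is monotone nondecreasing and ends at the number of SVs
#'   seen in any ordered sample.
#' @export
cumulative_growth <- function(presence, order = colnames(presence)) {
  unknown <- setdiff(order, colnames(presence))
  if (length(unknown) > 0) {
    abort(paste0("unknown sample(s) in order: ",
                 paste(unknown, collapse = ", ")))
  }
  carrier <- gt_carrier(presence[, order, drop = FALSE])
  first_seen <- apply(carrier, 1, function(x) {
    w <- which(x)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  n_new <- tabulate(first_seen, nbins = length(order))
  tibble(sample = order, n_new = n_new, cumulative = cumsum(n_new))
}

#' Classify SVs by cohort sharing
#'
#' Partition of all SVs with at least one carrier into `shared` (present in
#' all N samples), `major` (present in at least ceiling(N/2) samples, but
#' not all), `minor` (more than one, fewer than the major threshold) and
#' `singleton` (exactly one).  Presence means carrying at least one ALT
#' allele.  For N = 84 the major threshold is 42.
#'
#' @param gt dosage or presence matrix (SV x sample).
#' @param n_samples cohort size N (default `ncol(gt)`).
#' @return tibble with `sv_id`, `n_carriers` and `sharing_class`
#'   (`NA` for SVs with no carrier).
#' @export
classify_sharing <- function(gt, n_samples = ncol(gt)) {
  if (n_samples == 0) abort("cohort size N must be > 0")
  n_carriers <- rowSums(gt_carrier(gt))
  n_major <- ceiling(n_samples / 2)
  cls <- dplyr::case_when(
    n_carriers == 0 ~ NA_character_,
    n_carriers == n_samples ~ "shared",
    n_carriers >= n_major ~ "major",
    n_carriers > 1 ~ "minor",
    TRUE ~ "singleton"
  )
  tibble(sv_id = rownames(gt), n_carriers = as.integer(n_carriers),
         sharing_class = factor(cls, levels = c("shared", "major",
                                                "minor", "singleton")))
}

#' SVs absent from every control sample
#'
#' Selects SVs whose every *called* control genotype is homozygous
#' reference; missing genotypes are ignored.  These are the variants
#' private to the non-control part of the cohort that downstream
#' differentiation and introgression stages focus on.
#'
#' @param gt dosage matrix.
#' @param manifest population manifest.
#' @param control_pops populations to treat as controls; default is every
#'   population whose samples have role `control`.
#' @param catalog optional catalog for per-type counts.
#' @return list with `sv_ids` (character vector) and `type_counts`
#'   (tibble of per-`svtype` counts, `NULL` without a catalog).
#' @export
control_absent <- function(gt, manifest, control_pops = NULL,
                           catalog = NULL) {
  manifest <- population_manifest(manifest)
  if (is.null(control_pops)) {
    control_pops <- unique(manifest$population[manifest$role == "control"])
  }
  ctrl <- manifest$sample_id[manifest$population %in% control_pops]
  ctrl <- intersect(ctrl, colnames(gt))
  if (length(ctrl) == 0) abort("no control samples found")
  sub <- gt[, ctrl, drop = FALSE]
  absent <- rowSums(gt_carrier(sub)) == 0
  sv_ids <- rownames(gt)[absent]
  type_counts <- NULL
  if (!is.null(catalog)) {
    type_counts <- catalog |>
      dplyr::filter(.data$sv_id %in% sv_ids) |>
      dplyr::count(.data$svtype, name = "n")
  }
  list(sv_ids = sv_ids, type_counts = type_counts)
}

#' Annotate SVs by genic region
#'
#' Labels each SV `exonic`, `intronic`, `upstream_downstream` or
#' `intergenic` with precedence in that order.  Span types (DEL, DUP, INV)
#' are classified by any overlap of `[start, end]`; INS and BND by their
#' breakpoint alone.  `upstream_downstream` means within `updown_window` bp
#' of a gene span (5 kb by default, the common annotator convention).
#'
#' @param catalog SV catalog tibble.
#' @param genes interval tibble of gene spans.
#' @param exons interval tibble of exons (optional; without it no SV is
#'   called exonic).
#' @param updown_window flanking distance in bp defining
#'   upstream/downstream (default 5000).
#' @return tibble with `sv_id` and `region`.
#' @export
annotate_regions <- function(catalog, genes, exons = NULL,
                             updown_window = 5000) {
  catalog <- sv_catalog(catalog)
  point <- catalog$svtype %in% c("INS", "BND")
  region <- rep("intergenic", nrow(catalog))
  if (nrow(catalog) > 0 && !is.null(genes) && nrow(genes) > 0) {
    q <- as_granges(catalog, point = point)
    g <- as_granges(genes)
    flank <- suppressWarnings(
      GenomicRanges::resize(g, GenomicRanges::width(g) + 2 * updown_window,
                            fix = "center"))
    GenomicRanges::start(flank) <- pmax(GenomicRanges::start(flank), 1L)
    near <- suppressWarnings(
      IRanges::overlapsAny(q, flank))
    genic <- suppressWarnings(IRanges::overlapsAny(q, g))
    region[near] <- "upstream_downstream"
    region[genic] <- "intronic"
    if (!is.null(exons) && nrow(exons) > 0) {
      exonic <- suppressWarnings(IRanges::overlapsAny(q, as_granges(exons)))
      region[exonic] <- "exonic"
    }
  }
  tibble(sv_id = catalog$sv_id,
         region = factor(region, levels = c("exonic", "intronic",
                                            "upstream_downstream",
                                            "intergenic")))
}

#' Tag transposable-element-derived SVs
#'
#' Deletions and duplications are tagged when some repeat interval has a
#' reciprocal overlap of at least `min_reciprocal` (default 0.8) with the
#' SV span — i.e. the overlap covers that fraction of *both* the SV and the
#' repeat.  Insertions carry their own sequence, so their repeat status
#' comes from a sidecar table of per-insertion labels (e.g. produced by a
#' repeat annotator on the inserted sequences); inversions and break-ends
#' are never tagged.
#'
#' @param catalog SV catalog tibble.
#' @param repeats interval tibble of repeat annotations; the `label` column
#'   (repeat class) is carried through.
#' @param ins_labels optional tibble `sv_id`, `te_class` for insertions.
#' @param min_reciprocal minimum reciprocal-overlap fraction in `(0, 1]`.
#' @return tibble with `sv_id`, `te` (logical) and `te_class`.
#' @export
tag_te <- function(catalog, repeats, ins_labels = NULL,
                   min_reciprocal = 0.8) {
  if (min_reciprocal <= 0 || min_reciprocal > 1) {
    abort("min_reciprocal must be in (0, 1]")
  }
  catalog <- sv_catalog(catalog)
  te <- rep(FALSE, nrow(catalog))
  te_class <- rep(NA_character_, nrow(catalog))

  span <- which(catalog$svtype %in% c("DEL", "DUP"))
  if (length(span) > 0 && !is.null(repeats) && nrow(repeats) > 0) {
    q <- as_granges(catalog[span, ])
    r <- as_granges(repeats)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, r))
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      ri <- S4Vectors::subjectHits(hits)
      ov <- pmin(catalog$end[span][qi], repeats$end[ri]) -
        pmax(catalog$start[span][qi], repeats$start[ri]) + 1
      w_sv <- catalog$end[span][qi] - catalog$start[span][qi] + 1
      w_rep <- repeats$end[ri] - repeats$start[ri] + 1
      recip <- pmin(ov / w_sv, ov / w_rep)
      ok <- recip >= min_reciprocal
      if (any(ok)) {
        best <- tibble(i = span[qi[ok]], recip = recip[ok],
                       class = repeats$label[ri[ok]]) |>
          dplyr::group_by(.data$i) |>
          dplyr::arrange(dplyr::desc(.data$recip), .by_group = TRUE) |>
          dplyr::slice(1) |>
          dplyr::ungroup()
        te[best$i] <- TRUE
        te_class[best$i] <- best$class
      }
    }
  }
  if (!is.null(ins_labels) && nrow(ins_labels) > 0) {
    m <- match(catalog$sv_id, ins_labels$sv_id)
    is_ins <- catalog$svtype == "INS" & !is.na(m)
    lab <- ins_labels$te_class[m[is_ins]]
    te[is_ins] <- !is.na(lab)
    te_class[is_ins] <- lab
  }
  tibble(sv_id = catalog$sv_id, te = te, te_class = te_class)
}
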