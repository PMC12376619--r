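mk_call <- function(id, chrom, start, end, svtype = "DEL", svlen = NULL) {
  tibble::tibble(sv_id = id, chrom = chrom, start = start, end = end,
                 svtype = svtype,
                 svlen = if (is.null(svlen)) {
                   ifelse(svtype %in% c("INS", "BND"), 300L,
                          end - start + 1L)
                 } else svlen)
}

test_that("consensus filter keeps two-caller clusters and drops the rest", {
  a <- mk_call("a1", "chr1", 1000L, 2000L)
  b <- mk_call("b1", "chr1", 1100L, 2100L)
  kept <- consensus_filter(list(cuteSV = a, svim = b))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$sv_id, "a1")     # representative from first caller
  expect_equal(kept$n_callers, 2L)

  ## supported by one caller only -> dropped
  lone <- consensus_filter(list(cuteSV = a,
                                svim = mk_call("b2", "chr2", 1000L, 2000L)))
  expect_equal(nrow(lone), 0)

  ## same position, different type -> both dropped
  ins_b <- mk_call("b3", "chr1", 1000L, 1000L, svtype = "INS")
  expect_equal(nrow(consensus_filter(list(cuteSV = a, svim = ins_b))), 0)

  expect_error(consensus_filter(list(only = a)), "caller")
})

test_that("consensus policy matches pairwise enumeration at the 500-bp boundary", {
  for (d in c(0L, 250L, 500L, 501L, 800L)) {
    a <- mk_call("a1", "chr1", 10000L, 12000L)
    b <- mk_call("b1", "chr1", 10000L + d, 12000L + d)
    kept <- consensus_filter(list(ca = a, cb = b))
    expect_equal(nrow(kept), as.integer(d <= 500),
                 info = paste("breakpoint distance", d))
  }
})

test_that("sample merging is single-linkage and type-segregated", {
  s1 <- mk_call("x", "chr1", 1000L, 5000L)
  s2 <- mk_call("y", "chr1", 1000L, 5000L)
  m <- merge_samples(list(sampleA = s1, sampleB = s2))
  expect_equal(nrow(m$catalog), 1)
  expect_equal(unname(m$presence[1, ]), c(1L, 1L))
  expect_equal(m$catalog$sv_id, "sampleA:x")

  ## chained starts 1000/1400/1800 with <=500-bp links form one cluster
  chain <- merge_samples(list(
    s1 = mk_call("c1", "chr1", 1000L, 3000L),
    s2 = mk_call("c2", "chr1", 1400L, 3400L),
    s3 = mk_call("c3", "chr1", 1800L, 3800L)))
  expect_equal(nrow(chain$catalog), 1)
  expect_equal(chain$catalog$n_samples, 3L)

  ## same locus, different type -> distinct records
  two <- merge_samples(list(
    s1 = mk_call("d", "chr1", 1000L, 3000L, svtype = "DEL"),
    s2 = mk_call("i", "chr1", 1000L, 3000L, svtype = "INV")))
  expect_equal(nrow(two$catalog), 2)

  expect_equal(nrow(merge_samples(list())$catalog), 0)
})

test_that("merging agrees with a brute-force transitive-closure oracle", {
  withr::local_seed(31)
  for (rep in 1:5) {
    calls <- tibble::tibble(
      sv_id = paste0("v", 1:40),
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      start = sample.int(20000, 40),
      svtype = sample(c("DEL", "INV"), 40, replace = TRUE))
    calls$end <- calls$start + 5000L
    calls$svlen <- 5001L
    sets <- split(calls, rep(1:4, 10))
    names(sets) <- paste0("s", 1:4)
    m <- merge_samples(sets, merge_policy(max_breakpoint_dist = 500))
    oracle_cl <- brute_cluster(calls, 500)
    expect_equal(nrow(m$catalog), length(unique(oracle_cl)))
    ## cluster membership is input-order invariant
    m2 <- merge_samples(rev(sets), merge_policy(max_breakpoint_dist = 500))
    expect_equal(nrow(m2$catalog), nrow(m$catalog))
  }
})

test_that("growth curve equals a brute-force set-union recount", {
  p1 <- gt_mat(list(a = c(1L, 1L, 0L), b = c(1L, 1L, 0L), c = c(0L, 1L, 1L)))
  g <- cumulative_growth(p1)
  expect_equal(g$cumulative, c(2L, 3L, 3L))

  ## identical call sets: flat after the first sample
  flat <- gt_mat(list(a = c(1L, 1L), b = c(1L, 1L)))
  expect_equal(cumulative_growth(flat)$cumulative, c(2L, 2L))

  ## disjoint call sets: strictly increasing by each sample's count
  disj <- gt_mat(list(a = c(1L, 0L), b = c(0L, 1L)))
  expect_equal(cumulative_growth(disj)$n_new, c(1L, 1L))

  withr::local_seed(5)
  pres <- matrix(rbinom(20 * 15, 1, 0.2), 20,
                 dimnames = list(paste0("v", 1:20), paste0("s", 1:15)))
  storage.mode(pres) <- "integer"
  ord <- sample(colnames(pres))
  g2 <- cumulative_growth(pres, ord)
  oracle <- vapply(seq_along(ord), function(k) {
    sum(rowSums(pres[, ord[seq_len(k)], drop = FALSE]) > 0)
  }, numeric(1))
  expect_equal(g2$cumulative, oracle)
  expect_true(all(diff(g2$cumulative) >= 0))
  expect_error(cumulative_growth(pres, c(ord, "ghost")), "ghost")
})

test_that("sharing classes use the ceil(N/2) major threshold and partition", {
  N <- 84
  mk <- function(k) c(rep(1L, k), rep(0L, N - k))
  gt <- gt_mat(list(all = mk(84), maj = mk(42), min41 = mk(41),
                    min2 = mk(2), single = mk(1), none = mk(0)))
  cls <- classify_sharing(gt)
  expect_equal(as.character(cls$sharing_class),
               c("shared", "major", "minor", "minor", "singleton", NA))
  ## the four classes partition SVs with >= 1 carrier
  expect_equal(sum(table(cls$sharing_class)), sum(cls$n_carriers > 0))
  expect_error(classify_sharing(gt, n_samples = 0), "N")
})

test_that("control-absent selection matches an exhaustive scan", {
  man <- population_manifest(tibble::tibble(
    sample_id = paste0("s", 1:10),
    population = rep(c("popT", "popC"), each = 5),
    role = rep(c("target", "control"), each = 5)))

  gt <- gt_mat(list(
    keep = c(0L, 1L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    drop = c(0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),
    keep_miss = c(1L, 0L, 0L, 0L, 0L, NA, 0L, 0L, 0L, 0L)),
    samples = man$sample_id)
  ca <- control_absent(gt, man)
  expect_setequal(ca$sv_ids, c("keep", "keep_miss"))

  withr::local_seed(13)
  big <- matrix(sample(c(0:2, NA), 200 * 10, replace = TRUE,
                       prob = c(0.6, 0.2, 0.1, 0.1)), 200,
                dimnames = list(paste0("v", 1:200), man$sample_id))
  storage.mode(big) <- "integer"
  ca2 <- control_absent(big, man)
  ctrl <- man$sample_id[man$role == "control"]
  oracle <- rownames(big)[apply(big[, ctrl], 1, function(g) {
    all(g[!is.na(g)] == 0)
  })]
  expect_setequal(ca2$sv_ids, oracle)
  ## by construction no selected SV has a control carrier
  carriers <- rownames(big)[rowSums(big[, ctrl] > 0, na.rm = TRUE) > 0]
  expect_length(intersect(ca2$sv_ids, carriers), 0)

  expect_error(control_absent(gt, man, control_pops = "nope"), "control")
})

test_that("region annotation follows exonic > intronic > flank > intergenic", {
  genes <- interval_set(tibble::tibble(chrom = "chr1", start = 10000L,
                                       end = 20000L, label = "g1"))
  exons <- interval_set(tibble::tibble(chrom = "chr1",
                                       start = c(10000L, 15000L),
                                       end = c(10500L, 15500L), label = "g1"))
  cat <- sv_catalog(tibble::tibble(
    sv_id = c("exonic_del", "intron_ins", "span_del", "flank_del",
              "far_del", "ins_in_exon_flank"),
    chrom = "chr1",
    start = c(10400L, 12000L, 14900L, 21000L, 40000L, 9000L),
    end = c(10600L, 12000L, 15200L, 21200L, 40200L, 9000L),
    svtype = c("DEL", "INS", "DEL", "DEL", "DEL", "INS"),
    svlen = c(201L, 300L, 301L, 201L, 201L, 300L)))
  reg <- annotate_regions(cat, genes, exons)
  expect_equal(as.character(reg$region),
               c("exonic", "intronic", "exonic", "upstream_downstream",
                 "intergenic", "upstream_downstream"))
  ## empty gene set: everything intergenic
  reg0 <- annotate_regions(cat, genes[0, ], exons[0, ])
  expect_true(all(reg0$region == "intergenic"))
})

test_that("TE tagging applies the 80% reciprocal-overlap rule", {
  cat <- sv_catalog(tibble::tibble(
    sv_id = c("del_in", "del_half", "del_out", "ins_te", "inv_never"),
    chrom = "chr1",
    start = c(1000L, 1000L, 1000L, 9000L, 1000L),
    end = c(2000L, 2000L, 2000L, 9000L, 2000L),
    svtype = c("DEL", "DEL", "DEL", "INS", "INV"),
    svlen = c(1001L, 1001L, 1001L, 400L, 1001L)))
  repeats <- interval_set(tibble::tibble(
    chrom = "chr1", start = c(1050L, 1500L), end = c(1950L, 4000L),
    label = c("LINE", "LTR")))
  tags <- tag_te(cat, repeats,
                 ins_labels = tibble::tibble(sv_id = "ins_te",
                                             te_class = "SINE"))
  ## overlap 901 bp: 901/1001 = 0.90 on the SV side, 901/901 = 1 on the
  ## repeat side -> tagged; the [1500,4000] repeat fails on its own side
  expect_equal(tags$te, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(tags$te_class[1], "LINE")
  expect_equal(tags$te_class[4], "SINE")
  only_far <- tag_te(cat[3, ], repeats[2, ])
  expect_false(only_far$te)
  expect_error(tag_te(cat, repeats, min_reciprocal = 1.2), "min_reciprocal")
})

test_that("TE tagging agrees with brute-force reciprocal overlap on random fixtures", {
  withr::local_seed(41)
  n <- 300
  start <- sample.int(1e6, n)
  cat <- sv_catalog(tibble::tibble(
    sv_id = paste0("v", 1:n), chrom = "chr1", start = start,
    end = start + sample(50:4000, n, replace = TRUE),
    svtype = "DEL", svlen = 100L))
  cat$svlen <- cat$end - cat$start + 1L
  rstart <- sample.int(1e6, 200)
  repeats <- interval_set(tibble::tibble(
    chrom = "chr1", start = rstart,
    end = rstart + sample(50:4000, 200, replace = TRUE), label = "LINE"))
  tags <- tag_te(cat, repeats)
  oracle <- vapply(seq_len(n), function(i) {
    brute_reciprocal_tagged(cat$start[i], cat$end[i], repeats, 0.8)
  }, logical(1))
  expect_equal(tags$te, oracle)
})
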