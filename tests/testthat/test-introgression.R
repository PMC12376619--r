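intro_manifest <- function(n_target = 6, n_control = 6, n_donor = 12) {
  population_manifest(tibble::tibble(
    sample_id = c(paste0("t", seq_len(n_target)),
                  paste0("c", seq_len(n_control)),
                  paste0("y", seq_len(n_donor))),
    population = c(rep("highland", n_target), rep("lowland", n_control),
                   rep("yak", n_donor)),
    role = c(rep("target", n_target), rep("control", n_control),
             rep("donor", n_donor))))
}

test_that("candidate classification follows the donor-fixed / control-absent policy", {
  man <- intro_manifest()
  mk <- function(target, control, donor) {
    gt_mat(list(v = c(target, control, donor)), samples = man$sample_id)
  }
  ## donors fixed, controls clean, one target het -> candidate
  g1 <- mk(c(1L, rep(0L, 5)), rep(0L, 6), rep(2L, 12))
  expect_true(candidate_introgressed(g1, man)$candidate)
  ## a single control het kills it
  g2 <- mk(c(1L, rep(0L, 5)), c(1L, rep(0L, 5)), rep(2L, 12))
  expect_false(candidate_introgressed(g2, man)$candidate)
  ## 11/12 donors called, all ALT; one missing (8.3% <= 20%) -> candidate
  g3 <- mk(c(1L, rep(0L, 5)), rep(0L, 6), c(rep(2L, 11), NA))
  expect_true(candidate_introgressed(g3, man)$candidate)
  ## donor not fixed among called
  g4 <- mk(c(1L, rep(0L, 5)), rep(0L, 6), c(rep(2L, 11), 1L))
  expect_false(candidate_introgressed(g4, man)$candidate)
  ## no target carrier
  g5 <- mk(rep(0L, 6), rep(0L, 6), rep(2L, 12))
  expect_false(candidate_introgressed(g5, man)$candidate)
  ## too much donor missingness: 4/12 missing > 20%
  g6 <- mk(c(1L, rep(0L, 5)), rep(0L, 6), c(rep(2L, 8), rep(NA, 4)))
  expect_false(candidate_introgressed(g6, man)$candidate)

  man_no_donor <- man[man$role != "donor", ]
  expect_error(candidate_introgressed(
    g1[, man_no_donor$sample_id, drop = FALSE], man_no_donor), "donor")
})

test_that("the candidate set shrinks as the policy tightens", {
  co <- simulate_cohort(sim_config(n_sv_background = 400, n_hotspots = 0,
                                   n_differentiated = 0,
                                   n_introgressed = 40,
                                   error_rate = 0.03), seed = 33)
  loose <- candidate_introgressed(co$gt, co$manifest,
                                  donor_fixed_min = 0.8, control_max = 0.05)
  strict <- candidate_introgressed(co$gt, co$manifest)
  expect_true(all(strict$sv_id[strict$candidate] %in%
                    loose$sv_id[loose$candidate]))
  expect_lte(sum(strict$candidate), sum(loose$candidate))
})

test_that("allele-sharing distance counts shared alleles per site", {
  g_id <- gt_mat(list(s1 = c(0L, 1L, 2L, 1L), s2 = c(0L, 1L, 2L, 1L)))
  expect_equal(unname(allele_sharing_distance(t(g_id))["s1", "s2"]), 0)

  g_opp <- cbind(a = rep(0L, 10), b = rep(2L, 10))
  expect_equal(unname(allele_sharing_distance(g_opp)["a", "b"]), 1)

  g_half <- cbind(a = rep(0L, 10), b = rep(1L, 10))
  expect_equal(unname(allele_sharing_distance(g_half)["a", "b"]), 0.5)

  D <- allele_sharing_distance(cbind(a = c(0L, 2L), b = c(2L, 0L),
                                     c = c(1L, 1L)))
  expect_true(isSymmetric(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))

  g_na <- cbind(a = c(0L, NA), b = c(NA, 0L))
  expect_error(allele_sharing_distance(g_na), "a / b")
})

test_that("neighbor joining recovers additive trees exactly", {
  ## 3 taxa: branch lengths from the three-point formulas
  D3 <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, dimnames = list(letters[1:3],
                                                  letters[1:3]))
  tr3 <- nj_tree(D3)
  ## x = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])],
                 tr3$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.1, 0.2, 0.4),
               tolerance = 1e-12)

  withr::local_seed(55)
  for (i in 1:20) {
    tr <- random_additive_tree(sample(4:8, 1))
    D <- cophenetic(tr)
    rec <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
    ## branch lengths are recovered to machine tolerance on additive input
    expect_equal(sum(rec$edge.length), sum(ape::unroot(tr)$edge.length),
                 tolerance = 1e-8)
  }
  expect_error(nj_tree(D3[1:2, 1:2]), "3 taxa")
})

test_that("tree validation accepts donor-clustered carriers and rejects strays", {
  tr <- ape::read.tree(
    text = "(((carA:1,carB:1):1,(don1:1,don2:1):1):2,(oth1:1,oth2:1,oth3:1):1);")
  expect_equal(validate_candidate(tr, c("carA", "carB"), c("don1", "don2"),
                                  c("oth1", "oth2", "oth3")), "validated")
  ## a carrier nested among the others, away from donors
  expect_equal(validate_candidate(tr, c("carA", "oth1"), c("don1", "don2"),
                                  c("oth2", "oth3")), "rejected")
  expect_error(validate_candidate(tr, "ghost", c("don1", "don2"), "oth1"),
               "ghost")
})

test_that("heterozygous carriers on the donor stem are validated", {
  ## carriers carry one donor haplotype, so they sit between the cattle
  ## mass and the donor clade rather than inside the donors' minimal clade
  man <- intro_manifest(6, 6, 4)
  snp <- simulate_flanking_snps(man, carriers = c("t1", "t2"),
                                introgressed = TRUE, n_sites = 200,
                                seed = 81)
  tr <- nj_tree(allele_sharing_distance(snp))
  st <- validate_candidate(tr, c("t1", "t2"),
                           man$sample_id[man$role == "donor"],
                           setdiff(man$sample_id[man$role != "donor"],
                                   c("t1", "t2")))
  expect_equal(st, "validated")
  ## and a non-introgressed window is rejected
  snp0 <- simulate_flanking_snps(man, carriers = c("t1", "t2"),
                                 introgressed = FALSE, n_sites = 200,
                                 seed = 82)
  tr0 <- nj_tree(allele_sharing_distance(snp0))
  expect_equal(validate_candidate(tr0, c("t1", "t2"),
                                  man$sample_id[man$role == "donor"],
                                  setdiff(man$sample_id[man$role != "donor"],
                                          c("t1", "t2"))), "rejected")
})

test_that("frequency tables report per-population allele and carrier rates", {
  man <- intro_manifest(4, 4, 4)
  gt <- gt_mat(list(sv1 = c(1L, 1L, 0L, 0L, rep(0L, 4), rep(2L, 4)),
                    sv2 = c(rep(0L, 4), rep(0L, 4), rep(2L, 4))),
               samples = man$sample_id)
  fr <- introgression_frequencies(tibble::tibble(sv_id = c("sv1", "sv2")),
                                  gt, man)
  hi <- fr[fr$population == "highland" & fr$sv_id == "sv1", ]
  expect_equal(hi$af, 0.25)
  expect_equal(hi$carrier_rate, 0.5)
  yk <- fr[fr$population == "yak" & fr$sv_id == "sv2", ]
  expect_equal(yk$af, 1)
  expect_equal(nrow(fr), 2 * 3)
})
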