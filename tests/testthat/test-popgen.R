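test_that("allele and carrier frequencies count alleles as contracted", {
  gt <- gt_mat(list(
    all_het = rep(1L, 10),
    half = c(rep(2L, 5), rep(0L, 5)),
    mix = c(rep(2L, 3), 1L, rep(0L, 6)),
    with_na = c(2L, 2L, NA, NA, 0L, 0L, 0L, 0L, 0L, 0L),
    none = rep(NA_integer_, 10)))
  af <- allele_freq(gt)
  expect_equal(af$af[1:3], c(0.5, 0.5, 7 / 20))
  expect_equal(af$af[4], 4 / 16)   # missing excluded from both sides
  expect_true(is.na(af$af[5]))
  expect_equal(af$n_called[5], 0L)

  ## headline carrier rates are integer percentages
  c13 <- carrier_freq(gt_mat(list(v = c(rep(1L, 13), rep(0L, 23)))),
                      percent = TRUE)
  expect_equal(c13$carrier_rate, 36)
  c36 <- carrier_freq(gt_mat(list(v = c(rep(1L, 36), rep(0L, 76)))),
                      percent = TRUE)
  expect_equal(c36$carrier_rate, 32)
  expect_equal(carrier_freq(gt_mat(list(v = rep(0L, 8))),
                            percent = TRUE)$carrier_rate, 0)
})

test_that("Weir-Cockerham theta hits its closed-form anchor points", {
  ## fixed difference gives theta = 1 for any sample sizes >= 2
  for (n1 in c(2, 5, 10)) {
    for (n2 in c(2, 7)) {
      gt <- gt_mat(list(v = c(rep(2L, n1), rep(0L, n2))))
      th <- wc_fst(gt, list(A = paste0("s", 1:n1),
                            B = paste0("s", n1 + 1:n2)))
      expect_equal(th$theta, 1)
    }
  }
  ## identical genotype arrays: estimator noise at or below zero
  gt_same <- gt_mat(list(v = rep(c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L),
                                 2)))
  th0 <- wc_fst(gt_same, list(A = paste0("s", 1:10), B = paste0("s", 11:20)))
  expect_lte(th0$theta, 0)
  ## monomorphic site: undefined, components zero
  gt_mono <- gt_mat(list(v = rep(0L, 10)))
  thm <- wc_fst(gt_mono, list(A = paste0("s", 1:5), B = paste0("s", 6:10)))
  expect_true(is.na(thm$theta))
  expect_equal(thm$a + thm$b + thm$c, 0)
})

test_that("theta equals the independent ANOVA-route oracle", {
  ## the worked example: pop A = 5 HOM_REF + 5 HET, pop B = 10 HET
  gA <- c(rep(0L, 5), rep(1L, 5))
  gB <- rep(1L, 10)
  th <- wc_fst(gt_mat(list(v = c(gA, gB))),
               list(A = paste0("s", 1:10), B = paste0("s", 11:20)))
  oracle <- wc_anova_oracle(list(gA, gB))
  expect_equal(th$a, oracle$a, tolerance = 1e-12)
  expect_equal(th$b, oracle$b, tolerance = 1e-12)
  expect_equal(th$c, oracle$c, tolerance = 1e-12)
  expect_equal(th$theta, oracle$theta, tolerance = 1e-12)

  ## random configurations, including missing data and 3 populations
  withr::local_seed(17)
  for (i in 1:200) {
    r <- sample(2:3, 1)
    sizes <- sample(2:15, r, replace = TRUE)
    gts <- lapply(sizes, function(n) {
      g <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      g[runif(n) < 0.1] <- NA
      as.integer(g)
    })
    gt <- gt_mat(list(v = unlist(gts)))
    pops <- split(colnames(gt), rep(seq_len(r), sizes))
    th <- wc_fst(gt, pops)
    oracle <- wc_anova_oracle(gts)
    if (is.na(oracle$a)) {
      expect_true(is.na(th$theta))
    } else {
      expect_equal(th$a, oracle$a, tolerance = 1e-10)
      expect_equal(th$b, oracle$b, tolerance = 1e-10)
      expect_equal(th$c, oracle$c, tolerance = 1e-10)
      if (!is.na(oracle$theta)) {
        expect_equal(th$theta, oracle$theta, tolerance = 1e-10)
      }
    }
  }
})

test_that("windowed FST is a ratio of sums, not a mean of ratios", {
  comp <- tibble::tibble(chrom = "chr1", pos = c(10000, 20000),
                         a = c(1, 0), b = c(0.5, 1.5), c = c(0.5, 1.5))
  w <- windowed_fst(comp, window = 50000, step = 50000)
  expect_equal(nrow(w), 1)
  expect_equal(w$fst, 1 / 5)          # != mean(1/2, 0)
  expect_equal(w$n_sites, 2L)

  ## a lone site reproduces its own theta; empty windows are absent
  comp2 <- tibble::tibble(chrom = "chr1", pos = c(10000, 500000),
                          a = c(1, 2), b = c(1, 1), c = c(0, 1))
  w2 <- windowed_fst(comp2, window = 50000, step = 25000)
  expect_equal(w2$fst[1], 0.5)
  expect_true(all(w2$n_sites > 0))
  expect_error(windowed_fst(comp, window = -1), "window")
})

test_that("di reduces to the FST z-score for one pair and matches a spreadsheet recomputation", {
  theta1 <- tibble::tibble(sv_id = paste0("v", 1:6), pair = "t~c",
                           theta = c(0.1, 0.2, 0.05, 0.4, 0.15, 0.1))
  d1 <- di_statistic(theta1)
  expect_equal(d1$di$di,
               (theta1$theta - mean(theta1$theta)) / sd(theta1$theta),
               tolerance = 1e-12)

  ## 3 pairs x 5 SVs, recomputed cell by cell
  withr::local_seed(8)
  grid <- expand.grid(sv_id = paste0("v", 1:5),
                      pair = c("p1", "p2", "p3"),
                      stringsAsFactors = FALSE)
  grid$theta <- round(runif(15, 0, 0.5), 3)
  d3 <- di_statistic(tibble::as_tibble(grid))
  manual <- vapply(paste0("v", 1:5), function(v) {
    sum(vapply(c("p1", "p2", "p3"), function(p) {
      th <- grid$theta[grid$pair == p]
      x <- grid$theta[grid$pair == p & grid$sv_id == v]
      (x - mean(th)) / sd(th)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(d3$di$di[match(names(manual), d3$di$sv_id)],
               unname(manual), tolerance = 1e-12)

  ## degenerate pair: all SVs identical theta
  bad <- tibble::tibble(sv_id = paste0("v", 1:4), pair = "flat",
                        theta = rep(0.2, 4))
  expect_error(di_statistic(bad), "flat")
})

test_that("di is invariant under a constant shift of one pair's theta", {
  withr::local_seed(23)
  grid <- tidyr::expand_grid(sv_id = paste0("v", 1:50),
                             pair = c("p1", "p2"))
  grid$theta <- runif(100, 0, 0.4)
  base <- di_statistic(grid)$di
  shifted <- grid
  shifted$theta[shifted$pair == "p2"] <-
    shifted$theta[shifted$pair == "p2"] + 0.25
  expect_equal(di_statistic(shifted)$di$di, base$di, tolerance = 1e-12)
})

test_that("di outlier calling is a one-sided upper Z test at the normal quantile", {
  ## critical Z for alpha = 0.001 is the 99.9% normal quantile, 3.0902
  expect_equal(qnorm(0.999), 3.090232, tolerance = 1e-6)
  withr::local_seed(4)
  vals <- rnorm(2000)
  vals[1] <- 6
  out <- di_outliers(tibble::tibble(sv_id = paste0("v", seq_along(vals)),
                                    di = vals))
  expect_true(out$outlier[1])
  z1 <- (vals[1] - mean(vals)) / sd(vals)
  expect_equal(out$z[1], z1, tolerance = 1e-12)
  expect_equal(out$p[1], pnorm(z1, lower.tail = FALSE), tolerance = 1e-12)
  ## values just under the critical Z are not flagged
  expect_false(any(out$outlier[out$z < qnorm(0.999)]))
  expect_error(di_outliers(tibble::tibble(sv_id = c("a", "b"),
                                          di = c(1, 1))),
               "dispersion")
})

test_that("fst_pairs contrasts the pooled target group against each control population", {
  co <- simulate_cohort(sim_config(n_sv_background = 200, n_hotspots = 0,
                                   n_differentiated = 0,
                                   n_introgressed = 0), seed = 12)
  th <- fst_pairs(co$gt, co$manifest)
  ctrl <- unique(co$manifest$population[co$manifest$role == "control"])
  expect_setequal(unique(th$control), ctrl)
  expect_equal(unique(th$focal), "pooled_target")
  expect_equal(nrow(th), nrow(co$catalog) * length(ctrl))
  ## per-population focal mode scopes pairs by target population
  th2 <- fst_pairs(co$gt, co$manifest, focal = "per_population")
  tpops <- unique(co$manifest$population[co$manifest$role == "target"])
  expect_setequal(unique(th2$focal), tpops)
})
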