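# DERIVED values asserted here were computed with the helper oracles
# (enumeration / root-finding) before being frozen.

test_that("mutational frequency evaluates the screen formula", {
  expect_equal(mutational_frequency(27, 1000, 27, 1000), 1.0)
  expect_equal(mutational_frequency(10, 1e5, 2700, 1e5),
               log(1e-4) / log(0.027), tolerance = 1e-12)
  expect_error(mutational_frequency(0, 1e5, 2700, 1e5), "positive")
  expect_error(mutational_frequency(10, 1e5, 0, 1e5), "positive")
  expect_error(mutational_frequency(20, 10, 5, 10), "exceed")

  # strictly monotone in X_S when X_0/N_0 < 1: -ln(X_S/N_S) shrinks as
  # colonies grow, so the ratio strictly decreases
  f <- vapply(c(5, 10, 20, 40), mutational_frequency,
              numeric(1), n_s = 1e5, x_0 = 2700, n_0 = 1e5)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0))
})

test_that("clonogenic efficiency is the colony fraction", {
  expect_equal(clonogenic_efficiency(27, 1000), 0.027)
  expect_equal(clonogenic_efficiency(0, 50), 0)
  expect_error(clonogenic_efficiency(51, 50), "colonies")
  expect_error(clonogenic_efficiency(5, 0), "positive")
})

test_that("clopper_pearson matches the root-finding oracle and nests", {
  expect_equal(clopper_pearson(0, 10)[1], 0)
  expect_equal(clopper_pearson(10, 10)[2], 1)
  expect_equal(clopper_pearson(27, 92), oracle_clopper_pearson(27, 92),
               tolerance = 1e-9)
  withr::with_seed(4, {
    for (i in 1:25) {
      n <- sample(5:200, 1); x <- sample(0:n, 1)
      expect_equal(clopper_pearson(x, n), oracle_clopper_pearson(x, n),
                   tolerance = 1e-9)
      ci90 <- clopper_pearson(x, n, 0.90)
      ci99 <- clopper_pearson(x, n, 0.99)
      expect_true(ci99[1] <= ci90[1] && ci90[2] <= ci99[2])
    }
  })
  expect_error(clopper_pearson(5, 4), "0 <= x <= n")
})

test_that("exact rate-ratio test: worked cases and oracle agreement", {
  r <- exact_poisson_rate_ratio_test(5, 1, 5, 1)
  expect_equal(r$rate_ratio, 1.0)
  expect_equal(r$p_value, 1.0)
  expect_true(r$ci_low <= 1 && 1 <= r$ci_high)

  r0 <- exact_poisson_rate_ratio_test(0, 1, 10, 1)
  expect_equal(r0$p_value, 2 / 2^10)          # full enumeration of binom(10, 1/2)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$rate_ratio, 0)

  rInf <- exact_poisson_rate_ratio_test(10, 1, 0, 1)
  expect_equal(rInf$rate_ratio, Inf)
  expect_equal(rInf$ci_high, Inf)
  expect_gt(rInf$ci_low, 0)

  # Table-1-style totals: only the arithmetic estimate is asserted
  rt <- exact_poisson_rate_ratio_test(27, 1, 65, 1)
  expect_equal(rt$rate_ratio, 27 / 65)

  expect_error(exact_poisson_rate_ratio_test(0, 1, 0, 1), "at least one")
  expect_error(exact_poisson_rate_ratio_test(1, 0, 1, 1), "positive")

  # enumeration oracle on a grid, including unequal exposures
  withr::with_seed(2, {
    for (i in 1:60) {
      c1 <- sample(0:25, 1); c2 <- sample(0:25, 1)
      if (c1 + c2 == 0) c1 <- 1
      t1 <- runif(1, 0.5, 3); t2 <- runif(1, 0.5, 3)
      got <- exact_poisson_rate_ratio_test(c1, t1, c2, t2)
      expect_equal(got$p_value, oracle_rate_ratio_p(c1, c2, t1, t2),
                   tolerance = 1e-12)
      # swap invariance: p unchanged, ratio inverts
      sw <- exact_poisson_rate_ratio_test(c2, t2, c1, t1)
      expect_equal(sw$p_value, got$p_value, tolerance = 1e-12)
      if (c1 > 0 && c2 > 0)
        expect_equal(sw$rate_ratio, 1 / got$rate_ratio, tolerance = 1e-12)
    }
  })
})

test_that("rate-ratio test agrees with the base-R exact Poisson test", {
  cases <- list(c(3, 1, 9, 1), c(27, 1, 65, 1), c(12, 2.5, 4, 1.3), c(0, 1, 7, 1))
  for (cs in cases) {
    got <- exact_poisson_rate_ratio_test(cs[1], cs[2], cs[3], cs[4])
    ref <- stats::poisson.test(c(cs[1], cs[3]), c(cs[2], cs[4]))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("binomial enrichment test follows the minlike convention", {
  expect_equal(binomial_enrichment_test(0, 10, 0.5), 2 / 2^10)
  # exact mode of the null: p = 1 by enumeration
  expect_equal(binomial_enrichment_test(5, 10, 0.5), 1.0)
  expect_equal(binomial_enrichment_test(3, 20, 0.3),
               stats::binom.test(3, 20, 0.3)$p.value, tolerance = 1e-12)
  expect_error(binomial_enrichment_test(3, 10, 0), "p0")
  expect_error(binomial_enrichment_test(3, 10, 1.2), "p0")
  expect_error(binomial_enrichment_test(11, 10, 0.5), "k")
})

test_that("window profile tiles the locus and conserves reads", {
  loc <- locus_reference("locus", strrep("ACGT", 25))  # 100 bp
  v <- small_variants(pos = c(5L, 39L, 40L, 85L), ref = "A", alt = "G",
                      supporting_reads = c(2L, 3L, 1L, 4L),
                      total_reads = 100L)
  prof <- window_profile(v, loc)
  expect_equal(prof$window_start, c(0L, 40L, 80L))
  expect_equal(prof$window_len, c(40L, 40L, 20L))
  expect_equal(prof$event_reads, c(5L, 1L, 4L))
  expect_equal(sum(prof$event_reads), sum(v$supporting_reads))
  expect_equal(prof$frequency, prof$event_reads / 100)
  expect_true(all(prof$region == "intronic"))

  loc2 <- loc
  loc2$exons <- genomic_intervals("locus", 79L, 82L, "+", "exon_1")
  prof2 <- window_profile(v, loc2)
  expect_equal(prof2$region, c("intronic", "exonic", "exonic"))

  expect_error(window_profile(
    small_variants(150L, "A", "G", 1L, 10L), loc), "outside")
  empty <- small_variants(integer(), character(), character(), integer(), integer())
  expect_error(window_profile(empty, loc), "depth")
  expect_equal(sum(window_profile(empty, loc, depth = 10)$event_reads), 0L)
})

test_that("region comparison flags a selected exonic excess", {
  cfg <- sim_config(seed = 19)
  loc <- simulate_locus(cfg)
  uns <- simulate_small_variants(loc, cfg, "unselected")
  sel <- simulate_small_variants(loc, cfg, "selected")
  pu <- window_profile(uns, loc, depth = cfg$read_depth)
  ps <- window_profile(sel, loc, depth = cfg$read_depth)
  res <- compare_region_frequencies(pu, ps)
  expect_gt(res$exonic$rate_ratio, 1)
  expect_lt(res$exonic$p_value, 0.05)
  expect_gt(res$intronic$p_value, 0.001)   # intronic rates differ only by noise
  expect_true(res$intronic$rate_ratio < 2 && res$intronic$rate_ratio > 0.5)

  ident <- compare_region_frequencies(pu, pu)
  expect_equal(ident$exonic$rate_ratio, 1)
  expect_equal(ident$exonic$p_value, 1)
  expect_equal(ident$intronic$p_value, 1)

  # a region with zero totals errors out
  loc_noex <- loc; loc_noex$exons <- loc$exons[0, ]
  p0 <- window_profile(uns, loc_noex, depth = cfg$read_depth)
  expect_error(compare_region_frequencies(p0, p0), "region exonic|zero total")
})
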