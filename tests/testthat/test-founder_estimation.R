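test_that("filter variants treat private and shared singletons differently", {
  fx <- filter_fixture()
  fa <- apply_filter(fx$genotypes, fx$clusters, "A", "all")
  fb <- apply_filter(fx$genotypes, fx$clusters, "A", "drop_low_freq")
  fc_ <- apply_filter(fx$genotypes, fx$clusters, "A", "drop_nonprivate_low_freq")

  expect_setequal(fb$removed$individual, c("A01", "A02"))
  expect_setequal(fc_$removed$individual, "A02")
  expect_true(all(fc_$removed$individual %in% fb$removed$individual))
  # allele totals ordered b <= c <= a
  expect_lte(nrow(fb$target), nrow(fc_$target))
  expect_lte(nrow(fc_$target), nrow(fa$target))
  # the removed singletons drop out of the capture target
  expect_false(99 %in% fb$target$allele)
  expect_true(99 %in% fc_$target$allele)
  expect_false(98 %in% fc_$target$allele)
})

test_that("a shared singleton is removed by both filter variants", {
  fx <- filter_fixture()
  # make allele 99 shared by adding a carrier in cluster B
  tbl <- tibble::as_tibble(fx$genotypes)
  tbl$allele1[tbl$individual == "B01" & tbl$locus == "L1"] <- 99L
  g <- as_geno_tbl(tbl)
  fb <- apply_filter(g, fx$clusters, "A", "drop_low_freq")
  fc_ <- apply_filter(g, fx$clusters, "A", "drop_nonprivate_low_freq")
  expect_setequal(fb$removed$individual, c("A01", "A02"))
  expect_setequal(fc_$removed$individual, c("A01", "A02"))
})

test_that("filtering everything out is an error advising variant 'all'", {
  # every individual carries a singleton at its own private locus slot
  n <- 60
  g <- toy_geno(sprintf("i%02d", 1:n), "L1",
                seq_len(n), seq_len(n))
  expect_error(
    apply_filter(g, one_cluster(g), "X", "drop_low_freq"),
    "removed every individual")
})

test_that("simulated founder genotypes obey per-mode draw contracts", {
  g <- random_geno(n_ind = 6, n_loc = 3, n_all = 4, seed = 21)
  fc <- whole_cluster(g)
  # mode 1 at n = N with no missing data draws the entire pool
  full <- withr::with_seed(1, simulate_founder_genotypes(fc, 6, "resample"))
  expect_identical(full$copies, fc$target$count)
  # copies always sum to 2n per locus (with replacement modes)
  for (mode in c("empirical", "equal")) {
    sm <- withr::with_seed(2, simulate_founder_genotypes(fc, 3, mode))
    sums <- tapply(sm$copies, sm$locus, sum)
    expect_true(all(sums == 6))
  }
})

test_that("pool shortfalls under missing data draw the whole pool", {
  tbl <- tibble::as_tibble(random_geno(5, 2, 3, seed = 4))
  tbl$allele1[tbl$individual %in% c("i001", "i002") & tbl$locus == "L1"] <- NA
  tbl$allele2[tbl$individual %in% c("i001", "i002") & tbl$locus == "L1"] <- NA
  g <- as_geno_tbl(tbl)
  fc <- whole_cluster(g)
  expect_message(sm <- simulate_founder_genotypes(fc, 5, "resample"),
                 "entire pool")
  l1 <- sm[sm$locus == "L1", ]
  expect_identical(l1$copies, fc$target$count[fc$target$locus == "L1"])
  # capture at that locus is then certain in the MC
  res <- capture_probability_mc(fc, 5, "resample", replicates = 50, seed = 1)
  expect_equal(res$p_hat, 1)
})

test_that("exact capture probabilities match hand-derived values", {
  # equal frequencies, A = 2, n = 2: 1 - 2 * (1/2)^4
  g2 <- toy_geno(c("i1", "i2"), "L1", c(1, 2), c(1, 2))
  fc2 <- whole_cluster(g2)
  expect_equal(capture_probability_exact(fc2, 2, "equal"), 0.875)

  # resample, pool {A:3, B:1}, 2n = 2: only failure is missing the singleton
  g31 <- toy_geno(c("i1", "i2"), "L1", c(1, 1), c(2, 1))
  fc31 <- whole_cluster(g31)
  expect_equal(capture_probability_exact(fc31, 1, "resample"),
               1 - choose(3, 2) / choose(4, 2))

  # empirical, freqs {0.9, 0.1}, n = 1: 1 - 0.9^2 - 0.1^2 = 0.18
  g91 <- toy_geno(sprintf("i%d", 1:5), "L1", c(2, 1, 1, 1, 1), rep(1, 5))
  fc91 <- whole_cluster(g91)
  expect_equal(capture_probability_exact(fc91, 1, "empirical"), 0.18)
})

test_that("equal-frequency exact matches exhaustive enumeration (A <= 3, 2n <= 6)", {
  for (A in 1:3) {
    ind <- sprintf("i%d", seq_len(A))
    g <- toy_geno(ind, "L1", seq_len(A), seq_len(A))
    fc <- whole_cluster(g)
    for (n in 1:3) {
      br <- brute_equal_capture(A, 2 * n)
      expect_equal(capture_probability_exact(fc, n, "equal"),
                   br["hits"] / br["total"],
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # the worked single-locus value: A = 4, n = 2 -> 24/256
  g4 <- toy_geno(sprintf("i%d", 1:4), "L1", 1:4, 1:4)
  fc4 <- whole_cluster(g4)
  br <- brute_equal_capture(4, 4)
  expect_equal(unname(br["hits"]), 24)
  expect_equal(capture_probability_exact(fc4, 2, "equal"), 24 / 256)
})

test_that("Monte Carlo agrees with the exact oracle on random small instances", {
  worst <- 0
  for (seed in 1:6) {
    g <- random_geno(n_ind = sample(4:10, 1), n_loc = sample(1:3, 1),
                     n_all = sample(2:5, 1), seed = 300 + seed)
    fc <- whole_cluster(g)
    n <- sample.int(length(individuals(g)), 1)
    for (mode in c("resample", "empirical", "equal")) {
      pe <- capture_probability_exact(fc, n, mode)
      mc <- capture_probability_mc(fc, n, mode, replicates = 2000,
                                   seed = 400 + seed)
      se <- sqrt(pe * (1 - pe) / 2000)
      expect_lte(abs(mc$p_hat - pe), max(4 * se, 1e-9))
      worst <- max(worst, abs(mc$p_hat - pe) / max(se, 1e-9))
    }
  }
})

test_that("exact capture probability is non-decreasing in n", {
  for (seed in 1:4) {
    g <- random_geno(n_ind = 8, n_loc = 2, n_all = 4, seed = 500 + seed)
    fc <- whole_cluster(g)
    for (mode in c("resample", "empirical", "equal")) {
      p <- vapply(1:8, function(n) capture_probability_exact(fc, n, mode),
                  numeric(1))
      expect_true(all(diff(p) >= -1e-12))
    }
  }
})

test_that("resampling the full cluster always captures everything", {
  g <- random_geno(n_ind = 9, n_loc = 3, n_all = 5, seed = 61)
  fc <- whole_cluster(g)
  expect_equal(capture_probability_exact(fc, 9, "resample"), 1)
  mc <- capture_probability_mc(fc, 9, "resample", replicates = 500, seed = 2)
  expect_equal(mc$successes, 500L)
})

test_that("minimum_founders matches analytic worked examples", {
  # single locus, equal, A = 4: P(1) = 0, P(2) = 0.09375 >= 0.05 -> 2
  g4 <- toy_geno(sprintf("i%d", 1:4), "L1", 1:4, 1:4)
  est4 <- minimum_founders(apply_filter(g4, one_cluster(g4), "X", "all"),
                           founder_config("equal", seed = 9))
  expect_equal(est4$min_founders, 2L)
  expect_equal(est4$curve$successes[1], 0L)

  # 20 biallelic loci, equal: P(1) = 0.5^20, P(2) = 0.875^20 ~ 0.069 -> 2
  long <- expand.grid(individual = c("i1", "i2"),
                      locus = sprintf("L%02d", 1:20),
                      stringsAsFactors = FALSE)
  long$allele1 <- 1L
  long$allele2 <- rep(c(1L, 2L), each = 1, length.out = nrow(long))
  long$allele2[long$individual == "i1"] <- 2L
  long$allele1[long$individual == "i2"] <- 2L
  g20 <- as_geno_tbl(long)
  fc20 <- apply_filter(g20, one_cluster(g20), "X", "all")
  expect_equal(capture_probability_exact(fc20, 2, "equal"), 0.875^20)
  est20 <- minimum_founders(fc20, founder_config("equal", replicates = 2000,
                                                 seed = 10))
  expect_equal(est20$min_founders, 2L)

  # cluster of one individual, resample: full pool at n = 1
  g1 <- toy_geno("solo", c("L1", "L2"), c(1, 3), c(2, 3))
  est1 <- minimum_founders(apply_filter(g1, one_cluster(g1), "X", "all"),
                           founder_config("resample", seed = 11))
  expect_equal(est1$min_founders, 1L)
})

test_that("estimates are reproducible bit-for-bit under a fixed seed", {
  g <- random_geno(n_ind = 12, n_loc = 4, n_all = 5, seed = 88)
  fc <- whole_cluster(g)
  cfg <- founder_config("empirical", replicates = 300, seed = 123)
  e1 <- minimum_founders(fc, cfg)
  e2 <- minimum_founders(fc, cfg)
  expect_identical(e1$curve, e2$curve)
  expect_identical(e1$min_founders, e2$min_founders)
})

test_that("the equal-frequency model needs fewer founders on skewed spectra", {
  # strongly skewed: one common allele, several rare ones, several loci
  withr::with_seed(42, {
    n <- 40
    long <- expand.grid(individual = sprintf("i%02d", 1:n),
                        locus = sprintf("L%d", 1:5),
                        stringsAsFactors = FALSE)
    draw <- function(m) sample(1:5, m, replace = TRUE,
                               prob = c(0.8, 0.05, 0.05, 0.05, 0.05))
    long$allele1 <- draw(nrow(long))
    long$allele2 <- draw(nrow(long))
    g <- as_geno_tbl(long)
  })
  fc <- whole_cluster(g)
  e_eq <- minimum_founders(fc, founder_config("equal", seed = 1))
  e_emp <- minimum_founders(fc, founder_config("empirical", seed = 1))
  expect_lte(e_eq$min_founders, e_emp$min_founders)
})

test_that("genotype-unit resampling is available for sensitivity analysis", {
  g <- random_geno(n_ind = 10, n_loc = 3, n_all = 4, seed = 404)
  fc <- whole_cluster(g)
  res <- capture_probability_mc(fc, 10, "resample", replicates = 100,
                                seed = 6, resample_unit = "genotypes", x = g)
  expect_equal(res$p_hat, 1)  # all individuals drawn -> full allele set
  cfg <- founder_config("resample", replicates = 200, seed = 3,
                        resample_unit = "genotypes")
  est <- minimum_founders(fc, cfg, x = g)
  expect_lte(est$min_founders, 10L)
})

test_that("the report grid emits footnotes for degenerate filter variants", {
  fx <- filter_fixture()
  # cluster B: alleles 1, 2, 98 all common, none private (98 shared? no:
  # 98 occurs in A too; 1 and 2 occur in A; 5 at L2 shared) -> no private,
  # and no low-frequency alleles at N = 10 (singleton freq would be 0.05)
  rep <- run_founder_table(fx$genotypes, fx$clusters,
                           modes = c("resample", "equal"),
                           replicates = 100, seed = 2)
  b_rows <- rep[rep$cluster == "B", ]
  expect_true(all(b_rows$footnote[b_rows$variant == "drop_low_freq"] ==
                    "no_low_freq"))
  expect_true(all(b_rows$footnote[b_rows$variant == "drop_nonprivate_low_freq"] ==
                    "no_private"))
  expect_true(all(is.na(b_rows$min_founders[b_rows$variant ==
                                              "drop_nonprivate_low_freq"])))
  # variant b of a cluster with no low-frequency alleles equals variant a
  b_all <- b_rows[b_rows$variant == "all" & b_rows$mode == "resample", ]
  b_flt <- b_rows[b_rows$variant == "drop_low_freq" & b_rows$mode == "resample", ]
  expect_equal(b_flt$observed_alleles, b_all$observed_alleles)
  expect_equal(b_flt$min_founders, b_all$min_founders)

  # cluster A: all low-frequency alleles handled, grid reproducible
  rep2 <- run_founder_table(fx$genotypes, fx$clusters,
                            modes = c("resample", "equal"),
                            replicates = 100, seed = 2)
  expect_identical(rep, rep2)
})

test_that("equal-frequency runs are restricted to unfiltered clusters by default", {
  fx <- filter_fixture()
  rep <- run_founder_table(fx$genotypes, fx$clusters, modes = "equal",
                           replicates = 50, seed = 1)
  a_rows <- rep[rep$cluster == "A" & !is.na(rep$min_founders), ]
  expect_true(all(a_rows$variant == "all"))
})

test_that("tidy, glance and autoplot expose the capture curve", {
  g <- random_geno(n_ind = 8, n_loc = 2, n_all = 3, seed = 15)
  fc <- whole_cluster(g)
  est <- minimum_founders(fc, founder_config("resample", replicates = 200,
                                             seed = 4))
  td <- tidy(est)
  expect_true(all(c("cluster", "mode", "variant", "n", "successes",
                    "p_hat") %in% names(td)))
  expect_equal(nrow(glance(est)), 1)
  expect_s3_class(autoplot(est), "ggplot")
})
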