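test_that("pair and trio equations match the enumeration oracle", {
  set.seed(101)
  for (i in 1:60) {
    p <- runif(1, 0.02, 0.98)
    K <- runif(3, 0.005, 0.5)  # K_f, K_m, K_o
    orc_trio <- enumerate_mismatch_prob(p, K[1], K[2], K[3], "trio")
    impl_trio <- c(
      expected_mismatch_trio(p, K[1], K[2], K[3], "BB"),
      expected_mismatch_trio(p, K[1], K[2], K[3], "AB"),
      expected_mismatch_trio(p, K[1], K[2], K[3], "AA")
    )
    expect_lt(max(abs(unname(orc_trio) - impl_trio)), 1e-12)

    orc_pair <- enumerate_mismatch_prob(p, K[1], K[2], K[3], "pair")
    impl_pair <- c(
      expected_mismatch_pair(p, K[1], K[3], "BB"),
      expected_mismatch_pair(p, K[1], K[3], "AB"),
      expected_mismatch_pair(p, K[1], K[3], "AA")
    )
    expect_lt(max(abs(unname(orc_pair) - impl_pair)), 1e-12)
  }
})

test_that("printed identities hold: AB* pairs never mismatch, AA*/BB* symmetry, zero error limit", {
  set.seed(102)
  p <- runif(20, 0.05, 0.95)
  K1 <- runif(20, 0.01, 0.5)
  K2 <- runif(20, 0.01, 0.5)
  K3 <- runif(20, 0.01, 0.5)
  expect_equal(expected_mismatch_pair(p, K1, K2, "AB"), rep(0, 20))
  # BB* at p equals AA* at 1-p, exactly
  expect_identical(expected_mismatch_pair(p, K1, K2, "BB"),
                   expected_mismatch_pair(1 - p, K1, K2, "AA"))
  expect_identical(expected_mismatch_trio(p, K1, K2, K3, "BB"),
                   expected_mismatch_trio(1 - p, K1, K2, K3, "AA"))
  # no observation error, true parents: mismatch probability vanishes
  tiny <- 1e-14
  for (cl in c("AA", "AB", "BB")) {
    expect_lt(max(expected_mismatch_trio(p, tiny, tiny, tiny, cl)), 1e-12)
    expect_lt(max(expected_mismatch_pair(p, tiny, tiny, cl)), 1e-12)
  }
})

test_that("conditional probabilities stay in [0,1] and grow with each K", {
  grid <- seq(0.02, 0.5, length.out = 13)
  p <- 0.3
  for (cl in c("AA", "AB", "BB")) {
    for (K_fixed in c(0.05, 0.3)) {
      along_Kf <- expected_mismatch_trio(p, grid, K_fixed, K_fixed, cl)
      along_Km <- expected_mismatch_trio(p, K_fixed, grid, K_fixed, cl)
      along_Ko <- expected_mismatch_trio(p, K_fixed, K_fixed, grid, cl)
      for (v in list(along_Kf, along_Km, along_Ko)) {
        expect_true(all(v >= 0 & v <= 1))
        expect_true(all(diff(v) >= -1e-12))
      }
    }
  }
})

test_that("raw pair mismatches are exactly opposing apparent homozygotes", {
  res <- raw_mismatch_pair(c(2L, 1L, 0L, 2L), c(0L, 2L, 0L, 2L))
  expect_equal(res$n_mismatch, 1)
  expect_equal(res$n_compared, 4)
  expect_equal(res$raw_rate, 0.25)

  # an apparent heterozygote never mismatches a single parent
  expect_equal(raw_mismatch_pair(rep(1L, 5), c(0L, 1L, 2L, 0L, 2L))$n_mismatch, 0)

  all_missing <- raw_mismatch_pair(rep(NA_integer_, 3), c(0L, 1L, 2L))
  expect_equal(all_missing$n_compared, 0)
  expect_true(is.na(all_missing$raw_rate))
})

test_that("raw trio mismatches follow the Mendelian-impossibility rules", {
  # father AA, mother BB, offspring AA: opposing homozygotes
  expect_equal(raw_mismatch_trio(2L, 2L, 0L)$n_mismatch, 1)
  # father AA, mother AB, offspring AA: consistent
  expect_equal(raw_mismatch_trio(2L, 2L, 1L)$n_mismatch, 0)
  # both parents AA but offspring appears AB: impossible
  expect_equal(raw_mismatch_trio(1L, 2L, 2L)$n_mismatch, 1)
  # missing member removes the SNP from comparison
  expect_equal(raw_mismatch_trio(c(2L, 2L), c(0L, NA), c(2L, 0L))$n_compared, 1)
})

test_that("expected mismatch evaluates the worked examples", {
  expect_equal(expected_mismatch_trio(0.5, 0.5, 0.5, 0.5, "AB"), 0.375)
  expect_equal(expected_mismatch_trio(0.5, 0.5, 0.5, 0.5, "AA"), 0.625)
  expect_equal(expected_mismatch_pair(0.5, 0.5, 0.5, "AA"), 0.375)
  expect_error(expected_mismatch_pair(1, 0.5, 0.5, "AA"), "strictly")
  expect_error(expected_mismatch_trio(0.5, 0.7, 0.5, 0.5, "AA"), "K values")
})

test_that("deep sequencing drives the expected rate to zero", {
  dat <- small_herd(seed = 201, n_snps = 300, n_sires = 3, n_dams = 3,
                    n_offspring = 3, depth_mean = 50)
  st <- trio_mismatch_stats(dat$calls, dat$freqs_true, dat$truth$offspring[1],
                            dat$truth$sire[1], dat$truth$dam[1])
  expect_lt(st$expected_rate, 1e-10)
  expect_equal(st$n_mismatch, 0)
})

test_that("excess mismatch is the difference of rates on a shared SNP set", {
  expect_equal(excess_mismatch(0.03, 0.02), 0.01)
  expect_equal(excess_mismatch(0.02, 0.02), 0)
  expect_equal(excess_mismatch(0.015, 0.02), -0.005)  # negative EMM is legal
  expect_error(excess_mismatch(c(0.1, 0.2), 0.1), "same comparisons")
})

test_that("true trios have mean EMM near zero under the matched read model", {
  dat <- small_herd(seed = 202, n_snps = 4000, n_sires = 12, n_dams = 12,
                    n_offspring = 24, depth_mean = 3)
  emm <- vapply(seq_len(24), function(i) {
    trio_mismatch_stats(dat$calls, dat$freqs_true, dat$truth$offspring[i],
                        dat$truth$sire[i], dat$truth$dam[i])$emm
  }, numeric(1))
  expect_within_3se(emm, 0)
})

test_that("overdispersed reads scored with binomial expectations inflate EMM", {
  dat <- small_herd(seed = 203, n_snps = 4000, n_sires = 12, n_dams = 12,
                    n_offspring = 24, depth_mean = 3,
                    model = read_model("beta_binomial", alpha = 4))
  emm <- vapply(seq_len(24), function(i) {
    trio_mismatch_stats(dat$calls, dat$freqs_true, dat$truth$offspring[i],
                        dat$truth$sire[i], dat$truth$dam[i],
                        model = read_model("binomial"))$emm
  }, numeric(1))
  se <- sd(emm) / sqrt(length(emm))
  expect_gt(mean(emm), 3 * se)  # raw rates sit clearly above expectations
})

test_that("raw and expected rates use the identical comparison set", {
  dat <- small_herd(seed = 204, n_snps = 500, n_sires = 3, n_dams = 3,
                    n_offspring = 3, depth_mean = 1.5)
  st <- trio_mismatch_stats(dat$calls, dat$freqs_true, dat$truth$offspring[1],
                            dat$truth$sire[1], dat$truth$dam[1])
  d <- dat$calls$depth
  ids <- c(dat$truth$offspring[1], dat$truth$sire[1], dat$truth$dam[1])
  poly <- dat$freqs_true$p > 0 & dat$freqs_true$p < 1
  manual_n <- sum(poly & colSums(d[ids, ] >= 1) == 3)
  expect_equal(st$n_compared, manual_n)
})
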