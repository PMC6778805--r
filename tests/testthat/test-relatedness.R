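test_that("pairwise relatedness matches hand arithmetic", {
  # both heterozygous at p = 0.5: centered product is zero
  expect_equal(relatedness_pair(1L, 1L, 0.5)$r, 0)
  # both homozygous reference at p = 0.5: (1)(1) / 0.5 = 2
  expect_equal(relatedness_pair(2L, 2L, 0.5)$r, 2)
  # only shared non-missing polymorphic SNPs count
  res <- relatedness_pair(c(2L, NA, 1L), c(2L, 2L, NA), c(0.5, 0.5, 0.5))
  expect_equal(res$n_snps, 1)
  expect_equal(res$r, 2)
  # nothing shared: undefined
  expect_true(is.na(relatedness_pair(NA_integer_, 2L, 0.5)$r))
})

test_that("self-relatedness reduces to the uncorrected diagonal at high depth", {
  set.seed(301)
  p <- runif(200, 0.1, 0.9)
  g <- rbinom(200, 2, p)
  # at depth 50 the heterozygote correction 2K/(1-2K) is ~ 2^-49
  sr <- self_relatedness(g, rep(50L, 200), p)$self_relatedness
  plain <- sum((g - 2 * p)^2) / sum(2 * p * (1 - p))
  expect_equal(sr, plain, tolerance = 1e-10)
  # depth-1 cells are excluded; all depth-1 means undefined
  out <- self_relatedness(g, rep(1L, 200), p)
  expect_true(is.na(out$self_relatedness))
  expect_equal(out$n_snps, 0L)
})

test_that("relatedness recovers pedigree values on simulated low-depth data", {
  dat <- small_herd(seed = 302, n_snps = 5000, n_sires = 25, n_dams = 25,
                    n_offspring = 25, depth_mean = 2)
  grm <- build_grm(dat$calls, dat$freqs_true)
  # parent-offspring pairs: 0.5
  po <- mapply(function(o, s) grm$r[o, s], dat$truth$offspring, dat$truth$sire)
  expect_within_3se(po, 0.5)
  # founder-founder pairs are unrelated: 0
  sires <- dat$truth$sire[!duplicated(dat$truth$sire)]
  dams <- dat$truth$dam[!duplicated(dat$truth$dam)]
  unrel <- as.vector(grm$r[sires, dams])
  expect_within_3se(unrel, 0)
  # non-inbred founders: diagonal 1 + F = 1
  founders <- c(sires, dams)
  expect_within_3se(diag(grm$r)[founders], 1)
})

test_that("inbred founders raise the estimated self-relatedness to 1 + F", {
  cfg <- sim_config(n_snps = 8000, n_sires = 20, n_dams = 20, n_offspring = 0,
                    depth_mean = 4, inbreeding = 0.5, seed = 303)
  ped <- simulate_pedigree_genotypes(cfg)
  counts <- simulate_reads(ped$g, cfg)
  calls <- call_genotypes(counts)
  freqs <- known_freqs(calls, ped$p)
  sr <- vapply(rownames(calls$g), function(i) {
    self_relatedness(calls$g[i, ], calls$depth[i, ], freqs$p)$self_relatedness
  }, numeric(1))
  expect_within_3se(sr, 1.5)
})

test_that("low-depth relatedness agrees with full-depth truth in expectation", {
  # at depth ~50 every genotype is read correctly: the estimator equals the
  # same formula on true genotypes, pair by pair
  dat <- small_herd(seed = 304, n_snps = 800, n_sires = 5, n_dams = 5,
                    n_offspring = 5, depth_mean = 50)
  grm <- build_grm(dat$calls, dat$freqs_true)
  o <- dat$truth$offspring[1]; s <- dat$truth$sire[1]
  p <- dat$freqs_true$p
  manual <- sum((dat$g[o, ] - 2 * p) * (dat$g[s, ] - 2 * p)) / sum(2 * p * (1 - p))
  expect_equal(grm$r[o, s], manual, tolerance = 1e-6)
})

test_that("GRM is symmetric and its off-diagonal ignores the read model", {
  dat <- small_herd(seed = 305, n_snps = 1000, n_sires = 6, n_dams = 6,
                    n_offspring = 8, depth_mean = 2)
  g_bin <- build_grm(dat$calls, dat$freqs_true, read_model("binomial"))
  g_bb <- build_grm(dat$calls, dat$freqs_true, read_model("beta_binomial", alpha = 2))
  expect_identical(g_bin$r, t(g_bin$r))
  off <- upper.tri(g_bin$r)
  expect_identical(g_bin$r[off], g_bb$r[off])      # bitwise: K never enters
  expect_false(identical(diag(g_bin$r), diag(g_bb$r)))  # diagonal does depend on K
})

test_that("GRM principal components behave on structured and unstructured input", {
  # identity GRM: every informative component carries an equal share
  n <- 12
  grm_id <- structure(list(
    r = diag(n), n_snps = matrix(100L, n, n), ids = sprintf("i%02d", 1:n),
    model = "binomial"), class = "gbs_grm")
  pca <- grm_pca(grm_id)
  expect_equal(sum(pca$prop_var), 1)
  pos <- pca$prop_var[pca$prop_var > 1e-12]
  expect_equal(pos, rep(pos[1], length(pos)), tolerance = 1e-8)

  # two diverged subpopulations separate on PC1 with a dominant share
  cfg <- sim_config(n_snps = 2000, n_sires = 20, n_dams = 20, n_offspring = 40,
                    depth_mean = 3, n_subpops = 2, fst = 0.15, seed = 306)
  dat <- simulate_parentage_data(cfg)
  calls <- call_genotypes(dat$counts)
  freqs <- estimate_allele_freqs(dat$counts)
  grm <- build_grm(calls, freqs)
  pca2 <- grm_pca(grm)
  sub <- dat$candidates$subpop[match(pca2$scores$id, dat$candidates$id)]
  pc1 <- split(pca2$scores$PC1, sub)
  expect_true(max(pc1$pop1) < min(pc1$pop2) || max(pc1$pop2) < min(pc1$pop1))
  expect_gt(pca2$prop_var[1], 3 * pca2$prop_var[2])

  grm_bad <- grm_id
  grm_bad$r[2, 5] <- NA
  expect_error(grm_pca(grm_bad), "non-finite")
})

test_that("bootstrap support separates clear winners and exact duplicates", {
  dat <- small_herd(seed = 307, n_snps = 4000, n_sires = 6, n_dams = 6,
                    n_offspring = 6, depth_mean = 3)
  o <- dat$truth$offspring[1]
  true_sire <- dat$truth$sire[1]
  stranger <- setdiff(unique(dat$truth$sire), true_sire)[1]
  sup <- bootstrap_support(dat$calls, dat$freqs_true, o, true_sire, stranger,
                           n_boot = 200, seed = 11)
  expect_gt(sup, 0.99)

  # a candidate bootstrapped against itself ties every replicate
  sup_self <- bootstrap_support(dat$calls, dat$freqs_true, o, true_sire,
                                true_sire, n_boot = 200, seed = 12)
  expect_equal(sup_self, 0.5)

  # identical seeds reproduce; different seeds need not
  sup2 <- bootstrap_support(dat$calls, dat$freqs_true, o, true_sire, stranger,
                            n_boot = 200, seed = 11)
  expect_identical(sup, sup2)
  expect_error(bootstrap_support(dat$calls, dat$freqs_true, o, true_sire,
                                 stranger, n_boot = 200),
               "seed")
})

test_that("relatedness matrices round-trip through TSV", {
  dat <- small_herd(seed = 308, n_snps = 300, n_sires = 3, n_dams = 3,
                    n_offspring = 4, depth_mean = 3)
  grm <- build_grm(dat$calls, dat$freqs_true)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grm(grm, path)
  back <- read_grm(path)
  expect_equal(back, grm$r, tolerance = 1e-12)
})
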