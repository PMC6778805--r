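# Exhaustive-enumeration oracle for the conditional mismatch probabilities.
# Independent of the package's closed forms: enumerates all true genotype
# combinations for father and mother under Hardy-Weinberg proportions,
# Mendelian transmission to the offspring, and every observation outcome
# under the symmetric read-error model (homozygotes exact; a heterozygote
# shows all-one-allele with probability K each way). Returns
# P(apparent mismatch | offspring apparent class) for classes 0 (BB*),
# 1 (AB*), 2 (AA*).
enumerate_mismatch_prob <- function(p, K_f, K_m, K_o, type = c("trio", "pair")) {
  type <- match.arg(type)
  hwe <- c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  transmit <- function(g) switch(as.character(g),
    `0` = c(1, 0), `1` = c(0.5, 0.5), `2` = c(0, 1))  # P(ref allele = 0, 1)
  obs_prob <- function(g_true, g_obs, K) {
    if (g_true != 1) return(as.numeric(g_obs == g_true))
    if (g_obs == 1) 1 - 2 * K else K
  }
  num <- setNames(numeric(3), c("0", "1", "2"))
  den <- setNames(numeric(3), c("0", "1", "2"))
  for (gf in 0:2) for (gm in 0:2) {
    p_parents <- hwe[[as.character(gf)]] * hwe[[as.character(gm)]]
    tf <- transmit(gf); tm <- transmit(gm)
    for (af in 0:1) for (am in 0:1) {
      go <- af + am
      p_true <- p_parents * tf[af + 1] * tm[am + 1]
      if (p_true == 0) next
      for (of in 0:2) for (om in 0:2) for (oo in 0:2) {
        p_obs <- obs_prob(gf, of, K_f) * obs_prob(gm, om, K_m) *
          obs_prob(go, oo, K_o)
        if (p_obs == 0) next
        mismatch <- if (type == "trio") {
          (oo == 2 && (of == 0 || om == 0)) ||
            (oo == 0 && (of == 2 || om == 2)) ||
            (oo == 1 && ((of == 2 && om == 2) || (of == 0 && om == 0)))
        } else {
          (oo == 2 && of == 0) || (oo == 0 && of == 2)
        }
        key <- as.character(oo)
        den[[key]] <- den[[key]] + p_true * p_obs
        if (mismatch) num[[key]] <- num[[key]] + p_true * p_obs
      }
    }
  }
  num / den
}

# Frequencies tibble from known per-SNP p (the generator's truth), shaped
# like estimate_allele_freqs() output.
known_freqs <- function(calls, p) {
  tibble::tibble(
    snp_id = colnames(calls$g), p = p, total_depth = NA_integer_,
    usable = TRUE, monomorphic = p <= 0 | p >= 1
  )
}

# Small simulated dataset shared by several suites.
small_herd <- function(seed, n_snps = 1500, n_sires = 10, n_dams = 40,
                       n_offspring = 60, depth_mean = 3, ...) {
  cfg <- sim_config(n_snps = n_snps, n_sires = n_sires, n_dams = n_dams,
                    n_offspring = n_offspring, depth_mean = depth_mean,
                    seed = seed, ...)
  dat <- simulate_parentage_data(cfg)
  dat$calls <- call_genotypes(dat$counts)
  dat$freqs_true <- known_freqs(dat$calls, dat$true_freqs)
  dat
}

expect_within_3se <- function(values, target) {
  se <- stats::sd(values) / sqrt(length(values))
  expect_lt(abs(mean(values) - target), 3 * se + 1e-12)
}
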