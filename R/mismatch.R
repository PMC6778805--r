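#' Observed (raw) mismatches for a parent-offspring pair
#'
#' A pair mismatch is a pair of *opposing apparent homozygotes*: offspring and
#' putative parent each called homozygous, for different alleles. An apparent
#' heterozygote in either individual can never mismatch a single parent.
#' Comparison is restricted to SNPs where both members have at least one read.
#'
#' @param g_o,g_p Integer vectors of apparent genotypes (0/1/2, NA = missing)
#'   for offspring and parent, aligned on the same SNPs.
#' @return A one-row tibble: `n_mismatch`, `n_compared`, `raw_rate`
#'   (`NA` when nothing is comparable).
#' @examples
#' raw_mismatch_pair(c(2L, 1L, 0L, 2L), c(0L, 2L, 0L, 2L))  # 1 of 4
#' @export
raw_mismatch_pair <- function(g_o, g_p) {
  if (length(g_o) != length(g_p)) abort("Genotype vectors must be aligned (equal length).")
  both <- !is.na(g_o) & !is.na(g_p)
  mism <- both & ((g_o == 2L & g_p == 0L) | (g_o == 0L & g_p == 2L))
  n_compared <- sum(both)
  tibble::tibble(
    n_mismatch = sum(mism),
    n_compared = n_compared,
    raw_rate = if (n_compared > 0) sum(mism) / n_compared else NA_real_
  )
}

# Mendelian-impossible apparent trio, reading apparent genotypes as true:
#  (a) offspring opposing-homozygous to either parent;
#  (b) offspring heterozygous while both parents are homozygous for the same
#      allele;
#  (c) both parents homozygous for opposite alleles but offspring homozygous
#      (subsumed by (a); kept for clarity of the rule set).
trio_mismatch_indicator <- function(g_o, g_f, g_m) {
  opp_f <- (g_o == 2L & g_f == 0L) | (g_o == 0L & g_f == 2L)
  opp_m <- (g_o == 2L & g_m == 0L) | (g_o == 0L & g_m == 2L)
  het_hom <- g_o == 1L & ((g_f == 2L & g_m == 2L) | (g_f == 0L & g_m == 0L))
  opp_f | opp_m | het_hom
}

#' Observed (raw) mismatches for a parent-pair-offspring trio
#'
#' A trio mismatch is an apparent genotype triple that would be Mendelian-
#' impossible if the apparent genotypes were true: the offspring opposes
#' either parent homozygously; or the offspring appears heterozygous while
#' both parents appear homozygous for the same allele; or both parents appear
#' homozygous for opposite alleles yet the offspring appears homozygous.
#' Comparison is restricted to SNPs where all three members have reads.
#'
#' @param g_o,g_f,g_m Apparent genotype vectors (0/1/2, NA) for offspring,
#'   father, mother, aligned on the same SNPs.
#' @return A one-row tibble: `n_mismatch`, `n_compared`, `raw_rate`.
#' @export
raw_mismatch_trio <- function(g_o, g_f, g_m) {
  if (length(g_o) != length(g_f) || length(g_o) != length(g_m)) {
    abort("Genotype vectors must be aligned (equal length).")
  }
  all3 <- !is.na(g_o) & !is.na(g_f) & !is.na(g_m)
  mism <- all3 & trio_mismatch_indicator(g_o, g_f, g_m)
  n_compared <- sum(all3)
  tibble::tibble(
    n_mismatch = sum(mism),
    n_compared = n_compared,
    raw_rate = if (n_compared > 0) sum(mism) / n_compared else NA_real_
  )
}

check_mismatch_args <- function(p, Ks) {
  if (any(p <= 0 | p >= 1)) {
    abort("Allele frequency p must lie strictly in (0, 1); filter monomorphic SNPs first.")
  }
  for (K in Ks) {
    if (any(K <= 0 | K > 0.5)) abort("K values must lie in (0, 0.5].")
  }
  invisible(TRUE)
}

# The conditional mismatch probabilities, given the offspring apparent class,
# under Hardy-Weinberg equilibrium, random mating and non-inbred parents.
# Homozygotes are read without error; a heterozygote at depth k shows only one
# allele with probability K each way. The BB* case is the AA* case with
# p -> 1 - p.
pair_mismatch_prob <- function(p, K_par, K_off, g_off) {
  n <- max(length(p), length(K_par), length(K_off), length(g_off))
  p <- rep_len(p, n); Kf <- rep_len(K_par, n); Ko <- rep_len(K_off, n)
  g <- rep_len(as.integer(g_off), n)
  out <- numeric(n)
  aa <- g == 2L
  bb <- g == 0L
  out[aa] <- (1 - p[aa]) * (p[aa] * Kf[aa] + Kf[aa] * Ko[aa] + (1 - p[aa]) * Ko[aa]) /
    (p[aa] + 2 * (1 - p[aa]) * Ko[aa])
  q <- 1 - p[bb]
  out[bb] <- (1 - q) * (q * Kf[bb] + Kf[bb] * Ko[bb] + (1 - q) * Ko[bb]) /
    (q + 2 * (1 - q) * Ko[bb])
  out
}

trio_mismatch_prob <- function(p, K_f, K_m, K_o, g_off) {
  n <- max(length(p), length(K_f), length(K_m), length(K_o), length(g_off))
  p <- rep_len(p, n); Kf <- rep_len(K_f, n); Km <- rep_len(K_m, n)
  Ko <- rep_len(K_o, n); g <- rep_len(as.integer(g_off), n)
  out <- numeric(n)
  bracket <- function(Kf, Km, Ko) {
    2 * Ko + Km + Kf - Kf * Km + 2 * Km * Ko + 2 * Kf * Ko - 2 * Kf * Km * Ko
  }
  aa <- g == 2L
  if (any(aa)) {
    pa <- p[aa]
    out[aa] <- (pa^2 * (1 - pa) * (Km[aa] + Kf[aa]) * (1 + Ko[aa]) +
                  pa * (1 - pa)^2 * bracket(Kf[aa], Km[aa], Ko[aa]) +
                  2 * (1 - pa)^3 * Ko[aa]) /
      (pa + 2 * (1 - pa) * Ko[aa])
  }
  ab <- g == 1L
  if (any(ab)) {
    pb <- p[ab]
    out[ab] <- ((1 - 2 * pb * (1 - pb)) * (Km[ab] + Kf[ab]) +
                  4 * pb * (1 - pb) * Kf[ab] * Km[ab]) / 2
  }
  bb <- g == 0L
  if (any(bb)) {
    q <- 1 - p[bb]  # BB* is AA* with p -> 1 - p
    out[bb] <- (q^2 * (1 - q) * (Km[bb] + Kf[bb]) * (1 + Ko[bb]) +
                  q * (1 - q)^2 * bracket(Kf[bb], Km[bb], Ko[bb]) +
                  2 * (1 - q)^3 * Ko[bb]) /
      (q + 2 * (1 - q) * Ko[bb])
  }
  out
}

class_to_g <- function(class) {
  cl <- match.arg(class, c("AA", "AB", "BB"))
  switch(cl, AA = 2L, AB = 1L, BB = 0L)
}

#' Expected parent-offspring mismatch probability at one SNP
#'
#' The probability of an apparent opposing-homozygote mismatch between an
#' offspring and its *true* parent, conditional on the offspring's apparent
#' genotype class, given the reference allele frequency `p` and the no-call
#' probabilities `K` of parent and offspring at their actual read depths.
#' Apparent heterozygotes (`"AB"`) can never mismatch a single parent, so the
#' probability is exactly zero there.
#'
#' @param p Reference allele frequency, strictly in (0, 1). Vectorised.
#' @param K_parent,K_offspring No-call probabilities from [k_probability()].
#' @param class Offspring apparent class: `"AA"` (g = 2), `"AB"`, or `"BB"`.
#' @return Numeric vector of probabilities.
#' @examples
#' expected_mismatch_pair(0.5, 0.5, 0.5, "AA")  # 0.375
#' @export
expected_mismatch_pair <- function(p, K_parent, K_offspring, class) {
  g <- class_to_g(class)
  check_mismatch_args(p, list(K_parent, K_offspring))
  pair_mismatch_prob(p, K_parent, K_offspring, g)
}

#' Expected parent-pair-offspring (trio) mismatch probability at one SNP
#'
#' Probability of a Mendelian-impossible apparent trio for the *true* parents,
#' conditional on the offspring's apparent genotype class, with per-member
#' no-call probabilities `K` at their actual depths.
#'
#' @param p Reference allele frequency, strictly in (0, 1). Vectorised.
#' @param K_father,K_mother,K_offspring No-call probabilities.
#' @param class Offspring apparent class: `"AA"`, `"AB"`, or `"BB"`.
#' @return Numeric vector of probabilities.
#' @examples
#' expected_mismatch_trio(0.5, 0.5, 0.5, 0.5, "AA")  # 0.625
#' @export
expected_mismatch_trio <- function(p, K_father, K_mother, K_offspring, class) {
  g <- class_to_g(class)
  check_mismatch_args(p, list(K_father, K_mother, K_offspring))
  trio_mismatch_prob(p, K_father, K_mother, K_offspring, g)
}

#' Excess mismatch rate
#'
#' The observed mismatch rate minus the model-expected mismatch rate computed
#' on the same SNP set. Near zero for true parentage under a well-calibrated
#' read model; clearly positive for wrong parents. May legitimately be
#' (slightly) negative.
#'
#' @param raw_rate,expected_rate Rates computed on identical SNP sets.
#' @return `raw_rate - expected_rate`.
#' @export
excess_mismatch <- function(raw_rate, expected_rate) {
  if (length(raw_rate) != length(expected_rate)) {
    abort("raw and expected rates must come from the same comparisons.")
  }
  raw_rate - expected_rate
}

# Shared-SNP selector: polymorphic and every member has reads.
comparable_snps <- function(p, depths) {
  ok <- !is.na(p) & p > 0 & p < 1
  for (d in depths) ok <- ok & d >= 1L
  ok
}

#' Pair mismatch statistics (raw, expected, EMM) for one offspring-parent pair
#'
#' Computes raw and expected mismatch rates on exactly the same SNP set —
#' polymorphic SNPs where both members have at least one read — and their
#' difference, the excess mismatch rate (EMM). Expected rates use each
#' member's actual read depth via the read model's `K(k)`.
#'
#' @param calls A [call_genotypes()] result.
#' @param freqs Matching [estimate_allele_freqs()] tibble.
#' @param offspring,parent Individual ids (row names of the call matrix).
#' @param model A [read_model()].
#' @return One-row tibble: `offspring`, `parent`, `n_compared`, `n_mismatch`,
#'   `raw_rate`, `expected_rate`, `emm`.
#' @export
pair_mismatch_stats <- function(calls, freqs, offspring, parent,
                                model = read_model("binomial")) {
  stopifnot(inherits(calls, "genotype_calls"))
  check_freqs_alignment(calls, freqs)
  g_o <- calls$g[offspring, ]
  g_p <- calls$g[parent, ]
  use <- comparable_snps(freqs$p, list(calls$depth[offspring, ], calls$depth[parent, ]))
  raw <- raw_mismatch_pair(g_o[use], g_p[use])
  expected <- if (raw$n_compared > 0) {
    mean(pair_mismatch_prob(
      freqs$p[use],
      k_prob_lookup(model, calls$depth[parent, ][use]),
      k_prob_lookup(model, calls$depth[offspring, ][use]),
      g_o[use]
    ))
  } else {
    NA_real_
  }
  tibble::tibble(
    offspring = offspring, parent = parent,
    n_compared = raw$n_compared, n_mismatch = raw$n_mismatch,
    raw_rate = raw$raw_rate, expected_rate = expected,
    emm = raw$raw_rate - expected
  )
}

#' Trio mismatch statistics (raw, expected, EMM) for one putative trio
#'
#' As [pair_mismatch_stats()], but for the offspring with both putative
#' parents jointly: the comparison set is polymorphic SNPs where all three
#' members have reads, and both raw and expected rates are computed on it.
#'
#' @inheritParams pair_mismatch_stats
#' @param father,mother Individual ids of the putative parents.
#' @return One-row tibble: `offspring`, `father`, `mother`, `n_compared`,
#'   `n_mismatch`, `raw_rate`, `expected_rate`, `emm`.
#' @export
trio_mismatch_stats <- function(calls, freqs, offspring, father, mother,
                                model = read_model("binomial")) {
  stopifnot(inherits(calls, "genotype_calls"))
  check_freqs_alignment(calls, freqs)
  g_o <- calls$g[offspring, ]; g_f <- calls$g[father, ]; g_m <- calls$g[mother, ]
  use <- comparable_snps(freqs$p, list(
    calls$depth[offspring, ], calls$depth[father, ], calls$depth[mother, ]))
  raw <- raw_mismatch_trio(g_o[use], g_f[use], g_m[use])
  expected <- if (raw$n_compared > 0) {
    mean(trio_mismatch_prob(
      freqs$p[use],
      k_prob_lookup(model, calls$depth[father, ][use]),
      k_prob_lookup(model, calls$depth[mother, ][use]),
      k_prob_lookup(model, calls$depth[offspring, ][use]),
      g_o[use]
    ))
  } else {
    NA_real_
  }
  tibble::tibble(
    offspring = offspring, father = father, mother = mother,
    n_compared = raw$n_compared, n_mismatch = raw$n_mismatch,
    raw_rate = raw$raw_rate, expected_rate = expected,
    emm = raw$raw_rate - expected
  )
}

#' Per-SNP trio data for dispersion fitting
#'
#' Extracts, for one accepted trio, the quantities the expected trio mismatch
#' rate depends on at each comparable SNP: allele frequency, the three read
#' depths and the offspring apparent class — plus the trio's raw mismatch
#' rate. [fit_dispersion()] consumes a list of these, re-evaluating expected
#' rates for candidate overdispersion parameters without touching the raw
#' data again.
#'
#' @inheritParams trio_mismatch_stats
#' @return A list with `raw_rate`, `n_compared` and a tibble `snps`
#'   (`p`, `k_o`, `k_f`, `k_m`, `g_o`).
#' @export
trio_mismatch_data <- function(calls, freqs, offspring, father, mother) {
  stopifnot(inherits(calls, "genotype_calls"))
  check_freqs_alignment(calls, freqs)
  use <- comparable_snps(freqs$p, list(
    calls$depth[offspring, ], calls$depth[father, ], calls$depth[mother, ]))
  g_o <- calls$g[offspring, ][use]
  raw <- raw_mismatch_trio(g_o, calls$g[father, ][use], calls$g[mother, ][use])
  list(
    offspring = offspring, father = father, mother = mother,
    raw_rate = raw$raw_rate, n_compared = raw$n_compared,
    snps = tibble::tibble(
      p = freqs$p[use],
      k_o = calls$depth[offspring, ][use],
      k_f = calls$depth[father, ][use],
      k_m = calls$depth[mother, ][use],
      g_o = g_o
    )
  )
}
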