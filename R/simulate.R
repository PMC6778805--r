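#' Simulation configuration
#'
#' Study conditions for the built-in generator: a two-generation pedigree of
#' unrelated founders (sires and dams) and offspring with both parents drawn
#' from the founder sets, genotyped at independent biallelic SNPs, read at
#' low depth under one of the three allele-sampling models.
#'
#' Defaults emulate a single-season livestock breeding herd genotyped by GBS:
#' a few dozen sires, a few hundred dams and offspring, thousands of SNPs
#' with allele frequencies spread over `af_range`, and per-cell read depths
#' Poisson with mean 3 (depth 0 = missing), in line with the mean depths
#' low-cost GBS runs actually deliver.
#'
#' @param n_snps Number of independent SNPs.
#' @param n_sires,n_dams,n_offspring Pedigree sizes.
#' @param af_range Founder reference-allele frequencies are drawn uniformly
#'   on this interval.
#' @param depth_mean Mean of the per-cell Poisson read depth.
#' @param model A [read_model()] controlling heterozygote read sampling.
#' @param inbreeding Founder inbreeding coefficient F in \[0, 1\]: founder
#'   genotypes are drawn with `P(het) = 2p(1-p)(1-F)`.
#' @param missing_parent_fraction Fraction of true sires withheld from the
#'   candidate table (their offspring then have no true sire on offer).
#' @param n_subpops Number of subpopulations; founders are split evenly and
#'   offspring mate within subpopulation.
#' @param fst Divergence of subpopulation allele frequencies from the common
#'   ancestral frequency (Beta perturbation with variance `fst * p(1-p)`).
#' @param seed Integer seed; mandatory.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 3000, n_sires = 20, n_dams = 200,
                       n_offspring = 300, af_range = c(0.05, 0.95),
                       depth_mean = 3, model = read_model("binomial"),
                       inbreeding = 0, missing_parent_fraction = 0,
                       n_subpops = 1, fst = 0, seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  stopifnot(
    n_snps >= 1, n_sires >= 0, n_dams >= 0, n_offspring >= 0,
    length(af_range) == 2, af_range[1] > 0, af_range[2] < 1,
    af_range[1] <= af_range[2],
    depth_mean > 0, inherits(model, "read_model"),
    inbreeding >= 0, inbreeding <= 1,
    missing_parent_fraction >= 0, missing_parent_fraction < 1,
    n_subpops >= 1, fst >= 0, fst < 1
  )
  if (n_offspring > 0 && (n_sires == 0 || n_dams == 0)) {
    abort("Offspring requested but no founders of one sex.")
  }
  structure(
    list(n_snps = as.integer(n_snps), n_sires = as.integer(n_sires),
         n_dams = as.integer(n_dams), n_offspring = as.integer(n_offspring),
         af_range = af_range, depth_mean = depth_mean, model = model,
         inbreeding = inbreeding,
         missing_parent_fraction = missing_parent_fraction,
         n_subpops = as.integer(n_subpops), fst = fst,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

draw_founder_genotypes <- function(n, p, inbreeding) {
  # per individual x SNP: P(g=2) = p^2 + Fp(1-p), P(g=1) = 2p(1-p)(1-F)
  n_snp <- ncol(p)
  g <- matrix(0L, n, n_snp)
  u <- matrix(runif(n * n_snp), n, n_snp)
  p2 <- p^2 + inbreeding * p * (1 - p)
  phet <- 2 * p * (1 - p) * (1 - inbreeding)
  g[u < p2] <- 2L
  g[u >= p2 & u < p2 + phet] <- 1L
  g
}

transmit_allele <- function(g_parent) {
  # number of reference alleles transmitted (0/1) per cell
  out <- matrix(0L, nrow(g_parent), ncol(g_parent))
  out[g_parent == 2L] <- 1L
  het <- g_parent == 1L
  out[het] <- (runif(sum(het)) < 0.5) + 0L
  out
}

#' Simulate a pedigree with true genotypes
#'
#' Founders (sires, dams) are drawn from Hardy-Weinberg proportions at each
#' SNP (with optional founder inbreeding and subpopulation divergence);
#' offspring receive one allele from each parent, chosen uniformly, with
#' sire/dam drawn at random within subpopulation.
#'
#' @param config A [sim_config()].
#' @return A list: integer matrix `g` of true genotypes (individuals x SNPs),
#'   `truth` tibble (`offspring`, `sire`, `dam`), `roles` tibble (`id`,
#'   `role`, `subpop`), `p` ancestral frequencies, `p_subpop` matrix of
#'   per-subpopulation frequencies (one row per subpopulation).
#' @export
simulate_pedigree_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n_snp <- config$n_snps
    p0 <- runif(n_snp, config$af_range[1], config$af_range[2])
    p_sub <- matrix(p0, config$n_subpops, n_snp, byrow = TRUE)
    if (config$n_subpops > 1 && config$fst > 0) {
      # Balding-Nichols style drift: Beta with mean p0, variance fst*p0(1-p0)
      shape_mult <- (1 - config$fst) / config$fst
      for (s in seq_len(config$n_subpops)) {
        p_sub[s, ] <- rbeta(n_snp, p0 * shape_mult, (1 - p0) * shape_mult)
      }
      p_sub <- pmin(pmax(p_sub, 1e-6), 1 - 1e-6)
    }

    sire_ids <- sprintf("S%03d", seq_len(config$n_sires))
    dam_ids <- sprintf("D%03d", seq_len(config$n_dams))
    off_ids <- sprintf("O%03d", seq_len(config$n_offspring))
    sub_of <- function(n) rep_len(seq_len(config$n_subpops), n)

    sire_sub <- sub_of(config$n_sires)
    dam_sub <- sub_of(config$n_dams)
    g_sire <- draw_founder_genotypes(config$n_sires,
                                     p_sub[sire_sub, , drop = FALSE],
                                     config$inbreeding)
    g_dam <- draw_founder_genotypes(config$n_dams,
                                    p_sub[dam_sub, , drop = FALSE],
                                    config$inbreeding)

    off_sub <- sub_of(config$n_offspring)
    sire_of <- integer(config$n_offspring)
    dam_of <- integer(config$n_offspring)
    for (s in seq_len(config$n_subpops)) {
      oo <- which(off_sub == s)
      sire_of[oo] <- sample(which(sire_sub == s), length(oo), replace = TRUE)
      dam_of[oo] <- sample(which(dam_sub == s), length(oo), replace = TRUE)
    }
    g_off <- transmit_allele(g_sire[sire_of, , drop = FALSE]) +
      transmit_allele(g_dam[dam_of, , drop = FALSE])

    g <- rbind(g_sire, g_dam, g_off)
    rownames(g) <- c(sire_ids, dam_ids, off_ids)
    colnames(g) <- sprintf("snp%05d", seq_len(n_snp))

    list(
      g = g,
      truth = tibble::tibble(
        offspring = off_ids,
        sire = sire_ids[sire_of],
        dam = dam_ids[dam_of]
      ),
      roles = tibble::tibble(
        id = c(sire_ids, dam_ids, off_ids),
        role = rep(c("sire_candidate", "dam_candidate", "offspring"),
                   c(config$n_sires, config$n_dams, config$n_offspring)),
        subpop = paste0("pop", c(sire_sub, dam_sub, off_sub))
      ),
      p = p0,
      p_subpop = p_sub
    )
  })
}

# Heterozygote reference-read counts at given depths under each model family.
sample_het_ref_reads <- function(k, model) {
  n <- length(k)
  switch(model$family,
    binomial = rbinom(n, k, 0.5),
    beta_binomial = rbinom(n, k, rbeta(n, model$alpha, model$alpha)),
    modified_p = {
      # Markov chain over reads: first read fair, then repeat the previous
      # allele with probability pprime. Simulated read-by-read (the analytic
      # K never enters, so this stays an independent cross-check of it).
      out <- integer(n)
      active <- k >= 1L
      current <- integer(n)
      current[active] <- (runif(sum(active)) < 0.5) + 0L
      out <- out + current
      r <- 2L
      while (any(k >= r)) {
        idx <- which(k >= r)
        stay <- runif(length(idx)) < model$pprime
        current[idx][!stay] <- 1L - current[idx][!stay]
        out[idx] <- out[idx] + current[idx]
        r <- r + 1L
      }
      out
    }
  )
}

#' Simulate GBS read counts from true genotypes
#'
#' Per-cell depths are Poisson(`depth_mean`) (a depth of 0 leaves the cell
#' missing). Homozygotes yield reads of their single allele only; reads of
#' heterozygotes follow the configured sampling model: fair independent reads
#' (binomial), a Beta-drawn read probability per cell (beta-binomial), or the
#' Markov repeat-the-previous-allele chain (modified-p).
#'
#' @param g Integer matrix of true genotypes (individuals x SNPs, dimnames
#'   required), e.g. from [simulate_pedigree_genotypes()].
#' @param config A [sim_config()]; `depth_mean`, `model` and `seed` are used.
#' @return An [allele_counts()] object.
#' @export
simulate_reads <- function(g, config) {
  stopifnot(is.matrix(g), inherits(config, "sim_config"))
  withr_seed(config$seed + 1L, {
    n <- length(g)
    k <- matrix(rpois(n, config$depth_mean), nrow(g), ncol(g))
    ref <- matrix(0L, nrow(g), ncol(g), dimnames = dimnames(g))
    ref[g == 2L] <- k[g == 2L]
    het <- which(g == 1L & k > 0L)
    ref[het] <- sample_het_ref_reads(k[het], config$model)
    alt <- k - ref
    dimnames(alt) <- dimnames(g)
    allele_counts(ref, alt)
  })
}

#' Simulate a complete parentage dataset
#'
#' Convenience wrapper producing everything an assignment run needs: allele
#' counts, a candidate table (optionally with a fraction of true sires
#' withheld, for specificity testing), the true pedigree, and the true allele
#' frequencies.
#'
#' @param config A [sim_config()].
#' @return A list: `counts` ([allele_counts()]), `candidates`
#'   ([candidate_table()] including recorded true parents), `truth` tibble,
#'   `true_freqs`, `g` true genotypes, `withheld_sires` character vector.
#' @export
simulate_parentage_data <- function(config) {
  ped <- simulate_pedigree_genotypes(config)
  counts <- simulate_reads(ped$g, config)
  roles <- ped$roles
  withheld <- character(0)
  if (config$missing_parent_fraction > 0) {
    sires <- roles$id[roles$role == "sire_candidate"]
    n_drop <- floor(config$missing_parent_fraction * length(sires))
    if (n_drop > 0) {
      withheld <- withr_seed(config$seed + 2L, sample(sires, n_drop))
      roles <- dplyr::filter(roles, !(.data$id %in% withheld))
    }
  }
  cand <- dplyr::left_join(
    roles,
    dplyr::rename(ped$truth, id = "offspring",
                  recorded_sire = "sire", recorded_dam = "dam"),
    by = "id"
  )
  list(
    counts = counts,
    candidates = candidate_table(cand),
    truth = ped$truth,
    true_freqs = ped$p,
    g = ped$g,
    withheld_sires = withheld
  )
}
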