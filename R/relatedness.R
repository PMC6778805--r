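#' Pairwise relatedness from apparent genotypes
#'
#' The allele-frequency-standardised cross-product estimator
#' \deqn{\hat r = \sum_s (g_{is} - 2p_s)(g_{js} - 2p_s) / \sum_s 2 p_s (1 - p_s)}
#' over polymorphic SNPs non-missing in *both* individuals, with the
#' denominator summed over that same shared set. Because the apparent dosage
#' has expectation equal to the true dosage under any symmetric read-sampling
#' model, this is unbiased for pedigree relatedness at any read depth, and —
#' unlike the self-relatedness diagonal — does not depend on the read model's
#' `K` at all.
#'
#' @param g_i,g_j Apparent genotype vectors (0/1/2, NA) on the same SNPs.
#' @param p Reference allele frequencies for those SNPs. Monomorphic or
#'   undefined frequencies are excluded.
#' @return One-row tibble: `r` (NA when no SNP is shared) and `n_snps`.
#' @examples
#' relatedness_pair(c(2L, 1L), c(2L, 1L), c(0.5, 0.5))
#' @export
relatedness_pair <- function(g_i, g_j, p) {
  if (length(g_i) != length(g_j) || length(g_i) != length(p)) {
    abort("Genotype and frequency vectors must be aligned.")
  }
  use <- !is.na(g_i) & !is.na(g_j) & !is.na(p) & p > 0 & p < 1
  n <- sum(use)
  r <- if (n > 0) {
    sum((g_i[use] - 2 * p[use]) * (g_j[use] - 2 * p[use])) /
      sum(2 * p[use] * (1 - p[use]))
  } else {
    NA_real_
  }
  tibble::tibble(r = r, n_snps = n)
}

#' Depth-corrected self-relatedness (1 + F)
#'
#' The diagonal analogue of [relatedness_pair()]. A true heterozygote read at
#' depth `k` is sometimes seen as a homozygote, which inflates
#' \eqn{(g - 2p)^2} by `2K` on average; subtracting `2K/(1 - 2K)` from every
#' *apparent* heterozygote cell removes exactly that inflation (the
#' correction triggers with probability `1 - 2K` per true heterozygote),
#' leaving the estimator unbiased for `1 + F` under the read model without
#' any Hardy-Weinberg assumption. Cells at depth 1 carry no heterozygosity
#' signal and the correction factor is undefined there (`K = 0.5`), so only
#' cells with `k >= 2` enter.
#'
#' @param g_i Apparent genotype vector (0/1/2, NA).
#' @param depth_i Read depths for the same SNPs.
#' @param p Reference allele frequencies.
#' @param model A [read_model()]; self-relatedness, unlike pairwise
#'   relatedness, depends on the model through `K`.
#' @return One-row tibble: `self_relatedness` (an estimate of `1 + F`),
#'   `f_hat`, `n_snps`. NA and flagged when no SNP has depth >= 2.
#' @export
self_relatedness <- function(g_i, depth_i, p, model = read_model("binomial")) {
  if (length(g_i) != length(depth_i) || length(g_i) != length(p)) {
    abort("Genotype, depth and frequency vectors must be aligned.")
  }
  use <- !is.na(g_i) & depth_i >= 2L & !is.na(p) & p > 0 & p < 1
  n <- sum(use)
  if (n == 0) {
    return(tibble::tibble(self_relatedness = NA_real_, f_hat = NA_real_, n_snps = 0L))
  }
  K <- k_prob_lookup(model, depth_i[use])
  het_correction <- (2 * K / (1 - 2 * K)) * (g_i[use] == 1L)
  sr <- sum((g_i[use] - 2 * p[use])^2 - het_correction) /
    sum(2 * p[use] * (1 - p[use]))
  tibble::tibble(self_relatedness = sr, f_hat = sr - 1, n_snps = n)
}

#' Genomic relatedness matrix from apparent genotype calls
#'
#' Assembles all pairwise relatedness estimates ([relatedness_pair()]) and
#' depth-corrected self-relatedness diagonals ([self_relatedness()]) into a
#' symmetric matrix, with pair-specific denominators over each pair's shared
#' non-missing polymorphic SNP set. Off-diagonal entries are identical under
#' any read model (they do not involve `K`); only the diagonal changes with
#' the model.
#'
#' @param calls A [call_genotypes()] result (>= 2 individuals).
#' @param freqs Matching [estimate_allele_freqs()] tibble.
#' @param model A [read_model()], used for the diagonal only.
#' @return A `gbs_grm` object: list with symmetric matrix `r` (diagonal =
#'   `1 + F` estimates), integer matrix `n_snps` of per-pair shared SNP
#'   counts, and `ids`.
#' @export
build_grm <- function(calls, freqs, model = read_model("binomial")) {
  stopifnot(inherits(calls, "genotype_calls"))
  check_freqs_alignment(calls, freqs)
  if (nrow(calls$g) < 2) abort("Need at least 2 individuals.")
  poly <- !is.na(freqs$p) & freqs$p > 0 & freqs$p < 1
  g <- calls$g[, poly, drop = FALSE]
  depth <- calls$depth[, poly, drop = FALSE]
  p <- freqs$p[poly]
  w <- 2 * p * (1 - p)

  obs <- !is.na(g)
  z <- sweep(g, 2, 2 * p, "-")
  z[!obs] <- 0
  num <- tcrossprod(z)
  den <- tcrossprod(sweep(obs + 0, 2, w, "*"), obs + 0)
  n_snps <- tcrossprod(obs + 0)
  r <- ifelse(den > 0, num / den, NA_real_)

  ids <- rownames(g)
  for (i in seq_along(ids)) {
    sr <- self_relatedness(g[i, ], depth[i, ], p, model)
    r[i, i] <- sr$self_relatedness
    n_snps[i, i] <- sr$n_snps
  }
  dimnames(r) <- dimnames(n_snps) <- list(ids, ids)
  storage.mode(n_snps) <- "integer"
  structure(list(r = r, n_snps = n_snps, ids = ids,
                 model = model$family),
            class = "gbs_grm")
}

#' @export
print.gbs_grm <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("<gbs_grm> %d individuals (diagonal under %s model)\n",
              length(x$ids), x$model))
  cat(sprintf("  off-diagonal r: mean %.3f, range [%.3f, %.3f]\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Principal components of a genomic relatedness matrix
#'
#' Column-centres the GRM and eigendecomposes it (via [stats::prcomp()]),
#' returning per-individual component scores and each component's share of
#' the variation — the standard population-structure diagnostic for deciding
#' whether allele frequencies should be estimated per subpopulation.
#'
#' @param grm A [build_grm()] result.
#' @param n_components How many components to keep in the score table.
#' @return A `grm_pca` object: tibble `scores` (`id`, `PC1`, `PC2`, ...) and
#'   numeric `prop_var` (proportion of variation per component, summing to 1
#'   over the positive eigenvalues).
#' @export
grm_pca <- function(grm, n_components = 10) {
  stopifnot(inherits(grm, "gbs_grm"))
  bad <- which(!is.finite(grm$r), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pairs <- apply(head(bad, 5), 1, function(ij) {
      paste0(grm$ids[ij[1]], "/", grm$ids[ij[2]])
    })
    abort(paste0("GRM has non-finite entries for pairs: ",
                 paste(pairs, collapse = ", ")))
  }
  pc <- prcomp(grm$r, center = TRUE, scale. = FALSE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(id = grm$ids), scores)
  structure(list(scores = scores, prop_var = prop), class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat(sprintf("<grm_pca> %d individuals; PC1 %.1f%%, PC2 %.1f%% of variation\n",
              nrow(x$scores), 100 * x$prop_var[1], 100 * x$prop_var[2]))
  invisible(x)
}

#' Bootstrap support for the top-ranked candidate parent
#'
#' Resamples SNPs with replacement (keeping the original number of SNPs and
#' the full-data allele frequencies fixed), recomputes the offspring's
#' relatedness to the best and second-best candidates on each replicate, and
#' returns the fraction of replicates in which the best candidate stays more
#' related (ties count 1/2). Used to decide whether two close candidates are
#' distinguishable.
#'
#' @param calls A [call_genotypes()] result.
#' @param freqs Matching allele-frequency tibble (fixed across replicates).
#' @param offspring,candidate_best,candidate_second Individual ids.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return Support, a number in \[0, 1\].
#' @export
bootstrap_support <- function(calls, freqs, offspring, candidate_best,
                              candidate_second, n_boot = 1000, seed) {
  stopifnot(inherits(calls, "genotype_calls"))
  check_freqs_alignment(calls, freqs)
  if (missing(seed)) abort("`seed` is required.")
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  poly <- !is.na(freqs$p) & freqs$p > 0 & freqs$p < 1
  p <- freqs$p[poly]
  w <- 2 * p * (1 - p)
  g_o <- calls$g[offspring, poly]
  z_o <- g_o - 2 * p

  contrib <- function(candidate) {
    g_c <- calls$g[candidate, poly]
    both <- !is.na(g_o) & !is.na(g_c)
    if (!any(both)) {
      abort(paste0("No shared SNPs between ", offspring, " and ", candidate, "."))
    }
    num <- ifelse(both, z_o * (g_c - 2 * p), 0)
    den <- ifelse(both, w, 0)
    list(num = num, den = den)
  }
  best <- contrib(candidate_best)
  second <- contrib(candidate_second)

  n_snp <- length(p)
  withr_seed(seed, {
    wins <- 0
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_snp, n_snp, replace = TRUE)
      r_best <- sum(best$num[idx]) / sum(best$den[idx])
      r_second <- sum(second$num[idx]) / sum(second$den[idx])
      if (is.nan(r_best) || is.nan(r_second)) {
        wins <- wins + 0.5  # replicate hit an empty shared set; uninformative
      } else if (r_best > r_second) {
        wins <- wins + 1
      } else if (r_best == r_second) {
        wins <- wins + 0.5
      }
    }
    wins / n_boot
  })
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls do not disturb user RNG flow.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Write / read a relatedness matrix as TSV
#'
#' Tab-delimited with individual ids as both header and first column;
#' round-trips exactly at full double precision.
#'
#' @param grm A [build_grm()] result.
#' @param path Output file path.
#' @return `write_grm()` invisibly returns `path`; `read_grm()` returns a
#'   plain numeric matrix with id dimnames.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "gbs_grm"))
  df <- tibble::as_tibble(grm$r, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
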