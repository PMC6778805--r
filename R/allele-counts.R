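#' Allele count matrices
#'
#' The raw input of every analysis in gbsparent: a pair of non-negative
#' integer matrices (individuals in rows, SNPs in columns) holding reference
#' and alternate allele read counts. A cell with zero reads of both alleles is
#' the missing-data convention throughout; read depth is `ref + alt`.
#'
#' @param ref,alt Integer matrices of identical dimensions with unique row
#'   (individual) and column (SNP) names.
#' @return An `allele_counts` object.
#' @examples
#' ref <- matrix(c(3, 0, 0, 1), 2, 2,
#'               dimnames = list(c("i1", "i2"), c("s1", "s2")))
#' alt <- matrix(c(1, 0, 2, 1), 2, 2,
#'               dimnames = list(c("i1", "i2"), c("s1", "s2")))
#' allele_counts(ref, alt)
#' @export
allele_counts <- function(ref, alt) {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt))) {
    abort("`ref` and `alt` must have identical dimensions.")
  }
  if (is.null(rownames(ref)) || is.null(colnames(ref))) {
    abort("`ref` must have row (individual) and column (SNP) names.")
  }
  if (is.null(rownames(alt))) rownames(alt) <- rownames(ref)
  if (is.null(colnames(alt))) colnames(alt) <- colnames(ref)
  if (!identical(dimnames(ref), dimnames(alt))) {
    abort("`ref` and `alt` dimnames disagree.")
  }
  if (anyDuplicated(rownames(ref))) {
    abort(paste0("Duplicated individual ids: ",
                 paste(unique(rownames(ref)[duplicated(rownames(ref))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(ref))) {
    abort(paste0("Duplicated SNP ids: ",
                 paste(unique(colnames(ref)[duplicated(colnames(ref))]), collapse = ", ")))
  }
  if (anyNA(ref) || anyNA(alt)) abort("Counts must not be NA; missing cells are ref = alt = 0.")
  if (any(ref < 0) || any(alt < 0)) abort("Counts must be non-negative.")
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  structure(list(ref = ref, alt = alt), class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %d individuals x %d SNPs\n", nrow(x$ref), ncol(x$ref)))
  depth <- x$ref + x$alt
  cat(sprintf("  mean depth %.2f, call rate %.1f%%\n",
              mean(depth), 100 * mean(depth > 0)))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$ref)

individual_ids <- function(counts) rownames(counts$ref)
snp_ids <- function(counts) colnames(counts$ref)

subset_counts <- function(counts, individuals = NULL, snps = NULL) {
  i <- individuals %||% individual_ids(counts)
  s <- snps %||% snp_ids(counts)
  allele_counts(counts$ref[i, s, drop = FALSE], counts$alt[i, s, drop = FALSE])
}

#' Call apparent genotypes from allele counts
#'
#' Homozygotes are taken at face value; a heterozygote can masquerade as a
#' homozygote when only one allele happens to be read, so these are *apparent*
#' genotypes: `g = 2` when only reference reads are seen, `g = 0` when only
#' alternate reads, `g = 1` when both, and `NA` at depth zero. `g` counts
#' reference alleles in the apparent genotype.
#'
#' @param counts An [allele_counts()] object.
#' @return A `genotype_calls` object: list with integer matrix `g`
#'   (NA = missing) and integer depth matrix `depth` (`ref + alt`).
#' @examples
#' ref <- matrix(c(3L, 1L, 0L, 0L), 1, 4,
#'               dimnames = list("i1", paste0("s", 1:4)))
#' alt <- matrix(c(0L, 1L, 2L, 0L), 1, 4,
#'               dimnames = list("i1", paste0("s", 1:4)))
#' call_genotypes(allele_counts(ref, alt))$g
#' @export
call_genotypes <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  ref <- counts$ref
  alt <- counts$alt
  depth <- ref + alt
  g <- matrix(NA_integer_, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  g[ref > 0 & alt == 0] <- 2L
  g[ref > 0 & alt > 0] <- 1L
  g[ref == 0 & alt > 0] <- 0L
  structure(list(g = g, depth = depth), class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("<genotype_calls> %d individuals x %d SNPs, call rate %.1f%%\n",
              nrow(x$g), ncol(x$g), 100 * mean(!is.na(x$g))))
  invisible(x)
}

#' Estimate reference-allele frequencies from read counts
#'
#' Per SNP, the frequency is the reference read total divided by the overall
#' read total across the chosen individuals (each read counted once, so deep
#' samples carry more weight). SNPs with no reads at all are flagged unusable;
#' SNPs at frequency 0 or 1 are flagged monomorphic.
#'
#' @param counts An [allele_counts()] object.
#' @param individuals Optional character vector restricting the estimation
#'   group (e.g. one subpopulation). Default: all individuals.
#' @return A tibble with columns `snp_id`, `p`, `total_depth`, `usable`,
#'   `monomorphic`.
#' @examples
#' ref <- matrix(c(3L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' alt <- matrix(c(1L, 4L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' estimate_allele_freqs(allele_counts(ref, alt))  # p = 3/8
#' @export
estimate_allele_freqs <- function(counts, individuals = NULL) {
  stopifnot(inherits(counts, "allele_counts"))
  individuals <- individuals %||% individual_ids(counts)
  if (length(individuals) == 0) abort("Empty individual subset.")
  missing_ids <- setdiff(individuals, individual_ids(counts))
  if (length(missing_ids) > 0) {
    abort(paste0("Unknown individuals: ", paste(head(missing_ids, 5), collapse = ", ")))
  }
  ref <- unname(colSums(counts$ref[individuals, , drop = FALSE]))
  tot <- ref + unname(colSums(counts$alt[individuals, , drop = FALSE]))
  p <- ifelse(tot > 0, ref / tot, NA_real_)
  tibble::tibble(
    snp_id = snp_ids(counts),
    p = p,
    total_depth = as.integer(tot),
    usable = tot > 0,
    monomorphic = !is.na(p) & (p <= 0 | p >= 1)
  )
}

#' Hardy-Weinberg disequilibrium per SNP
#'
#' The observed frequency of the reference-allele homozygote (among
#' non-missing apparent calls) minus its Hardy-Weinberg expectation `p^2`.
#' Strongly negative values at high depth are the signature of collapsed
#' duplicated loci and are used as a filter (see [filter_snps()]); because
#' undetected heterozygotes inflate apparent homozygosity at low depth,
#' mildly positive values are normal for GBS data.
#'
#' @param calls A [call_genotypes()] result.
#' @param freqs An [estimate_allele_freqs()] tibble aligned to the same SNPs.
#' @return A tibble with `snp_id`, `d`, `n_called`. `d` is `NA` where no
#'   individual was called.
#' @export
hw_disequilibrium <- function(calls, freqs) {
  stopifnot(inherits(calls, "genotype_calls"))
  check_freqs_alignment(calls, freqs)
  n_called <- unname(colSums(!is.na(calls$g)))
  n_hom_ref <- unname(colSums(calls$g == 2L, na.rm = TRUE))
  d <- ifelse(n_called > 0, n_hom_ref / n_called - freqs$p^2, NA_real_)
  tibble::tibble(snp_id = colnames(calls$g), d = d, n_called = as.integer(n_called))
}

check_freqs_alignment <- function(calls, freqs) {
  if (!identical(freqs$snp_id, colnames(calls$g))) {
    abort("`freqs` must cover exactly the SNPs of `calls`, in order.")
  }
  invisible(TRUE)
}

#' Filter SNPs on Hardy-Weinberg disequilibrium and minor allele frequency
#'
#' Retains SNPs whose disequilibrium `d` is not below `hwdis_min` (the filter
#' removes SNPs *strictly below* the threshold, so `d = hwdis_min` is kept)
#' and whose minor allele frequency exceeds `maf_min`. With the default
#' `maf_min = 0` this discards monomorphic SNPs, which carry no parentage
#' information. SNPs with undefined `p` or `d` (no reads / no calls) are
#' dropped as unusable.
#'
#' @param calls A [call_genotypes()] result.
#' @param freqs Matching [estimate_allele_freqs()] tibble.
#' @param hwdis_min Lowest admissible disequilibrium (default -0.05).
#' @param maf_min Minor allele frequency must strictly exceed this (default 0).
#' @return A tibble with one row per SNP: `snp_id`, `p`, `maf`, `d`, `keep`,
#'   and `reason` (`NA` for retained SNPs). The per-rule exclusion counts are
#'   attached as attribute `"exclusions"`.
#' @export
filter_snps <- function(calls, freqs, hwdis_min = -0.05, maf_min = 0) {
  stopifnot(inherits(calls, "genotype_calls"))
  if (!is.numeric(hwdis_min) || length(hwdis_min) != 1 || hwdis_min > 0) {
    abort("`hwdis_min` must be a single non-positive number.")
  }
  if (!is.numeric(maf_min) || length(maf_min) != 1 || maf_min < 0 || maf_min >= 0.5) {
    abort("`maf_min` must be in [0, 0.5).")
  }
  hw <- hw_disequilibrium(calls, freqs)
  maf <- pmin(freqs$p, 1 - freqs$p)
  reason <- rep(NA_character_, nrow(freqs))
  reason[is.na(freqs$p) | is.na(hw$d)] <- "unusable"
  reason[is.na(reason) & maf <= maf_min] <- "maf"
  reason[is.na(reason) & hw$d < hwdis_min] <- "hw_disequilibrium"
  out <- tibble::tibble(
    snp_id = freqs$snp_id,
    p = freqs$p,
    maf = maf,
    d = hw$d,
    keep = is.na(reason),
    reason = reason
  )
  attr(out, "exclusions") <- dplyr::count(dplyr::filter(out, !.data$keep),
                                          .data$reason, name = "n_excluded")
  out
}
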