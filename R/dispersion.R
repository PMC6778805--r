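#' Estimate a read-overdispersion parameter from accepted trios
#'
#' Real GBS reads tend to cluster (the same allele is recruited repeatedly),
#' so observed mismatch rates of even *true* trios sit above binomial
#' expectations. The remedy: take trios accepted under the binomial model
#' (the conservative choice for expected mismatch rates), and choose the
#' overdispersion parameter — `alpha` for the beta-binomial family, `pprime`
#' for the modified-p family — that minimises the sum of squared deviations
#' of the trios' raw mismatch rates from their model-expected rates. Expected
#' rates are re-evaluated for each candidate parameter from the trios'
#' cached per-SNP frequency/depth/class data; only `K(k)` changes with the
#' parameter. Scalar minimisation uses [stats::optimize()] (on a log scale
#' for `alpha`).
#'
#' @param trios A list of [trio_mismatch_data()] results (the accepted trios).
#' @param family `"beta_binomial"` or `"modified_p"`.
#' @param bracket Search interval; defaults `[0.1, 1e6]` for `alpha`
#'   (log-scale search) and `[0.5, 0.999]` for `pprime`.
#' @param tol Convergence tolerance on the parameter.
#' @return A `dispersion_fit` object: `family`, `parameter`, `objective`
#'   (sum of squares at the optimum), `n_trios`, `bracket`, `at_edge`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_snps = 2000, n_sires = 5, n_dams = 5, n_offspring = 10,
#'                   model = read_model("beta_binomial", alpha = 4), seed = 1)
#' dat <- simulate_parentage_data(cfg)
#' calls <- call_genotypes(dat$counts)
#' freqs <- estimate_allele_freqs(dat$counts)
#' trios <- lapply(seq_len(10), function(i) {
#'   with(dat$truth[i, ], trio_mismatch_data(calls, freqs, offspring, sire, dam))
#' })
#' fit_dispersion(trios, "beta_binomial")
#' }
#' @export
fit_dispersion <- function(trios, family = c("beta_binomial", "modified_p"),
                           bracket = NULL, tol = 1e-6) {
  family <- match.arg(family)
  if (length(trios) == 0) abort("Need at least one accepted trio.")
  if (length(trios) < 2) {
    warn("Fewer than 2 trios; the fit is low-confidence.")
  }
  bracket <- bracket %||% switch(family,
    beta_binomial = c(0.1, 1e6),
    modified_p = c(0.5, 0.999))
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])

  # concatenate per-trio SNP data once; rowsum() by trio index per candidate
  snps <- dplyr::bind_rows(lapply(trios, `[[`, "snps"), .id = "trio")
  trio_idx <- as.integer(snps$trio)
  raw <- vapply(trios, `[[`, numeric(1), "raw_rate")
  n_per <- vapply(trios, `[[`, numeric(1), "n_compared")
  if (any(n_per == 0)) abort("A trio has no comparable SNPs.")

  objective <- function(theta) {
    m <- switch(family,
      beta_binomial = read_model("beta_binomial", alpha = theta),
      modified_p = read_model("modified_p", pprime = theta))
    prob <- trio_mismatch_prob(
      snps$p,
      k_prob_lookup(m, snps$k_f),
      k_prob_lookup(m, snps$k_m),
      k_prob_lookup(m, snps$k_o),
      snps$g_o
    )
    expected <- rowsum(prob, trio_idx)[, 1] / n_per
    sum((raw - expected)^2)
  }

  if (family == "beta_binomial") {
    opt <- optimize(function(lt) objective(exp(lt)), log(bracket), tol = tol)
    parameter <- exp(opt$minimum)
    edge_tol <- 1e-2  # on the log scale
    at_edge <- min(abs(log(parameter) - log(bracket))) < edge_tol
  } else {
    opt <- optimize(objective, bracket, tol = tol)
    parameter <- opt$minimum
    at_edge <- min(abs(parameter - bracket)) < 1e-4
  }
  if (at_edge) {
    warn(sprintf("Optimum at the %s bracket edge (%.4g); the %s model may be degenerate here.",
                 family, parameter, family))
  }
  structure(
    list(family = family, parameter = parameter, objective = opt$objective,
         n_trios = length(trios), bracket = bracket, at_edge = at_edge),
    class = "dispersion_fit"
  )
}

#' @export
print.dispersion_fit <- function(x, ...) {
  par_name <- if (x$family == "beta_binomial") "alpha" else "pprime"
  cat(sprintf("<dispersion_fit> %s: %s = %.4g (SS = %.4g over %d trios%s)\n",
              x$family, par_name, x$parameter, x$objective, x$n_trios,
              if (x$at_edge) ", at bracket edge" else ""))
  invisible(x)
}

#' @method tidy dispersion_fit
#' @export
tidy.dispersion_fit <- function(x, ...) {
  tibble::tibble(
    term = if (x$family == "beta_binomial") "alpha" else "pprime",
    estimate = x$parameter,
    family = x$family,
    at_edge = x$at_edge
  )
}

#' @method glance dispersion_fit
#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, parameter = x$parameter, objective = x$objective,
    n_trios = x$n_trios, at_edge = x$at_edge
  )
}

#' Fit both overdispersion families and recommend one
#'
#' Fits the beta-binomial and modified-p families to the same accepted trios
#' and recommends the family with the smaller sum of squared deviations.
#'
#' @inheritParams fit_dispersion
#' @return A `dispersion_comparison`: tibble `fits` (one row per family) and
#'   `recommended` (family name), with the fitted objects attached. The
#'   recommendation is flagged low-confidence below 2 trios.
#' @export
compare_families <- function(trios, tol = 1e-6) {
  fits <- list(
    beta_binomial = fit_dispersion(trios, "beta_binomial", tol = tol),
    modified_p = fit_dispersion(trios, "modified_p", tol = tol)
  )
  tbl <- dplyr::bind_rows(lapply(fits, glance))
  structure(
    list(fits = tbl, models = fits,
         recommended = tbl$family[which.min(tbl$objective)],
         low_confidence = length(trios) < 2),
    class = "dispersion_comparison"
  )
}

#' @export
print.dispersion_comparison <- function(x, ...) {
  cat("<dispersion_comparison>\n")
  print(x$fits)
  cat(sprintf("recommended: %s%s\n", x$recommended,
              if (x$low_confidence) " (low confidence: < 2 trios)" else ""))
  invisible(x)
}

#' @method tidy dispersion_comparison
#' @export
tidy.dispersion_comparison <- function(x, ...) x$fits
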