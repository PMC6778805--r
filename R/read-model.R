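#' Allele-sampling read models
#'
#' A read model specifies `K(k)`: the probability that a true heterozygote
#' shows *only* reference (equivalently, only alternate) alleles when read at
#' depth `k`. All supported families are symmetric in the two alleles and
#' give `K(1) = 0.5` — a single read can only ever show one allele.
#'
#' * `binomial`: reads sample alleles independently and fairly, `K = 1/2^k`.
#' * `beta_binomial`: the per-site read probability is drawn from a symmetric
#'   Beta(`alpha`, `alpha`) before binomial sampling, modelling hidden
#'   clustering of the alleles recruited for sequencing (e.g. PCR stacking);
#'   `K = Gamma(k + alpha) Gamma(2 alpha) / (Gamma(k + 2 alpha) Gamma(alpha))`.
#'   Approaches the binomial model as `alpha -> Inf`.
#' * `modified_p`: reads form a Markov chain — the first read is fair, each
#'   later read repeats the previous allele with probability `pprime`;
#'   `K = (1/2) pprime^(k-1)`. `pprime = 0.5` recovers the binomial model.
#'
#' @param family One of `"binomial"`, `"beta_binomial"`, `"modified_p"`.
#' @param alpha Beta-binomial overdispersion parameter (> 0); smaller means
#'   more clustered reads.
#' @param pprime Modified-p repeat probability, in `[0.5, 1)`.
#' @return A `read_model` object.
#' @seealso [k_probability()], [fit_dispersion()]
#' @examples
#' k_probability(read_model("binomial"), 1:4)
#' k_probability(read_model("beta_binomial", alpha = 1), 3)  # 1/(k+1) = 0.25
#' @export
read_model <- function(family = c("binomial", "beta_binomial", "modified_p"),
                       alpha = NULL, pprime = NULL) {
  family <- match.arg(family)
  if (family == "beta_binomial") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
      abort("`beta_binomial` requires a single `alpha` > 0.")
    }
  } else if (!is.null(alpha)) {
    abort("`alpha` only applies to the beta_binomial family.")
  }
  if (family == "modified_p") {
    if (is.null(pprime) || !is.numeric(pprime) || length(pprime) != 1 ||
        pprime < 0.5 || pprime >= 1) {
      abort("`modified_p` requires a single `pprime` in [0.5, 1).")
    }
  } else if (!is.null(pprime)) {
    abort("`pprime` only applies to the modified_p family.")
  }
  structure(list(family = family, alpha = alpha, pprime = pprime),
            class = "read_model")
}

#' @export
print.read_model <- function(x, ...) {
  par <- switch(x$family,
    binomial = "",
    beta_binomial = sprintf(" (alpha = %g)", x$alpha),
    modified_p = sprintf(" (pprime = %g)", x$pprime))
  cat(sprintf("<read_model> %s%s\n", x$family, par))
  invisible(x)
}

#' No-call probability K at read depth k
#'
#' Probability that a true heterozygote is observed as all-reference (or,
#' symmetrically, all-alternate) at depth `k`, under the model's closed form.
#' The beta-binomial form is evaluated in log-gamma space so large depths and
#' large `alpha` do not overflow.
#'
#' @param model A [read_model()].
#' @param k Integer vector of read depths, all >= 1.
#' @return Numeric vector of probabilities in (0, 0.5].
#' @export
k_probability <- function(model, k) {
  stopifnot(inherits(model, "read_model"))
  if (length(k) == 0) return(numeric(0))
  if (anyNA(k) || any(k < 1)) {
    abort("Read depths must all be >= 1; K is undefined at depth 0.")
  }
  switch(model$family,
    binomial = 0.5^k,
    beta_binomial = {
      a <- model$alpha
      exp(lgamma(k + a) + lgamma(2 * a) - lgamma(k + 2 * a) - lgamma(a))
    },
    modified_p = 0.5 * model$pprime^(k - 1)
  )
}

# K looked up from a table over depths 1..k_max; depths beyond the cap fall
# back to the closed form. Exact (the table is the closed form), just faster
# inside all-SNP scans where depths are small integers.
k_prob_lookup <- function(model, depth, k_max = 500L) {
  kk <- depth
  top <- max(kk)
  if (top <= k_max) {
    k_probability(model, seq_len(top))[kk]
  } else {
    out <- numeric(length(kk))
    small <- kk <= k_max
    tab <- k_probability(model, seq_len(k_max))
    out[small] <- tab[kk[small]]
    out[!small] <- k_probability(model, kk[!small])
    out
  }
}
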