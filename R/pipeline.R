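#' Run the full parentage pipeline
#'
#' Filter SNPs (Hardy-Weinberg disequilibrium and minor allele frequency),
#' estimate allele frequencies — either combined across all individuals or
#' separately per subpopulation — build the genomic relatedness matrix,
#' compute its principal components as a structure diagnostic, and assign
#' parentage. In per-subpopulation mode each subpopulation is analysed with
#' its own frequencies, and the zero-MAF discard is re-applied within the
#' subpopulation (a SNP fixed within a herd is uninformative there even if
#' polymorphic overall).
#'
#' @param counts An [allele_counts()] object.
#' @param candidates A [candidate_table()]; per-subpopulation mode uses its
#'   `subpop` column.
#' @param freq_mode `"combined"` or `"per_subpopulation"`.
#' @param model A [read_model()].
#' @param thresholds An [assignment_thresholds()].
#' @param hwdis_min,maf_min SNP filter settings (see [filter_snps()]).
#' @param mode,sexes Passed to [assign_parentage()].
#' @param seed Integer seed.
#' @param output_dir If non-NULL, writes the assignment report, GRM, PCA
#'   scores, SNP filter table and the resolved configuration (JSON) there.
#' @return A `gbs_pipeline` list: `config`, `filter` (per-SNP filter table),
#'   `freqs` (combined mode) or `freqs_by_subpop`, `grm`, `pca`,
#'   `assignments`.
#' @export
run_pipeline <- function(counts, candidates,
                         freq_mode = c("combined", "per_subpopulation"),
                         model = read_model("binomial"),
                         thresholds = assignment_thresholds(),
                         hwdis_min = -0.05, maf_min = 0,
                         mode = "assign", sexes = "both",
                         seed = 1L, output_dir = NULL) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(inherits(counts, "allele_counts"))
  candidates <- validate_candidates(
    candidate_table(as.data.frame(candidates), allow_sex_overlap = TRUE), counts)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  calls <- stage("genotype_calling", call_genotypes(counts))
  freqs_all <- stage("allele_frequencies", estimate_allele_freqs(counts))
  flt <- stage("snp_filter",
               filter_snps(calls, freqs_all, hwdis_min = hwdis_min, maf_min = maf_min))
  keep_snps <- flt$snp_id[flt$keep]
  counts_f <- subset_counts(counts, snps = keep_snps)
  calls_f <- call_genotypes(counts_f)
  freqs_f <- freqs_all[match(keep_snps, freqs_all$snp_id), ]

  grm <- stage("grm", build_grm(calls_f, freqs_f, model))
  pca <- stage("pca", grm_pca(grm))

  config <- list(
    freq_mode = freq_mode, model = model$family,
    model_parameter = model$alpha %||% model$pprime,
    hwdis_min = hwdis_min, maf_min = maf_min,
    thresholds = unclass(thresholds), mode = mode, sexes = sexes, seed = seed,
    n_individuals = nrow(counts$ref), n_snps_input = ncol(counts$ref),
    n_snps_retained = length(keep_snps)
  )

  if (freq_mode == "combined") {
    assignments <- stage("assignment",
      assign_parentage(counts_f, candidates, freqs = freqs_f, model = model,
                       thresholds = thresholds, mode = mode, sexes = sexes,
                       grm = grm, seed = seed))
    freqs_by_subpop <- NULL
  } else {
    subpops <- candidates$subpop[match(individual_ids(counts_f), candidates$id)]
    if (all(is.na(subpops))) {
      abort("Pipeline stage 'assignment' failed: per_subpopulation mode needs a subpop column.")
    }
    freqs_by_subpop <- list()
    parts <- list()
    for (sp in sort(unique(stats::na.omit(subpops)))) {
      ids <- individual_ids(counts_f)[!is.na(subpops) & subpops == sp]
      freqs_sp <- estimate_allele_freqs(counts_f, individuals = ids)
      # re-apply the zero-MAF discard within the subpopulation
      usable <- freqs_sp$usable & !freqs_sp$monomorphic &
        pmin(freqs_sp$p, 1 - freqs_sp$p) > maf_min
      counts_sp <- subset_counts(counts_f, individuals = ids,
                                 snps = freqs_sp$snp_id[usable])
      freqs_sp <- freqs_sp[usable, ]
      cand_sp <- candidates[candidates$id %in% ids, ]
      freqs_by_subpop[[sp]] <- freqs_sp
      parts[[sp]] <- stage(paste0("assignment_", sp),
        assign_parentage(counts_sp, cand_sp, freqs = freqs_sp, model = model,
                         thresholds = thresholds, mode = mode, sexes = sexes,
                         seed = seed))
    }
    assignments <- dplyr::bind_rows(parts, .id = "subpop")
    attr(assignments, "thresholds") <- unclass(thresholds)
    class(assignments) <- c("parentage_assignments", class(assignments))
  }

  result <- structure(
    list(config = config, filter = flt,
         freqs = if (freq_mode == "combined") freqs_f else NULL,
         freqs_by_subpop = freqs_by_subpop,
         grm = grm, pca = pca, assignments = assignments),
    class = "gbs_pipeline"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_assignments(assignments, file.path(output_dir, "assignments.tsv"))
    write_grm(grm, file.path(output_dir, "grm.tsv"))
    readr::write_tsv(pca$scores, file.path(output_dir, "pca_scores.tsv"),
                     progress = FALSE)
    readr::write_tsv(flt, file.path(output_dir, "snp_filter.tsv"),
                     progress = FALSE)
    jsonlite::write_json(config, file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.gbs_pipeline <- function(x, ...) {
  cat(sprintf("<gbs_pipeline> %s frequencies, %s read model\n",
              x$config$freq_mode, x$config$model))
  cat(sprintf("  SNPs: %d in, %d retained; PC1 %.1f%% of variation\n",
              x$config$n_snps_input, x$config$n_snps_retained,
              100 * x$pca$prop_var[1]))
  print(glance(x$assignments))
  invisible(x)
}

#' Metric distribution tables for threshold tuning
#'
#' Histograms (as tibbles, not figures) of best-candidate relatedness, pair
#' excess mismatch and trio excess mismatch across an assignment run — the
#' distributions one inspects to choose thresholds.
#'
#' @param assignments A `parentage_assignments` tibble.
#' @param binwidths Named list of bin widths (`r`, `emm`, `trio_emm`).
#' @return A tibble: `metric`, `bin_lower`, `bin_upper`, `n`.
#' @export
metric_distributions <- function(assignments,
                                 binwidths = list(r = 0.05, emm = 0.005,
                                                  trio_emm = 0.005)) {
  one <- function(vals, width, name) {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NULL)
    lo <- floor(min(vals) / width) * width
    breaks <- seq(lo, max(vals) + width, by = width)
    cut_idx <- findInterval(vals, breaks, rightmost.closed = TRUE)
    tibble::tibble(
      metric = name,
      bin_lower = breaks[sort(unique(cut_idx))],
      bin_upper = breaks[sort(unique(cut_idx)) + 1],
      n = as.integer(table(cut_idx))
    )
  }
  dplyr::bind_rows(
    one(c(assignments$sire_r, assignments$dam_r), binwidths$r, "relatedness"),
    one(c(assignments$sire_emm, assignments$dam_emm), binwidths$emm, "pair_emm"),
    one(assignments$trio_emm, binwidths$trio_emm, "trio_emm")
  )
}
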