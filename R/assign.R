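#' Assignment thresholds
#'
#' All decision rules of the assignment strategy in one place. Comparisons
#' are inclusive: a candidate passes at exactly `rel_min` or exactly
#' `emm_max`. Defaults are the working thresholds of a typical livestock
#' analysis: relatedness at least 0.4 (a parent-offspring pair sits near 0.5
#' or above), pair excess mismatch at most 0.01, trio excess mismatch at most
#' 0.02 (looser, because any of three genotypes can contribute an error),
#' candidates within 0.05 relatedness of each other are "too close" and go to
#' the bootstrap with a conservative 0.99 support requirement, and a parent
#' pair is rejected when the parents' relatedness exceeds twice the
#' offspring's inbreeding estimate by more than 0.2.
#'
#' @param rel_min Minimum best-candidate relatedness.
#' @param emm_max Maximum pair excess mismatch rate.
#' @param trio_emm_max Maximum trio excess mismatch rate.
#' @param closeness_window Relatedness gap below which the runner-up is "too
#'   close" and bootstrap support is required.
#' @param bootstrap_min Minimum bootstrap support to keep a close call.
#' @param inbreeding_diff_max Maximum admissible `r_FM - 2 F_O` (upper bound
#'   only; low values are fine).
#' @param n_boot Bootstrap replicates.
#' @param n_alternates Candidates per sex examined in the alternate search.
#' @return A `gbs_thresholds` list.
#' @export
assignment_thresholds <- function(rel_min = 0.4, emm_max = 0.01,
                                  trio_emm_max = 0.02, closeness_window = 0.05,
                                  bootstrap_min = 0.99,
                                  inbreeding_diff_max = 0.2,
                                  n_boot = 1000, n_alternates = 2) {
  stopifnot(
    is.finite(rel_min),
    emm_max >= -1, emm_max <= 1, trio_emm_max >= -1, trio_emm_max <= 1,
    closeness_window >= 0, bootstrap_min >= 0, bootstrap_min <= 1,
    is.finite(inbreeding_diff_max), n_boot >= 1, n_alternates >= 1
  )
  structure(
    list(rel_min = rel_min, emm_max = emm_max, trio_emm_max = trio_emm_max,
         closeness_window = closeness_window, bootstrap_min = bootstrap_min,
         inbreeding_diff_max = inbreeding_diff_max,
         n_boot = as.integer(n_boot), n_alternates = as.integer(n_alternates)),
    class = "gbs_thresholds"
  )
}

#' Rank candidate parents by relatedness
#'
#' Orders a candidate set by estimated relatedness to the offspring,
#' descending; exact ties are flagged and broken deterministically by
#' candidate id. Candidates sharing no SNPs with the offspring are dropped.
#'
#' @param grm A [build_grm()] result covering offspring and candidates.
#' @param offspring Offspring id.
#' @param candidates Character vector of candidate ids.
#' @return A tibble `candidate_id`, `r`, `n_snps`, `tied`, best first.
#' @export
rank_candidates <- function(grm, offspring, candidates) {
  stopifnot(inherits(grm, "gbs_grm"))
  candidates <- setdiff(intersect(candidates, grm$ids), offspring)
  if (length(candidates) == 0) {
    return(tibble::tibble(candidate_id = character(0), r = numeric(0),
                          n_snps = integer(0), tied = logical(0)))
  }
  r <- grm$r[offspring, candidates]
  n <- grm$n_snps[offspring, candidates]
  keep <- !is.na(r) & n > 0
  out <- tibble::tibble(candidate_id = candidates[keep], r = unname(r[keep]),
                        n_snps = unname(n[keep]))
  out <- dplyr::arrange(out, dplyr::desc(.data$r), .data$candidate_id)
  out$tied <- duplicated(out$r) | duplicated(out$r, fromLast = TRUE)
  out
}

#' Pair-level threshold check
#'
#' A single-parent assignment passes when relatedness is at least `rel_min`
#' and the pair excess mismatch rate at most `emm_max` (both inclusive).
#'
#' @param r Best-candidate relatedness.
#' @param emm Pair excess mismatch rate.
#' @param thresholds An [assignment_thresholds()].
#' @return A list: `pass` (logical) and `reasons` (character, empty on pass).
#' @export
apply_pair_thresholds <- function(r, emm, thresholds = assignment_thresholds()) {
  reasons <- character(0)
  if (is.na(r) || r < thresholds$rel_min) reasons <- c(reasons, "relatedness_low")
  if (is.na(emm) || emm > thresholds$emm_max) reasons <- c(reasons, "emm_high")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Resolve two close candidates by bootstrap
#'
#' If the best and second-best candidates' relatedness differ by at least the
#' closeness window, the best is kept outright (no bootstrap run). Otherwise
#' SNPs are resampled ([bootstrap_support()]) and the assignment is kept only
#' if the best candidate wins at least `bootstrap_min` of the replicates.
#'
#' @param calls,freqs Data for [bootstrap_support()].
#' @param offspring,best,second Individual ids.
#' @param gap `r_best - r_second`.
#' @param thresholds An [assignment_thresholds()].
#' @param seed Integer seed for the bootstrap stream.
#' @return A list: `keep`, `support` (NA when no bootstrap was needed).
#' @export
resolve_close_candidates <- function(calls, freqs, offspring, best, second, gap,
                                     thresholds = assignment_thresholds(), seed) {
  if (is.na(gap) || gap >= thresholds$closeness_window) {
    return(list(keep = TRUE, support = NA_real_))
  }
  support <- bootstrap_support(calls, freqs, offspring, best, second,
                               n_boot = thresholds$n_boot, seed = seed)
  list(keep = support >= thresholds$bootstrap_min, support = support)
}

#' Trio consistency checks
#'
#' A provisional parent pair must have (i) a trio excess mismatch rate no
#' greater than `trio_emm_max`, and (ii) parents not substantially more
#' related to each other than the offspring's inbreeding explains:
#' `r_FM - 2 F_O <= inbreeding_diff_max`. Only the upper bound of the
#' inbreeding check is enforced — the damaging error mode is a wrong parent
#' that is a close relative of the correct one. When the offspring's
#' inbreeding estimate is undefined (no SNPs at depth >= 2) the inbreeding
#' check is skipped with a warning.
#'
#' @param trio_emm Trio excess mismatch rate.
#' @param r_fm Relatedness between the putative parents.
#' @param f_o Offspring inbreeding estimate (may be NA).
#' @param thresholds An [assignment_thresholds()].
#' @return A list: `pass`, `fail_code` (`"E"`, `"I"` or NA), `value`
#'   (`r_fm - 2 f_o`).
#' @export
trio_checks <- function(trio_emm, r_fm, f_o,
                        thresholds = assignment_thresholds()) {
  emm_fail <- !is.na(trio_emm) && trio_emm > thresholds$trio_emm_max
  value <- r_fm - 2 * f_o
  if (is.na(f_o)) {
    warn("Offspring inbreeding undefined (no depth >= 2 SNPs); inbreeding check skipped.")
    inb_fail <- FALSE
    value <- NA_real_
  } else {
    inb_fail <- !is.na(value) && value > thresholds$inbreeding_diff_max
  }
  list(
    pass = !emm_fail && !inb_fail,
    fail_code = if (emm_fail) "E" else if (inb_fail) "I" else NA_character_,
    value = value
  )
}

# Evaluate top-n_alternates sire x dam combinations after the best pair
# failed a trio check. Combinations must pass pair thresholds per member and
# the trio checks; the passing combination with the lowest trio EMM wins.
search_alternates <- function(calls, freqs, model, offspring, sire_tbl, dam_tbl,
                              f_o, grm, thresholds) {
  n_s <- min(nrow(sire_tbl), thresholds$n_alternates)
  n_d <- min(nrow(dam_tbl), thresholds$n_alternates)
  best <- NULL
  for (i in seq_len(n_s)) {
    for (j in seq_len(n_d)) {
      sire <- sire_tbl$candidate_id[i]
      dam <- dam_tbl$candidate_id[j]
      if (sire == dam) next  # one individual cannot be both parents
      ok_s <- apply_pair_thresholds(sire_tbl$r[i], sire_tbl$emm[i], thresholds)
      ok_d <- apply_pair_thresholds(dam_tbl$r[j], dam_tbl$emm[j], thresholds)
      if (!ok_s$pass || !ok_d$pass) next
      trio <- trio_mismatch_stats(calls, freqs, offspring, sire, dam, model)
      checks <- trio_checks(trio$emm, grm$r[sire, dam], f_o, thresholds)
      if (!checks$pass) next
      if (is.null(best) || trio$emm < best$trio_emm) {
        best <- list(sire_idx = i, dam_idx = j, sire = sire, dam = dam,
                     trio_emm = trio$emm, value = checks$value)
      }
    }
  }
  best
}

empty_sex_cols <- function(prefix) {
  setNames(
    list(NA_character_, NA_real_, NA_real_, NA_character_, NA_real_, NA_real_, FALSE),
    paste0(prefix, c("", "_r", "_emm", "_second", "_gap", "_support", "_pass"))
  )
}

# Evaluate one sex for one offspring: rank, EMM for top candidates, pair
# thresholds + closeness resolution for the best. Returns the augmented
# ranking table and the per-record fields. With rank_by = "emm" every
# candidate's pair EMM is computed and "best" means lowest EMM (relatedness
# stays a veto); the SNP bootstrap is specific to relatedness ranking and is
# not applied in that mode.
evaluate_sex <- function(calls, freqs, model, grm, offspring, candidate_ids,
                         thresholds, seed, prefix, rank_by = "relatedness") {
  ranked <- rank_candidates(grm, offspring, candidate_ids)
  fields <- empty_sex_cols(prefix)
  if (nrow(ranked) == 0) {
    return(list(ranked = ranked, fields = fields, assigned = FALSE))
  }
  if (rank_by == "emm") {
    ranked$emm <- vapply(ranked$candidate_id, function(cand) {
      pair_mismatch_stats(calls, freqs, offspring, cand, model)$emm
    }, numeric(1))
    ranked <- dplyr::arrange(ranked, .data$emm, .data$candidate_id)
    ranked$tied <- duplicated(ranked$emm) | duplicated(ranked$emm, fromLast = TRUE)
  } else {
    n_eval <- min(nrow(ranked), thresholds$n_alternates)
    ranked$emm <- NA_real_
    for (i in seq_len(n_eval)) {
      ranked$emm[i] <- pair_mismatch_stats(calls, freqs, offspring,
                                           ranked$candidate_id[i], model)$emm
    }
  }
  gap <- if (nrow(ranked) >= 2) ranked$r[1] - ranked$r[2] else Inf
  ok <- apply_pair_thresholds(ranked$r[1], ranked$emm[1], thresholds)
  support <- NA_real_
  keep <- TRUE
  if (rank_by == "relatedness" && ok$pass && nrow(ranked) >= 2) {
    res <- resolve_close_candidates(calls, freqs, offspring,
                                    ranked$candidate_id[1],
                                    ranked$candidate_id[2],
                                    gap, thresholds, seed)
    keep <- res$keep
    support <- res$support
  }
  fields[[paste0(prefix, "")]] <- ranked$candidate_id[1]
  fields[[paste0(prefix, "_r")]] <- ranked$r[1]
  fields[[paste0(prefix, "_emm")]] <- ranked$emm[1]
  fields[[paste0(prefix, "_second")]] <- if (nrow(ranked) >= 2) ranked$candidate_id[2] else NA_character_
  fields[[paste0(prefix, "_gap")]] <- if (is.finite(gap)) gap else NA_real_
  fields[[paste0(prefix, "_support")]] <- support
  fields[[paste0(prefix, "_pass")]] <- ok$pass && keep
  list(ranked = ranked, fields = fields, assigned = ok$pass && keep)
}

#' Assign parentage for every offspring
#'
#' Runs the full strategy per offspring: (1) rank candidate fathers by
#' relatedness, (2) rank candidate mothers, (3) veto best candidates whose
#' relatedness is too low or pair excess mismatch too high, (4) resolve
#' too-close runner-ups by SNP bootstrap, (5) check the combined trio (trio
#' excess mismatch, and parent relatedness against twice the offspring
#' inbreeding). If the best pair fails a trio check, combinations of the top
#' candidates per sex are searched for the lowest-trio-EMM pair passing all
#' checks (code `A` when that differs from the best-relatedness pair).
#'
#' Decision codes: `Y` both parents assigned; `A` an alternate (non-best)
#' pair assigned; `E` trio excess mismatch too high, no rescue; `I`
#' inbreeding check failed, no rescue; `F`/`M` father/mother only; `N`
#' neither.
#'
#' @param counts An [allele_counts()] object.
#' @param candidates A [candidate_table()].
#' @param freqs Allele frequencies; default: estimated from all individuals
#'   in `counts` and filtered with [filter_snps()] defaults.
#' @param model A [read_model()] for expected mismatch rates and the GRM
#'   diagonal.
#' @param thresholds An [assignment_thresholds()].
#' @param mode `"assign"` matches against the full candidate sets;
#'   `"verify"` restricts each offspring's candidate sets to its recorded
#'   parents.
#' @param sexes Assign `"both"` parents (with trio checks) or a single sex
#'   (`"sire"` / `"dam"`; trio-level steps are skipped).
#' @param rank_by `"relatedness"` (default: relatedness ranks, EMM vetoes) or
#'   `"emm"` (lowest pair EMM ranks, relatedness vetoes; the SNP bootstrap —
#'   a relatedness-resampling device — is not applied in this mode).
#' @param grm Optionally a precomputed [build_grm()] over the same filtered
#'   SNP set.
#' @param seed Integer seed driving the bootstrap streams.
#' @return A `parentage_assignments` tibble, one row per offspring, with the
#'   thresholds attached as attribute `"thresholds"`.
#' @export
assign_parentage <- function(counts, candidates, freqs = NULL,
                             model = read_model("binomial"),
                             thresholds = assignment_thresholds(),
                             mode = c("assign", "verify"),
                             sexes = c("both", "sire", "dam"),
                             rank_by = c("relatedness", "emm"),
                             grm = NULL, seed = 1L) {
  mode <- match.arg(mode)
  sexes <- match.arg(sexes)
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(counts, "allele_counts"))
  candidates <- validate_candidates(candidate_table(as.data.frame(candidates),
                                                    allow_sex_overlap = TRUE),
                                    counts)

  calls <- call_genotypes(counts)
  if (is.null(freqs)) {
    freqs <- estimate_allele_freqs(counts)
    flt <- filter_snps(calls, freqs)
    keep_snps <- flt$snp_id[flt$keep]
    counts <- subset_counts(counts, snps = keep_snps)
    calls <- call_genotypes(counts)
    freqs <- freqs[match(keep_snps, freqs$snp_id), ]
  }
  check_freqs_alignment(calls, freqs)
  if (is.null(grm)) grm <- build_grm(calls, freqs, model)

  offspring_ids <- candidates$id[candidates$role == "offspring" & candidates$genotyped]
  sire_pool <- candidates$id[candidates$role == "sire_candidate" & candidates$genotyped]
  dam_pool <- candidates$id[candidates$role == "dam_candidate" & candidates$genotyped]

  records <- vector("list", length(offspring_ids))
  for (oi in seq_along(offspring_ids)) {
    o <- offspring_ids[oi]
    rec <- tryCatch(
      assign_one(calls, freqs, model, grm, o, candidates, sire_pool, dam_pool,
                 thresholds, mode, sexes, rank_by, seed = seed + oi),
      error = function(e) {
        warn(sprintf("Assignment failed for %s: %s", o, conditionMessage(e)))
        tibble::tibble(offspring = o, code = NA_character_)
      }
    )
    records[[oi]] <- rec
  }
  out <- dplyr::bind_rows(records)
  attr(out, "thresholds") <- unclass(thresholds)
  attr(out, "model") <- model$family
  class(out) <- c("parentage_assignments", class(out))
  out
}

assign_one <- function(calls, freqs, model, grm, offspring, candidates,
                       sire_pool, dam_pool, thresholds, mode, sexes, rank_by,
                       seed) {
  if (mode == "verify") {
    row <- candidates[candidates$id == offspring & candidates$role == "offspring", ]
    sire_pool <- intersect(row$recorded_sire, sire_pool)
    dam_pool <- intersect(row$recorded_dam, dam_pool)
  }
  do_sire <- sexes %in% c("both", "sire")
  do_dam <- sexes %in% c("both", "dam")

  sire <- if (do_sire) {
    evaluate_sex(calls, freqs, model, grm, offspring, sire_pool, thresholds,
                 seed, "sire", rank_by)
  } else {
    list(ranked = NULL, fields = empty_sex_cols("sire"), assigned = FALSE)
  }
  dam <- if (do_dam) {
    evaluate_sex(calls, freqs, model, grm, offspring, dam_pool, thresholds,
                 seed + 100000L, "dam", rank_by)
  } else {
    list(ranked = NULL, fields = empty_sex_cols("dam"), assigned = FALSE)
  }

  rec <- tibble::as_tibble(c(list(offspring = offspring), sire$fields, dam$fields))
  rec$trio_emm <- NA_real_
  rec$r_fm <- NA_real_
  rec$f_o <- NA_real_
  rec$inbreeding_check <- NA_real_

  if (sexes != "both") {
    rec$code <- if (sire$assigned) "F" else if (dam$assigned) "M" else "N"
    return(finalize_record(rec, sexes))
  }

  if (sire$assigned && dam$assigned) {
    s1 <- rec$sire; d1 <- rec$dam
    if (s1 == d1) {
      # same individual topped both candidate sets; cannot be both parents
      rec$code <- "N"
      return(rec)
    }
    trio <- trio_mismatch_stats(calls, freqs, offspring, s1, d1, model)
    f_o <- grm$r[offspring, offspring] - 1
    checks <- trio_checks(trio$emm, grm$r[s1, d1], f_o, thresholds)
    rec$trio_emm <- trio$emm
    rec$r_fm <- grm$r[s1, d1]
    rec$f_o <- f_o
    rec$inbreeding_check <- checks$value
    if (checks$pass) {
      rec$code <- "Y"
      return(rec)
    }
    alt <- search_alternates(calls, freqs, model, offspring,
                             sire$ranked, dam$ranked, f_o, grm, thresholds)
    if (!is.null(alt)) {
      rec$sire <- alt$sire
      rec$sire_r <- sire$ranked$r[alt$sire_idx]
      rec$sire_emm <- sire$ranked$emm[alt$sire_idx]
      rec$dam <- alt$dam
      rec$dam_r <- dam$ranked$r[alt$dam_idx]
      rec$dam_emm <- dam$ranked$emm[alt$dam_idx]
      rec$trio_emm <- alt$trio_emm
      rec$r_fm <- grm$r[alt$sire, alt$dam]
      rec$inbreeding_check <- alt$value
      rec$code <- "A"
      return(rec)
    }
    rec$code <- checks$fail_code  # E or I: pair rejected, parent at fault unknown
    return(rec)
  }
  rec$code <- if (sire$assigned) "F" else if (dam$assigned) "M" else "N"
  rec
}

finalize_record <- function(rec, sexes) {
  rec
}

#' @export
print.parentage_assignments <- function(x, ...) {
  cat(sprintf("<parentage_assignments> %d offspring\n", nrow(x)))
  print(table(code = x$code, useNA = "ifany"))
  NextMethod()
}

#' Summarise an assignment run
#'
#' One row: offspring counts per decision code plus overall assignment rate
#' (codes Y and A).
#'
#' @param x A `parentage_assignments` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance parentage_assignments
#' @export
glance.parentage_assignments <- function(x, ...) {
  codes <- c("Y", "A", "I", "E", "F", "M", "N")
  counts <- vapply(codes, function(cc) sum(x$code == cc, na.rm = TRUE), integer(1))
  out <- tibble::as_tibble(as.list(setNames(counts, paste0("n_", codes))))
  out$n_offspring <- nrow(x)
  out$assignment_rate <- if (nrow(x) > 0) (counts[["Y"]] + counts[["A"]]) / nrow(x) else NA_real_
  out
}
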