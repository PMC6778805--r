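#' Candidate-parent table
#'
#' Declares which individuals are offspring and which are candidate sires /
#' dams, with an optional subpopulation label and optional recorded parents
#' (used by verification mode). Candidate sets are global per role, as in a
#' herd where any listed sire could in principle have fathered any offspring.
#'
#' @param x A data frame with columns `id`, `role` (one of `offspring`,
#'   `sire_candidate`, `dam_candidate`) and optionally `subpop`,
#'   `recorded_sire`, `recorded_dam`. An individual may appear once per role.
#' @param allow_sex_overlap Permit the same id in both the sire and dam
#'   candidate sets (default FALSE).
#' @return A `candidate_table` tibble.
#' @export
candidate_table <- function(x, allow_sex_overlap = FALSE) {
  x <- tibble::as_tibble(x)
  required <- c("id", "role")
  if (!all(required %in% names(x))) {
    abort("Candidate table needs columns `id` and `role`.")
  }
  ok_roles <- c("offspring", "sire_candidate", "dam_candidate")
  bad <- setdiff(unique(x$role), ok_roles)
  if (length(bad) > 0) {
    abort(paste0("Unknown role token(s): ", paste(bad, collapse = ", "),
                 ". Expected: ", paste(ok_roles, collapse = ", "), "."))
  }
  dup <- x[duplicated(x[c("id", "role")]), ]
  if (nrow(dup) > 0) {
    abort(paste0("Duplicated ", dup$role[1], " row for id: ", dup$id[1]))
  }
  sires <- x$id[x$role == "sire_candidate"]
  dams <- x$id[x$role == "dam_candidate"]
  overlap <- intersect(sires, dams)
  if (length(overlap) > 0 && !allow_sex_overlap) {
    abort(paste0("Ids in both sire and dam candidate sets (set ",
                 "`allow_sex_overlap = TRUE` to permit): ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  for (col in c("subpop", "recorded_sire", "recorded_dam")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  out <- x[c("id", "role", "subpop", "recorded_sire", "recorded_dam")]
  if (sum(out$role == "offspring") > 0 &&
      (length(sires) == 0 || length(dams) == 0)) {
    warn("Offspring present but a candidate set is empty.")
  }
  class(out) <- c("candidate_table", class(out))
  out
}

#' Read a candidate-parent table from a delimited file
#'
#' Comma- or tab-delimited, with a header naming at least `id` and `role`;
#' see [candidate_table()] for the accepted columns and role tokens.
#'
#' @param path File path.
#' @param allow_sex_overlap Passed to [candidate_table()].
#' @return A `candidate_table` tibble.
#' @export
read_candidates <- function(path, allow_sex_overlap = FALSE) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  candidate_table(tbl, allow_sex_overlap = allow_sex_overlap)
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Flag candidate-table ids missing from the genotype data
#'
#' Individuals listed in the candidate table but absent from the count matrix
#' (unavailable or not successfully genotyped) are flagged and excluded from
#' matching by the assignment routines.
#'
#' @param candidates A [candidate_table()].
#' @param counts An [allele_counts()] object.
#' @return The candidate table with a logical `genotyped` column.
#' @export
validate_candidates <- function(candidates, counts) {
  stopifnot(inherits(candidates, "candidate_table"),
            inherits(counts, "allele_counts"))
  candidates$genotyped <- candidates$id %in% individual_ids(counts)
  n_missing <- sum(!candidates$genotyped)
  if (n_missing > 0) {
    inform(sprintf("%d candidate-table id(s) not genotyped; excluded from matching.",
                   n_missing))
  }
  candidates
}

# Trailing per-SNP summary columns commonly appended by Tassel/UNEAK hmc
# output; matched case-insensitively and skipped.
default_hmc_summary_cols <- c(
  "HetCount_allele1", "HetCount_allele2", "Count_allele1", "Count_allele2",
  "Frequency", "alleles", "chrom", "pos", "strand", "assembly#", "center",
  "protLSID", "assayLSID", "panelLSID", "QCcode"
)

#' Read a Tassel/UNEAK HapMap hmc allele-count table
#'
#' Tab-delimited, optionally gzipped; first column is the SNP identifier,
#' sample columns encode counts as `"ref|alt"`, and trailing per-SNP summary
#' columns (recognised by header name, configurable) are skipped. The first
#' count of each cell is taken as the reference allele throughout the
#' package. Unknown trailing columns whose cells are not `"int|int"` tokens
#' are dropped with a warning rather than silently included.
#'
#' @param path File path (`.gz` handled transparently).
#' @param summary_cols Header names (case-insensitive) of non-sample columns
#'   to skip.
#' @return An [allele_counts()] object, transposed to individuals x SNPs.
#' @export
read_hmc <- function(path, summary_cols = default_hmc_summary_cols) {
  raw_header <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(raw_header)) {
    abort(paste0("Duplicate sample header: ",
                 raw_header[duplicated(raw_header)][1]))
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tbl) < 2) abort("hmc file has no sample columns.")
  headers <- names(tbl)
  is_summary <- tolower(headers) %in% tolower(summary_cols)
  is_summary[1] <- FALSE
  candidate_cols <- which(!is_summary)[-1]

  token_re <- "^[0-9]+\\|[0-9]+$"
  conforms <- vapply(candidate_cols, function(j) {
    all(grepl(token_re, tbl[[j]]))
  }, logical(1))

  if (!all(conforms)) {
    bad <- candidate_cols[!conforms]
    # a column where *no* cell is a count token and which sits at the trailing
    # edge is an unrecognised summary column; a column with a mix of valid and
    # invalid tokens is malformed sample data
    all_noncount <- vapply(bad, function(j) !any(grepl(token_re, tbl[[j]])), logical(1))
    is_trailing <- vapply(bad, function(j) all(seq(j, ncol(tbl)) %in%
                                                 c(bad, which(is_summary))), logical(1))
    malformed <- bad[!(all_noncount & is_trailing)]
    if (length(malformed) > 0) {
      j <- malformed[1]
      i <- which(!grepl(token_re, tbl[[j]]))[1]
      abort(sprintf(
        "Malformed count token '%s' at SNP '%s', column '%s' (expected 'int|int').",
        tbl[[j]][i], tbl[[1]][i], headers[j]))
    }
    warn(paste0("Unknown trailing non-count column(s) skipped: ",
                paste(headers[bad], collapse = ", ")))
    candidate_cols <- setdiff(candidate_cols, bad)
  }
  if (length(candidate_cols) == 0) abort("hmc file has no sample columns.")

  snps <- tbl[[1]]
  if (anyDuplicated(snps)) {
    abort(paste0("Duplicated SNP identifier: ", snps[duplicated(snps)][1]))
  }
  samples <- headers[candidate_cols]
  n_snp <- length(snps)
  ref <- matrix(0L, length(samples), n_snp, dimnames = list(samples, snps))
  alt <- ref
  for (idx in seq_along(candidate_cols)) {
    parts <- strsplit(tbl[[candidate_cols[idx]]], "|", fixed = TRUE)
    ref[idx, ] <- as.integer(vapply(parts, `[[`, character(1), 1))
    alt[idx, ] <- as.integer(vapply(parts, `[[`, character(1), 2))
  }
  allele_counts(ref, alt)
}

#' Write an allele-count matrix in hmc layout
#'
#' The inverse of [read_hmc()] (sample columns only, no summary columns);
#' used mainly to build fixtures and for lossless interchange with hmc-based
#' tooling.
#'
#' @param counts An [allele_counts()] object.
#' @param path Output path (`.gz` compresses).
#' @return Invisibly, `path`.
#' @export
write_hmc <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  cells <- matrix(paste0(t(counts$ref), "|", t(counts$alt)),
                  ncol(counts$ref), nrow(counts$ref))
  df <- tibble::as_tibble(setNames(as.data.frame(cells), individual_ids(counts)))
  df <- dplyr::bind_cols(tibble::tibble(`rs#` = snp_ids(counts)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read allele counts from a VCF with per-sample allelic depths
#'
#' Uses the per-sample `AD` field (reference and alternate depths) of
#' biallelic sites. Multiallelic sites are skipped (their count is reported
#' via a message); sites or cells without usable `AD` become missing
#' (ref = alt = 0).
#'
#' @param path VCF path (bgzip/gzip accepted).
#' @return An [allele_counts()] object (individuals x SNPs).
#' @export
read_vcf_counts <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) abort("VCF has no sample columns.")
  alt_field <- vcfR::getALT(v)
  multi <- grepl(",", alt_field, fixed = TRUE)
  if (sum(multi) > 0) {
    inform(sprintf("Skipped %d multiallelic site(s).", sum(multi)))
  }
  if (all(multi)) {
    warn("All sites multiallelic; returning an empty matrix.")
  }
  keep <- !multi
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0("site", which(is.na(ids)))
  ad <- vcfR::extract.gt(v, element = "AD")
  ad <- ad[keep, , drop = FALSE]
  rownames(ad) <- ids[keep]
  parse_side <- function(ad, side) {
    out <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(ad), "0,0", ad), ",", fixed = TRUE),
                        function(x) if (length(x) >= side) x[side] else "0",
                        character(1))))
    out[is.na(out)] <- 0L
    matrix(out, nrow(ad), ncol(ad), dimnames = dimnames(ad))
  }
  ref <- t(parse_side(ad, 1L))
  alt <- t(parse_side(ad, 2L))
  allele_counts(ref, alt)
}

#' Read / write the generic two-matrix count format
#'
#' The package's lossless interchange format: two tab-delimited matrices
#' (reference counts and alternate counts) sharing row (individual) and
#' column (SNP) headers, first column named `id`.
#'
#' @param counts An [allele_counts()] object.
#' @param ref_path,alt_path Paths for the two matrices.
#' @return `write_counts_tsv()` invisibly returns the paths;
#'   `read_counts_tsv()` returns an [allele_counts()] object.
#' @export
write_counts_tsv <- function(counts, ref_path, alt_path) {
  stopifnot(inherits(counts, "allele_counts"))
  for (side in list(list(m = counts$ref, p = ref_path),
                    list(m = counts$alt, p = alt_path))) {
    df <- tibble::as_tibble(side$m, rownames = "id")
    readr::write_tsv(df, side$p, progress = FALSE)
  }
  invisible(c(ref_path, alt_path))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(ref_path, alt_path) {
  read_side <- function(path) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1]]
    m
  }
  allele_counts(read_side(ref_path), read_side(alt_path))
}

assignment_report_cols <- c(
  "offspring", "code",
  "sire", "sire_r", "sire_emm", "sire_second", "sire_gap", "sire_support",
  "dam", "dam_r", "dam_emm", "dam_second", "dam_gap", "dam_support",
  "trio_emm", "r_fm", "f_o", "inbreeding_check"
)

#' Write / read a parentage assignment report
#'
#' One row per offspring with every decision metric and the final code
#' (Y/A/I/E/F/M/N), in a fixed column order; the thresholds used are stored
#' in commented header lines so the file round-trips into an equivalent
#' assignment table.
#'
#' @param records A `parentage_assignments` tibble from [assign_parentage()].
#' @param path Output TSV path.
#' @return `write_assignments()` invisibly returns `path`;
#'   `read_assignments()` returns the tibble with the thresholds re-attached.
#' @export
write_assignments <- function(records, path) {
  thr <- attr(records, "thresholds")
  header <- character(0)
  if (!is.null(thr)) {
    header <- sprintf("# threshold %s = %s", names(thr),
                      vapply(thr, format, character(1)))
  }
  cols <- intersect(assignment_report_cols, names(records))
  out <- records[c(cols, setdiff(names(records), cols))]
  writeLines(header, path)
  suppressWarnings(
    readr::write_tsv(out, path, append = length(header) > 0,
                     col_names = TRUE, progress = FALSE)
  )
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# threshold ", lines)
  tbl <- readr::read_tsv(I(lines[!hdr]), show_col_types = FALSE, progress = FALSE)
  if (any(hdr)) {
    kv <- sub("^# threshold ", "", lines[hdr])
    keys <- sub(" = .*$", "", kv)
    vals <- as.numeric(sub("^.* = ", "", kv))
    attr(tbl, "thresholds") <- setNames(as.list(vals), keys)
  }
  tbl
}
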