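#' Construct an allele call (a cis list of variants on one chromosome)
#'
#' @param variants Character vector of normalized variant ids asserted in cis
#'   (length >= 1, no duplicates).
#' @param parental_origin `"paternal"`, `"maternal"`, or `"unknown"`.
#' @return An object of class `allele_call`.
#' @export
allele_call <- function(variants, parental_origin = "unknown") {
  variants <- as.character(variants)
  if (!length(variants)) stop("an allele call needs at least one variant")
  if (anyDuplicated(variants)) {
    stop("duplicate variant id within one allele call: ",
         paste(unique(variants[duplicated(variants)]), collapse = ", "))
  }
  parental_origin <- match.arg(parental_origin, c("paternal", "maternal", "unknown"))
  structure(list(variants = variants, parental_origin = parental_origin),
            class = "allele_call")
}

PHASE_METHODS <- c("trios", "ccs_reads", "maternal_only", "paternal_only",
                   "not_determined")
PATHOGENICITY_GROUPS <- c("two_PLP", "one_PLP_one_VUS", "two_VUS")

#' Construct a proband record
#'
#' A cohort row: two allele calls (identical for homozygotes), with sex,
#' the phase method used, and the pathogenicity group.
#'
#' @param proband_id Unique proband identifier.
#' @param sex `"M"`, `"F"`, or `"unknown"`.
#' @param allele1,allele2 [allele_call()] objects.
#' @param phase_method One of `r paste0('"', PHASE_METHODS, '"', collapse = ", ")`.
#' @param group One of `r paste0('"', PATHOGENICITY_GROUPS, '"', collapse = ", ")`.
#' @return An object of class `proband_record`.
#' @export
proband_record <- function(proband_id, sex, allele1, allele2,
                           phase_method = "not_determined", group = "two_PLP") {
  stopifnot(inherits(allele1, "allele_call"), inherits(allele2, "allele_call"))
  sex <- match.arg(sex, c("M", "F", "unknown"))
  phase_method <- match.arg(phase_method, PHASE_METHODS)
  group <- match.arg(group, PATHOGENICITY_GROUPS)
  structure(list(proband_id = as.character(proband_id), sex = sex,
                 allele1 = allele1, allele2 = allele2,
                 phase_method = phase_method, group = group),
            class = "proband_record")
}

carried_variants <- function(record) {
  unique(c(record$allele1$variants, record$allele2$variants))
}

# dosage of one variant id within a record (0, 1, or 2)
record_dosage <- function(record, variant_id) {
  sum(variant_id %in% record$allele1$variants) +
    sum(variant_id %in% record$allele2$variants)
}

#' Read a proband cohort table
#'
#' Reads a TSV with columns `proband_id`, `sex`, `variant1`, `origin1`,
#' `variant2`, `origin2`, `phase_method`, `group`. Semicolon-separated variant
#' strings are split into cis member lists ([split_cis()]); every member label
#' must resolve in the variant annotation table after normalization.
#' Homozygous rows carry the same allele string twice and produce two
#' identical allele calls.
#'
#' @param cohort_path Path to the cohort TSV.
#' @param variants A `variant_table` (from [read_variants()]) or a path to one.
#' @return An object of class `cohort`: a list of [proband_record()]s with the
#'   variant table attached as attribute `"variants"`.
#' @examples
#' cohort <- read_cohort(
#'   system.file("extdata", "table1_cohort.tsv", package = "cishap"),
#'   system.file("extdata", "table1_variants.tsv", package = "cishap"))
#' length(cohort)  # 106 probands
#' @export
read_cohort <- function(cohort_path, variants) {
  if (is.character(variants)) variants <- read_variants(variants)
  stopifnot(inherits(variants, "variant_table"))
  df <- read.delim(cohort_path, stringsAsFactors = FALSE,
                   na.strings = character(), colClasses = "character")
  required <- c("proband_id", "sex", "variant1", "origin1", "variant2",
                "origin2", "phase_method", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$proband_id)) {
    stop("duplicate proband id(s): ",
         paste(unique(df$proband_id[duplicated(df$proband_id)]), collapse = ", "))
  }
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    calls <- lapply(1:2, function(k) {
      members <- split_cis(row[[paste0("variant", k)]])[[1]]
      unresolved <- setdiff(members, variants$id)
      if (length(unresolved)) {
        stop(sprintf("row %d (proband %s): variant label(s) not in annotation table: %s",
                     i, row$proband_id, paste(unresolved, collapse = ", ")))
      }
      origin <- row[[paste0("origin", k)]]
      allele_call(members, if (nzchar(origin)) origin else "unknown")
    })
    records[[i]] <- proband_record(row$proband_id, row$sex, calls[[1]], calls[[2]],
                                   row$phase_method, row$group)
  }
  structure(records, class = "cohort", variants = variants)
}

#' Write a cohort back to its normalized TSV form
#'
#' Inverse of [read_cohort()]: writing a cohort that was read from a
#' normalized table reproduces that table byte-identically.
#'
#' @param cohort A `cohort` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort, function(r) {
    fmt_origin <- function(o) if (o == "unknown") "" else o
    data.frame(
      proband_id = r$proband_id, sex = r$sex,
      variant1 = paste(r$allele1$variants, collapse = "; "),
      origin1 = fmt_origin(r$allele1$parental_origin),
      variant2 = paste(r$allele2$variants, collapse = "; "),
      origin2 = fmt_origin(r$allele2$parental_origin),
      phase_method = r$phase_method, group = r$group,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count occurrences of a variant allele across a cohort
#'
#' Total occurrences across both allele calls of all probands; homozygotes
#' count twice. Variants absent from the cohort count zero.
#'
#' @param cohort A `cohort` object.
#' @param variant_id Normalized variant id.
#' @return Integer allele count.
#' @export
allele_count <- function(cohort, variant_id) {
  variant_id <- normalize_variant_label(variant_id)
  sum(vapply(cohort, record_dosage, integer(1), variant_id = variant_id))
}

#' Distinct variant ids observed in a cohort, with per-class tallies
#'
#' Returns the union of all member variant ids across all allele calls.
#' Multi-variant cis calls contribute each member separately. The per-class
#' tally (attribute `"by_class"`) uses the annotation table attached to the
#' cohort.
#'
#' @param cohort A `cohort` object.
#' @return Character vector of distinct ids with attribute `by_class`
#'   (a named table of counts by variant class).
#' @seealso [distinct_alleles()] for counting multi-variant cis calls as
#'   single allele units, the convention behind the published total.
#' @export
distinct_variants <- function(cohort) {
  ids <- sort(unique(unlist(lapply(cohort, carried_variants))))
  variants <- attr(cohort, "variants")
  by_class <- table(factor(variants$vclass[match(ids, variants$id)],
                           levels = VARIANT_CLASSES))
  structure(ids, by_class = by_class)
}

#' Distinct allele units observed in a cohort
#'
#' Counts each distinct allele call as one unit, so a recurring multi-variant
#' cis allele such as `c.[79G>A;1320G>C]` is a single distinct allele. This is
#' the counting convention under which the published cohort total (74 distinct
#' alleles, of them 34 missense) is reproduced; member-wise counting
#' ([distinct_variants()]) yields one more because the recurring pair
#' contributes two member ids.
#'
#' @param cohort A `cohort` object.
#' @return Character vector of distinct allele-unit keys (members joined with
#'   `";"`), with attribute `by_class`: the variant class when all members
#'   share one, otherwise `"mixed"`.
#' @export
distinct_alleles <- function(cohort) {
  calls <- unlist(lapply(cohort, function(r) {
    c(paste(r$allele1$variants, collapse = ";"),
      paste(r$allele2$variants, collapse = ";"))
  }))
  keys <- sort(unique(calls))
  variants <- attr(cohort, "variants")
  cls <- vapply(strsplit(keys, ";", fixed = TRUE), function(members) {
    vc <- unique(variants$vclass[match(members, variants$id)])
    if (length(vc) == 1L) vc else "mixed"
  }, character(1))
  structure(keys, by_class = table(cls))
}

#' Number of probands carrying at least one structural variant
#'
#' A proband counts once if any allele call contains a variant of class
#' `sv_deletion`, `sv_duplication`, or `cxsv`, regardless of how many SV
#' alleles it carries.
#'
#' @param cohort A `cohort` object.
#' @return Integer count of SV-carrier probands.
#' @export
sv_carrier_count <- function(cohort) {
  variants <- attr(cohort, "variants")
  sv_ids <- variants$id[variants$vclass %in% SV_CLASSES]
  sum(vapply(cohort, function(r) any(carried_variants(r) %in% sv_ids), logical(1)))
}

#' Cohort summary statistics
#'
#' One call computing the headline cohort numbers: proband count, distinct
#' variant ids and distinct allele units, distinct structural variants,
#' per-class tallies, allele counts for chosen variants, and the SV-carrier
#' count.
#'
#' @param cohort A `cohort` object.
#' @param count_ids Variant ids to tabulate allele counts for (default: the
#'   ids present in the cohort).
#' @return A list with elements `n_probands`, `n_distinct_variants`,
#'   `n_distinct_alleles`, `n_distinct_svs`, `by_class`, `allele_counts`,
#'   `sv_carriers`.
#' @export
cohort_stats <- function(cohort, count_ids = NULL) {
  dv <- distinct_variants(cohort)
  by_class <- attr(dv, "by_class")
  if (is.null(count_ids)) count_ids <- as.character(dv)
  counts <- vapply(count_ids, function(id) allele_count(cohort, id), integer(1))
  list(
    n_probands = length(cohort),
    n_distinct_variants = length(dv),
    n_distinct_alleles = length(distinct_alleles(cohort)),
    n_distinct_svs = sum(by_class[SV_CLASSES]),
    by_class = by_class,
    allele_counts = counts,
    sv_carriers = sv_carrier_count(cohort)
  )
}
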