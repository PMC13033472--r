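#' Construct a haplotype (an ordered set of variants on one chromosome)
#'
#' Members are stored in genomic order when a variant table is supplied;
#' anchors are the members flagged as common GWAS anchor alleles.
#'
#' @param members Character vector of variant ids (non-empty).
#' @param variants Optional `variant_table` used to order members by
#'   coordinate and to flag anchors.
#' @param id Haplotype identifier; defaults to the members joined with `";"`.
#' @return An object of class `haplotype` with fields `id`, `members`,
#'   `anchors`.
#' @export
haplotype <- function(members, variants = NULL, id = NULL) {
  members <- unique(as.character(members))
  if (!length(members)) stop("a haplotype needs at least one member")
  anchors <- character()
  if (!is.null(variants)) {
    idx <- match(members, variants$id)
    if (anyNA(idx)) {
      stop("member(s) not in variant table: ",
           paste(members[is.na(idx)], collapse = ", "))
    }
    members <- members[order(variants$start[idx])]
    anchors <- members[variants$anchor[match(members, variants$id)] %in% TRUE]
  }
  structure(list(id = id %||% paste(members, collapse = ";"),
                 members = members, anchors = anchors),
            class = "haplotype")
}

#' Protein-level display name of a haplotype
#'
#' Builds a `p.[...]`-style display name from the `protein` column of the
#' variant table, falling back to the variant id where no protein name is
#' recorded. Following the display convention of the cohort figure,
#' `drop_terminated_upstream = TRUE` omits nonsense/frameshift members lying
#' 5' (in transcript order) of an anchor, since the anchor is irrelevant on a
#' transcript truncated before it; the haplotype itself always stores the full
#' member set.
#'
#' @param h A [haplotype()].
#' @param variants A `variant_table` with `protein` and coordinate columns.
#' @param drop_terminated_upstream Apply the display exclusion (default
#'   `FALSE`).
#' @param transcript_strand `"-"` (default; the OCA2 locus) or `"+"`: display
#'   order is transcript order, which on the minus strand is descending
#'   genomic coordinate.
#' @return A character display name.
#' @export
display_name <- function(h, variants, drop_terminated_upstream = FALSE,
                         transcript_strand = "-") {
  members <- h$members
  idx <- match(members, variants$id)
  ord <- order(variants$start[idx], decreasing = (transcript_strand == "-"))
  members <- members[ord]
  idx <- idx[ord]
  if (drop_terminated_upstream && length(h$anchors)) {
    # transcript on the minus strand: 5' of an anchor = larger genomic start
    anchor_start <- min(variants$start[match(h$anchors, variants$id)])
    truncating <- variants$vclass[idx] %in% c("nonsense", "frameshift_indel")
    keep <- !(truncating & variants$start[idx] > anchor_start)
    members <- members[keep]
    idx <- idx[keep]
  }
  labels <- variants$protein[idx]
  labels[is.na(labels) | !nzchar(labels)] <- members[is.na(labels) | !nzchar(labels)]
  labels <- sub("^p\\.", "", labels)
  paste0("p.[", paste(labels, collapse = ";"), "]")
}

# maximal cliques of the cis graph over one proband's variants
cis_cliques <- function(ids, calls) {
  edges <- character(0)
  for (cl in calls) {
    if (cl$relation == "cis" && all(cl$pair %in% ids)) edges <- c(edges, cl$pair)
  }
  if (!length(edges)) return(list())
  g <- igraph::make_graph(edges, directed = FALSE)
  cliques <- igraph::max_cliques(g, min = 2)
  lapply(cliques, function(cl) sort(names(cl)))
}

#' Classify one proband's support for a haplotype
#'
#' A proband is `phase_validated` for a haplotype when it carries every member
#' allele and every member pair is resolved cis; `genotype_consistent` when it
#' carries every member allele but at least one pair is unresolved (and none
#' is trans); `inconsistent` when it carries every member allele but at least
#' one pair is resolved trans (or conflicts); and `no_match` when some member
#' allele is absent.
#'
#' @param record A [proband_record()].
#' @param phase_calls List of `phase_call`s for the proband (named `"a|b"`,
#'   as returned by [resolve_proband()]).
#' @param h A [haplotype()].
#' @return One of `"phase_validated"`, `"genotype_consistent"`,
#'   `"inconsistent"`, `"no_match"`.
#' @export
match_proband <- function(record, phase_calls, h) {
  members <- h$members
  if (!all(members %in% carried_variants(record))) return("no_match")
  if (length(members) == 1L) return("phase_validated")
  lookup <- function(a, b) {
    key1 <- paste(a, b, sep = "|")
    key2 <- paste(b, a, sep = "|")
    phase_calls[[key1]] %||% phase_calls[[key2]]
  }
  pairs <- combn(sort(members), 2L, simplify = FALSE)
  relations <- vapply(pairs, function(p) {
    cl <- lookup(p[1], p[2])
    if (is.null(cl)) "ambiguous" else cl$relation
  }, character(1))
  if (any(relations %in% c("trans", "conflict", "mendelian_error"))) {
    "inconsistent"
  } else if (all(relations == "cis")) {
    "phase_validated"
  } else {
    "genotype_consistent"
  }
}

#' Build the catalog of recurring multi-variant cis-haplotypes
#'
#' Emits one haplotype for every maximal set of variants phased pairwise cis
#' on a chromosome of at least one proband; identical member sets merge across
#' probands. Every proband is then matched against every catalog haplotype
#' with [match_proband()] and counted at chromosome level: a proband
#' homozygous for every member contributes two observations.
#'
#' @param phase_calls Named list (by proband id) of phase-call lists, as
#'   produced by [resolve_proband()] per proband.
#' @param cohort A `cohort` object.
#' @return A `data.frame` with class `haplotype_catalog`: columns `id`,
#'   `members`, `n_members`, `anchors`, `phase_validated`,
#'   `genotype_consistent`, `inconsistent`, plus the haplotype objects in
#'   attribute `"haplotypes"`.
#' @export
build_catalog <- function(phase_calls, cohort) {
  variants <- attr(cohort, "variants")
  member_sets <- list()
  for (r in cohort) {
    calls <- phase_calls[[r$proband_id]]
    if (is.null(calls)) next
    for (cl in cis_cliques(carried_variants(r), calls)) {
      key <- paste(cl, collapse = ";")
      member_sets[[key]] <- cl
    }
  }
  haps <- lapply(member_sets, haplotype, variants = variants)
  names(haps) <- vapply(haps, `[[`, character(1), "id")
  rows <- lapply(haps, function(h) {
    pv <- gc_ <- inc <- 0L
    for (r in cohort) {
      status <- match_proband(r, phase_calls[[r$proband_id]] %||% list(), h)
      if (status == "no_match") next
      hom <- all(vapply(h$members, function(v) record_dosage(r, v) == 2L, logical(1)))
      w <- if (hom) 2L else 1L
      if (status == "phase_validated") pv <- pv + w
      if (status == "genotype_consistent") gc_ <- gc_ + w
      if (status == "inconsistent") inc <- inc + w
    }
    data.frame(id = h$id, members = paste(h$members, collapse = ";"),
               n_members = length(h$members),
               anchors = paste(h$anchors, collapse = ";"),
               phase_validated = pv, genotype_consistent = gc_,
               inconsistent = inc, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = character(), members = character(), n_members = integer(),
               anchors = character(), phase_validated = integer(),
               genotype_consistent = integer(), inconsistent = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, haplotypes = haps,
            class = c("haplotype_catalog", "data.frame"))
}

#' Cohort allele-frequency enrichment of a variant over a reference MAF
#'
#' The cohort allele frequency is the allele count over `2 *` the number of
#' probands; the fold enrichment divides it by a reference population MAF.
#' The reference stratum is the caller's choice and is deliberately a free
#' parameter.
#'
#' @param cohort A `cohort` object.
#' @param variant_id Normalized variant id.
#' @param reference_maf Reference population MAF (> 0; a zero reference yields
#'   an infinite fold with a warning).
#' @return A list with `cohort_af` and `fold`.
#' @export
cohort_enrichment <- function(cohort, variant_id, reference_maf) {
  af <- allele_count(cohort, variant_id) / (2 * length(cohort))
  fold <- if (reference_maf > 0) {
    af / reference_maf
  } else {
    warning("reference MAF is zero; fold enrichment undefined (reported Inf)")
    if (af > 0) Inf else 0
  }
  list(cohort_af = af, fold = fold)
}
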