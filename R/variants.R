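#' Variant classes recognised by the cohort model
#' @keywords internal
VARIANT_CLASSES <- c(
  "missense", "nonsense", "frameshift_indel", "inframe_indel",
  "splice_region", "deep_intronic", "sv_deletion", "sv_duplication",
  "cxsv", "regulatory_snp", "synonymous"
)

SV_CLASSES <- c("sv_deletion", "sv_duplication", "cxsv")

#' Normalize a variant label
#'
#' Collapses the typographic variation seen in published cohort tables into a
#' single canonical label per variant: unicode hyphens/dashes become ASCII
#' `-`, thousands separators inside positions are dropped (`c.2433-22,889T>A`
#' -> `c.2433-22889T>A`), and internal whitespace is removed
#' (`c.2310 T>G` -> `c.2310T>G`). The two complex structural variants are
#' mapped to stable symbolic identifiers: any label mentioning "CxSV" becomes
#' `cxsv_143kb_invdup` when it also mentions an inversion/duplication alone,
#' or `cxsv_143kb_184kb_del` when it carries the 184 kb deletion.
#'
#' @param x Character vector of raw variant labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_variant_label("c.2310 T>G")
#' normalize_variant_label("143 kb/184 kb CxSV")
#' @export
normalize_variant_label <- function(x) {
  x <- gsub("[‐‑‒–—−]", "-", x)
  x <- gsub("(?<=[0-9]),(?=[0-9])", "", x, perl = TRUE)
  x <- gsub("\\s+", "", x)
  is_cxsv <- grepl("cxsv", x, ignore.case = TRUE)
  if (any(is_cxsv)) {
    invdup <- is_cxsv & grepl("inv", x, ignore.case = TRUE) &
      !grepl("184", x, fixed = TRUE)
    x[is_cxsv & !invdup] <- "cxsv_143kb_184kb_del"
    x[invdup] <- "cxsv_143kb_invdup"
  }
  x
}

#' Split a cis allele string into its member variant labels
#'
#' Allele calls listing several variants on one chromosome separate members
#' with `;`. Semicolons inside square brackets belong to a single symbolic SV
#' label (e.g. `g.[27975445_27984368dup;27984368_27984369insTTAACA]`) and are
#' not split points.
#'
#' @param x Character vector of allele-call strings.
#' @return List of character vectors of normalized member labels.
#' @keywords internal
split_cis <- function(x) {
  lapply(x, function(s) {
    out <- character()
    depth <- 0L
    cur <- ""
    for (ch in strsplit(s, "")[[1]]) {
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
      if (ch == ";" && depth == 0L) {
        out <- c(out, cur)
        cur <- ""
      } else {
        cur <- paste0(cur, ch)
      }
    }
    out <- c(out, cur)
    out <- normalize_variant_label(trimws(out))
    out[nzchar(out)]
  })
}

#' Construct a one-row variant annotation table
#'
#' Convenience constructor for tests and generators; real analyses read the
#' full annotation table with [read_variants()].
#'
#' @param id Normalized variant label.
#' @param vclass One of the recognised variant classes.
#' @param contig,start,end 1-based inclusive genomic coordinates.
#' @param ref_allele,alt_allele Allele strings (empty for symbolic SVs).
#' @param population_maf Population minor allele frequency in `[0, 1]`, or `NA`.
#' @param anchor Logical; `TRUE` for a common GWAS anchor allele.
#' @param retention_factor Per-allele fraction of full-length expression
#'   retained, in `(0, 1]`, or `NA`.
#' @param ... Further columns (e.g. `protein`, `rsid`).
#' @return A one-row `data.frame` with class `variant_table`.
#' @export
variant <- function(id, vclass, contig = "chr15", start = 1L, end = start,
                    ref_allele = "", alt_allele = "", population_maf = NA_real_,
                    anchor = FALSE, retention_factor = NA_real_, ...) {
  df <- data.frame(
    id = id, vclass = vclass, contig = contig,
    start = as.integer(start), end = as.integer(end),
    ref_allele = ref_allele, alt_allele = alt_allele,
    population_maf = as.numeric(population_maf), anchor = anchor,
    retention_factor = as.numeric(retention_factor),
    stringsAsFactors = FALSE, ...
  )
  validate_variant_table(df)
}

#' Read a variant annotation table
#'
#' Reads a TSV with at least the columns `id`, `vclass`, `contig`, `start`,
#' `end`, `population_maf`, `anchor`; optional columns (`hgvs_c`, `hgvs_g`,
#' `rsid`, `protein`, `ref_allele`, `alt_allele`, `retention_factor`, `note`)
#' are carried through. Labels are normalized on read and the table invariants
#' are enforced: unique ids, `start <= end`, and anchors must have a recorded
#' common-range MAF (>= 0.01).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with class `variant_table`.
#' @seealso The packaged cohort annotation:
#'   `system.file("extdata", "table1_variants.tsv", package = "cishap")`.
#' @export
read_variants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("id", "vclass", "contig", "start", "end", "population_maf", "anchor")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("variant table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$id <- normalize_variant_label(df$id)
  df$anchor <- as.logical(df$anchor)
  for (col in c("ref_allele", "alt_allele", "hgvs_c", "hgvs_g", "protein", "rsid")) {
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  }
  if (!"retention_factor" %in% names(df)) df$retention_factor <- NA_real_
  validate_variant_table(df)
}

validate_variant_table <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("duplicate variant id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  bad_class <- setdiff(df$vclass, VARIANT_CLASSES)
  if (length(bad_class)) {
    stop("unknown variant class(es): ", paste(bad_class, collapse = ", "))
  }
  if (any(df$end < df$start)) {
    stop("variant(s) with end < start: ",
         paste(df$id[df$end < df$start], collapse = ", "))
  }
  anchors <- df[df$anchor %in% TRUE, , drop = FALSE]
  if (nrow(anchors) &&
      (any(is.na(anchors$population_maf)) || any(anchors$population_maf < 0.01))) {
    stop("anchor variants must carry a population MAF >= 0.01")
  }
  maf <- df$population_maf
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) stop("population_maf outside [0, 1]")
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Classify a variant as rare or common by population frequency
#'
#' A variant is `"rare"` when its population MAF is strictly below the
#' threshold and `"common"` otherwise; a missing MAF yields `"unknown"` rather
#' than a silent rare call.
#'
#' @param v A `variant_table` row (or whole table), or a numeric MAF vector.
#' @param threshold Strict rarity threshold; default 0.01.
#' @return Character vector in `{"rare", "common", "unknown"}`.
#' @examples
#' classify_rarity(0.05792)  # "common"
#' classify_rarity(0.0011)   # "rare"
#' classify_rarity(0.01)     # boundary is common (strict <)
#' @export
classify_rarity <- function(v, threshold = 0.01) {
  maf <- if (is.data.frame(v)) v$population_maf else as.numeric(v)
  out <- ifelse(is.na(maf), "unknown", ifelse(maf < threshold, "rare", "common"))
  as.character(out)
}
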