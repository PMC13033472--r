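#' Construct a phased population panel
#'
#' A panel holds `2 * n_individuals` phased haplotypes over a site list, each
#' site coded `0` (ref) or `1` (alt).
#'
#' @param haplotypes Integer matrix (rows = haplotypes, columns = sites) of
#'   0/1 alleles; column names are the site/variant ids. The row count must be
#'   even (two haplotypes per individual).
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(haplotypes) {
  haplotypes <- as.matrix(haplotypes)
  if (is.null(colnames(haplotypes))) stop("panel columns must be named by site id")
  if (nrow(haplotypes) %% 2L != 0L) {
    stop("a phased panel has exactly two haplotypes per individual")
  }
  if (!all(haplotypes %in% 0:1)) stop("panel alleles must be coded 0 (ref) / 1 (alt)")
  structure(list(haplotypes = haplotypes,
                 n_individuals = nrow(haplotypes) %/% 2L),
            class = "phased_panel")
}

#' Read a phased panel from a haplotype-matrix TSV
#'
#' First column `hap_id`, remaining columns one per site with 0/1 alleles.
#'
#' @param path Path to the TSV.
#' @return A [phased_panel()].
#' @export
read_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  phased_panel(m)
}

#' Write a phased panel to a haplotype-matrix TSV
#'
#' @param panel A [phased_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  m <- panel$haplotypes
  df <- data.frame(hap_id = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Population haplotype frequency of an allele pattern
#'
#' The fraction of panel haplotypes carrying every required allele of the
#' pattern, unconstrained at all other sites.
#'
#' @param panel A [phased_panel()].
#' @param pattern Named vector of required alleles (values 0/1, or
#'   `"ref"`/`"alt"`), named by site id. All pattern sites must exist in the
#'   panel.
#' @return Haplotype frequency in `[0, 1]`.
#' @examples
#' panel <- phased_panel(matrix(c(1, 1, 0, 0, 1, 0, 0, 0), ncol = 2,
#'                              dimnames = list(NULL, c("s1", "s2"))))
#' panel_hf(panel, c(s1 = 1))
#' @export
panel_hf <- function(panel, pattern) {
  stopifnot(inherits(panel, "phased_panel"))
  if (!nrow(panel$haplotypes)) stop("empty panel: no haplotypes to match")
  if (is.character(pattern)) {
    pattern <- setNames(ifelse(pattern == "alt", 1L, 0L), names(pattern))
  }
  missing_sites <- setdiff(names(pattern), colnames(panel$haplotypes))
  if (length(missing_sites)) {
    stop("pattern site(s) absent from panel: ",
         paste(missing_sites, collapse = ", "))
  }
  sub <- panel$haplotypes[, names(pattern), drop = FALSE]
  hits <- rowSums(sub == matrix(pattern, nrow(sub), length(pattern),
                                byrow = TRUE)) == length(pattern)
  mean(hits)
}
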