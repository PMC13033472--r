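#' Read a repeat-element track from a BED file
#'
#' The BED name column holds the repeat class (`LINE`, `SINE`, `LTR`, or
#' `other`). Intervals are returned in the BED convention: 0-based, half-open
#' `[start, end)`.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with class `repeat_track` and columns `contig`,
#'   `start`, `end` (0-based half-open) and `repeat_class`.
#' @export
read_repeats <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  repeat_track(
    contig = as.character(GenomicRanges::seqnames(gr)),
    # rtracklayer imports BED as 1-based closed ranges; undo for half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    repeat_class = if (!is.null(gr$name)) gr$name else rep("other", length(gr))
  )
}

#' Construct a repeat track from coordinates
#'
#' @param contig Character vector of contig names.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param repeat_class Repeat class per interval (`LINE`, `SINE`, `LTR`,
#'   `other`).
#' @return A `data.frame` with class `repeat_track`.
#' @export
repeat_track <- function(contig, start, end, repeat_class = "other") {
  df <- data.frame(contig = as.character(contig), start = as.integer(start),
                   end = as.integer(end),
                   repeat_class = as.character(repeat_class),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("repeat intervals need start < end (half-open)")
  bad <- setdiff(df$repeat_class, c("LINE", "SINE", "LTR", "other"))
  if (length(bad)) stop("unknown repeat class(es): ", paste(bad, collapse = ", "))
  class(df) <- c("repeat_track", "data.frame")
  df
}

#' Flag structural-variant junction endpoints that fall in repeat elements
#'
#' Each SV contributes two junction breakpoints. Breakpoints sit between
#' bases: for an SV spanning 1-based inclusive `[start, end]`, the left
#' junction is the 0-based coordinate `start - 1` and the right junction is
#' `end`. A junction overlaps a repeat interval when it lies in the half-open
#' `[start, end)` BED interval on the same contig, so a junction exactly at a
#' BED end coordinate is not flagged. SVs on a contig absent from the repeat
#' track are flagged non-overlapping with a warning.
#'
#' @param svs A `variant_table` (rows of class `sv_deletion`,
#'   `sv_duplication`, or `cxsv`; other rows are dropped).
#' @param repeats A `repeat_track` from [read_repeats()] or [repeat_track()].
#' @return A `data.frame` with columns `id`, `start_in_repeat`,
#'   `end_in_repeat`, `repeat_classes` (comma-separated classes hit, `""` when
#'   none).
#' @export
annotate_junctions <- function(svs, repeats) {
  stopifnot(inherits(repeats, "repeat_track"))
  if (inherits(svs, "variant_table") || is.data.frame(svs)) {
    svs <- svs[svs$vclass %in% SV_CLASSES, , drop = FALSE]
  } else {
    stop("`svs` must be a variant table")
  }
  if (!nrow(svs)) {
    return(data.frame(id = character(), start_in_repeat = logical(),
                      end_in_repeat = logical(), repeat_classes = character(),
                      stringsAsFactors = FALSE))
  }
  missing_contig <- setdiff(unique(svs$contig), unique(repeats$contig))
  if (length(missing_contig)) {
    warning("contig(s) absent from repeat track, endpoints flagged non-overlapping: ",
            paste(missing_contig, collapse = ", "))
  }
  # junction points in 0-based coordinates; represent point x as the 1-based
  # base x+1 and the half-open repeat [s, e) as 1-based closed [s+1, e]
  points <- GenomicRanges::GRanges(
    rep(svs$contig, 2L),
    IRanges::IRanges(start = c(svs$start - 1L, svs$end) + 1L, width = 1L)
  )
  rep_gr <- GenomicRanges::GRanges(
    repeats$contig,
    IRanges::IRanges(start = repeats$start + 1L, end = repeats$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(points, rep_gr))
  n <- nrow(svs)
  flagged <- rep(FALSE, 2L * n)
  flagged[unique(S4Vectors::queryHits(hits))] <- TRUE
  classes <- vapply(seq_len(n), function(i) {
    idx <- S4Vectors::queryHits(hits) %in% c(i, i + n)
    paste(sort(unique(repeats$repeat_class[S4Vectors::subjectHits(hits)[idx]])),
          collapse = ",")
  }, character(1))
  data.frame(id = svs$id,
             start_in_repeat = flagged[seq_len(n)],
             end_in_repeat = flagged[n + seq_len(n)],
             repeat_classes = classes,
             stringsAsFactors = FALSE)
}
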