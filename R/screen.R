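#' Enumerate every single-base substitution in a splice window's flanks
#'
#' Every window position except the two consensus dinucleotide positions and
#' the anchor position (when the window has one) is mutated to its three
#' alternative bases, yielding `3 * (L - 2 - n_excluded)` edits — 477 for the
#' default 162-bp window geometry with one anchor.
#'
#' @param w A [splice_window()], normally with `anchor_position` set.
#' @return A `data.frame` with columns `window_position`, `ref`, `alt`.
#' @export
enumerate_snvs <- function(w) {
  stopifnot(inherits(w, "splice_window"))
  d <- w$dinucleotide_start
  excluded <- c(d, d + 1L, w$anchor_position)
  pos <- setdiff(seq_len(w$length), excluded)
  ref <- w$sequence[pos]
  out <- do.call(rbind, lapply(seq_along(pos), function(i) {
    data.frame(window_position = pos[i], ref = ref[i],
               alt = setdiff(DNA_BASES, ref[i]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify screen points against the diagonal and the reference score
#'
#' A point lies below the identity diagonal (`anchor_decreases`) when the
#' score in cis with the anchor is strictly lower than the score of the
#' variant alone, above it (`anchor_increases`) when strictly higher; equality
#' sits on the diagonal and belongs to neither class. `retention_increasing`
#' flags haplotypes scoring strictly above the reference sequence, read as
#' favouring exon retention and proper splicing.
#'
#' @param score_alone,score_with_anchor,reference_score Numeric vectors (or a
#'   `data.frame` with those columns as the first argument).
#' @return A `data.frame` of logicals: `anchor_decreases`, `anchor_increases`,
#'   `retention_increasing`.
#' @export
classify_point <- function(score_alone, score_with_anchor = NULL,
                           reference_score = NULL) {
  if (is.data.frame(score_alone)) {
    df <- score_alone
    score_alone <- df$score_alone
    score_with_anchor <- df$score_with_anchor
    reference_score <- df$reference_score
  }
  data.frame(
    anchor_decreases = score_with_anchor < score_alone,
    anchor_increases = score_with_anchor > score_alone,
    retention_increasing = score_with_anchor > reference_score
  )
}

#' Run the splice-window saturation screen
#'
#' For each splice site, enumerates every flank substitution
#' ([enumerate_snvs()]) and scores it alone and in cis with the window's
#' anchor allele, recording the reference score and the diagonal/retention
#' classes of every point. The screen is fully deterministic: rerunning it
#' reproduces the report bit-identically.
#'
#' @param models Named list of [train_scorer()] models by site type.
#' @param windows Named list of [splice_window()]s (same names), each with
#'   `anchor_position` set.
#' @param anchor_alt Alternative base of the anchor allele (applied at each
#'   window's own `anchor_position`).
#' @return An object of class `screen_report`: list with `records` (one row
#'   per site x substitution: `site`, `window_position`, `ref`, `alt`,
#'   `score_alone`, `score_with_anchor`, `reference_score`, and class flags)
#'   and `summary` (per-site counts and reference scores).
#' @export
run_screen <- function(models, windows, anchor_alt) {
  stopifnot(length(windows) >= 1L, all(names(windows) %in% names(models)))
  anchor_alt <- toupper(anchor_alt)
  records <- lapply(names(windows), function(site) {
    w <- windows[[site]]
    m <- models[[site]]
    anchor <- haplotype_edit(w$anchor_position, anchor_alt)
    ref_score <- splice_score(m, w)
    snvs <- enumerate_snvs(w)
    alone <- vapply(seq_len(nrow(snvs)), function(i) {
      splice_score(m, w, haplotype_edit(snvs$window_position[i], snvs$alt[i]))
    }, numeric(1))
    with_anchor <- vapply(seq_len(nrow(snvs)), function(i) {
      splice_score(m, w, rbind(haplotype_edit(snvs$window_position[i], snvs$alt[i]),
                               anchor))
    }, numeric(1))
    cbind(data.frame(site = site, stringsAsFactors = FALSE), snvs,
          data.frame(score_alone = alone, score_with_anchor = with_anchor,
                     reference_score = ref_score),
          classify_point(alone, with_anchor, ref_score))
  })
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  summary <- do.call(rbind, lapply(split(records, records$site), function(df) {
    data.frame(site = df$site[1], n_records = nrow(df),
               reference_score = df$reference_score[1],
               anchor_decreases = sum(df$anchor_decreases),
               anchor_increases = sum(df$anchor_increases),
               retention_increasing = sum(df$retention_increasing),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary), class = "screen_report")
}

#' Scatter plot of a saturation screen (score alone vs. in cis with anchor)
#'
#' One panel per site: each substitution's solo score on the x-axis against
#' its score in cis with the anchor on the y-axis, with the identity diagonal
#' and reference-score crosshairs.
#'
#' @param x A `screen_report`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.screen_report <- function(x, ...) {
  sites <- unique(x$records$site)
  old <- graphics::par(mfrow = c(1, length(sites)))
  on.exit(graphics::par(old))
  for (s in sites) {
    df <- x$records[x$records$site == s, ]
    cols <- ifelse(df$anchor_increases, "darkgreen",
                   ifelse(df$anchor_decreases, "grey30", "grey70"))
    plot(df$score_alone, df$score_with_anchor, col = cols, pch = 16,
         xlab = "score, variant alone", ylab = "score, variant + anchor",
         main = s, ...)
    graphics::abline(0, 1, lty = 2)
    graphics::abline(v = df$reference_score[1], h = df$reference_score[1],
                     lty = 3, col = "blue")
  }
  invisible(x)
}

#' Write screen records and summary to TSV files
#'
#' @param report A `screen_report`.
#' @param records_path,summary_path Output paths (either may be `NULL` to
#'   skip).
#' @return `report`, invisibly.
#' @export
write_screen <- function(report, records_path = NULL, summary_path = NULL) {
  if (!is.null(records_path)) {
    write.table(report$records, records_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    write.table(report$summary, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(report)
}
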