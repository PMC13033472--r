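#' Call exon-level copy number from SNP-array log R ratios
#'
#' Compares a sample's mean exonic-probe LRR for one region against the
#' distribution of per-sample control means: `z = (mean_sample -
#' mean(controls)) / sd(controls)`. A depressed z beyond `z_del` indicates a
#' heterozygous deletion (copy number 1); a mean at or below `hom_floor`
#' indicates a homozygous deletion (copy number 0). The defaults (`z_del` -3,
#' `hom_floor` -1.5) reflect standard array expectations: a one-copy loss
#' shifts LRR by roughly -0.45 while a two-copy loss collapses intensity far
#' below -1.5.
#'
#' @param sample_obs `data.frame` with columns `sample_id`, `probe_id`,
#'   `region`, `lrr` for the test sample (>= 1 probe in the region).
#' @param controls Same columns for control samples (>= 2 distinct control
#'   samples in the region; zero control spread is a hard error).
#' @param region Region to call (default: the single region present in
#'   `sample_obs`).
#' @param z_del Z threshold at or below which a deletion is called (default
#'   -3).
#' @param hom_floor Mean-LRR floor at or below which the call is homozygous
#'   deletion (default -1.5).
#' @return A list of class `cnv_call`: `sample_id`, `region`, `mean_lrr`,
#'   `z`, `copy_number` (0, 1 or 2), `confidence_note`.
#' @export
call_cnv <- function(sample_obs, controls, region = NULL,
                     z_del = -3, hom_floor = -1.5) {
  cols <- c("sample_id", "probe_id", "region", "lrr")
  stopifnot(all(cols %in% names(sample_obs)), all(cols %in% names(controls)))
  if (is.null(region)) {
    region <- unique(sample_obs$region)
    if (length(region) != 1L) stop("specify `region` when multiple are present")
  }
  s <- sample_obs[sample_obs$region == region, ]
  ctl <- controls[controls$region == region, ]
  if (!nrow(s)) stop("no sample probes in region ", region)
  control_means <- tapply(ctl$lrr, ctl$sample_id, mean)
  if (length(control_means) < 2L) {
    stop("at least two control samples are required for region ", region)
  }
  sd_ctl <- sd(control_means)
  if (sd_ctl == 0) stop("degenerate controls: zero variance across control means")
  mean_lrr <- mean(s$lrr)
  z <- (mean_lrr - mean(control_means)) / sd_ctl
  copy_number <- if (mean_lrr <= hom_floor) 0L else if (z <= z_del) 1L else 2L
  note <- sprintf("z=%.2f vs %d controls (sd %.3f); thresholds z_del=%g, hom_floor=%g",
                  z, length(control_means), sd_ctl, z_del, hom_floor)
  structure(list(sample_id = unique(s$sample_id)[1], region = region,
                 mean_lrr = mean_lrr, z = z, copy_number = copy_number,
                 confidence_note = note),
            class = "cnv_call")
}
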