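#' Construct a multiplicative allele-dosage expression model
#'
#' Mean expression at dosage `d` is `baseline * retention^d`; observation
#' noise is log-normal with standard deviation `noise_sd` on the natural-log
#' scale. The per-allele percent reduction is `(1 - retention) * 100`.
#'
#' @param baseline Mean expression (TPM) at dosage 0; > 0.
#' @param retention Per-allele retention factor in `(0, 1]`.
#' @param noise_sd Log-scale noise standard deviation; >= 0.
#' @return An object of class `dosage_model`.
#' @export
dosage_model <- function(baseline = 100, retention = 0.73, noise_sd = 0.15) {
  stopifnot(baseline > 0, retention > 0, retention <= 1, noise_sd >= 0)
  structure(list(baseline = baseline, retention = retention,
                 noise_sd = noise_sd,
                 percent_reduction = (1 - retention) * 100),
            class = "dosage_model")
}

#' Effective full-length expression of a multi-anchor haplotype
#'
#' Under the multiplicative model each anchor allele independently retains a
#' fraction of correct full-length transcript, so a haplotype's effective
#' expression is the product of its anchors' retention factors; the empty
#' haplotype retains everything. With the canonical ~20%-per-allele anchors
#' (retention 0.80 each), a two-anchor haplotype retains 0.64 of full-length
#' expression.
#'
#' @param retention_factors Numeric vector of per-anchor retention factors in
#'   `(0, 1]` (possibly empty). Any missing value is a hard error: retention
#'   must be known for every anchor on the haplotype.
#' @return Effective expression fraction in `(0, 1]`.
#' @examples
#' effective_expression(c(rs1800404 = 0.80, rs12913832 = 0.80))  # 0.64
#' @export
effective_expression <- function(retention_factors) {
  if (!length(retention_factors)) return(1)
  if (anyNA(retention_factors)) {
    stop("missing retention factor for anchor(s): ",
         paste(names(retention_factors)[is.na(retention_factors)] %||% "?",
               collapse = ", "))
  }
  if (any(retention_factors <= 0 | retention_factors > 1)) {
    stop("retention factors must lie in (0, 1]")
  }
  prod(retention_factors)
}

#' Effective expression of a haplotype from a variant table
#'
#' Looks up the `retention_factor` of each anchor member in the variant table
#' and multiplies them ([effective_expression()]).
#'
#' @param h A [haplotype()].
#' @param variants A `variant_table` with a `retention_factor` column.
#' @return Effective expression fraction.
#' @export
haplotype_effective_expression <- function(h, variants) {
  anchors <- h$anchors
  rf <- variants$retention_factor[match(anchors, variants$id)]
  names(rf) <- anchors
  effective_expression(rf)
}

#' Simulate expression samples under a dosage model
#'
#' `tpm = baseline * retention^dosage * exp(e)`, `e ~ Normal(0, noise_sd^2)`,
#' reproducible under `seed`.
#'
#' @param model A [dosage_model()].
#' @param dosages Integer vector of per-sample anchor dosages in `{0, 1, 2}`.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `sample_id`, `dosage`, `tpm`.
#' @export
simulate_expression <- function(model, dosages, seed = NULL) {
  stopifnot(inherits(model, "dosage_model"), all(dosages %in% 0:2))
  sim <- function() {
    eps <- rnorm(length(dosages), 0, model$noise_sd)
    data.frame(sample_id = sprintf("s%03d", seq_along(dosages)),
               dosage = as.integer(dosages),
               tpm = model$baseline * model$retention^dosages * exp(eps),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) sim() else with_seed(seed, sim())
}

#' Fit the allele-dosage expression model
#'
#' The default log-linear fit regresses `log(tpm)` on dosage by ordinary
#' least squares: the intercept estimates `log(baseline)` and the slope
#' `log(retention)`, so the per-allele percent reduction is
#' `(1 - exp(slope)) * 100`. `method = "group_means"` instead regresses the
#' log of the per-dosage group means on dosage, and `method = "additive"` fits
#' `tpm ~ dosage` on the natural scale as a sensitivity check (per-allele
#' reduction relative to the fitted baseline).
#'
#' @param samples A `data.frame` with columns `dosage` and `tpm` (all
#'   `tpm > 0`; at least two distinct dosage values).
#' @param method `"loglinear"` (default), `"group_means"`, or `"additive"`.
#' @return A list with `baseline`, `retention`, `percent_reduction`,
#'   `se_log_retention` (NA for `group_means` with < 3 groups or `additive`),
#'   `method`, and the underlying `fit`.
#' @export
fit_dosage <- function(samples, method = c("loglinear", "group_means", "additive")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(samples), all(c("dosage", "tpm") %in% names(samples)))
  if (length(unique(samples$dosage)) < 2L) {
    stop("at least two distinct dosage groups are required")
  }
  if (any(samples$tpm <= 0)) {
    stop("tpm values must be positive; add a pseudo-TPM offset before fitting")
  }
  if (method == "additive") {
    fit <- lm(tpm ~ dosage, data = samples)
    baseline <- unname(coef(fit)[1])
    slope <- unname(coef(fit)[2])
    retention <- 1 + slope / baseline
    return(list(baseline = baseline, retention = retention,
                percent_reduction = -slope / baseline * 100,
                se_log_retention = NA_real_, method = method, fit = fit))
  }
  data <- if (method == "group_means") {
    means <- tapply(samples$tpm, samples$dosage, mean)
    data.frame(dosage = as.numeric(names(means)), tpm = as.numeric(means))
  } else {
    samples
  }
  fit <- lm(log(tpm) ~ dosage, data = data)
  slope <- unname(coef(fit)[2])
  se <- if (nrow(data) > 2L) sqrt(vcov(fit)[2, 2]) else NA_real_
  list(baseline = exp(unname(coef(fit)[1])), retention = exp(slope),
       percent_reduction = (1 - exp(slope)) * 100,
       se_log_retention = se, method = method, fit = fit)
}
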