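#' Aggregate alt-supporting signal across a patient-specific panel
#'
#' Sums, over the active panel targets only, the alt-supporting molecule
#' count `k`, the total unique molecule count `M`, and the expected
#' background noise `lambda = sum(e_t * M_t)` — the mean of the Poisson null
#' used for detection.
#'
#' @param observations data.frame of per-target observations: `target_id`,
#'   `total_molecules`, `alt_molecules`, `noise_rate`, and optionally
#'   `active` (defaults to all active).
#' @param active_only Restrict sums to active targets (default `TRUE`).
#' @return List with `k`, `M`, `lambda_noise`.
#' @export
aggregate_panel_signal <- function(observations, active_only = TRUE) {
  stopifnot(is.data.frame(observations),
            all(c("total_molecules", "alt_molecules", "noise_rate") %in%
                  names(observations)))
  obs <- observations
  if (active_only && "active" %in% names(obs))
    obs <- obs[obs$active, , drop = FALSE]
  if (nrow(obs) == 0)
    stop("no active targets to aggregate")
  if (any(obs$alt_molecules < 0 | obs$alt_molecules > obs$total_molecules))
    stop("alt_molecules must lie in [0, total_molecules]")
  if (any(obs$noise_rate <= 0))
    stop("noise_rate must be > 0 for every target (apply the rate floor)")
  list(k = sum(obs$alt_molecules),
       M = sum(obs$total_molecules),
       lambda_noise = sum(obs$noise_rate * obs$total_molecules))
}

#' Tumor fraction in parts per million
#'
#' `ppm = 1e6 * k / M`, where `k` is the aggregated alt-supporting molecule
#' count and `M` the total unique molecule count across the panel.
#'
#' @param k Alt-supporting unique molecules.
#' @param M Total unique molecules (> 0).
#' @return Tumor fraction in ppm.
#' @export
compute_ppm <- function(k, M) {
  if (any(M <= 0)) stop("M must be > 0")
  if (any(k < 0 | k > M)) stop("k must lie in [0, M]")
  1e6 * k / M
}

#' One-tailed Poisson detection test
#'
#' The observed aggregate signal `k` is tested against the expected
#' background noise `lambda` as the mean of a Poisson distribution:
#' `p = P(X >= k)` for `X ~ Poisson(lambda)`, the inclusive upper tail
#' (survival function at `k - 1`). `p` is 1 at `k = 0`.
#'
#' @param k Observed alt-supporting molecule count (non-negative integer,
#'   vectorized).
#' @param lambda_noise Expected background molecule count (> 0).
#' @return p-value(s) in (0, 1].
#' @export
poisson_detection_test <- function(k, lambda_noise) {
  if (any(lambda_noise <= 0))
    stop("lambda_noise must be > 0 (floor the error model upstream)")
  if (any(k < 0) || any(k != round(k)))
    stop("k must be a non-negative integer count")
  # overwhelming signal underflows the tail to 0; keep p strictly positive
  pmax(stats::ppois(k - 1, lambda = lambda_noise, lower.tail = FALSE),
       .Machine$double.xmin)
}

#' Classify a sample as ctDNA-positive or -negative
#'
#' Detection rests on the Poisson test p-value alone (never on an
#' allele-frequency cutoff): the sample is called detected when
#' `p <= p_threshold`, boundary inclusive.
#'
#' @param p_value p-value(s) from [poisson_detection_test()].
#' @param p_threshold Significance threshold, default 0.001 (chosen so
#'   analytical specificity exceeds 99.9%).
#' @return Logical detection status.
#' @export
call_detection_status <- function(p_value, p_threshold = 0.001) {
  if (any(p_value <= 0 | p_value > 1)) stop("p_value must lie in (0, 1]")
  p_value <= p_threshold
}

#' Tumor molecules per millilitre of plasma
#'
#' Rescales the detected tumor molecule count by the plasma volume from which
#' the cfDNA library was extracted (extraction efficiency taken as 1).
#'
#' @param k Tumor-derived (alt-supporting) molecule count.
#' @param plasma_volume_ml Plasma volume in ml (> 0).
#' @return Molecules per ml.
#' @export
tumor_molecules_per_ml <- function(k, plasma_volume_ml) {
  if (any(plasma_volume_ml <= 0)) stop("plasma_volume_ml must be > 0")
  k / plasma_volume_ml
}

#' Detect ctDNA in one sample from per-target observations
#'
#' Convenience wrapper running [aggregate_panel_signal()],
#' [compute_ppm()], [poisson_detection_test()] and
#' [call_detection_status()].
#'
#' @inheritParams aggregate_panel_signal
#' @inheritParams call_detection_status
#' @param plasma_volume_ml Optional plasma volume; when given,
#'   `tumor_molecules_per_ml` is reported.
#' @param sample_id Optional identifier carried through.
#' @return A `sample_detection_result`: list with `sample_id`, `k`, `M`,
#'   `lambda_noise`, `ppm`, `p_value`, `detected`, `tumor_molecules_per_ml`.
#' @export
detect_ctdna <- function(observations, p_threshold = 0.001,
                         plasma_volume_ml = NULL, sample_id = NA_character_) {
  agg <- aggregate_panel_signal(observations)
  p <- poisson_detection_test(agg$k, agg$lambda_noise)
  structure(list(sample_id = sample_id,
                 k = agg$k,
                 M = agg$M,
                 lambda_noise = agg$lambda_noise,
                 ppm = compute_ppm(agg$k, agg$M),
                 p_value = p,
                 detected = call_detection_status(p, p_threshold),
                 tumor_molecules_per_ml = if (is.null(plasma_volume_ml))
                   NA_real_ else tumor_molecules_per_ml(agg$k, plasma_volume_ml)),
            class = "sample_detection_result")
}

#' @export
print.sample_detection_result <- function(x, ...) {
  cat("ctDNA detection result", if (!is.na(x$sample_id))
    paste0(" [", x$sample_id, "]"), "\n",
    "  k = ", x$k, " alt molecules of M = ", x$M, " (",
    signif(x$ppm, 4), " ppm)\n",
    "  noise lambda = ", signif(x$lambda_noise, 4),
    ", p = ", signif(x$p_value, 4), " -> ",
    if (x$detected) "DETECTED" else "not detected", "\n", sep = "")
  invisible(x)
}

#' Predict the 95% limit of detection of a panel
#'
#' The LOD is the tumor fraction at which detection succeeds with probability
#' `sensitivity_target` at the configured specificity threshold. Analytic
#' construction: the critical signal count is
#' `k_crit = min{k : P(Poisson(lambda) >= k) <= p_threshold}`, and the
#' required total signal mean is
#' `mu* = min{mu : P(Poisson(mu) >= k_crit) >= sensitivity_target}` (found by
#' bisection); then `lod95_ppm = 1e6 / M * (mu* - lambda)`, the tumor-derived
#' component of the mean expressed as a fraction of `M` molecules. The
#' Monte-Carlo variant instead simulates detection over a tumor-fraction
#' search and agrees with the analytic value within Monte-Carlo error.
#'
#' @param assumed_M Assumed total unique molecules across the panel (> 0).
#' @param assumed_lambda Assumed aggregate background noise mean (> 0).
#' @param p_threshold Detection threshold, default 0.001.
#' @param sensitivity_target Target detection probability, default 0.95.
#' @param method `"analytic"` (default) or `"monte_carlo"`.
#' @param n_rep Simulations per evaluation for the Monte-Carlo method.
#' @param seed Seed for the Monte-Carlo method.
#' @return A `lod_estimate`: list with `lod95_ppm`, `k_crit`, `mu_star`,
#'   `p_threshold`, `sensitivity_target`, `assumed_M`, `assumed_lambda`,
#'   `method`, and `mc_se_ppm` (NA for analytic).
#' @export
predict_panel_lod <- function(assumed_M, assumed_lambda, p_threshold = 0.001,
                              sensitivity_target = 0.95,
                              method = c("analytic", "monte_carlo"),
                              n_rep = 4000L, seed = NULL) {
  method <- match.arg(method)
  if (assumed_M <= 0) stop("assumed_M must be > 0")
  if (assumed_lambda <= 0) stop("assumed_lambda must be > 0")
  k_crit <- detection_critical_count(assumed_lambda, p_threshold)

  if (method == "analytic") {
    # smallest mu with upper-tail mass >= target at k_crit; tail is strictly
    # increasing in mu so bisection applies
    f <- function(mu) stats::ppois(k_crit - 1, mu, lower.tail = FALSE) -
      sensitivity_target
    upper <- max(2 * k_crit, 10)
    while (f(upper) < 0) upper <- upper * 2
    mu_star <- stats::uniroot(f, c(0, upper), tol = 1e-10)$root
    mc_se <- NA_real_
  } else {
    if (!is.null(seed)) set.seed(seed)
    det_frac <- function(mu) {
      mean(stats::rpois(n_rep, mu) >= k_crit)
    }
    lo <- assumed_lambda
    hi <- max(2 * k_crit, 10)
    while (det_frac(hi) < sensitivity_target) hi <- hi * 2
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      if (det_frac(mid) < sensitivity_target) lo <- mid else hi <- mid
    }
    mu_star <- (lo + hi) / 2
    # binomial SE of the detection fraction mapped through the local slope
    slope <- stats::dpois(k_crit - 1, mu_star)
    mc_se <- sqrt(sensitivity_target * (1 - sensitivity_target) / n_rep) /
      slope * 1e6 / assumed_M
  }
  if (mu_star <= assumed_lambda)
    stop("target sensitivity unreachable: required signal mean does not ",
         "exceed the noise mean")
  structure(list(lod95_ppm = 1e6 / assumed_M * (mu_star - assumed_lambda),
                 k_crit = k_crit,
                 mu_star = mu_star,
                 p_threshold = p_threshold,
                 sensitivity_target = sensitivity_target,
                 assumed_M = assumed_M,
                 assumed_lambda = assumed_lambda,
                 method = method,
                 mc_se_ppm = mc_se),
            class = "lod_estimate")
}

# smallest integer k whose inclusive Poisson upper tail is <= p_threshold
detection_critical_count <- function(lambda, p_threshold = 0.001) {
  k <- stats::qpois(1 - p_threshold, lambda)  # fast starting point
  while (stats::ppois(k - 1, lambda, lower.tail = FALSE) > p_threshold)
    k <- k + 1L
  while (k > 0 &&
         stats::ppois(k - 2, lambda, lower.tail = FALSE) <= p_threshold)
    k <- k - 1L
  as.integer(k)
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat("Predicted 95% LOD: ", signif(x$lod95_ppm, 3), " ppm (", x$method,
      ")\n  k_crit = ", x$k_crit, ", mu* = ", signif(x$mu_star, 4),
      ", M = ", format(x$assumed_M, big.mark = ","),
      ", lambda = ", signif(x$assumed_lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Stratify a cohort by the median ctDNA level of detected samples
#'
#' Undetected samples form the `negative` group; detected samples at or below
#' the median ppm of the detected set are `low`, the rest `high` (values
#' equal to the median go to `low`).
#'
#' @param results List of `sample_detection_result`s, or a data.frame with
#'   columns `ppm` and `detected` (and optionally `sample_id`).
#' @return A `cohort_stratification`: list with `groups` (data.frame:
#'   `sample_id`, `ppm`, `detected`, `group`) and `median_ppm_of_detected`
#'   (NA when nothing is detected).
#' @export
stratify_cohort_by_median <- function(results) {
  if (is.data.frame(results)) {
    df <- results
    if (!"sample_id" %in% names(df))
      df$sample_id <- paste0("sample", seq_len(nrow(df)))
  } else {
    df <- do.call(rbind, lapply(results, function(r)
      data.frame(sample_id = r$sample_id, ppm = r$ppm, detected = r$detected,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("ppm", "detected") %in% names(df)))
  med <- if (any(df$detected)) stats::median(df$ppm[df$detected]) else NA_real_
  grp <- rep("negative", nrow(df))
  grp[df$detected & df$ppm <= med] <- "low"
  grp[df$detected & df$ppm > med] <- "high"
  df$group <- grp
  structure(list(groups = df[, c("sample_id", "ppm", "detected", "group")],
                 median_ppm_of_detected = med),
            class = "cohort_stratification")
}

#' @export
print.cohort_stratification <- function(x, ...) {
  cat("Cohort stratification (median detected ppm = ",
      signif(x$median_ppm_of_detected, 4), ")\n", sep = "")
  print(table(x$groups$group))
  invisible(x)
}
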