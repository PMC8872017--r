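# Missing-value imputation with Gaussian-process regression and per-feature
# z-score normalization. The GP is fitted per feature over the time axis of
# one series (never across patients); kernel hyperparameters are fixed by
# configuration so results are deterministic. Imputation runs before
# normalization; the denoising autoencoder (dae.R) runs after.

#' Gaussian-process imputation configuration
#'
#' Squared-exponential kernel `k(t, t') = signal_var * exp(-(t - t')^2 /
#' (2 * length_scale^2))` with observation noise `noise_var`. Values are fixed
#' (no marginal-likelihood optimization) to keep runs deterministic; the
#' defaults (3 h length scale on standardized values) suit hourly vitals.
#'
#' @param length_scale kernel length scale in hours (> 0).
#' @param signal_var signal variance (> 0).
#' @param noise_var observation-noise variance (> 0).
#' @param clamp optional c(lo, hi): imputed values outside this range are
#'   clamped (GP extrapolation can leave the physiologic range).
#' @return a `nasga_gpr_config`.
#' @export
gpr_config <- function(length_scale = 3, signal_var = 1, noise_var = 1e-2,
                       clamp = NULL) {
  if (length_scale <= 0 || signal_var <= 0 || noise_var <= 0)
    stop_config("length_scale, signal_var and noise_var must be > 0")
  structure(list(length_scale = length_scale, signal_var = signal_var,
                 noise_var = noise_var, clamp = clamp),
            class = "nasga_gpr_config")
}

se_kernel <- function(t1, t2, ls, sv) {
  sv * exp(-outer(t1, t2, "-")^2 / (2 * ls^2))
}

#' Impute gaps in an hourly series with the GP posterior mean
#'
#' Missing entries are replaced by the posterior mean of a squared-
#' exponential GP conditioned on the observed (hour, value) pairs; observed
#' values are preserved. The series is internally standardized by the
#' observed mean/sd so `signal_var` is on a unit scale. With zero observed
#' values, `fallback` (e.g. the training-split feature mean) is used and the
#' `fallback_used` attribute is set.
#'
#' @param y numeric series with `NA` gaps.
#' @param config a [gpr_config()].
#' @param times observation times (default `0:(length(y)-1)` hours).
#' @param fallback value used when nothing is observed (default `NA`).
#' @return the completed series.
#' @export
gpr_impute <- function(y, config = gpr_config(), times = NULL,
                       fallback = NA_real_) {
  stopifnot(inherits(config, "nasga_gpr_config"))
  t_all <- times %||% (seq_along(y) - 1)
  obs <- which(!is.na(y))
  mis <- which(is.na(y))
  if (!length(mis)) return(y)
  if (!length(obs)) {
    out <- rep(fallback, length(y))
    attr(out, "fallback_used") <- TRUE
    return(out)
  }
  mu <- mean(y[obs])
  sdv <- stats::sd(y[obs])
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  z <- (y[obs] - mu) / sdv
  Koo <- se_kernel(t_all[obs], t_all[obs], config$length_scale,
                   config$signal_var)
  diag(Koo) <- diag(Koo) + config$noise_var
  Kmo <- se_kernel(t_all[mis], t_all[obs], config$length_scale,
                   config$signal_var)
  post <- Kmo %*% solve(Koo, z)
  imputed <- mu + sdv * as.numeric(post)
  if (!is.null(config$clamp))
    imputed <- pmin(pmax(imputed, config$clamp[1]), config$clamp[2])
  y[mis] <- imputed
  y
}

#' Impute all missing entries of an episode set
#'
#' Each feature column of each 5 h window is imputed independently with
#' [gpr_impute()], conditioning only on observations inside the window (no
#' information crosses the window boundary). Columns with no observation at
#' all fall back to the per-feature means in `feature_means` (typically the
#' training-split means).
#'
#' @param es a `nasga_episodes`.
#' @param config a [gpr_config()].
#' @param feature_means named numeric vector of fallback means; computed from
#'   the observed values of `es` itself when omitted.
#' @return a complete `nasga_episodes` (no `NA` left).
#' @export
impute_episodes <- function(es, config = gpr_config(), feature_means = NULL) {
  if (is.null(feature_means)) {
    feature_means <- apply(es$x, 3, function(m) mean(m, na.rm = TRUE))
    feature_means[!is.finite(feature_means)] <- 0
  }
  n <- n_episodes(es)
  for (j in seq_along(es$features)) {
    fb <- feature_means[[es$features[j]]] %||% 0
    if (!is.finite(fb)) fb <- 0
    slab <- es$x[, , j, drop = FALSE]
    if (!anyNA(slab)) next
    for (i in seq_len(n)) {
      col <- es$x[i, , j]
      if (anyNA(col))
        es$x[i, , j] <- as.numeric(gpr_impute(col, config, fallback = fb))
    }
  }
  es
}

#' Fit / apply / invert a per-feature z-score normalizer
#'
#' Location and scale are learned from the training split only; constant
#' features get scale 1. `apply_normalizer` followed by `invert_normalizer`
#' recovers the input.
#'
#' @param train a complete `nasga_episodes` (training split).
#' @return `fit_normalizer`: a `nasga_normalizer` (per-feature mean/sd).
#' @export
fit_normalizer <- function(train) {
  m <- apply(train$x, 3, mean)
  s <- apply(train$x, 3, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  structure(list(mean = m, sd = s, features = train$features),
            class = "nasga_normalizer")
}

#' @rdname fit_normalizer
#' @param es episode set to transform.
#' @param norm a `nasga_normalizer`.
#' @export
apply_normalizer <- function(es, norm) {
  for (j in seq_along(norm$features))
    es$x[, , j] <- (es$x[, , j] - norm$mean[j]) / norm$sd[j]
  es
}

#' @rdname fit_normalizer
#' @export
invert_normalizer <- function(es, norm) {
  for (j in seq_along(norm$features))
    es$x[, , j] <- es$x[, , j] * norm$sd[j] + norm$mean[j]
  es
}
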