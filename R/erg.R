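# ERG amplitude-versus-intensity dose-response fitting.
#
# Standard model:  R = Rmax / (1 + 10^(logKA - logI))
# Biphasic model:  R = Rmax f / (1 + 10^(logKA - logI))
#                    + Rmax (1 - f) / (1 + 10^(logKB - logI))
# with I the flash intensity (cd s/m^2), Rmax the saturating amplitude (uV),
# KA (and KB) the half-maximal intensities and f the fraction of the curve
# carried by KA. All fitting is done in log10-intensity space.

.dr_predict <- function(par, logI, model) {
  if (model == "standard") {
    par[["r_max"]] / (1 + 10^(par[["log_ka"]] - logI))
  } else {
    par[["r_max"]] * par[["f"]] / (1 + 10^(par[["log_ka"]] - logI)) +
      par[["r_max"]] * (1 - par[["f"]]) / (1 + 10^(par[["log_kb"]] - logI))
  }
}

#' Construct an ERG amplitude sweep
#'
#' @param intensities Flash intensities in cd s/m^2, positive, strictly
#'   increasing.
#' @param amplitudes Eye-averaged wave amplitudes in microvolts, same length.
#' @param wave `"a"` or `"b"`.
#' @param regime `"scotopic"` or `"photopic"`.
#' @return Object of class `erg_sweep`.
#' @export
erg_sweep <- function(intensities, amplitudes, wave = c("a", "b"),
                      regime = c("scotopic", "photopic")) {
  wave <- match.arg(wave); regime <- match.arg(regime)
  stopifnot(length(intensities) == length(amplitudes))
  if (any(intensities <= 0)) stop("intensities must be positive")
  if (any(diff(intensities) <= 0)) stop("intensities must be strictly increasing")
  structure(list(intensities = as.numeric(intensities),
                 amplitudes = as.numeric(amplitudes),
                 wave = wave, regime = regime),
            class = "erg_sweep")
}

#' Fit an ERG dose-response model
#'
#' Unweighted least squares in log10-intensity space with box constraints
#' Rmax >= 0 and f in [0, 1]. For the biphasic model the identifiability
#' tie-break logKA < logKB is enforced by reordering (swapping KA/KB and
#' replacing f by 1 - f leaves the curve unchanged). Initialization splits
#' the log-intensity range around its midpoint for logKA/logKB with f = 0.5.
#'
#' @param sweep An [erg_sweep()] or data frame with columns `intensities`
#'   (or `intensity_cds_m2`) and `amplitudes` (or `amplitude_uV`).
#' @param model `"standard"` (3+ points) or `"biphasic"` (5+ points).
#' @return Object of class `dose_response_fit`: `model`, `r_max`, `log_ka`,
#'   optionally `log_kb` and `f`, standard errors (`se_*`), `residual_ss`,
#'   `n_points`.
#' @export
fit_dose_response <- function(sweep, model = c("standard", "biphasic")) {
  model <- match.arg(model)
  d <- .erg_xy(sweep)
  n <- nrow(d)
  if (model == "standard" && n < 3) stop("insufficient points: standard model needs >= 3")
  if (model == "biphasic" && n < 5) stop("insufficient points: biphasic model needs >= 5")

  logI <- d$logI; R <- d$R
  rmax0 <- max(R)
  mid <- mean(range(logI)); span <- diff(range(logI))

  if (model == "standard") {
    starts <- list(c(r_max = rmax0, log_ka = mid),
                   c(r_max = rmax0, log_ka = stats::median(logI)),
                   c(r_max = rmax0 * 1.2, log_ka = mid - span / 4))
    lower <- c(0, -Inf); upper <- c(Inf, Inf)
  } else {
    ka_grid <- c(min(logI), mid - span / 4, mid)
    kb_grid <- c(mid, mid + span / 4, max(logI))
    f_grid <- c(0.3, 0.5, 0.7, 1)
    starts <- list()
    for (ka in ka_grid) for (kb in kb_grid) for (fv in f_grid) {
      if (ka <= kb) starts <- c(starts, list(
        c(r_max = rmax0, log_ka = ka, log_kb = kb, f = fv)))
    }
    lower <- c(0, -Inf, -Inf, 0); upper <- c(Inf, Inf, Inf, 1)
  }

  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      minpack.lm::nls.lm(par = s,
                         fn = function(p) R - .dr_predict(as.list(p), logI, model),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || sum(o$fvec^2) < sum(best$fvec^2))) best <- o
  }
  if (is.null(best)) stop("fit failure: ", model, " dose-response did not converge")

  par <- as.list(best$par)
  ss <- sum(best$fvec^2)
  dof <- n - length(par)
  covm <- tryCatch(solve(best$hessian) * (ss / max(dof, 1)) * 2,
                   error = function(e) matrix(NA_real_, length(par), length(par)))
  ses <- sqrt(pmax(diag(covm), 0))
  names(ses) <- names(best$par)

  if (model == "biphasic" && par$log_ka > par$log_kb) {
    par[c("log_ka", "log_kb")] <- par[c("log_kb", "log_ka")]
    ses[c("log_ka", "log_kb")] <- ses[c("log_kb", "log_ka")]
    par$f <- 1 - par$f
  }

  structure(
    c(list(model = model),
      par,
      list(se = ses, residual_ss = ss, n_points = n)),
    class = "dose_response_fit"
  )
}

#' Predict ERG amplitude from a fitted dose-response model
#'
#' @param fit A `dose_response_fit`.
#' @param intensity Flash intensities in cd s/m^2; must be > 0.
#' @return Predicted amplitudes (uV).
#' @export
predict_dose_response <- function(fit, intensity) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (any(intensity <= 0)) stop("intensity must be > 0")
  .dr_predict(fit, log10(intensity), fit$model)
}

#' Select between standard and biphasic dose-response models
#'
#' The standard model is nested in the biphasic model (f = 1), so the two are
#' compared by an extra-sum-of-squares F test with 2 numerator degrees of
#' freedom (the biphasic model adds logKB and f):
#' F = ((SS_std - SS_bi)/2) / (SS_bi/(n - 4)). The biphasic model is chosen
#' iff p < alpha.
#'
#' @param sweep As for [fit_dose_response()]; needs >= 5 points.
#' @param alpha Significance level (default 0.05).
#' @return List: `preferred` (`dose_response_fit`), `standard`, `biphasic`,
#'   `f_statistic`, `df_num`, `df_den`, `p_value`, `alpha`.
#' @export
select_erg_model <- function(sweep, alpha = 0.05) {
  d <- .erg_xy(sweep)
  n <- nrow(d)
  if (n < 5) stop("degrees-of-freedom error: model selection needs >= 5 points")
  std <- fit_dose_response(sweep, "standard")
  bi <- fit_dose_response(sweep, "biphasic")
  df_den <- n - 4
  # the biphasic fit can never be worse than the nested standard fit
  ss_bi <- min(bi$residual_ss, std$residual_ss)
  gain <- std$residual_ss - ss_bi
  scale_ss <- max(std$residual_ss, sum(d$R^2))
  if (gain <= 1e-12 * scale_ss) {
    # identical residuals to numerical precision: no evidence for a 2nd site
    f_stat <- 0
  } else {
    f_stat <- (gain / 2) / (ss_bi / df_den)
  }
  p <- stats::pf(f_stat, 2, df_den, lower.tail = FALSE)
  list(preferred = if (p < alpha) bi else std,
       standard = std, biphasic = bi,
       f_statistic = f_stat, df_num = 2L, df_den = as.integer(df_den),
       p_value = p, alpha = alpha)
}

.erg_xy <- function(sweep) {
  if (inherits(sweep, "erg_sweep")) {
    data.frame(logI = log10(sweep$intensities), R = sweep$amplitudes)
  } else {
    d <- as.data.frame(sweep)
    icol <- intersect(c("intensities", "intensity_cds_m2", "intensity"), names(d))[1]
    acol <- intersect(c("amplitudes", "amplitude_uV", "amplitude"), names(d))[1]
    if (is.na(icol) || is.na(acol)) stop("sweep must carry intensity and amplitude columns")
    if (any(d[[icol]] <= 0)) stop("intensities must be positive")
    data.frame(logI = log10(d[[icol]]), R = d[[acol]])
  }
}
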