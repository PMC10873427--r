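# Rectangular-hyperbola FRET saturation fits and the specificity F test.

#' Fit a FRET saturation curve
#'
#' Fits E = Emax * x / (EC50 + x) to efficiency-versus-A:D points by
#' unweighted nonlinear least squares (Levenberg-Marquardt with box
#' constraints Emax in [0, 1], EC50 > 0). Starting values are Emax = max(E)
#' (clamped into the bounds) and EC50 = median(A:D), with a small multi-start
#' fallback grid if the first attempt fails to converge.
#'
#' @param points Data frame with columns `acceptor_donor_ratio` and
#'   `efficiency` (a column named after `component`, e.g. `e_total`, is also
#'   accepted).
#' @param component One of `"total"`, `"dm_sensitive"`, `"dm_insensitive"`.
#' @return An object of class `fret_curve_fit`: `component`, `e_max`, `ec50`,
#'   `se_e_max`, `se_ec50`, `residual_ss`, `n_points`, plus the data used.
#' @export
fit_fret_curve <- function(points,
                           component = c("total", "dm_sensitive", "dm_insensitive")) {
  component <- match.arg(component)
  xy <- .fret_xy(points, component)
  if (nrow(xy) < 3) stop("insufficient data: need at least 3 points")
  if (any(xy$x < 0)) stop("A:D ratios must be >= 0")

  start_emax <- min(max(max(xy$y), 0.01), 1)
  ec50_grid <- unique(pmax(c(stats::median(xy$x), mean(xy$x), max(xy$x) / 2,
                             min(xy$x[xy$x > 0], 1), 5 * max(xy$x)), 1e-3))
  emax_grid <- unique(c(start_emax, 0.5, 0.05, 1))
  starts <- lapply(seq_len(length(ec50_grid) * length(emax_grid)), function(i) {
    c(emax = emax_grid[(i - 1) %% length(emax_grid) + 1],
      ec50 = ec50_grid[(i - 1) %/% length(emax_grid) + 1])
  })
  fit <- .hyperbola_nls(xy, starts)
  if (is.null(fit)) {
    stop("fit failure: hyperbola did not converge from any start (n = ",
         nrow(xy), ", max E = ", signif(max(xy$y), 3), ")")
  }
  co <- summary(fit)$coefficients
  structure(
    list(component = component,
         e_max = co["emax", "Estimate"],
         ec50 = co["ec50", "Estimate"],
         se_e_max = co["emax", "Std. Error"],
         se_ec50 = co["ec50", "Std. Error"],
         residual_ss = sum(stats::residuals(fit)^2),
         n_points = nrow(xy),
         data = xy),
    class = "fret_curve_fit"
  )
}

#' Predicted efficiency from a fitted FRET curve
#'
#' @param fit A `fret_curve_fit`.
#' @param acceptor_donor_ratio A:D values (>= 0).
#' @return Predicted efficiencies.
#' @export
predict_fret <- function(fit, acceptor_donor_ratio) {
  stopifnot(inherits(fit, "fret_curve_fit"))
  fit$e_max * acceptor_donor_ratio / (fit$ec50 + acceptor_donor_ratio)
}

#' Extra-sum-of-squares F test against the non-specific FRET ceiling
#'
#' A fitted Emax is only evidence of physiological complexes if it exceeds
#' the non-specific FRET ceiling. The null model fixes Emax at the ceiling
#' (EC50 stays free); the alternative frees both parameters. With SS0 and SS1
#' the residual sums of squares of the null and full fits on n points,
#'
#' \deqn{F = \frac{(SS_0 - SS_1)/1}{SS_1/(n - 2)}}
#'
#' and p comes from the upper tail of F(1, n - 2). The call is one-sided in
#' interpretation: `is_specific` additionally requires the fitted Emax to
#' exceed the ceiling.
#'
#' @param points As for [fit_fret_curve()].
#' @param e_max_nonspecific Non-specific FRET Emax ceiling (required; the
#'   value is calibration-dependent and must be supplied per component).
#' @param alpha Significance level (default 0.05).
#' @param component Which efficiency column to test.
#' @return Object of class `specificity_result` with `f_statistic`, `df_num`,
#'   `df_den`, `p_value`, `e_max_nonspecific`, `is_specific`, `ss_null`,
#'   `ss_alt`, and the full fit.
#' @export
test_specificity <- function(points, e_max_nonspecific, alpha = 0.05,
                             component = c("total", "dm_sensitive", "dm_insensitive")) {
  component <- match.arg(component)
  xy <- .fret_xy(points, component)
  n <- nrow(xy)
  if (n < 4) stop("degrees-of-freedom error: need more points than free model parameters + 1")
  stopifnot(is.finite(e_max_nonspecific), e_max_nonspecific >= 0)

  full <- fit_fret_curve(xy, component = component)
  ss_alt <- full$residual_ss

  # null: Emax pinned to the ceiling, EC50 free
  null_resid <- function(p) xy$y - e_max_nonspecific * xy$x / (p[1] + xy$x)
  nullfits <- lapply(c(full$ec50, stats::median(xy$x), max(xy$x) / 2 + 1e-3),
                     function(s0) {
    tryCatch(
      minpack.lm::nls.lm(par = max(s0, 1e-6), fn = null_resid,
                         lower = 1e-9, upper = Inf,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  nullfits <- Filter(Negate(is.null), nullfits)
  if (length(nullfits) == 0) stop("fit failure: null (ceiling) model did not converge")
  ss_null <- min(vapply(nullfits, function(f) sum(f$fvec^2), numeric(1)))

  df_den <- n - 2
  f_stat <- ((ss_null - ss_alt) / 1) / (ss_alt / df_den)
  p <- stats::pf(f_stat, 1, df_den, lower.tail = FALSE)
  structure(
    list(f_statistic = f_stat,
         df_num = 1L,
         df_den = as.integer(df_den),
         p_value = p,
         e_max_nonspecific = e_max_nonspecific,
         is_specific = (p < alpha) && (full$e_max > e_max_nonspecific),
         ss_null = ss_null,
         ss_alt = ss_alt,
         alpha = alpha,
         fit = full),
    class = "specificity_result"
  )
}

#' Fraction of specific FRET carried by each component
#'
#' Components failing the specificity test contribute zero. The remaining
#' specific Emax values are normalized to fractions summing to one. If both
#' components are non-specific there is no specific signal to apportion and a
#' flagged absence is returned instead of numbers.
#'
#' @param fit_sensitive,fit_insensitive `fret_curve_fit` objects for the
#'   DM-sensitive and DM-insensitive components of one sample set.
#' @param specific_sensitive,specific_insensitive Logical specificity flags
#'   (from [test_specificity()]).
#' @return List with `defined` (logical), `fraction_sensitive`,
#'   `fraction_insensitive` (NA when `defined` is FALSE).
#' @export
component_fractions <- function(fit_sensitive, fit_insensitive,
                                specific_sensitive, specific_insensitive) {
  stopifnot(inherits(fit_sensitive, "fret_curve_fit"),
            inherits(fit_insensitive, "fret_curve_fit"))
  e_s <- if (isTRUE(specific_sensitive)) fit_sensitive$e_max else 0
  e_i <- if (isTRUE(specific_insensitive)) fit_insensitive$e_max else 0
  total <- e_s + e_i
  if (total <= 0) {
    return(list(defined = FALSE,
                fraction_sensitive = NA_real_,
                fraction_insensitive = NA_real_))
  }
  list(defined = TRUE,
       fraction_sensitive = e_s / total,
       fraction_insensitive = e_i / total)
}

# extract (x, y) for a component from a flexible points table
.fret_xy <- function(points, component) {
  points <- as.data.frame(points)
  xcol <- intersect(c("acceptor_donor_ratio", "x"), names(points))[1]
  ycols <- c("efficiency", "y",
             paste0("e_", sub("^total$", "total", component)),
             switch(component,
                    total = "e_total",
                    dm_sensitive = "e_dm_sensitive",
                    dm_insensitive = "e_dm_insensitive"))
  ycol <- intersect(ycols, names(points))[1]
  if (is.na(xcol) || is.na(ycol)) {
    stop("points must contain an A:D column and an efficiency column")
  }
  data.frame(x = points[[xcol]], y = points[[ycol]])
}

.hyperbola_nls <- function(xy, starts) {
  best <- NULL; best_ss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ emax * x / (ec50 + x), data = xy,
        start = as.list(s),
        lower = c(0, 1e-9), upper = c(1, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::residuals(fit)^2)
      if (ss < best_ss) { best <- fit; best_ss <- ss }
    }
  }
  best
}
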