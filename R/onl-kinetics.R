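# Outer-nuclear-layer degeneration kinetics: spider-plot windowing, joint
# constrained one-phase-decay fits, rate comparisons, and discrimination of
# one-hit (exponential) versus cumulative-damage (sigmoidal) loss kinetics.

#' Reference photoreceptor-loss rate constants for the knockin models
#'
#' Published one-phase-decay rate constants k (month^-1, with standard
#' errors) of outer-nuclear-layer thinning in C57BL/6J (B6) mice and in mice
#' heterozygous or homozygous for the P23H or G188R rhodopsin mutation, by
#' retinal region. These are the reference inputs for fold-change statements
#' about degeneration speed (e.g. G188R/+ versus P23H/+).
#'
#' @return Tibble with columns `region`, `genotype`, `k`, `se_k`.
#' @export
onl_decay_rates <- function() {
  tibble::tibble(
    region = rep(c("superior", "inferior"), each = 5),
    genotype = rep(c("B6", "P23H_het", "G188R_het", "P23H_hom", "G188R_hom"), 2),
    k = c(4.1e-9, 0.24, 0.49, 1.84, 3.29,
          3.4e-3, 0.41, 0.78, 1.55, 3.51),
    se_k = c(0.006, 0.02, 0.03, 0.12, 0.29,
             0.008, 0.03, 0.07, 0.12, 0.42)
  )
}

#' Average spider-plot counts over the standard eccentricity window
#'
#' Kinetic time courses use the mean of the nuclei counts at 600, 800, and
#' 1000 micrometres from the optic nerve. Eccentricity is signed: positive is
#' superior, negative inferior; the region selects the sign.
#'
#' @param profile Data frame with columns `eccentricity_um` and
#'   `nuclei_count` (one spider profile).
#' @param region `"superior"` or `"inferior"`.
#' @param positions Unsigned window positions in micrometres.
#' @return Mean count over the window positions.
#' @export
window_average <- function(profile, region = c("superior", "inferior"),
                           positions = c(600, 800, 1000)) {
  region <- match.arg(region)
  profile <- as.data.frame(profile)
  sgn <- if (region == "superior") 1 else -1
  vals <- vapply(positions, function(p) {
    hit <- which(profile$eccentricity_um == sgn * p)
    if (length(hit) == 0) {
      stop(sprintf("missing position: no entry at %d um for %s region",
                   sgn * p, region))
    }
    mean(profile$nuclei_count[hit])
  }, numeric(1))
  mean(vals)
}

.decay_predict <- function(y0, k, plateau, x) (y0 - plateau) * exp(-k * x) + plateau

#' Joint constrained one-phase-decay fit
#'
#' Fits y = (y0 - plateau) * exp(-k x) + plateau to one or more nuclei-count
#' time courses by global least squares. Series analysed together share one
#' y0 (the age-zero layer thickness) and each gets its own rate constant k
#' (month^-1); the plateau is fixed (default 1 nucleus, the residual cone
#' row, so the model describes rod loss only). Standard errors come from the
#' Gauss-Newton covariance of the joint fit.
#'
#' @param series Named list of data frames, each with columns `age` (months,
#'   > 0) and `value` (windowed mean nuclei count); each series needs at
#'   least 3 time points. A single data frame is treated as one series.
#' @param share_y0 Share y0 across series (default TRUE). With FALSE each
#'   series is fit independently and results are pooled into one report.
#' @param plateau Fixed floor (default 1).
#' @return Object of class `joint_decay_fit`: `shared_y0`, `se_y0`,
#'   `per_series` (tibble `series`, `k`, `se_k`), `plateau_fixed`,
#'   `residual_ss`, `n_points`, `converged`.
#' @export
fit_one_phase_decay <- function(series, share_y0 = TRUE, plateau = 1) {
  if (is.data.frame(series)) series <- list(series = series)
  if (is.null(names(series)) || any(names(series) == "")) {
    names(series) <- paste0("series_", seq_along(series))
  }
  series <- lapply(series, as.data.frame)
  for (nm in names(series)) {
    d <- series[[nm]]
    if (nrow(d) < 3) stop("series '", nm, "' has fewer than 3 time points")
    if (any(d$age <= 0)) stop("ages must be > 0 (series '", nm, "')")
  }

  if (!share_y0 && length(series) > 1) {
    fits <- lapply(names(series), function(nm) {
      fit_one_phase_decay(series[nm], share_y0 = TRUE, plateau = plateau)
    })
    per <- dplyr::bind_rows(lapply(fits, `[[`, "per_series"))
    return(structure(
      list(shared_y0 = vapply(fits, `[[`, numeric(1), "shared_y0"),
           se_y0 = vapply(fits, `[[`, numeric(1), "se_y0"),
           per_series = per,
           plateau_fixed = plateau,
           residual_ss = sum(vapply(fits, `[[`, numeric(1), "residual_ss")),
           n_points = sum(vapply(fits, `[[`, numeric(1), "n_points")),
           converged = all(vapply(fits, `[[`, logical(1), "converged"))),
      class = "joint_decay_fit"))
  }

  ns <- length(series)
  ages <- lapply(series, `[[`, "age")
  vals <- lapply(series, `[[`, "value")
  n_tot <- sum(lengths(vals))

  # starts: y0 from the youngest observations; k from a log-linear slope
  y0_0 <- max(vapply(vals, max, numeric(1)))
  k_0 <- vapply(seq_len(ns), function(i) {
    y <- vals[[i]] - plateau
    ok <- y > 1e-6
    if (sum(ok) >= 2) {
      sl <- -stats::coef(stats::lm(log(y[ok]) ~ ages[[i]][ok]))[2]
      max(min(sl, 50), 1e-4)
    } else 1
  }, numeric(1))

  resid_fn <- function(par) {
    y0 <- par[1]; ks <- par[-1]
    unlist(lapply(seq_len(ns), function(i) {
      vals[[i]] - .decay_predict(y0, ks[i], plateau, ages[[i]])
    }), use.names = FALSE)
  }
  out <- minpack.lm::nls.lm(
    par = c(y0_0, k_0),
    lower = c(plateau, rep(0, ns)),
    upper = rep(Inf, ns + 1),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  converged <- out$info %in% 1:4
  if (!converged) {
    warning("joint decay fit did not converge cleanly (nls.lm info = ",
            out$info, ": ", out$message, ")")
  }
  ss <- sum(out$fvec^2)
  dof <- n_tot - (ns + 1)
  covm <- tryCatch({
    hi <- solve(out$hessian)
    hi * (ss / max(dof, 1)) * 2  # hessian is 2 J'J at the optimum
  }, error = function(e) matrix(NA_real_, ns + 1, ns + 1))
  ses <- sqrt(pmax(diag(covm), 0))

  structure(
    list(shared_y0 = out$par[1],
         se_y0 = ses[1],
         per_series = tibble::tibble(series = names(series),
                                     k = out$par[-1],
                                     se_k = ses[-1]),
         plateau_fixed = plateau,
         residual_ss = ss,
         n_points = n_tot,
         converged = converged),
    class = "joint_decay_fit"
  )
}

#' Compare two photoreceptor-loss rate constants
#'
#' @param k_a,k_b Rate constants in month^-1; `k_b` is the denominator and
#'   must be > 0.
#' @return List of class `rate_comparison`: `ratio` (k_a / k_b),
#'   `percent_difference` (100 * (ratio - 1)), `rounded_ratio` (nearest
#'   integer, halves away from zero, matching "x times faster" statements).
#' @export
rate_ratio <- function(k_a, k_b) {
  if (!is.finite(k_b) || k_b <= 0) stop("undefined ratio: k_b must be > 0")
  ratio <- k_a / k_b
  structure(
    list(ratio = ratio,
         percent_difference = 100 * (ratio - 1),
         rounded_ratio = as.integer(sign(ratio) * floor(abs(ratio) + 0.5))),
    class = "rate_comparison"
  )
}

.aicc <- function(ss, n, n_par) {
  p <- n_par + 1  # + residual variance
  if (n - p - 1 <= 0) return(Inf)
  n * log(ss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' One-hit versus cumulative-damage kinetics
#'
#' Exponential photoreceptor loss is the signature of one-hit (stochastic,
#' constant-risk) cell death; cumulative damage predicts sigmoidal kinetics.
#' Fits the one-phase decay (2 free parameters: y0, k; floor fixed) and a
#' descending-sigmoid alternative
#' y = plateau + (y0 - plateau) / (1 + exp((x - x50) / s))
#' (3 free parameters) to the same points and compares them by small-sample
#' AIC (AICc; the models are not nested).
#'
#' @param points Data frame with columns `age` and `value`; at least 5 points
#'   (replicate-level per-mouse points satisfy this at the standard 4-age
#'   design).
#' @param plateau Fixed floor (default 1).
#' @return List: `ss_exponential`, `ss_sigmoid`, `aicc_exponential`,
#'   `aicc_sigmoid`, `preferred` (`"exponential"` or `"sigmoid"`), and both
#'   parameter sets.
#' @export
compare_decay_models <- function(points, plateau = 1) {
  points <- as.data.frame(points)
  n <- nrow(points)
  if (n < 5) stop("insufficient points: the sigmoid alternative needs at least 5")
  x <- points$age; y <- points$value

  efit <- fit_one_phase_decay(list(series = points), plateau = plateau)
  ss_exp <- efit$residual_ss

  sig_resid <- function(par) {
    y - (plateau + (par[1] - plateau) / (1 + exp((x - par[2]) / par[3])))
  }
  starts <- list(c(max(y), stats::median(x), diff(range(x)) / 4),
                 c(max(y), mean(range(x)), diff(range(x)) / 10),
                 c(max(y), min(x), diff(range(x)) / 2))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = sig_resid,
                         lower = c(plateau, -Inf, 1e-6),
                         upper = c(Inf, Inf, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || sum(o$fvec^2) < sum(best$fvec^2))) best <- o
  }
  if (is.null(best)) stop("fit failure: sigmoid alternative did not converge")
  ss_sig <- sum(best$fvec^2)

  aicc_exp <- .aicc(max(ss_exp, .Machine$double.xmin), n, 2)
  aicc_sig <- .aicc(max(ss_sig, .Machine$double.xmin), n, 3)
  list(ss_exponential = ss_exp,
       ss_sigmoid = ss_sig,
       aicc_exponential = aicc_exp,
       aicc_sigmoid = aicc_sig,
       preferred = if (aicc_exp <= aicc_sig) "exponential" else "sigmoid",
       exponential = list(y0 = efit$shared_y0, k = efit$per_series$k[1],
                          plateau = plateau),
       sigmoid = list(y0 = best$par[1], x50 = best$par[2], s = best$par[3],
                      plateau = plateau))
}
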