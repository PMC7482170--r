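# Single-hit multitarget survival model:
#   S(D) = 1 - (1 - exp(-D / D0))^n
# D0 is the mean lethal dose per target, n the extrapolation number
# (continuous, >= 1). The quasi-threshold ("shoulder") dose is
# Dq = D0 * ln(n); Dq = 0 iff n = 1, and S(0) = 1 for any parameters.

#' Single-hit multitarget survival function
#'
#' @param dose Dose(s) in Gray.
#' @param d0 Mean lethal dose per target (Gy, > 0).
#' @param n Extrapolation number (>= 1).
#' @return Predicted surviving fraction(s).
#' @export
shmt_survival <- function(dose, d0, n) {
  stopifnot(d0 > 0, n >= 1)
  1 - (1 - exp(-dose / d0))^n
}

#' Per-dose survival fractions
#'
#' @param observations `data.frame` with columns `dose_gy`, `n_sown`,
#'   `n_survived` and `replicate`.
#' @param normalize Divide all fractions by the mean 0-Gy control fraction
#'   when that control is below 1 (default `FALSE`: absolute fractions).
#' @return A `data.frame` with `dose_gy`, `mean_fraction`, `se_fraction`
#'   (`NA` for a single replicate) and `n_reps`.
#' @export
survival_fractions <- function(observations, normalize = FALSE) {
  obs <- observations
  stopifnot(all(c("dose_gy", "n_sown", "n_survived") %in% names(obs)))
  if (any(obs$n_sown <= 0)) stop("n_sown must be positive")
  if (any(obs$n_survived < 0 | obs$n_survived > obs$n_sown))
    stop("n_survived must be between 0 and n_sown")
  frac <- obs$n_survived / obs$n_sown
  doses <- sort(unique(obs$dose_gy))
  out <- data.frame(
    dose_gy = doses,
    mean_fraction = vapply(doses, function(d) mean(frac[obs$dose_gy == d]),
                           0),
    se_fraction = vapply(doses, function(d) {
      f <- frac[obs$dose_gy == d]
      if (length(f) > 1L) se_mean(f) else NA_real_
    }, 0),
    n_reps = vapply(doses, function(d) sum(obs$dose_gy == d), 0L))
  if (normalize && 0 %in% doses) {
    ctrl <- out$mean_fraction[out$dose_gy == 0]
    if (ctrl < 1 && ctrl > 0) {
      out$mean_fraction <- pmin(1, out$mean_fraction / ctrl)
      out$se_fraction <- out$se_fraction / ctrl
    }
  }
  out
}

#' Fit the single-hit multitarget model
#'
#' Unweighted least squares on the linear survival-fraction scale, with a
#' deterministic multi-start over a log-spaced (D0, n) grid to avoid local
#' minima of the non-convex residual surface. Ties are broken by lowest
#' residual sum of squares, then lowest extrapolation number.
#'
#' @param dose Doses in Gray (>= 3 distinct values including a low-dose or
#'   control point).
#' @param fraction Surviving fractions in (0, 1]; zeros are replaced by
#'   `zero_floor`.
#' @param zero_floor Floor substituted for fractions of 0 (default `1/180`,
#'   i.e. half a plant out of three replicates of 30).
#' @param d0_grid,n_grid Optional start grids; sensible log-spaced defaults
#'   are derived from the dose range.
#' @return An object of class `survival_fit`: list with `d0_gy`,
#'   `n_extrapolation`, `dq_gy` (`= d0_gy * log(n_extrapolation)`), `rss`,
#'   `se` (approximate standard errors for d0, n and Dq; `NA` when the
#'   fit sits on the `n = 1` boundary), `converged`, `n_starts_converged`
#'   and the data. When no start converges the object has
#'   `converged = FALSE` and carries diagnostics instead of parameters.
#' @export
#' @examples
#' d <- seq(0, 600, by = 50)
#' f <- shmt_survival(d, d0 = 200, n = 3)
#' fit <- fit_single_hit_multitarget(d, f)
#' c(fit$d0_gy, fit$n_extrapolation, fit$dq_gy)
fit_single_hit_multitarget <- function(dose, fraction, zero_floor = 1 / 180,
                                       d0_grid = NULL, n_grid = NULL) {
  stopifnot(length(dose) == length(fraction), all(dose >= 0))
  if (length(unique(dose)) < 3L)
    stop("at least 3 distinct doses are required")
  fraction[fraction <= 0] <- zero_floor
  if (any(fraction > 1)) stop("fractions must be in (0, 1]")
  dmax <- max(dose[dose > 0])
  if (is.null(d0_grid))
    d0_grid <- exp(seq(log(dmax / 30), log(3 * dmax), length.out = 7))
  if (is.null(n_grid)) n_grid <- c(1, 2, 4, 8, 16, 32)
  dat <- data.frame(dose = dose, fraction = fraction)
  fits <- list()
  for (d0s in d0_grid) for (ns in n_grid) {
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      fraction ~ 1 - (1 - exp(-dose / d0))^n,
      data = dat, start = list(d0 = d0s, n = ns),
      lower = c(d0 = 1e-9, n = 1), upper = c(d0 = Inf, n = 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      silent = TRUE)
    if (!inherits(f, "try-error")) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L)
    return(structure(list(converged = FALSE,
                          diagnostics = "no start converged",
                          dose = dose, fraction = fraction),
                     class = "survival_fit"))
  rss <- vapply(fits, deviance, 0)
  nval <- vapply(fits, function(f) unname(coef(f)["n"]), 0)
  ord <- order(rss, nval)
  # ties in RSS (to numerical noise) resolved by lowest n
  best_rss <- rss[ord[1L]]
  tied <- which(rss <= best_rss + 1e-10 * max(1, best_rss))
  best <- fits[[tied[which.min(nval[tied])]]]
  cf <- coef(best)
  d0 <- unname(cf["d0"]); nn <- unname(cf["n"])
  dq <- d0 * log(nn)
  se <- c(d0 = NA_real_, n = NA_real_, dq = NA_real_)
  vc <- try(suppressWarnings(vcov(best)), silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(vc))) {
    se["d0"] <- sqrt(vc["d0", "d0"])
    se["n"] <- sqrt(vc["n", "n"])
    # delta method for Dq = d0 * log(n)
    g <- c(log(nn), d0 / nn)
    v <- drop(t(g) %*% vc %*% g)
    if (is.finite(v) && v >= 0) se["dq"] <- sqrt(v)
  }
  structure(list(d0_gy = d0, n_extrapolation = nn, dq_gy = dq,
                 rss = deviance(best), se = se, converged = TRUE,
                 n_starts_converged = length(fits),
                 dose = dose, fraction = fraction),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("single-hit multitarget fit: NOT converged (",
        x$diagnostics, ")\n", sep = "")
    return(invisible(x))
  }
  cat("single-hit multitarget fit\n")
  cat(sprintf("  D0 = %.4g Gy (se %.3g)\n", x$d0_gy, x$se["d0"]))
  cat(sprintf("  n  = %.4g (se %.3g)\n", x$n_extrapolation, x$se["n"]))
  cat(sprintf("  Dq = %.4g Gy (se %.3g)\n", x$dq_gy, x$se["dq"]))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, length(x$dose)))
  invisible(x)
}

#' Predicted survival curve of a fit
#'
#' @param fit A converged `survival_fit`.
#' @param dose Doses at which to predict (default: 200 points spanning the
#'   fitted dose range).
#' @return `data.frame` with `dose_gy` and `fraction`.
#' @export
predict_survival <- function(fit, dose = NULL) {
  stopifnot(inherits(fit, "survival_fit"), isTRUE(fit$converged))
  if (is.null(dose))
    dose <- seq(0, max(fit$dose), length.out = 200)
  data.frame(dose_gy = dose,
             fraction = shmt_survival(dose, fit$d0_gy,
                                      fit$n_extrapolation))
}
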