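#' Hill growth-curve parameters
#'
#' Container for the three parameters of the Hill sigmoid
#' \eqn{l(a) = l_{max} a^n / (t_{1/2}^n + a^n)} used as the size-versus-age
#' calibration curve of an organ rank.
#'
#' @param l_max mature (asymptotic) length, in micrometres; must be > 0.
#' @param t_half age at which length reaches \code{l_max / 2}, in hours;
#'   must be > 0.
#' @param n Hill exponent (dimensionless steepness); must be > 0.
#'
#' @return An object of class \code{hill_params}.
#' @examples
#' hp <- hill_params(l_max = 100, t_half = 200, n = 3)
#' hill_eval(hp, 200)  # 50
#' @export
hill_params <- function(l_max, t_half, n) {
  stopifnot(is.numeric(l_max), is.numeric(t_half), is.numeric(n),
            length(l_max) == 1L, length(t_half) == 1L, length(n) == 1L)
  if (!(l_max > 0 && t_half > 0 && n > 0))
    stop("all Hill parameters (l_max, t_half, n) must be strictly positive")
  structure(list(l_max = l_max, t_half = t_half, n = n),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill growth curve: l_max = %.6g um, t_half = %.6g h, n = %.4g\n",
              x$l_max, x$t_half, x$n))
  invisible(x)
}

#' Evaluate the Hill growth curve
#'
#' @param params a \code{\link{hill_params}} object.
#' @param age_h organ age(s) since initiation, hours; must be >= 0.
#' @return Length(s) in micrometres: \code{l_max * age^n / (t_half^n + age^n)}.
#' @export
hill_eval <- function(params, age_h) {
  stopifnot(inherits(params, "hill_params"), all(age_h >= 0))
  # evaluate on the log-ratio scale for numerical stability at large n
  r <- (age_h / params$t_half)^params$n
  out <- params$l_max * r / (1 + r)
  out[is.infinite(r)] <- params$l_max
  out
}

#' Invert the Hill growth curve: age from length
#'
#' Exact inverse of \code{\link{hill_eval}}:
#' \eqn{a = t_{1/2} (l / (l_{max} - l))^{1/n}}. This is the calibration used
#' to date organs from their measured size.
#'
#' @param params a \code{\link{hill_params}} object.
#' @param length_um measured length(s), micrometres; must lie in
#'   (0, l_max) unless \code{clamp = TRUE}.
#' @param clamp if \code{TRUE}, lengths at or above
#'   \code{(1 - clamp_eps) * l_max} are clamped to that value (with a
#'   warning) instead of raising an error; mature organs routinely exceed
#'   the fitted asymptote under measurement noise.
#' @param clamp_eps relative clamping margin, default \code{1e-3}.
#' @return Age(s) in hours since initiation.
#' @export
hill_inverse <- function(params, length_um, clamp = FALSE, clamp_eps = 1e-3) {
  stopifnot(inherits(params, "hill_params"), all(length_um > 0))
  l <- length_um
  if (clamp) {
    cap <- (1 - clamp_eps) * params$l_max
    n_over <- sum(l >= cap)
    if (n_over > 0) {
      warning(sprintf("%d length(s) >= (1 - %.0e) * l_max clamped before inversion",
                      n_over, clamp_eps))
      l <- pmin(l, cap)
    }
  } else if (any(l >= params$l_max)) {
    stop("length >= l_max cannot be inverted; use clamp = TRUE to cap near-mature lengths")
  }
  params$t_half * (l / (params$l_max - l))^(1 / params$n)
}

#' Growth features of a fitted Hill curve
#'
#' Derives the age of maximal growth (inflection of the length curve), the
#' maximal absolute growth rate, and the relative growth rate at that age.
#' With \eqn{l(a) = l_{max} a^n / (t_{1/2}^n + a^n)} the derivative is
#' \eqn{l'(a) = l_{max} n t_{1/2}^n a^{n-1} / (t_{1/2}^n + a^n)^2}, maximal at
#' \eqn{t_{infl} = t_{1/2} ((n-1)/(n+1))^{1/n}} provided \eqn{n > 1}. For
#' \eqn{n \le 1} the growth rate is maximal at age 0+ and the inflection age
#' is undefined; the result is returned with \code{defined = FALSE}.
#'
#' @param params a \code{\link{hill_params}} object.
#' @return A list of class \code{growth_features}: \code{t_infl} (h),
#'   \code{v_max} (um/h), \code{rgr_at_infl} (1/h), \code{defined}.
#' @export
growth_features <- function(params) {
  stopifnot(inherits(params, "hill_params"))
  n <- params$n; th <- params$t_half; lm <- params$l_max
  if (n <= 1) {
    return(structure(list(t_infl = NA_real_, v_max = NA_real_,
                          rgr_at_infl = NA_real_, defined = FALSE),
                     class = "growth_features"))
  }
  t_infl <- th * ((n - 1) / (n + 1))^(1 / n)
  v_max <- hill_deriv(params, t_infl)
  rgr <- v_max / hill_eval(params, t_infl)
  structure(list(t_infl = t_infl, v_max = v_max, rgr_at_infl = rgr,
                 defined = TRUE),
            class = "growth_features")
}

#' @export
print.growth_features <- function(x, ...) {
  if (!x$defined) {
    cat("growth features undefined (Hill exponent n <= 1: growth rate maximal at age 0+)\n")
  } else {
    cat(sprintf("t_infl = %.4g h, v_max = %.4g um/h, RGR at t_infl = %.4g 1/h\n",
                x$t_infl, x$v_max, x$rgr_at_infl))
  }
  invisible(x)
}

# analytic derivative dl/da of the Hill curve
hill_deriv <- function(params, age_h) {
  n <- params$n; th <- params$t_half; lm <- params$l_max
  lm * n * th^n * age_h^(n - 1) / (th^n + age_h^n)^2
}

#' Shift size observations from plant age to organ age
#'
#' Subtracts the organ's initiation time \code{T_h} from plant ages; rows
#' at or before initiation carry no size information and are dropped (their
#' number is reported via an attribute and a message).
#'
#' @param lengths data frame with columns \code{individual_id},
#'   \code{plant_age_h}, \code{length_um}.
#' @param T_h initiation time of the rank, hours since sowing (>= 0).
#' @param quiet suppress the dropped-row message.
#' @return The input with a \code{leaf_age_h} column, pre-initiation rows
#'   removed; attribute \code{n_dropped} records how many were removed.
#' @export
shift_to_leaf_age <- function(lengths, T_h, quiet = FALSE) {
  stopifnot(is.data.frame(lengths),
            all(c("plant_age_h", "length_um") %in% names(lengths)),
            length(T_h) == 1L, T_h >= 0)
  lengths$leaf_age_h <- lengths$plant_age_h - T_h
  keep <- lengths$leaf_age_h > 0
  n_dropped <- sum(!keep)
  if (n_dropped == nrow(lengths))
    stop("all observations predate the initiation time T_h; nothing to fit")
  if (n_dropped > 0 && !quiet)
    message(sprintf("shift_to_leaf_age: dropped %d pre-initiation row(s)", n_dropped))
  out <- lengths[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Inverse-variance weights from age-binned length variances
#'
#' Groups shifted observations into fixed-width age bins and assigns every
#' observation the weight 1/var(lengths in its bin). Bins with fewer than
#' \code{min_per_bin} observations inherit the pooled variance of the
#' adjacent bins (fallback counted in the \code{n_fallback} attribute);
#' degenerate zero-variance bins are capped at \code{max_weight}.
#'
#' @param shifted data frame with columns \code{leaf_age_h}, \code{length_um}.
#' @param bin_width_h bin width in hours (> 0), default 24.
#' @param min_per_bin minimum observations for a bin to use its own
#'   variance, default 3.
#' @param max_weight cap applied when a bin variance is ~0, default 1e6.
#' @return Numeric vector of per-observation weights.
#' @export
estimate_time_variances <- function(shifted, bin_width_h = 24,
                                    min_per_bin = 3, max_weight = 1e6) {
  stopifnot(bin_width_h > 0, nrow(shifted) > 0)
  a <- shifted$leaf_age_h
  l <- shifted$length_um
  bin <- floor(a / bin_width_h)
  ubin <- sort(unique(bin))
  v <- vapply(ubin, function(b) {
    x <- l[bin == b]
    if (length(x) >= min_per_bin) var(x) else NA_real_
  }, numeric(1))
  n_fallback <- 0L
  for (i in seq_along(ubin)) {
    if (is.na(v[i])) {
      # pool the nearest bins that do have a variance
      ok <- which(!is.na(v))
      if (length(ok) == 0L) {
        v[i] <- var(l)  # single-bin degenerate data
      } else {
        nearest <- ok[order(abs(ubin[ok] - ubin[i]))][seq_len(min(2L, length(ok)))]
        v[i] <- mean(v[nearest])
      }
      n_fallback <- n_fallback + 1L
    }
  }
  v[!is.finite(v) | v <= 0] <- 1 / max_weight
  w <- 1 / v[match(bin, ubin)]
  w <- pmin(w, max_weight)
  attr(w, "n_fallback") <- n_fallback
  w
}

# shared multi-start scaffold for the sigmoid fits: jitter the data-driven
# start by deterministic factors in [1/2, 2] on each parameter and keep the
# best converged nlsLM fit (no RNG use, so callers' seeds are untouched)
multistart_nlsLM <- function(formula, data, start0, lower, weights,
                             n_starts = 8L) {
  best <- NULL
  p <- length(start0)
  # low-discrepancy deterministic jitter grid on the log2 scale
  g <- outer(seq_len(n_starts - 1L), seq_len(p),
             function(i, j) 2 * (((i * 0.618034 * j) %% 1) - 0.5))
  jit <- rbind(rep(1, p), 2^g)
  for (s in seq_len(nrow(jit))) {
    start <- as.list(unlist(start0) * jit[s, ])
    names(start) <- names(start0)
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                        weights = weights,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(weights * resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Fit the Hill growth curve by weighted non-linear least squares
#'
#' Minimizes \eqn{\sum_i w_i (l_i - l(a_i; \theta))^2} over
#' \eqn{\theta = (l_{max}, t_{1/2}, n)} with positivity bounds, using
#' Levenberg-Marquardt from multiple jittered starts. Start values follow
#' the usual sigmoid heuristics: \code{l_max0 = 1.05 max(l)}, \code{t_half0}
#' at the observation closest to half of that, \code{n0 = 2}.
#'
#' @param shifted data frame with \code{leaf_age_h} and \code{length_um}.
#' @param weights per-observation weights (e.g. from
#'   \code{\link{estimate_time_variances}}); default uniform.
#' @param n_starts number of multi-start jitters (default 8).
#' @return An object of class \code{hill_fit}: \code{params}
#'   (\code{hill_params}), \code{weighted_sse}, \code{residuals},
#'   \code{fitted}, \code{n_obs}, and \code{plateau_seen} — \code{FALSE}
#'   when the data do not reach the fitted \code{t_half}, flagging a
#'   poorly identified \code{l_max}.
#' @export
fit_hill <- function(shifted, weights = NULL, n_starts = 8L) {
  stopifnot(nrow(shifted) >= 10)
  if (is.null(weights)) weights <- rep(1, nrow(shifted))
  stopifnot(length(weights) == nrow(shifted), all(weights > 0))
  d <- data.frame(a = shifted$leaf_age_h, l = shifted$length_um, w = weights)
  lmax0 <- 1.05 * max(d$l)
  th0 <- d$a[which.min(abs(d$l - lmax0 / 2))]
  if (th0 <= 0) th0 <- median(d$a)
  start0 <- list(l_max = lmax0, t_half = th0, n = 2)
  best <- multistart_nlsLM(l ~ l_max * a^n / (t_half^n + a^n), data = d,
                           start0 = start0,
                           lower = c(l_max = 1e-8, t_half = 1e-8, n = 1e-3),
                           weights = d$w, n_starts = n_starts)
  if (is.null(best))
    stop("Hill fit failed to converge from any start; check the data range and weights")
  cf <- coef(best$fit)
  params <- hill_params(cf[["l_max"]], cf[["t_half"]], cf[["n"]])
  structure(list(params = params,
                 weighted_sse = best$rss,
                 residuals = resid(best$fit),
                 fitted = fitted(best$fit),
                 n_obs = nrow(d),
                 plateau_seen = max(d$a) > params$t_half),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("weighted SSE %.6g on %d observations\n", x$weighted_sse, x$n_obs))
  if (!x$plateau_seen)
    cat("warning: data truncated before t_half; l_max poorly identified\n")
  invisible(x)
}

#' Compare sigmoid growth models by AIC
#'
#' Fits the Hill curve, the 3-parameter logistic
#' \eqn{l_{max} / (1 + e^{-r (a - t_0)})} and the Gompertz curve
#' \eqn{l_{max} e^{-e^{-r (a - t_0)}}} to the same weighted data and ranks
#' them by AIC computed from the weighted residual sum of squares.
#'
#' @inheritParams fit_hill
#' @return Data frame (one row per converged model, best first) with
#'   columns \code{model}, \code{weighted_sse}, \code{aic}, and a
#'   \code{fits} attribute holding the fitted objects.
#' @export
compare_sigmoid_models <- function(shifted, weights = NULL, n_starts = 8L) {
  stopifnot(nrow(shifted) >= 10)
  if (is.null(weights)) weights <- rep(1, nrow(shifted))
  d <- data.frame(a = shifted$leaf_age_h, l = shifted$length_um, w = weights)
  if (var(d$l) == 0)
    stop("constant lengths: all sigmoid fits are degenerate")
  lmax0 <- 1.05 * max(d$l)
  th0 <- d$a[which.min(abs(d$l - lmax0 / 2))]
  if (th0 <= 0) th0 <- median(d$a)
  r0 <- 4 / diff(range(d$a))
  specs <- list(
    hill = list(formula = l ~ l_max * a^n / (t_half^n + a^n),
                start0 = list(l_max = lmax0, t_half = th0, n = 2),
                lower = c(1e-8, 1e-8, 1e-3)),
    logistic = list(formula = l ~ l_max / (1 + exp(-r * (a - t0))),
                    start0 = list(l_max = lmax0, r = r0, t0 = th0),
                    lower = c(1e-8, 1e-8, -Inf)),
    gompertz = list(formula = l ~ l_max * exp(-exp(-r * (a - t0))),
                    start0 = list(l_max = lmax0, r = r0, t0 = th0),
                    lower = c(1e-8, 1e-8, -Inf)))
  rows <- list(); fits <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    best <- multistart_nlsLM(sp$formula, d, sp$start0, sp$lower, d$w, n_starts)
    if (is.null(best)) {
      warning(sprintf("%s fit did not converge; model dropped", nm))
      next
    }
    n <- nrow(d); p <- length(sp$start0)
    aic <- n * log(best$rss / n) + 2 * (p + 1)
    rows[[nm]] <- data.frame(model = nm, weighted_sse = best$rss, aic = aic)
    fits[[nm]] <- best$fit
  }
  if (length(rows) == 0L) stop("no sigmoid model converged")
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Date organs from their measured lengths
#'
#' Inverts the calibrated Hill curve for each length and adds the rank's
#' initiation time to obtain absolute ages (since sowing). Rows whose
#' length cannot be inverted in strict mode (l >= l_max) are returned with
#' \code{NA} ages and collected in the \code{failed} attribute rather than
#' aborting the batch.
#'
#' @param params calibrated \code{\link{hill_params}}.
#' @param T_h initiation time of the rank, hours.
#' @param lengths_um numeric vector of measured lengths.
#' @param clamp passed to \code{\link{hill_inverse}}.
#' @return Data frame \code{length_um, age_since_init_h, absolute_age_h}.
#' @export
date_organs <- function(params, T_h, lengths_um, clamp = FALSE) {
  stopifnot(T_h >= 0, all(lengths_um > 0))
  age <- rep(NA_real_, length(lengths_um))
  failed <- integer(0)
  for (i in seq_along(lengths_um)) {
    a <- tryCatch(hill_inverse(params, lengths_um[i], clamp = clamp),
                  error = function(e) NA_real_)
    if (is.na(a)) failed <- c(failed, i) else age[i] <- a
  }
  if (length(failed) > 0 && !clamp)
    warning(sprintf("date_organs: %d length(s) >= l_max could not be dated (strict mode)",
                    length(failed)))
  out <- data.frame(length_um = lengths_um,
                    age_since_init_h = age,
                    absolute_age_h = age + T_h)
  attr(out, "failed") <- failed
  out
}

#' Tooth age from leaf age and tooth initiation time
#'
#' A tooth initiated \code{tooth_initiation_h} hours after its leaf is
#' \code{leaf_age_h - tooth_initiation_h} hours old. Negative results mean
#' the tooth has not yet been initiated on that leaf; they are returned as
#' \code{NA} and flagged, so downstream tooth analyses can exclude them.
#'
#' @param leaf_age_h leaf age(s) since leaf initiation, hours.
#' @param tooth_initiation_h tooth initiation time(s), hours after leaf
#'   initiation.
#' @return Numeric vector of tooth ages (h); \code{NA} where not yet
#'   initiated, with the offending indices in the \code{flagged} attribute.
#' @export
tooth_age <- function(leaf_age_h, tooth_initiation_h) {
  age <- leaf_age_h - tooth_initiation_h
  flagged <- which(age < 0)
  age[flagged] <- NA_real_
  attr(age, "flagged") <- flagged
  age
}
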