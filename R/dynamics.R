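#' Logistic transition hazard
#'
#' Per-capita rate at which individuals in category k-1 acquire their k-th
#' organ: \eqn{\sigma_k(t) = c_k / (1 + e^{-b_k (t - a_k)})}. The inflection
#' time \eqn{a_k} places the transition, \eqn{b_k} sets its steepness and
#' \eqn{c_k} scales the saturated rate. The sigmoid form makes transitions
#' fire sequentially: a hazard is negligible long before its inflection
#' time and saturates at \eqn{c_k} after it.
#'
#' @param params_k list or named vector with elements \code{a}, \code{b},
#'   \code{c} (\code{b >= 0}, \code{c > 0}; \code{b = 0} is the boundary
#'   case of a constant hazard \code{c/2}).
#' @param t time(s), hours.
#' @return Hazard value(s), 1/h; non-decreasing in \code{t}, tending to 0
#'   as \code{t -> -Inf} and to \code{c} as \code{t -> +Inf}.
#' @export
transition_hazard <- function(params_k, t) {
  a <- params_k[["a"]]; b <- params_k[["b"]]; cc <- params_k[["c"]]
  stopifnot(b >= 0, cc > 0)
  cc / (1 + exp(-b * (t - a)))
}

#' Simulate the organ-apparition population model
#'
#' Integrates the compartmental ODE cascade in which a population of N
#' individuals flows one-way through categories of increasing organ number,
#' each category feeding the next:
#' \deqn{dN_0/dt = -\sigma_1(t) N_0, \qquad
#'       dN_k/dt = \sigma_k(t) N_{k-1} - \sigma_{k+1}(t) N_k, \qquad
#'       dN_K/dt = \sigma_K(t) N_{K-1},}
#' with initial conditions \eqn{N_0(0) = N}, \eqn{N_k(0) = 0} (all
#' individuals start with no organ) and logistic hazards
#' \code{\link{transition_hazard}}. Integration uses an implicit,
#' stiff-capable method (default RADAU IIA) with \code{rtol = 1e-6},
#' \code{atol = 1e-9 * N}; total occupancy is conserved to within
#' \code{1e-6 * N} on the output grid.
#'
#' @param params data frame with columns \code{k} (1..K), \code{a},
#'   \code{b}, \code{c} — one row per transition.
#' @param N population size.
#' @param K maximal category (defaults to \code{nrow(params)}).
#' @param t_span length-2 vector (start, end), start >= 0.
#' @param grid output times (defaults to 200 points over \code{t_span});
#'   times outside \code{t_span} are dropped.
#' @param method \code{deSolve} integration method.
#' @param rtol,atol integration tolerances.
#' @return List of class \code{population_dynamics}: \code{times},
#'   \code{occupancy} (matrix, columns = categories 0..K), \code{N},
#'   \code{K}.
#' @export
simulate_population_model <- function(params, N, K = nrow(params), t_span,
                                      grid = NULL, method = "radau",
                                      rtol = 1e-6, atol = 1e-9 * N) {
  stopifnot(is.data.frame(params), all(c("a", "b", "c") %in% names(params)),
            nrow(params) == K, K >= 1, length(t_span) == 2L,
            t_span[1] >= 0, t_span[2] > t_span[1])
  if (any(params$b < 0) || any(params$c < 0))
    stop("transition parameters require b >= 0 and c >= 0")
  if (is.null(grid)) grid <- seq(t_span[1], t_span[2], length.out = 200)
  times <- sort(unique(c(t_span[1], grid[grid >= t_span[1] & grid <= t_span[2]])))
  aa <- params$a; bb <- params$b; cc <- params$c
  rhs <- function(t, y, parms) {
    sig <- cc / (1 + exp(-bb * (t - aa)))
    flux <- sig * y[1:K]
    dy <- c(-flux[1], flux) - c(0, flux[-1], 0)
    list(dy)
  }
  y0 <- c(N, rep(0, K))
  sol <- tryCatch(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 method = method, rtol = rtol, atol = atol),
    error = function(e) e)
  if (inherits(sol, "error") || nrow(sol) < length(times)) {
    msg <- if (inherits(sol, "error")) conditionMessage(sol) else "incomplete integration"
    stop(sprintf("ODE integration failed (%s); params: a=(%s) b=(%s) c=(%s)", msg,
                 paste(signif(aa, 4), collapse = ","),
                 paste(signif(bb, 4), collapse = ","),
                 paste(signif(cc, 4), collapse = ",")))
  }
  occ <- unname(as.matrix(sol[, -1, drop = FALSE]))
  structure(list(times = times, occupancy = occ, N = N, K = as.integer(K)),
            class = "population_dynamics")
}

#' @export
print.population_dynamics <- function(x, ...) {
  cat(sprintf("population model trajectories: N = %g, categories 0..%d, %d time points on [%.4g, %.4g] h\n",
              x$N, x$K, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# cumulative proportion P_{>=k}(t) = sum_{j>=k} N_j(t) / N from an occupancy
# matrix (columns 0..K); k >= 1
cumulative_proportion <- function(occupancy, N, k) {
  rowSums(occupancy[, (k + 1):ncol(occupancy), drop = FALSE]) / N
}
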