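#' Category maps from raw organ counts
#'
#' A category map sends a raw organ count to a category index 0..K. The
#' \code{"identity"} map tracks every rank. The \code{"odd"} map bins
#' counts so that successive categories open when odd ranks 3, 5, 7, ...
#' are initiated: category 0 holds counts 0-2 and category j >= 1 holds
#' counts 2j+1 and 2j+2 (so count 3 -> category 1, count 5 -> category 2).
#' This mirrors analyses that consider odd-ranked organs only, and doubles
#' the spacing between estimated initiation times.
#'
#' @param type \code{"identity"}, \code{"odd"}, or \code{"custom"}.
#' @param fun for \code{type = "custom"}, a vectorized function
#'   count -> category index (must be order-preserving and return
#'   non-negative integers, \code{NA} for unmappable counts).
#' @return An object of class \code{category_map}.
#' @export
category_map <- function(type = c("identity", "odd", "custom"), fun = NULL) {
  type <- match.arg(type)
  f <- switch(type,
              identity = function(count) as.integer(count),
              odd = function(count) as.integer(pmax(0, (count - 1) %/% 2)),
              custom = {
                stopifnot(is.function(fun))
                fun
              })
  structure(list(type = type, fun = f), class = "category_map")
}

#' Assign observations to organ-count categories
#'
#' @param observations data frame of static snapshots with columns
#'   \code{individual_id}, \code{age_h} and \code{organ_count} (or
#'   \code{count}).
#' @param map a \code{\link{category_map}} (default identity).
#' @param K maximal category; inferred as the largest mapped category when
#'   \code{NULL}.
#' @return The observations with a \code{category} column; attribute
#'   \code{K}.
#' @export
categorize <- function(observations, map = category_map("identity"), K = NULL) {
  stopifnot(is.data.frame(observations), inherits(map, "category_map"))
  if (nrow(observations) == 0L) stop("empty observations")
  cnt_col <- intersect(c("organ_count", "count"), names(observations))[1]
  if (is.na(cnt_col)) stop("observations need an 'organ_count' (or 'count') column")
  if (!"age_h" %in% names(observations)) stop("observations need an 'age_h' column")
  counts <- observations[[cnt_col]]
  if (any(counts < 0)) stop("negative organ counts")
  cat_idx <- map$fun(counts)
  bad <- which(is.na(cat_idx) | cat_idx < 0)
  if (length(bad) > 0)
    stop(sprintf("counts outside the category map's range at rows: %s",
                 paste(head(bad, 10), collapse = ", ")))
  observations$category <- as.integer(cat_idx)
  if (is.null(K)) K <- max(observations$category)
  if (any(observations$category > K))
    stop("observed categories exceed the supplied K")
  attr(observations, "K") <- as.integer(K)
  observations
}

#' Balance category sizes by resampling
#'
#' The ergodic reconstruction treats the cross-sectional sample as the
#' trajectory of a closed population of N individuals, so every category
#' must hold the same number of observations. N is set to the size of the
#' most represented category; under-represented categories keep their
#' original rows and are topped up by seeded sampling with replacement.
#'
#' @param categorized output of \code{\link{categorize}}.
#' @param seed integer RNG seed for the resampling.
#' @return A list: \code{observations} (balanced data frame), \code{N},
#'   \code{K}.
#' @export
resample_categories <- function(categorized, seed = 1L) {
  stopifnot("category" %in% names(categorized))
  K <- attr(categorized, "K")
  if (is.null(K)) K <- max(categorized$category)
  sizes <- vapply(0:K, function(k) sum(categorized$category == k), integer(1))
  empty <- which(sizes == 0L) - 1L
  if (length(empty) > 0)
    stop(sprintf("empty categor%s: %s — every category 0..K needs at least one observation",
                 if (length(empty) > 1) "ies" else "y",
                 paste(empty, collapse = ", ")))
  N <- max(sizes)
  set.seed(seed)
  parts <- lapply(0:K, function(k) {
    rows <- categorized[categorized$category == k, , drop = FALSE]
    deficit <- N - nrow(rows)
    if (deficit > 0) {
      extra <- rows[sample.int(nrow(rows), deficit, replace = TRUE), , drop = FALSE]
      rows <- rbind(rows, extra)
    }
    rows
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  list(observations = out, N = as.integer(N), K = as.integer(K))
}

#' Reconstruct empirical category-occupancy dynamics
#'
#' Under the ergodicity assumption, the balanced cross-sectional sample is
#' read as the temporal evolution of N individuals flowing one-way through
#' categories 0..K. Counting backwards from infinity (where everyone has
#' reached category K) gives the closed forms, with
#' \eqn{C_k(t)} the cumulative number of category-k observations at ages
#' \eqn{\le t}:
#' \deqn{N_0(t) = N - C_0(t), \quad N_k(t) = C_{k-1}(t) - C_k(t), \quad
#'       N_K(t) = C_{K-1}(t),}
#' evaluated as right-continuous step functions at the sorted observation
#' ages. The construction conserves \eqn{\sum_k N_k(t) = N} exactly at
#' every time. Sampling noise can make mid-category values transiently
#' negative (\eqn{C_k > C_{k-1}}); they are kept as-is (the fitted model is
#' non-negative, and clamping would bias the cost) and a warning reports
#' how many.
#'
#' @param balanced output of \code{\link{resample_categories}} (or a list
#'   with \code{observations}, \code{N}, \code{K}).
#' @return An object of class \code{step_dynamics}: \code{times} (sorted
#'   unique ages), \code{occupancy} (matrix, one column per category 0..K),
#'   \code{N}, \code{K}.
#' @export
empirical_dynamics <- function(balanced) {
  obs <- balanced$observations; N <- balanced$N; K <- balanced$K
  stopifnot(is.data.frame(obs), N >= 1, K >= 0)
  times <- sort(unique(obs$age_h))
  # C[j, k+1] = number of category-k observations with age <= times[j]
  C <- vapply(0:K, function(k) {
    ages_k <- sort(obs$age_h[obs$category == k])
    findInterval(times, ages_k)
  }, numeric(length(times)))
  C <- matrix(C, nrow = length(times))
  occ <- matrix(0, nrow = length(times), ncol = K + 1)
  occ[, 1] <- N - C[, 1]
  if (K >= 1) {
    if (K >= 2)
      for (k in 1:(K - 1)) occ[, k + 1] <- C[, k] - C[, k + 1]
    occ[, K + 1] <- C[, K]
  }
  n_neg <- sum(occ < 0)
  if (n_neg > 0)
    warning(sprintf("empirical occupancy has %d negative value(s) from sampling noise (kept unclamped)",
                    n_neg))
  structure(list(times = times, occupancy = occ, N = as.integer(N),
                 K = as.integer(K)),
            class = "step_dynamics")
}

#' @export
print.step_dynamics <- function(x, ...) {
  cat(sprintf("empirical step dynamics: N = %d individuals, %d categories (0..%d), %d event times on [%.4g, %.4g] h\n",
              x$N, x$K + 1, x$K, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
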