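#' G*-statistics from a hierarchy of non-identity probabilities
#'
#' A structured population can be summarised by an ordered sequence
#' `h = (h_0, ..., h_L)` in which `h_i` is the probability that a pair of
#' genes sampled at level `i` of the hierarchy (gametes within a zygote,
#' individuals within a deme, demes within the metapopulation, ...) are
#' *not* identical by state (non-IBS), ignoring structure at lower levels.
#' The association at level `i` relative to the level below is
#' `G_i* = (h_i - h_{i-1}) / h_i`, and the total association is
#' `G_IT* = 1 - h_0 / h_L`.  These are the diversity-based analogs of
#' Wright's F-statistics: `G_1*` plays the role of F_IS and, for the
#' two-level island hierarchy, `G_2*` is the analog of Nei's G_ST.
#'
#' The complements multiply across levels:
#' `prod(1 - G_i*) = h_0 / h_L = 1 - G_IT*`.  Negative values are
#' meaningful (association at a level lower than the level beneath it) and
#' are returned as-is, never clamped.
#'
#' @param h Numeric vector of non-IBS probabilities `(h_0, ..., h_L)`,
#'   each in `[0, 1]`, with `L >= 1`.  `h_i` must be strictly positive for
#'   `i >= 1` (a zero means the population is fixed at that level and the
#'   ratio is undefined).
#'
#' @return An object of class `g_statistics`: a list with elements `h`,
#'   `per_level` (the `G_1*, ..., G_L*`) and `total` (`G_IT*`).
#'   [tidy()] returns one row per level; [glance()] a one-row summary.
#'
#' @examples
#' g_statistics(c(0.2, 0.5, 0.8))
#' tidy(g_statistics(c(0.2, 0.5, 0.8)))
#' @export
g_statistics <- function(h) {
  h <- as.numeric(h)
  if (length(h) < 2) {
    abort("`h` must contain at least two levels (h_0 and h_1).")
  }
  if (anyNA(h) || any(h < 0) || any(h > 1)) {
    abort("all elements of `h` must be probabilities in [0, 1].")
  }
  zero <- which(h[-1] == 0)
  if (length(zero)) {
    abort(sprintf(
      "h_%d is zero: the population is fixed at that level and G_%d* is undefined.",
      zero[1], zero[1]
    ))
  }
  L <- length(h) - 1L
  per_level <- (h[-1] - h[-length(h)]) / h[-1]
  total <- 1 - h[1] / h[length(h)]
  structure(
    list(h = h, per_level = per_level, total = total, L = L),
    class = "g_statistics"
  )
}

#' @export
print.g_statistics <- function(x, ...) {
  cat("G*-statistics over", x$L, "level(s)\n")
  cat("  h:", paste(signif(x$h, 6), collapse = ", "), "\n")
  for (i in seq_len(x$L)) {
    cat(sprintf("  G_%d* = %.6g\n", i, x$per_level[i]))
  }
  cat(sprintf("  G_IT* = %.6g\n", x$total))
  invisible(x)
}

#' @rdname g_statistics
#' @param x A `g_statistics` object.
#' @param ... Unused.
#' @method tidy g_statistics
#' @export
tidy.g_statistics <- function(x, ...) {
  tibble::tibble(
    level = seq_len(x$L),
    h_lower = x$h[-length(x$h)],
    h_upper = x$h[-1],
    g_star = x$per_level
  )
}

#' @rdname g_statistics
#' @method glance g_statistics
#' @export
glance.g_statistics <- function(x, ...) {
  tibble::tibble(L = x$L, g_it_star = x$total, h0 = x$h[1], hL = x$h[length(x$h)])
}

#' Wright's F-statistic partition
#'
#' Recovers `F_IS` and `F_ST` from the correlation between uniting gametes
#' `F_IT` and the correlation `G_w` between gametes sampled at random from
#' the whole population: `F_IS = (F_IT - G_w) / (1 - G_w)`, `F_ST = G_w`.
#' The classical partition `1 - F_IT = (1 - F_IS)(1 - F_ST)` then holds by
#' construction.  Vectorised over both arguments.
#'
#' @param f_it Correlation between uniting gametes (F_IT).
#' @param g_w Correlation between random gametes from the population; must
#'   be `< 1`.
#' @return A tibble with columns `f_is`, `f_st` and `f_it`.
#' @examples
#' wright_partition(0.192, 0.1)
#' @export
wright_partition <- function(f_it, g_w) {
  if (any(g_w >= 1)) {
    abort("`g_w` must be < 1 (the partition denominator 1 - G_w is zero).")
  }
  tibble::tibble(
    f_is = (f_it - g_w) / (1 - g_w),
    f_st = g_w,
    f_it = f_it
  )
}

#' Non-IBS hierarchy of the island model
#'
#' Assembles the three-level non-identity hierarchy of a subdivided
#' population from the identity-by-state probabilities `f` (uniting
#' gametes), `g_w` (distinct individuals, same deme) and `g_b` (distinct
#' demes), at finite deme size `N` and deme count `d`:
#' \deqn{h_0 = 1 - f}
#' \deqn{h_1 = \frac{(1-f)/2}{N} + (1 - g_w)(1 - 1/N)}
#' \deqn{h_2 = h_1 / d + (1 - g_b)(1 - 1/d)}
#' The `1/N` term in `h_1` is the chance that both genes come from one
#' individual, where a random gene pair is non-IBS with probability
#' `(1-f)/2` (the pair is the same physical gene with probability 1/2).
#' The `1/N` and `1/d` terms are kept exactly; no large-`N` truncation is
#' applied, so complete identity (`f = g_w = g_b = 1`) gives exactly
#' `h = (0, 0, 0)`.
#'
#' @param f,g_w,g_b IBS probabilities in `[0, 1]`.
#' @param N Diploid reproductives per deme (`>= 1`).
#' @param d Number of demes (`>= 1`).
#' @return Named numeric vector `c(h0, h1, h2)`, suitable as input to
#'   [g_statistics()].
#' @examples
#' island_levels(f = 0, g_w = 0, g_b = 0, N = 2, d = 2)
#' g_statistics(island_levels(0.3, 0.2, 0.1, N = 50, d = 5))
#' @export
island_levels <- function(f, g_w, g_b, N, d) {
  stopifnot(
    f >= 0, f <= 1, g_w >= 0, g_w <= 1, g_b >= 0, g_b <= 1,
    N >= 1, d >= 1
  )
  h0 <- 1 - f
  h1 <- ((1 - f) / 2) / N + (1 - g_w) * (1 - 1 / N)
  h2 <- h1 / d + (1 - g_b) * (1 - 1 / d)
  c(h0 = h0, h1 = h1, h2 = h2)
}
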