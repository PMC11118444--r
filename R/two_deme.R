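#' Two-deme model parameters
#'
#' Raw parameters for the asymmetric two-deme model: deme sizes `N0`,
#' `N1`, backward migration rates `m0`, `m1` (the probability that a gene
#' sampled in the deme had its parent in the other deme) and mutation rate
#' `u`.  The analytic results assume migration and mutation rates of the
#' order of the inverse of the average deme size; larger rates are
#' accepted but flagged with a warning, since the scaled steady-state
#' predictions (and the negativity threshold [r_min()]) need not hold
#' there.
#'
#' @param N0,N1 Reproductive deme sizes (integers `>= 1`).
#' @param m0,m1 Backward migration rates in `[0, 1]`.
#' @param u Mutation rate in `[0, 1)`.
#' @return A list of class `two_deme_params`.
#' @export
two_deme_params <- function(N0, N1, m0, m1, u) {
  stopifnot(
    N0 >= 1, N0 == round(N0), N1 >= 1, N1 == round(N1),
    m0 >= 0, m0 <= 1, m1 >= 0, m1 <= 1, u >= 0, u < 1
  )
  N <- (N0 + N1) / 2
  if (max(m0, m1) > 25 / N) {
    warn(paste(
      "migration rate large relative to 1/N: the low-migration scaling",
      "behind the steady-state formulas (and r_min) may not apply."
    ))
  }
  structure(
    list(N0 = as.integer(N0), N1 = as.integer(N1), m0 = m0, m1 = m1, u = u),
    class = "two_deme_params"
  )
}

#' Coalescent scaling of two-deme parameters
#'
#' With `N = (N0 + N1)/2` the average deme size, returns
#' `r = N0 / (N0 + N1)` (proportion of reproductives in deme 0),
#' `M_i = 4 N m_i` and `theta = 4 N u`.
#'
#' @param p A [two_deme_params] object.
#' @return A one-row tibble with columns `r`, `M0`, `M1`, `theta`, `N`.
#' @examples
#' scale_two_deme(two_deme_params(700, 300, 1e-3, 4e-4, 1e-4))
#' @export
scale_two_deme <- function(p) {
  stopifnot(inherits(p, "two_deme_params"))
  N <- (p$N0 + p$N1) / 2
  tibble::tibble(
    r = p$N0 / (p$N0 + p$N1),
    M0 = 4 * N * p$m0,
    M1 = 4 * N * p$m1,
    theta = 4 * N * p$u,
    N = N
  )
}

## First-step linear system shared by the identity and time solvers.
## States: W0 (both lineages in deme 0), W1, B (one in each deme).
## Rates (time in units of 2N generations): pair coalescence 1/(2r) in W0,
## 1/(2(1-r)) in W1; migration out of W0 at M0 (either lineage), out of W1
## at M1; from B, the deme-0 lineage moves at M0/2 (-> W1) and the deme-1
## lineage at M1/2 (-> W0); mutation hits the pair at total rate theta.

#' Stationary IBS probabilities of the asymmetric two-deme model
#'
#' Solves the structured-coalescent first-step system for the probability
#' that a pair of lineages coalesces before either mutates (the
#' infinite-alleles identity), for pairs sampled both from deme 0
#' (`g_w0`), both from deme 1 (`g_w1`), or one from each (`g_b`):
#' \deqn{g_{W0}\left(\tfrac{1}{2r} + M_0 + \theta\right) = \tfrac{1}{2r} + M_0 g_B}
#' \deqn{g_{W1}\left(\tfrac{1}{2(1-r)} + M_1 + \theta\right) = \tfrac{1}{2(1-r)} + M_1 g_B}
#' \deqn{g_B\left(\tfrac{M_0 + M_1}{2} + \theta\right) = \tfrac{M_0}{2} g_{W1} + \tfrac{M_1}{2} g_{W0}}
#' Without mutation (`theta = 0`) all identities are 1.  With mutation but
#' no migration the demes never share ancestry and `g_b = 0` (returned
#' with a warning).
#'
#' The fitted object also carries the deme-specific structure indices
#' [beta_wt()] and [gst_deme()] for both demes, the negativity threshold
#' [r_min()], the hard-migration flag, the diversity distance
#' [nei_distance()], and the expected pair coalescence times with
#' Slatkin's `F_ST*` ([coalescence_times()]).
#'
#' @param r Proportion of reproductives in deme 0, in `(0, 1)`.
#' @param M0,M1 Scaled migration rates `4 N m_i` (`>= 0`).
#' @param theta Scaled mutation rate `4 N u` (`>= 0`).
#' @return An object of class `two_deme_fit`; see [tidy.two_deme_fit()]
#'   and [glance.two_deme_fit()].
#' @examples
#' fit <- two_deme_steady_state(r = 0.7, M0 = 4, M1 = 0.5, theta = 0.5)
#' glance(fit)
#' @export
two_deme_steady_state <- function(r, M0, M1, theta) {
  ident <- two_deme_identities(r, M0, M1, theta)
  g_w0 <- ident[["g_w0"]]; g_w1 <- ident[["g_w1"]]; g_b <- ident[["g_b"]]
  times <- if (M0 + M1 > 0) coalescence_times(r, M0, M1) else NULL
  structure(
    list(
      r = r, M0 = M0, M1 = M1, theta = theta,
      g_w0 = g_w0, g_w1 = g_w1, g_b = g_b,
      beta_wt0 = if (g_b < 1) beta_wt(g_w0, g_b) else NA_real_,
      beta_wt1 = if (g_b < 1) beta_wt(g_w1, g_b) else NA_real_,
      gst0_star = if (g_w0 < 1 || g_b < 1) gst_deme(g_w0, g_b, r) else NA_real_,
      gst1_star = if (g_w1 < 1 || g_b < 1) gst_deme(g_w1, g_b, 1 - r) else NA_real_,
      r_min = if (M0 + M1 + theta > 0) r_min(M0, M1, theta) else NA_real_,
      hard_migration = is_hard_migration(r, M0, M1),
      d_star = if (all(c(g_w0, g_w1, g_b) > 0)) {
        nei_distance(g_w0, g_w1, g_b)
      } else {
        NA_real_
      },
      times = times,
      fst_slatkin = if (is.null(times)) NA_real_ else slatkin_fst(times)
    ),
    class = "two_deme_fit"
  )
}

#' @rdname two_deme_steady_state
#' @return `two_deme_identities()` returns just the named triple
#'   `c(g_w0, g_w1, g_b)`.
#' @export
two_deme_identities <- function(r, M0, M1, theta) {
  stopifnot(r > 0, r < 1, M0 >= 0, M1 >= 0, theta >= 0)
  if (theta == 0) {
    if (M0 + M1 == 0) {
      warn("theta = 0 with no migration: between-deme identity is undefined; returning NA.")
      return(c(g_w0 = 1, g_w1 = 1, g_b = NA_real_))
    }
    return(c(g_w0 = 1, g_w1 = 1, g_b = 1))
  }
  if (M0 + M1 == 0) {
    warn("no migration between demes: lineages from different demes never coalesce (g_b = 0).")
    c0 <- 1 / (2 * r); c1 <- 1 / (2 * (1 - r))
    return(c(g_w0 = c0 / (c0 + theta), g_w1 = c1 / (c1 + theta), g_b = 0))
  }
  c0 <- 1 / (2 * r); c1 <- 1 / (2 * (1 - r))
  A <- rbind(
    c(c0 + M0 + theta, 0, -M0),
    c(0, c1 + M1 + theta, -M1),
    c(-M1 / 2, -M0 / 2, (M0 + M1) / 2 + theta)
  )
  b <- c(c0, c1, 0)
  setNames(solve(A, b), c("g_w0", "g_w1", "g_b"))
}

#' Deme-specific structure indices
#'
#' `beta_wt()` is the population-specific F_ST analog comparing
#' within-deme to between-deme identity,
#' `(g_w0 - g_b) / (1 - g_b)`; `gst_deme()` is the G_ST*-based analog
#' `(1 - r)(g_w0 - g_b) / [r (1 - g_w0) + (1 - r)(1 - g_b)]`, where `r` is
#' the focal deme's share of reproductives.  Both are negative exactly
#' when between-deme identity exceeds within-deme identity
#' (`g_b > g_w0`), and `|beta_wt| >= |gst_deme|` everywhere, with equality
#' only when both vanish.  `index_difference()` evaluates the closed form
#' of `beta_wt - gst_deme`.
#'
#' @param g_w0 Within-deme IBS probability of the focal deme.
#' @param g_b Between-deme IBS probability (`< 1` for `beta_wt`).
#' @param r Focal deme's proportion of reproductives in `(0, 1)`.
#' @return The index value (vectorised).
#' @examples
#' beta_wt(0.6, 0.5)
#' gst_deme(0.6, 0.5, 0.5)
#' @export
beta_wt <- function(g_w0, g_b) {
  if (any(g_b >= 1)) abort("g_b = 1: between-deme diversity is zero, beta_WT undefined.")
  (g_w0 - g_b) / (1 - g_b)
}

#' @rdname beta_wt
#' @export
gst_deme <- function(g_w0, g_b, r) {
  stopifnot(all(r > 0 & r < 1))
  den <- r * (1 - g_w0) + (1 - r) * (1 - g_b)
  if (any(den <= 0)) abort("g_w0 = g_b = 1: no diversity at either level, G_ST,0* undefined.")
  (1 - r) * (g_w0 - g_b) / den
}

#' @rdname beta_wt
#' @export
index_difference <- function(g_w0, g_b, r) {
  stopifnot(all(r > 0 & r < 1))
  if (any(g_b >= 1)) abort("g_b = 1: difference undefined.")
  den <- r * (1 - g_w0) + (1 - r) * (1 - g_b)
  if (any(den <= 0)) abort("degenerate denominator.")
  (g_w0 - g_b) * r * (1 - g_w0) / (den * (1 - g_b))
}

#' Threshold deme share for negative structure indices
#'
#' Deme-specific indices for deme 0 go negative (`g_b > g_w0` at steady
#' state) only when deme 0's share of reproductives exceeds
#' \deqn{r_{\min} = \frac{1 + M_0 + 2(M_1 + \theta)}{2(M_0 + M_1 + \theta)},}
#' which always exceeds 1/2: negativity needs the focal deme to hold the
#' majority of reproductives.  Values above 1 mean negativity is
#' unattainable for any `r` (in particular whenever `M0 <= 1`).
#'
#' @param M0,M1 Scaled migration rates (`>= 0`).
#' @param theta Scaled mutation rate (`>= 0`); `M0 + M1 + theta` must be
#'   positive.
#' @return `r_min` (vectorised).
#' @examples
#' r_min(4, 0.5, 0.5)  # 0.7
#' @export
r_min <- function(M0, M1, theta) {
  if (any(M0 + M1 + theta <= 0)) {
    abort("r_min requires M0 + M1 + theta > 0.")
  }
  (1 + M0 + 2 * (M1 + theta)) / (2 * (M0 + M1 + theta))
}

#' Hard (conservative) migration
#'
#' Hard migration constrains the numbers of newly migrated genes to be
#' equal between the demes: `N0 m0 = N1 m1`, i.e. `r M0 = (1 - r) M1`.
#' `hard_migration_partner()` returns the `M1` completing a hard-migration
#' pair for given `r` and `M0`; `is_hard_migration()` tests the constraint
#' (absolute tolerance `1e-12`).  Under hard migration the steady-state
#' deme-specific indices are never negative.
#'
#' @param r Deme 0's share of reproductives in `(0, 1)`.
#' @param M0,M1 Scaled migration rates.
#' @return `M1` for `hard_migration_partner()`; a logical for
#'   `is_hard_migration()`.
#' @examples
#' hard_migration_partner(0.75, 1)  # 3
#' @export
hard_migration_partner <- function(r, M0) {
  stopifnot(all(r > 0 & r < 1), all(M0 >= 0))
  r * M0 / (1 - r)
}

#' @rdname hard_migration_partner
#' @export
is_hard_migration <- function(r, M0, M1) {
  stopifnot(all(r > 0 & r < 1))
  abs(r * M0 - (1 - r) * M1) <= 1e-12
}

#' Diversity-based distance between two demes
#'
#' The IBS analog of Nei's genetic distance for the two-deme model:
#' \deqn{D^* = -\tfrac{1}{2}\left[\log(g_b / g_{w,0}) +
#'   \log(g_b / g_{w,1})\right].}
#' At any steady state of this model `D*` is strictly positive unless
#' `g_b = g_{w,0} = g_{w,1}`; unlike the deme-specific F_ST analogs it
#' cannot go negative at stationarity.
#'
#' @param g_w0,g_w1 Within-deme IBS probabilities (strictly positive).
#' @param g_b Between-deme IBS probability (strictly positive).
#' @return `D*` (natural log; vectorised).
#' @examples
#' nei_distance(0.6, 0.6, 0.3)  # log(2)
#' @export
nei_distance <- function(g_w0, g_w1, g_b) {
  if (any(c(g_w0, g_w1, g_b) <= 0)) {
    abort("all identities must be strictly positive (distance diverges at 0).")
  }
  -0.5 * (log(g_b / g_w0) + log(g_b / g_w1))
}

#' Expected pair coalescence times and Slatkin's F_ST*
#'
#' Solves the mutation-free first-step system of the two-deme coalescent
#' for the expected time to the most recent common ancestor of a pair, by
#' starting configuration: `E_W0` (both from deme 0), `E_W1`, `E_B` (one
#' from each), in units of `2N` generations.  Sampling two individuals
#' uniformly from the metapopulation gives within-deme and overall
#' expectations
#' \deqn{E(T_s) = \frac{r^2 E_{W0} + (1-r)^2 E_{W1}}{r^2 + (1-r)^2}, \quad
#'       E(T) = r^2 E_{W0} + (1-r)^2 E_{W1} + 2 r (1-r) E_B,}
#' and Slatkin's coalescence-time index
#' `F_ST* = (E(T) - E(T_s)) / E(T)`, which converges to the
#' diversity-based G_ST analog as mutation vanishes.
#'
#' @inheritParams two_deme_steady_state
#' @param weighting `"pair-uniform"` (default; two individuals drawn
#'   uniformly, within-deme pairs weighted `r^2`, `(1-r)^2`) or
#'   `"deme-uniform"` (demes weighted equally).
#' @return `coalescence_times()` returns a `coalescence_times` list with
#'   elements `E_W0`, `E_W1`, `E_B`, `E_Ts`, `E_T`; `slatkin_fst()` the
#'   scalar index.
#' @examples
#' ct <- coalescence_times(r = 0.5, M0 = 1, M1 = 1)
#' slatkin_fst(ct)
#' @export
coalescence_times <- function(r, M0, M1,
                              weighting = c("pair-uniform", "deme-uniform")) {
  stopifnot(r > 0, r < 1, M0 >= 0, M1 >= 0)
  weighting <- match.arg(weighting)
  if (M0 + M1 == 0) {
    abort("M0 = M1 = 0: lineages in different demes never coalesce (reducible chain).")
  }
  c0 <- 1 / (2 * r); c1 <- 1 / (2 * (1 - r))
  A <- rbind(
    c(c0 + M0, 0, -M0),
    c(0, c1 + M1, -M1),
    c(-M1 / 2, -M0 / 2, (M0 + M1) / 2)
  )
  tt <- solve(A, rep(1, 3))
  E_W0 <- tt[1]; E_W1 <- tt[2]; E_B <- tt[3]
  wts <- if (weighting == "pair-uniform") c(r^2, (1 - r)^2) else c(0.5, 0.5)
  E_Ts <- (wts[1] * E_W0 + wts[2] * E_W1) / sum(wts)
  E_T <- r^2 * E_W0 + (1 - r)^2 * E_W1 + 2 * r * (1 - r) * E_B
  structure(
    list(E_W0 = E_W0, E_W1 = E_W1, E_B = E_B, E_Ts = E_Ts, E_T = E_T,
         r = r, weighting = weighting),
    class = "coalescence_times"
  )
}

#' @rdname coalescence_times
#' @param ct A `coalescence_times` object.
#' @export
slatkin_fst <- function(ct) {
  stopifnot(inherits(ct, "coalescence_times"))
  (ct$E_T - ct$E_Ts) / ct$E_T
}

#' @export
print.two_deme_fit <- function(x, ...) {
  cat(sprintf("two-deme model: r = %g, M0 = %g, M1 = %g, theta = %g\n",
              x$r, x$M0, x$M1, x$theta))
  cat(sprintf("  g_w0 = %.6g, g_w1 = %.6g, g_b = %.6g\n",
              x$g_w0, x$g_w1, x$g_b))
  cat(sprintf("  beta_WT0 = %.6g, G_ST,0* = %.6g (r_min = %.6g%s)\n",
              x$beta_wt0, x$gst0_star, x$r_min,
              if (isTRUE(x$hard_migration)) ", hard migration" else ""))
  cat(sprintf("  D* = %.6g, Slatkin F_ST* = %.6g\n", x$d_star, x$fst_slatkin))
  invisible(x)
}

#' @rdname two_deme_steady_state
#' @param x A `two_deme_fit` object.
#' @param ... Unused.
#' @method tidy two_deme_fit
#' @export
tidy.two_deme_fit <- function(x, ...) {
  vals <- c(
    g_w0 = x$g_w0, g_w1 = x$g_w1, g_b = x$g_b,
    beta_WT0 = x$beta_wt0, beta_WT1 = x$beta_wt1,
    GST0_star = x$gst0_star, GST1_star = x$gst1_star,
    r_min = x$r_min, D_star = x$d_star,
    E_W0 = if (is.null(x$times)) NA_real_ else x$times$E_W0,
    E_W1 = if (is.null(x$times)) NA_real_ else x$times$E_W1,
    E_B = if (is.null(x$times)) NA_real_ else x$times$E_B,
    FST_slatkin = x$fst_slatkin
  )
  tibble::tibble(quantity = names(vals), value = unname(vals))
}

#' @rdname two_deme_steady_state
#' @method glance two_deme_fit
#' @export
glance.two_deme_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r, M0 = x$M0, M1 = x$M1, theta = x$theta,
    g_w0 = x$g_w0, g_w1 = x$g_w1, g_b = x$g_b,
    beta_wt0 = x$beta_wt0, gst0_star = x$gst0_star,
    r_min = x$r_min, hard_migration = x$hard_migration,
    d_star = x$d_star, fst_slatkin = x$fst_slatkin
  )
}
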