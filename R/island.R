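#' Island-model parameters
#'
#' Demographic and mutational parameters for Wright's island model with
#' partial self-fertilization: `d` demes of `N` diploid reproductives,
#' selfing probability `s`, per-generation K-allele mutation rate `u` and
#' backward migration rate `m` (the probability that a gene's parent
#' resided in another deme, uniform over the `d - 1` alternatives).
#' `K = Inf` selects the infinite-alleles model exactly, not as a large-K
#' approximation.
#'
#' @param N Diploid reproductives per deme (integer `>= 1`).
#' @param d Number of demes (integer `>= 1`); `d = 1` forces `m = 0`.
#' @param s Selfing probability in `[0, 1]`.
#' @param u Per-generation mutation rate in `[0, 1)`.
#' @param m Per-generation backward migration rate in `[0, 1]`.
#' @param K Number of allelic classes (integer `>= 2`) or `Inf`.
#' @return A list of class `island_params`.
#' @examples
#' island_params(N = 50, d = 5, s = 0.5, u = 1e-3, m = 1e-3, K = 4)
#' @export
island_params <- function(N, d, s = 0, u = 0, m = 0, K = Inf) {
  stopifnot(
    length(N) == 1, N >= 1, N == round(N),
    length(d) == 1, d >= 1, d == round(d),
    s >= 0, s <= 1, u >= 0, u < 1, m >= 0, m <= 1,
    is.infinite(K) || (K >= 2 && K == round(K))
  )
  if (d == 1 && m > 0) {
    abort("a single deme (d = 1) admits no migration; set m = 0.")
  }
  structure(
    list(N = as.integer(N), d = as.integer(d), s = s, u = u, m = m, K = K),
    class = "island_params"
  )
}

#' @export
print.island_params <- function(x, ...) {
  cat(sprintf(
    "island model: d = %d demes x N = %d, s = %g, u = %g, m = %g, K = %s\n",
    x$d, x$N, x$s, x$u, x$m, if (is.infinite(x$K)) "Inf" else x$K
  ))
  invisible(x)
}

#' Coalescent-scaled island parameters
#'
#' Converts raw island parameters to the scaled quantities in which the
#' asymptotic results are expressed: `M = 4Nm`, `theta = 4Nu`, and the
#' relative coalescence rate `Delta = N / Ne = 1 / (1 - s/2)`.
#'
#' @param p An [island_params] object.
#' @return A one-row tibble with columns `M`, `theta`, `Delta`, `Ne`,
#'   `sigma`, `d`, `K`.
#' @export
scale_island_params <- function(p) {
  stopifnot(inherits(p, "island_params"))
  eff <- effective_size(p$N, p$s)
  tibble::tibble(
    M = 4 * p$N * p$m,
    theta = 4 * p$N * p$u,
    Delta = eff$Delta,
    Ne = eff$Ne,
    sigma = uniparental_prob(p$s, p$N),
    d = p$d,
    K = p$K
  )
}

#' Probability that a random offspring is uniparental
#'
#' With selfing probability `s` in a deme of `N` reproductives, the
#' uniting gametes of a random offspring were contributed by a single
#' individual with probability `sigma = s + (1 - s)/N`: deliberate selfing
#' plus the chance that the outcross partner drawn from the gamete pool is
#' the mother herself.
#'
#' @param s Selfing probability in `[0, 1]`.
#' @param N Deme size (`>= 1`).
#' @return `sigma`, vectorised over the inputs.
#' @export
uniparental_prob <- function(s, N) {
  stopifnot(all(s >= 0 & s <= 1), all(N >= 1))
  s + (1 - s) / N
}

#' Resolution of a shared-parent gene pair to outcross
#'
#' Two lineages tracing to a shared parent either coalesce (the parent was
#' uniparental and both gametes carry the same complement, probability
#' 1/2) or escape into distinct individuals.  Racing the two absorbing
#' states gives the probability of resolving to outcross,
#' `(1 - sigma) / (1 - sigma/2)`.
#'
#' @param sigma Uniparental probability in `[0, 1]` (see
#'   [uniparental_prob()]).
#' @return Outcross-resolution probability; 0 when `sigma = 1`.
#' @export
outcross_resolution_prob <- function(sigma) {
  stopifnot(all(sigma >= 0 & sigma <= 1))
  (1 - sigma) / (1 - sigma * COMPLEMENT_COALESCENCE)
}

#' Effective deme size under partial selfing
#'
#' Selfing accelerates pair coalescence: `Ne = N (1 - s/2)`, so the
#' relative coalescence rate is `Delta = N / Ne = 1 / (1 - s/2)`, ranging
#' from 1 (random mating) to 2 (complete selfing).
#'
#' @inheritParams uniparental_prob
#' @return A list with elements `Ne` and `Delta`.
#' @export
effective_size <- function(N, s) {
  stopifnot(all(N >= 1), all(s >= 0 & s <= 1))
  list(Ne = N * (1 - s / 2), Delta = 1 / (1 - s / 2))
}

#' One generation of K-allele mutation acting on an identity probability
#'
#' Each of the two compared lineages mutates independently with
#' probability `u`; a mutation moves the gene to any of the other `K - 1`
#' allelic classes with uniform probability.  A currently identical pair
#' stays identical with probability `A = (1-u)^2 + u^2/(K-1)`; a
#' non-identical pair becomes identical with probability
#' `B = 2u(1-u)/(K-1) + u^2 (K-2)/(K-1)^2`.  Under infinite alleles
#' (`K = Inf`) every mutation destroys identity: `A = (1-u)^2`, `B = 0`.
#'
#' @param g Identity probability in `[0, 1]` (vectorised).
#' @param u Mutation rate in `[0, 1)`.
#' @param K Allele-class count (`>= 2`) or `Inf`.
#' @return Post-mutation identity probability `A g + B (1 - g)`.
#' @export
mutation_step <- function(g, u, K = Inf) {
  stopifnot(all(g >= 0 & g <= 1), u >= 0, u < 1)
  cf <- mutation_coefs(u, K)
  cf$A * g + cf$B * (1 - g)
}

mutation_coefs <- function(u, K) {
  if (is.infinite(K)) {
    list(A = (1 - u)^2, B = 0)
  } else {
    list(
      A = (1 - u)^2 + u^2 / (K - 1),
      B = 2 * u * (1 - u) / (K - 1) + u^2 * (K - 2) / (K - 1)^2
    )
  }
}

## Same-deme / different-deme mixing probabilities for two genes whose
## parent demes are chosen independently by backward migration.
migration_mixing <- function(m, d) {
  if (d == 1) return(list(psi = 1, chi = 0))
  list(
    psi = (1 - m)^2 + m^2 / (d - 1),
    chi = 2 * m * (1 - m) / (d - 1) + m^2 * (d - 2) / (d - 1)^2
  )
}

#' One-generation identity recursion for the island model
#'
#' Advances the identity triple `(f, g_w, g_b)` — IBS probabilities for
#' uniting gametes, for distinct individuals within a deme, and for
#' individuals in distinct demes — by one generation of the island model
#' with partial selfing, backward migration and K-allele mutation.  The
#' map is exact for the discrete-generation reproduction scheme of
#' [sim_island()] (parent deme chosen per offspring, mother uniform within
#' it, father equal to the mother with probability `s`, mutation applied
#' independently to each transmitted gene) and is affine in
#' `(f, g_w, g_b)`.
#'
#' With `sigma = s + (1-s)/N`,
#' `psi, chi` the probabilities that two independently migrating genes end
#' in the same deme (from same / different demes), and
#' `w = (1/N)(1+f)/2 + (1 - 1/N) g_w` the identity of two genes from the
#' same deme allowing parent-sharing:
#' \deqn{f' = a(\sigma (1+f)/2 + (1-\sigma) g_w)}
#' \deqn{g_w' = a(\psi w + (1-\psi) g_b)}
#' \deqn{g_b' = a(\chi w + (1-\chi) g_b)}
#' where `a()` is [mutation_step()].
#'
#' @param x Numeric identity triple `c(f, g_w, g_b)`, each in `[0, 1]`.
#' @param p An [island_params] object.
#' @return Named numeric triple `c(f, g_w, g_b)` for the next generation.
#' @examples
#' island_step(c(0, 0, 0), island_params(N = 10, d = 2, s = 1, m = 0.01))
#' @export
island_step <- function(x, p) {
  stopifnot(inherits(p, "island_params"), length(x) == 3,
            all(x >= 0 & x <= 1))
  sys <- island_system(p)
  out <- as.vector(sys$M %*% x + sys$b)
  setNames(out, c("f", "g_w", "g_b"))
}

## Affine map x' = M x + b of the one-generation recursion.
island_system <- function(p) {
  sigma <- uniparental_prob(p$s, p$N)
  mix <- migration_mixing(p$m, p$d)
  cf <- mutation_coefs(p$u, p$K)
  a1 <- cf$A - cf$B                       # a(g) = B + a1 g
  N <- p$N
  M <- rbind(
    a1 * c(sigma / 2, 1 - sigma, 0),
    a1 * c(mix$psi / (2 * N), mix$psi * (1 - 1 / N), 1 - mix$psi),
    a1 * c(mix$chi / (2 * N), mix$chi * (1 - 1 / N), 1 - mix$chi)
  )
  b <- cf$B + a1 * c(sigma / 2, mix$psi / (2 * N), mix$chi / (2 * N))
  list(M = M, b = b)
}

#' Stationary identity probabilities of the island model
#'
#' Solves the affine one-generation recursion ([island_step()]) for its
#' unique fixed point by an exact 3x3 linear solve.  Without mutation
#' (`u = 0`) drift eventually fixes the metapopulation and all identities
#' are 1.  The fitted object carries the stationary triple, the non-IBS
#' hierarchy `(h_0, h_1, h_2)` at the model's own `N` and `d`
#' ([island_levels()]), the finite-population statistics `G_1*`, `G_2*`,
#' `G_IT*`, and the large-`N` asymptotic predictions [gis_star()] and
#' [gst_star()] for comparison.
#'
#' @param p An [island_params] object.
#' @return An object of class `island_fit`; see [tidy.island_fit()] and
#'   [glance.island_fit()].
#' @examples
#' fit <- island_steady_state(
#'   island_params(N = 1000, d = 10, s = 0.5, u = 2.5e-5, m = 2.5e-4)
#' )
#' glance(fit)
#' @export
island_steady_state <- function(p) {
  stopifnot(inherits(p, "island_params"))
  if (p$u == 0) {
    ident <- c(f = 1, g_w = 1, g_b = 1)
  } else {
    sys <- island_system(p)
    A <- diag(3) - sys$M
    if (abs(det(A)) < 1e-300) {
      abort("internal error: singular identity system.")   # nocov
    }
    ident <- setNames(solve(A, sys$b), c("f", "g_w", "g_b"))
  }
  sc <- scale_island_params(p)
  h <- island_levels(ident["f"], ident["g_w"], ident["g_b"], p$N, p$d)
  gs <- if (all(h[-1] > 0)) g_statistics(h) else NULL
  structure(
    list(
      params = p,
      scaled = sc,
      identities = ident,
      h = h,
      g1 = if (is.null(gs)) NA_real_ else gs$per_level[1],
      g2 = if (is.null(gs) || p$d == 1) NA_real_ else gs$per_level[2],
      git = if (is.null(gs)) NA_real_ else gs$total,
      gis_asymptotic = gis_star(p$s),
      gst_asymptotic = if (p$d >= 2) {
        gst_star(Delta = sc$Delta, d = p$d, M = sc$M, theta = sc$theta, K = p$K)
      } else {
        NA_real_
      }
    ),
    class = "island_fit"
  )
}

#' @export
print.island_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  f = %.6g, g_w = %.6g, g_b = %.6g\n",
              x$identities["f"], x$identities["g_w"], x$identities["g_b"]))
  cat(sprintf("  G_1* = %.6g, G_2* = %.6g, G_IT* = %.6g\n", x$g1, x$g2, x$git))
  cat(sprintf("  asymptotic: G_IS* = %.6g, G_ST* = %.6g\n",
              x$gis_asymptotic, x$gst_asymptotic))
  invisible(x)
}

#' @rdname island_steady_state
#' @param x An `island_fit` object.
#' @param ... Unused.
#' @method tidy island_fit
#' @export
tidy.island_fit <- function(x, ...) {
  tibble::tibble(
    quantity = c("f", "g_w", "g_b", "h0", "h1", "h2",
                 "G1_star", "G2_star", "GIT_star",
                 "GIS_star_asymptotic", "GST_star_asymptotic"),
    value = c(unname(x$identities), unname(x$h),
              x$g1, x$g2, x$git, x$gis_asymptotic, x$gst_asymptotic)
  )
}

#' @rdname island_steady_state
#' @method glance island_fit
#' @export
glance.island_fit <- function(x, ...) {
  tibble::tibble(
    N = x$params$N, d = x$params$d, s = x$params$s,
    M = x$scaled$M, theta = x$scaled$theta, Delta = x$scaled$Delta,
    f = unname(x$identities["f"]),
    g_w = unname(x$identities["g_w"]),
    g_b = unname(x$identities["g_b"]),
    g1_star = x$g1, g2_star = x$g2, git_star = x$git,
    gis_star_asym = x$gis_asymptotic, gst_star_asym = x$gst_asymptotic
  )
}

#' Asymptotic within-individual association under partial selfing
#'
#' The large-`N` limit of `G_1*` (the F_IS analog) depends on the selfing
#' rate alone: `G_IS* = (s/2) / (1 - s/2)`.  `gis_star_finite()` gives the
#' finite-population statistic `(f - g_w) / (1 - g_w)` from an identity
#' triple.
#'
#' @param s Selfing probability in `[0, 1]` (vectorised).
#' @return The asymptotic `G_IS*`.
#' @export
gis_star <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  (s / 2) / (1 - s / 2)
}

#' @rdname gis_star
#' @param f,g_w IBS probabilities; `g_w` must be `< 1`.
#' @export
gis_star_finite <- function(f, g_w) {
  if (any(g_w >= 1)) abort("g_w = 1: within-deme diversity is zero, G_1* undefined.")
  (f - g_w) / (1 - g_w)
}

#' Asymptotic G_ST* of the island model
#'
#' The stationary between-deme association in scaled parameters:
#' \deqn{G_{ST}^* = \frac{\Delta}{\Delta + \frac{d}{d-1}\left[M \frac{d}{d-1}
#'   + \theta \frac{K}{K-1}\right]}}
#' with `Delta = 1/(1 - s/2)` the relative coalescence rate, `M = 4Nm`,
#' `theta = 4Nu`, and `K/(K-1) -> 1` under infinite alleles.  At
#' `Delta = 1`, `theta = 0`, `K = Inf` and `d -> Inf` this reduces to the
#' classical `1 / (1 + M)`.
#'
#' @param Delta Relative coalescence rate (`>= 1`).
#' @param d Deme count (`>= 2`).
#' @param M Scaled migration rate `4Nm` (`>= 0`).
#' @param theta Scaled mutation rate `4Nu` (`>= 0`).
#' @param K Allele-class count or `Inf`.
#' @return `G_ST*`, vectorised over `M` and `theta`.
#' @examples
#' gst_star(Delta = 1, d = 10, M = 1, theta = 0.1)
#' @export
gst_star <- function(Delta, d, M, theta, K = Inf) {
  stopifnot(all(Delta >= 1), all(M >= 0), all(theta >= 0))
  if (d < 2) abort("G_ST* requires at least two demes (d >= 2).")
  kfac <- if (is.infinite(K)) 1 else K / (K - 1)
  Delta / (Delta + (d / (d - 1)) * (M * d / (d - 1) + theta * kfac))
}

#' Stationary identity of an unstructured population
#'
#' Malecot's limit for the IBS probability between two random genes in a
#' single panmictic population under infinite-alleles mutation,
#' `1 / (1 + theta)`, which also follows from the Ewens sampling formula
#' for samples of size 2.
#'
#' @param theta Scaled mutation rate `4Nu` (`>= 0`, vectorised).
#' @return `1 / (1 + theta)`.
#' @export
unstructured_identity <- function(theta) {
  stopifnot(all(theta >= 0))
  1 / (1 + theta)
}
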