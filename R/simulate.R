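#' Forward Wright-Fisher simulation of the island model
#'
#' Simulates discrete generations of the island model as an independent
#' stochastic oracle for [island_steady_state()].  Each offspring chooses
#' its parents' deme by backward migration (stay with probability
#' `1 - m`, each other deme with probability `m/(d-1)`), a mother uniform
#' in that deme, and a father who is the mother with probability `s` and
#' otherwise uniform in the deme (so the outcross partner is again the
#' mother with probability `1/N`); each transmitted gene mutates
#' independently with probability `u` under the K-allele (or
#' infinite-alleles) model.  Deme sizes stay fixed.  Loci are independent
#' replicates: every locus draws its own pedigree each generation, so
#' per-locus time averages are independent across loci and the standard
#' errors are computed across loci.
#'
#' After `burn_in` generations the identity probabilities `f` (uniting
#' gametes, estimated as the homozygosity of the produced offspring),
#' `g_w` (allele matching between genes of distinct individuals in a
#' deme, equal deme weights) and `g_b` (between-deme matching, averaged
#' over deme pairs) are recorded every `sample_every` generations,
#' `n_samples` times, and averaged.
#'
#' @param p An [island_params] object.
#' @param n_loci Number of independent loci (replicate chains).
#' @param burn_in Generations discarded before sampling; default
#'   `20 * 2 * N * d`, well beyond the mixing time when `u`, `m` are of
#'   order `1/N`.
#' @param sample_every Generations between samples; default `2 * N`.
#' @param n_samples Number of sampled generations.
#' @param seed Integer seed; every random draw flows from it.
#' @param keep_state Keep the final population state (needed by
#'   [sim_genotypes()]).
#' @return An object of class `sim_estimates` with per-locus and combined
#'   estimates of `(f, g_w, g_b)`, standard errors across loci, effective
#'   sample counts and seed provenance.
#' @examples
#' p <- island_params(N = 20, d = 2, s = 0.5, u = 0.005, m = 0.005, K = 2)
#' sim_island(p, n_loci = 10, burn_in = 400, n_samples = 10, seed = 1)
#' @export
sim_island <- function(p, n_loci = 100, burn_in = NULL, sample_every = NULL,
                       n_samples = 50, seed = NULL, keep_state = FALSE) {
  stopifnot(inherits(p, "island_params"), n_loci >= 1, n_samples >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- 20L * 2L * p$N * p$d
  if (is.null(sample_every)) sample_every <- 2L * p$N
  n <- p$N * p$d
  L <- as.integer(n_loci)

  ## initial state: maximal diversity (unique labels under K = Inf,
  ## uniform labels under finite K); burn-in erases the choice
  if (is.infinite(p$K)) {
    pop <- array(seq_len(n * 2L * L), dim = c(n, 2L, L))
    counter <- n * 2L * L
  } else {
    pop <- array(sample.int(p$K, n * 2L * L, replace = TRUE) - 1L,
                 dim = c(n, 2L, L))
    counter <- 0L
  }

  home <- rep(rep.int(seq_len(p$d) - 1L, rep.int(p$N, p$d)), times = L)
  loc_off <- rep((seq_len(L) - 1L) * (2L * n), each = n)

  state <- list(pop = pop, counter = counter)
  for (g in seq_len(burn_in)) {
    state <- wf_generation(state, p, home, loc_off)
  }

  acc_f <- matrix(NA_real_, n_samples, L)
  acc_gw <- matrix(NA_real_, n_samples, L)
  acc_gb <- matrix(NA_real_, n_samples, L)
  for (k in seq_len(n_samples)) {
    for (g in seq_len(sample_every)) {
      state <- wf_generation(state, p, home, loc_off)
    }
    st <- island_identity_stats(state$pop, p$N, p$d)
    acc_f[k, ] <- st$f
    acc_gw[k, ] <- st$g_w
    acc_gb[k, ] <- st$g_b
  }

  per_locus <- tibble::tibble(
    locus = seq_len(L),
    f_hat = colMeans(acc_f),
    g_w_hat = colMeans(acc_gw),
    g_b_hat = if (p$d >= 2) colMeans(acc_gb) else NA_real_
  )
  est <- c(
    f = mean(per_locus$f_hat),
    g_w = mean(per_locus$g_w_hat),
    g_b = if (p$d >= 2) mean(per_locus$g_b_hat) else NA_real_
  )
  se <- c(
    f = sd(per_locus$f_hat) / sqrt(L),
    g_w = sd(per_locus$g_w_hat) / sqrt(L),
    g_b = if (p$d >= 2) sd(per_locus$g_b_hat) / sqrt(L) else NA_real_
  )

  ## stationarity check: first vs second half of the sampling window
  ## (needs enough samples per half to average over autocorrelation)
  half <- n_samples %/% 2L
  for (nm in if (n_samples >= 10) c("f", "gw", "gb") else character(0)) {
    if (nm == "gb" && p$d < 2) next
    acc <- switch(nm, f = acc_f, gw = acc_gw, gb = acc_gb)
    d1 <- colMeans(acc[seq_len(half), , drop = FALSE])
    d2 <- colMeans(acc[(half + 1L):n_samples, , drop = FALSE])
    dd <- d2 - d1
    sed <- sd(dd) / sqrt(L)
    if (sed > 0 && abs(mean(dd)) > 2 * sed) {
      warn(sprintf(
        "estimates of %s drift between sampling-window halves (%.4g vs %.4g): consider a longer burn-in.",
        nm, mean(d1), mean(d2)
      ))
    }
  }

  structure(
    list(
      params = p, per_locus = per_locus, estimate = est, se = se,
      n_eff = c(loci = L, samples = n_samples),
      burn_in = burn_in, sample_every = sample_every, seed = seed,
      state = if (keep_state) state$pop else NULL
    ),
    class = "sim_estimates"
  )
}

## One Wright-Fisher generation, vectorised over individuals and loci.
wf_generation <- function(state, p, home, loc_off) {
  pop <- state$pop
  n <- p$N * p$d
  L <- dim(pop)[3]
  nl <- n * L

  pd <- home
  if (p$d > 1 && p$m > 0) {
    mig <- runif(nl) < p$m
    nm <- sum(mig)
    if (nm > 0) {
      pd[mig] <- (pd[mig] + sample.int(p$d - 1L, nm, replace = TRUE)) %% p$d
    }
  }
  mother <- pd * p$N + sample.int(p$N, nl, replace = TRUE)
  father <- pd * p$N + sample.int(p$N, nl, replace = TRUE)
  if (p$s > 0) {
    selfed <- runif(nl) < p$s
    father[selfed] <- mother[selfed]
  }
  mat <- pop[mother + n * (runif(nl) < 0.5) + loc_off]
  pat <- pop[father + n * (runif(nl) < 0.5) + loc_off]

  counter <- state$counter
  if (p$u > 0) {
    for (nm2 in c("mat", "pat")) {
      v <- get(nm2)
      mut <- runif(nl) < p$u
      k <- sum(mut)
      if (k > 0) {
        if (is.infinite(p$K)) {
          v[mut] <- counter + seq_len(k)
          counter <- counter + k
        } else {
          v[mut] <- (v[mut] + sample.int(p$K - 1L, k, replace = TRUE)) %% p$K
        }
        assign(nm2, v)
      }
    }
  }
  newpop <- array(0L, dim = c(n, 2L, L))
  newpop[, 1L, ] <- mat
  newpop[, 2L, ] <- pat
  list(pop = newpop, counter = counter)
}

## Per-locus identity statistics of a population state.
island_identity_stats <- function(pop, N, d) {
  n <- N * d
  L <- dim(pop)[3]
  deme_of <- rep.int(seq_len(d), rep.int(N, d))
  hom <- pop[, 1L, , drop = FALSE] == pop[, 2L, , drop = FALSE]
  dim(hom) <- c(n, L)
  f <- colMeans(hom)
  g_w <- numeric(L)
  g_b <- rep(NA_real_, L)
  npairs <- d * (d - 1) / 2
  for (l in seq_len(L)) {
    genes <- c(pop[, 1L, l], pop[, 2L, l])
    gdeme <- c(deme_of, deme_of)
    u <- unique(genes)
    ui <- match(genes, u)
    C <- matrix(0, d, length(u))
    for (j in seq_len(d)) {
      C[j, ] <- tabulate(ui[gdeme == j], nbins = length(u))
    }
    P <- tcrossprod(C)
    homc <- colSums(matrix(hom[, l], N, d))
    g_w[l] <- mean((diag(P) - 2 * N - 2 * homc) / (4 * N * (N - 1)))
    if (d >= 2) {
      g_b[l] <- sum(P[upper.tri(P)]) / (npairs * 4 * N^2)
    }
  }
  list(f = f, g_w = g_w, g_b = g_b)
}

#' @export
print.sim_estimates <- function(x, ...) {
  cat("Monte Carlo identity estimates (", x$n_eff[["loci"]], " loci x ",
      x$n_eff[["samples"]], " sampled generations)\n", sep = "")
  for (nm in names(x$estimate)) {
    if (!is.na(x$estimate[[nm]])) {
      cat(sprintf("  %-4s = %.5f (se %.5f)\n", nm, x$estimate[[nm]], x$se[[nm]]))
    }
  }
  invisible(x)
}

#' @rdname sim_island
#' @param x A `sim_estimates` object.
#' @param ... Unused.
#' @method tidy sim_estimates
#' @export
tidy.sim_estimates <- function(x, ...) {
  tibble::tibble(
    quantity = names(x$estimate),
    estimate = unname(x$estimate),
    se = unname(x$se)
  ) |>
    dplyr::filter(!is.na(.data$estimate))
}

#' Backward-time pair sampler for the island model
#'
#' Traces a pair of gene lineages backward through the island model and
#' scores identity by state, as an oracle independent of the analytic
#' recursion.  Each generation both lineages mutate with probability `u`
#' (allele labels follow the K-allele chain; under `K = Inf` any mutation
#' destroys identity) and the genealogical state then updates: two genes
#' in one individual resolve through selfing (coalesce with probability
#' `sigma/2` per generation); two genes in one deme share a parent with
#' probability `1/N` once their parent demes coincide; migration moves
#' lineages between demes with the same mixing probabilities as the
#' forward process.
#'
#' @param p An [island_params] object.
#' @param start Starting configurations to estimate: any of
#'   `"within_individual"` (estimates `f`), `"within_deme"` (`g_w`),
#'   `"between_demes"` (`g_b`).
#' @param reps Replicates per configuration.
#' @param seed Integer seed.
#' @param max_gen Generation cap; replicates still uncoalesced at the cap
#'   are scored as non-identical with a warning (this can only persist
#'   when migration disconnects the demes).
#' @return A tibble with columns `start`, `estimate`, `se`, `n`.
#' @examples
#' p <- island_params(N = 20, d = 2, u = 0.01, m = 0.01, K = 2)
#' sim_pair_island(p, reps = 2000, seed = 1)
#' @export
sim_pair_island <- function(p,
                            start = c("within_individual", "within_deme",
                                      "between_demes"),
                            reps = 1e5, seed = NULL, max_gen = NULL) {
  stopifnot(inherits(p, "island_params"))
  start <- match.arg(start, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_gen)) {
    mix_rate <- 2 * p$u + p$m + 1 / (2 * p$N * p$d)
    max_gen <- ceiling(200 / mix_rate)
  }
  if (p$d == 1) start <- setdiff(start, "between_demes")
  out <- purrr::map(start, function(s0) {
    id <- pair_island_once(p, s0, reps, max_gen)
    tibble::tibble(
      start = s0,
      estimate = mean(id),
      se = sqrt(mean(id) * (1 - mean(id)) / reps),
      n = reps
    )
  })
  dplyr::bind_rows(out)
}

pair_island_once <- function(p, s0, reps, max_gen) {
  sigma <- uniparental_prob(p$s, p$N)
  mix <- migration_mixing(p$m, p$d)
  st <- rep.int(switch(s0,
    within_individual = 1L, within_deme = 2L, between_demes = 3L
  ), reps)
  finiteK <- !is.infinite(p$K)
  if (finiteK) {
    a1 <- integer(reps); a2 <- integer(reps)
  } else {
    mutated <- logical(reps)
  }
  identical_at_coal <- logical(reps)
  active <- rep.int(TRUE, reps)
  gen <- 0L
  while (any(active) && gen < max_gen) {
    gen <- gen + 1L
    idx <- which(active)
    nact <- length(idx)
    if (p$u > 0) {
      if (finiteK) {
        for (al in c("a1", "a2")) {
          mut <- runif(nact) < p$u
          k <- sum(mut)
          if (k > 0) {
            v <- get(al)
            v[idx[mut]] <- (v[idx[mut]] +
                              sample.int(p$K - 1L, k, replace = TRUE)) %% p$K
            assign(al, v)
          }
        }
      } else {
        hit <- (runif(nact) < p$u) | (runif(nact) < p$u)
        mutated[idx[hit]] <- TRUE
        ## identity already lost: resolve immediately
        done <- idx[hit]
        if (length(done)) {
          active[done] <- FALSE
          idx <- which(active)
          nact <- length(idx)
          if (nact == 0L) break
        }
      }
    }
    s <- st[idx]
    u1 <- runif(nact); u2 <- runif(nact); u3 <- runif(nact)
    newst <- s
    coal <- logical(nact)
    isF <- s == 1L
    if (any(isF)) {
      uni <- u1[isF] < sigma
      coal[isF] <- uni & (u2[isF] < COMPLEMENT_COALESCENCE)
      newst[isF] <- ifelse(uni, 1L, 2L)
    }
    isWB <- s != 1L
    if (any(isWB)) {
      psame <- ifelse(s[isWB] == 2L, mix$psi, mix$chi)
      same <- u1[isWB] < psame
      share <- same & (u2[isWB] < 1 / p$N)
      coal[isWB] <- share & (u3[isWB] < COMPLEMENT_COALESCENCE)
      newst[isWB] <- ifelse(same,
                            ifelse(share, 1L, 2L),
                            3L)
    }
    st[idx] <- newst
    if (any(coal)) {
      ci <- idx[coal]
      identical_at_coal[ci] <- if (finiteK) a1[ci] == a2[ci] else !mutated[ci]
      active[ci] <- FALSE
    }
  }
  if (any(active)) {
    warn(sprintf(
      "%d of %d pair replicates did not coalesce within %d generations; scored as non-identical.",
      sum(active), reps, max_gen
    ))
  }
  identical_at_coal
}

#' Backward-time pair samplers for the two-deme model
#'
#' Continuous-time races among coalescence, migration and mutation for a
#' pair of lineages in the asymmetric two-deme model, in the scaling of
#' [two_deme_steady_state()] (time in units of `2N` generations;
#' coalescence rates `1/(2r)` and `1/(2(1-r))`, per-lineage migration
#' `M_i/2`, pair mutation rate `theta`).  `sim_two_deme_identity()`
#' scores identity as coalescence before any mutation (infinite-alleles);
#' `sim_two_deme_times()` runs the mutation-free chain and returns mean
#' coalescence times by starting configuration.
#'
#' @param r,M0,M1,theta Scaled two-deme parameters (see
#'   [two_deme_steady_state()]).
#' @param reps Replicates per starting configuration.
#' @param seed Integer seed.
#' @return A tibble with one row per starting configuration (`W0`, `W1`,
#'   `B`): identity estimate (or mean time) with standard error.
#' @examples
#' sim_two_deme_identity(r = 0.7, M0 = 4, M1 = 0.5, theta = 0.5,
#'                       reps = 2000, seed = 1)
#' @export
sim_two_deme_identity <- function(r, M0, M1, theta, reps = 1e5, seed = NULL) {
  stopifnot(r > 0, r < 1, M0 >= 0, M1 >= 0, theta >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map(c("W0", "W1", "B"), function(s0) {
    id <- two_deme_race(r, M0, M1, theta, s0, reps, want_time = FALSE)
    tibble::tibble(
      start = s0,
      estimate = mean(id),
      se = sqrt(mean(id) * (1 - mean(id)) / reps),
      n = reps
    )
  })
  dplyr::bind_rows(out)
}

#' @rdname sim_two_deme_identity
#' @export
sim_two_deme_times <- function(r, M0, M1, reps = 1e5, seed = NULL) {
  stopifnot(r > 0, r < 1, M0 >= 0, M1 >= 0)
  if (M0 + M1 == 0) {
    abort("M0 = M1 = 0: lineages in different demes never coalesce.")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map(c("W0", "W1", "B"), function(s0) {
    tt <- two_deme_race(r, M0, M1, 0, s0, reps, want_time = TRUE)
    tibble::tibble(
      start = s0,
      estimate = mean(tt),
      se = sd(tt) / sqrt(reps),
      n = reps
    )
  })
  dplyr::bind_rows(out)
}

two_deme_race <- function(r, M0, M1, theta, s0, reps, want_time) {
  st <- rep.int(match(s0, c("W0", "W1", "B")), reps)
  res <- if (want_time) numeric(reps) else logical(reps)
  tacc <- numeric(reps)
  active <- rep.int(TRUE, reps)
  crate <- c(1 / (2 * r), 1 / (2 * (1 - r)), 0)
  mrate <- c(M0, M1, (M0 + M1) / 2)
  repeat {
    idx <- which(active)
    if (!length(idx)) break
    s <- st[idx]
    total <- crate[s] + mrate[s] + theta
    tacc[idx] <- tacc[idx] + stats::rexp(length(idx), total)
    u <- runif(length(idx)) * total
    coal <- u < crate[s]
    mut <- !coal & (u < crate[s] + theta)
    mig <- !coal & !mut
    if (any(coal)) {
      ci <- idx[coal]
      if (want_time) res[ci] <- tacc[ci] else res[ci] <- TRUE
      active[ci] <- FALSE
    }
    if (any(mut)) active[idx[mut]] <- FALSE     # identity lost
    if (any(mig)) {
      mi <- idx[mig]
      sm <- st[mi]
      news <- integer(length(mi))
      news[sm != 3L] <- 3L
      inB <- sm == 3L
      if (any(inB)) {
        ## which lineage migrates: deme-0 lineage (-> W1) w.p. M0/(M0+M1)
        news[inB] <- ifelse(runif(sum(inB)) < M0 / (M0 + M1), 2L, 1L)
      }
      st[mi] <- news
    }
  }
  res
}

#' Sample a genotype table from a simulated island population
#'
#' Draws individuals without replacement from each deme of the final
#' state of a forward simulation at stationarity and emits a genotype
#' table ([read_genotypes()] format): columns `id`, `deme`, then one
#' column per locus coded `"a/b"`.  Because [sim_island()] gives every
#' locus its own pedigree, loci in the table are independent.
#'
#' @param p An [island_params] object.
#' @param n_per_deme Individuals sampled per deme (`<= N`).
#' @param n_loci Number of independent loci.
#' @param seed Integer seed (drives both the simulation and the
#'   sampling).
#' @param ... Passed to [sim_island()] (e.g. `burn_in`).
#' @return A genotype tibble.
#' @examples
#' p <- island_params(N = 10, d = 2, u = 0.01, m = 0.01, K = 4)
#' sim_genotypes(p, n_per_deme = 5, n_loci = 3, seed = 1, burn_in = 200)
#' @export
sim_genotypes <- function(p, n_per_deme, n_loci, seed = NULL, ...) {
  stopifnot(inherits(p, "island_params"), n_per_deme >= 1)
  if (n_per_deme > p$N) {
    abort(sprintf("cannot sample %d individuals from demes of size %d.",
                  n_per_deme, p$N))
  }
  if (n_loci == 0) {
    sim <- NULL
  } else {
    sim <- sim_island(p, n_loci = n_loci, seed = seed, keep_state = TRUE, ...)
  }
  if (!is.null(seed)) set.seed(seed + 1L)
  ids <- character(0)
  demes <- character(0)
  rows <- list()
  for (j in seq_len(p$d)) {
    pick <- sort(sample.int(p$N, n_per_deme)) + (j - 1L) * p$N
    ids <- c(ids, sprintf("d%d_i%d", j, seq_len(n_per_deme)))
    demes <- c(demes, rep.int(sprintf("deme%d", j), n_per_deme))
    rows[[j]] <- pick
  }
  tab <- tibble::tibble(id = ids, deme = demes)
  if (n_loci > 0) {
    pick_all <- unlist(rows)
    for (l in seq_len(n_loci)) {
      tab[[sprintf("locus%d", l)]] <-
        paste0(sim$state[pick_all, 1L, l], "/", sim$state[pick_all, 2L, l])
    }
  }
  tab
}
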