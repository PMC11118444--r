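# Independent Monte Carlo / enumeration oracles used to cross-check the
# analytic implementations.  These deliberately share no code with the
# package internals.

# Gene-dropping estimate of an inbreeding coefficient: founders receive
# unique allele labels, every non-founder inherits one random allele from
# each parent; F is the probability the focal individual's two alleles
# are copies of one founder gene.
gene_drop_inbreeding <- function(ped, individual, reps = 1e5) {
  n <- nrow(ped)
  a1 <- matrix(0L, reps, n)
  a2 <- matrix(0L, reps, n)
  lab <- 0L
  for (i in seq_len(n)) {               # ped is topologically ordered
    if (is.na(ped$sire[i])) {
      a1[, i] <- lab + 1L
      a2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      si <- match(ped$sire[i], ped$id)
      di <- match(ped$dam[i], ped$id)
      pick1 <- stats::runif(reps) < 0.5
      pick2 <- stats::runif(reps) < 0.5
      a1[, i] <- ifelse(pick1, a1[, si], a2[, si])
      a2[, i] <- ifelse(pick2, a1[, di], a2[, di])
    }
  }
  k <- match(individual, ped$id)
  mean(a1[, k] == a2[, k])
}

# Brute-force plug-in identity estimates from a genotype tibble: explicit
# loops over individual pairs and their four cross-gene comparisons,
# equal deme weights, single locus.
enum_identities <- function(g, locus) {
  parts <- strsplit(g[[locus]], "[/|]")
  a <- do.call(rbind, lapply(parts, function(p) if (is.null(p)) c(NA, NA) else p))
  ok <- !is.na(g[[locus]])
  f <- mean(a[ok, 1] == a[ok, 2])
  demes <- sort(unique(g$deme))
  pair_mean <- function(i, j) {
    mean(c(a[i, 1] == a[j, 1], a[i, 1] == a[j, 2],
           a[i, 2] == a[j, 1], a[i, 2] == a[j, 2]))
  }
  gw <- sapply(demes, function(dm) {
    idx <- which(ok & g$deme == dm)
    if (length(idx) < 2) return(NA_real_)
    prs <- utils::combn(idx, 2)
    mean(apply(prs, 2, function(p) pair_mean(p[1], p[2])))
  })
  gb <- if (length(demes) >= 2) {
    dp <- utils::combn(length(demes), 2)
    mean(apply(dp, 2, function(q) {
      i1 <- which(ok & g$deme == demes[q[1]])
      i2 <- which(ok & g$deme == demes[q[2]])
      if (!length(i1) || !length(i2)) return(NA_real_)
      mean(outer(i1, i2, Vectorize(pair_mean)))
    }), na.rm = TRUE)
  } else {
    NA_real_
  }
  list(f = f, g_w = mean(gw, na.rm = TRUE), g_b = gb)
}

# Random valid non-IBS hierarchy for property tests.
random_hierarchy <- function(L) {
  h <- stats::runif(L + 1, min = 0.05, max = 1)
  h
}
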