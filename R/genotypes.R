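#' Read and write genotype tables
#'
#' The native genotype format is a TSV with columns `id`, `deme`, then
#' one column per locus holding an unordered diploid call coded `"a/b"`
#' (any non-slash allele labels; `|` accepted as separator and treated
#' identically, so phased and unphased calls parse to the same unordered
#' pair).  Missing genotypes are `./.` (or empty/NA).  VCF input parses
#' diploid `GT` fields with allele indices as labels; multiallelic sites
#' are kept; a two-column sample-to-deme mapping (TSV: sample, deme) is
#' required.
#'
#' @param path Path to the genotype file.
#' @param format `"table"` (native TSV) or `"vcf"`.
#' @param deme_map For VCF input: path to a two-column TSV (sample, deme)
#'   or a data frame with those columns.
#' @return A genotype tibble: `id`, `deme`, then one character column per
#'   locus with `"a/b"` calls and `NA` for missing.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' g <- tibble::tibble(id = c("i1", "i2"), deme = c("A", "A"),
#'                     L1 = c("a/a", "a/b"))
#' write_genotypes(g, tf)
#' read_genotypes(tf)
#' @export
read_genotypes <- function(path, format = c("table", "vcf"), deme_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "table") {
    read_genotype_table(path)
  } else {
    read_genotype_vcf(path, deme_map)
  }
}

read_genotype_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("id", "deme") %in% names(tab)[1:2])) {
    abort("genotype table must start with columns 'id' and 'deme'.")
  }
  loci <- setdiff(names(tab), c("id", "deme"))
  for (lc in loci) {
    x <- tab[[lc]]
    miss <- is.na(x) | x %in% c(".", "./.", ".|.")
    x[miss] <- NA_character_
    bad <- !miss & !grepl("^[^/|]+[/|][^/|]+$", x)
    if (any(bad)) {
      abort(sprintf(
        "malformed genotype '%s' at locus '%s', line %d.",
        x[which(bad)[1]], lc, which(bad)[1] + 1L
      ))
    }
    tab[[lc]] <- x
  }
  if (anyNA(tab$deme)) abort("every individual needs a deme label.")
  tab
}

read_genotype_vcf <- function(path, deme_map) {
  if (is.null(deme_map)) {
    abort("VCF input requires a sample-to-deme mapping (`deme_map`).")
  }
  if (is.character(deme_map)) {
    deme_map <- readr::read_tsv(
      deme_map, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  deme_map <- tibble::as_tibble(deme_map)
  names(deme_map)[1:2] <- c("sample", "deme")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  unknown <- setdiff(samples, deme_map$sample)
  if (length(unknown)) {
    abort(sprintf("VCF sample(s) absent from deme map: %s",
                  paste(unknown, collapse = ", ")))
  }
  loci <- rownames(gt)
  if (is.null(loci)) {
    loci <- paste0(vcf@fix[, "CHROM"], ":", vcf@fix[, "POS"])
  }
  tab <- tibble::tibble(
    id = samples,
    deme = deme_map$deme[match(samples, deme_map$sample)]
  )
  for (i in seq_along(loci)) {
    x <- gt[i, ]
    miss <- is.na(x) | x %in% c(".", "./.", ".|.")
    x[miss] <- NA_character_
    ok <- miss | grepl("^[0-9]+[/|][0-9]+$", x)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort(sprintf(
        "non-diploid or malformed GT '%s' for sample '%s' at site '%s'.",
        x[bad], samples[bad], loci[i]
      ))
    }
    tab[[loci[i]]] <- unname(x)
  }
  tab
}

#' @rdname read_genotypes
#' @param g A genotype tibble.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(all(c("id", "deme") %in% names(g)))
  readr::write_tsv(g, path, na = "./.")
}

## Split a genotype tibble into two allele-label character matrices.
genotype_alleles <- function(g) {
  loci <- setdiff(names(g), c("id", "deme"))
  n <- nrow(g)
  a1 <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (j in seq_along(loci)) {
    x <- g[[loci[j]]]
    ok <- !is.na(x)
    parts <- strsplit(x[ok], "[/|]")
    a1[ok, j] <- vapply(parts, `[`, "", 1L)
    a2[ok, j] <- vapply(parts, `[`, "", 2L)
  }
  list(a1 = a1, a2 = a2, loci = loci)
}

#' Estimate IBS probabilities from a genotype table
#'
#' Plug-in estimators of the identity-by-state probabilities that
#' parameterise the island hierarchy: per locus, `f_hat` is the
#' proportion of homozygous individuals; `g_w_hat` averages, over all
#' unordered pairs of distinct individuals within a deme, the mean of the
#' four cross-individual gene comparisons; `g_b_hat` does the same over
#' cross-deme pairs.  Demes receive equal weight by default (matching the
#' exchangeable demes of the island model); `deme_weights = "size"`
#' weights demes (and deme pairs) by their callable sample sizes.
#' Missing genotypes are excluded pairwise; a deme with fewer than two
#' callable individuals at a locus contributes no `g_w_hat` there, and a
#' statistic with no usable data is reported as `NA`, never zero.
#'
#' @param g A genotype tibble (see [read_genotypes()]).
#' @param deme_weights `"equal"` or `"size"`.
#' @return An object of class `identity_estimates` with per-locus,
#'   per-deme and combined (averaged over loci) estimates.  [tidy()]
#'   returns the per-locus tibble, [glance()] the combined one-row
#'   summary.
#' @examples
#' g <- tibble::tibble(
#'   id = c("i1", "i2", "i3", "i4"),
#'   deme = c("A", "A", "B", "B"),
#'   L1 = c("a/a", "a/b", "b/b", "b/b")
#' )
#' glance(estimate_identities(g))
#' @export
estimate_identities <- function(g, deme_weights = c("equal", "size")) {
  deme_weights <- match.arg(deme_weights)
  stopifnot(all(c("id", "deme") %in% names(g)))
  al <- genotype_alleles(g)
  if (!length(al$loci)) abort("no locus columns in genotype table.")
  demes <- sort(unique(g$deme))
  d <- length(demes)
  L <- length(al$loci)

  by_deme <- vector("list", L)
  by_pair <- vector("list", L)
  per_locus <- tibble::tibble(
    locus = al$loci, f_hat = NA_real_, g_w_hat = NA_real_, g_b_hat = NA_real_
  )
  for (l in seq_len(L)) {
    x1 <- al$a1[, l]; x2 <- al$a2[, l]
    ok <- !is.na(x1)
    per_locus$f_hat[l] <- if (any(ok)) mean(x1[ok] == x2[ok]) else NA_real_

    gw <- rep(NA_real_, d); nj <- integer(d)
    counts <- vector("list", d)
    for (j in seq_len(d)) {
      sel <- ok & g$deme == demes[j]
      nj[j] <- sum(sel)
      genes <- c(x1[sel], x2[sel])
      counts[[j]] <- if (nj[j] > 0) table(genes) else NULL
      if (nj[j] >= 2) {
        S <- sum(as.numeric(counts[[j]])^2)
        hom <- sum(x1[sel] == x2[sel])
        gw[j] <- (S - 2 * nj[j] - 2 * hom) / (4 * nj[j] * (nj[j] - 1))
      }
    }
    by_deme[[l]] <- tibble::tibble(
      locus = al$loci[l], deme = demes, g_w_hat = gw, n = nj
    )
    wj <- if (deme_weights == "equal") rep(1, d) else nj
    use <- !is.na(gw)
    per_locus$g_w_hat[l] <- if (any(use)) {
      sum(wj[use] * gw[use]) / sum(wj[use])
    } else {
      NA_real_
    }

    if (d >= 2) {
      pr <- combn(d, 2)
      gb <- rep(NA_real_, ncol(pr)); wp <- numeric(ncol(pr))
      for (q in seq_len(ncol(pr))) {
        j <- pr[1, q]; k <- pr[2, q]
        if (nj[j] >= 1 && nj[k] >= 1) {
          cj <- counts[[j]]; ck <- counts[[k]]
          common <- intersect(names(cj), names(ck))
          m <- if (length(common)) {
            sum(as.numeric(cj[common]) * as.numeric(ck[common]))
          } else {
            0
          }
          gb[q] <- m / (4 * nj[j] * nj[k])
          wp[q] <- if (deme_weights == "equal") 1 else nj[j] * nj[k]
        }
      }
      by_pair[[l]] <- tibble::tibble(
        locus = al$loci[l], deme1 = demes[pr[1, ]], deme2 = demes[pr[2, ]],
        g_b_hat = gb
      )
      use <- !is.na(gb)
      per_locus$g_b_hat[l] <- if (any(use)) {
        sum(wp[use] * gb[use]) / sum(wp[use])
      } else {
        NA_real_
      }
    }
  }

  combined <- tibble::tibble(
    f_hat = mean(per_locus$f_hat, na.rm = TRUE),
    g_w_hat = mean(per_locus$g_w_hat, na.rm = TRUE),
    g_b_hat = if (d >= 2) mean(per_locus$g_b_hat, na.rm = TRUE) else NA_real_,
    n_loci = L,
    n_demes = d
  )
  structure(
    list(
      per_locus = per_locus,
      by_deme = dplyr::bind_rows(by_deme),
      by_deme_pair = if (d >= 2) dplyr::bind_rows(by_pair) else NULL,
      combined = combined,
      deme_weights = deme_weights
    ),
    class = "identity_estimates"
  )
}

#' @export
print.identity_estimates <- function(x, ...) {
  cat("IBS identity estimates over", nrow(x$per_locus), "locus/loci\n")
  print(x$combined)
  invisible(x)
}

#' @rdname estimate_identities
#' @param x An `identity_estimates` object.
#' @param ... Unused.
#' @method tidy identity_estimates
#' @export
tidy.identity_estimates <- function(x, ...) x$per_locus

#' @rdname estimate_identities
#' @method glance identity_estimates
#' @export
glance.identity_estimates <- function(x, ...) x$combined

#' Estimate the non-IBS hierarchy and G*-statistics from genotypes
#'
#' Builds the three-level hierarchy `(h_0, h_1, h_2)` per locus from the
#' identity estimates of [estimate_identities()] via [island_levels()],
#' then combines loci by averaging the `h` levels across loci *before*
#' forming ratios (a ratio of averages, following the construction of
#' multilocus gene-diversity indices), yielding combined `G_1*`, `G_2*`
#' and `G_IT*`.  Per-locus statistics are also returned so either
#' combination can be formed downstream.
#'
#' @param g A genotype tibble.
#' @param N Census deme size used in the `1/N` terms; defaults to the
#'   mean number of genotyped individuals per deme.
#' @param d Census deme count; defaults to the number of demes sampled.
#' @param deme_weights Passed to [estimate_identities()].
#' @return An object of class `hierarchy_fit` with elements `per_locus`
#'   (tibble of per-locus `h` and `G*` values), `h` (combined levels),
#'   `g_stats` (combined [g_statistics()]), `identities`, `N`, `d` and
#'   `dropped_loci`.
#' @examples
#' g <- tibble::tibble(
#'   id = c("i1", "i2", "i3", "i4"),
#'   deme = c("A", "A", "B", "B"),
#'   L1 = c("a/a", "a/b", "b/b", "b/b")
#' )
#' estimate_hierarchy(g)$h
#' @export
estimate_hierarchy <- function(g, N = NULL, d = NULL,
                               deme_weights = c("equal", "size")) {
  est <- estimate_identities(g, deme_weights = deme_weights)
  demes_sampled <- est$combined$n_demes
  if (is.null(d)) d <- demes_sampled
  if (is.null(N)) {
    N <- mean(table(g$deme))
  }
  if (N < 1) abort("census deme size N must be >= 1.")
  pl <- est$per_locus
  single_deme <- demes_sampled < 2
  usable <- !is.na(pl$f_hat) & !is.na(pl$g_w_hat) &
    (single_deme | !is.na(pl$g_b_hat))
  dropped <- pl$locus[!usable]
  if (!any(usable)) abort("no locus with sufficient data for the hierarchy.")

  h0 <- 1 - pl$f_hat
  h1 <- ((1 - pl$f_hat) / 2) / N + (1 - pl$g_w_hat) * (1 - 1 / N)
  h2 <- if (single_deme) rep(NA_real_, nrow(pl)) else {
    h1 / d + (1 - pl$g_b_hat) * (1 - 1 / d)
  }
  g1 <- ifelse(h1 > 0, (h1 - h0) / h1, NA_real_)
  g2 <- if (single_deme) rep(NA_real_, nrow(pl)) else {
    ifelse(h2 > 0, (h2 - h1) / h2, NA_real_)
  }
  git <- if (single_deme) g1 else ifelse(h2 > 0, 1 - h0 / h2, NA_real_)
  per_locus <- tibble::tibble(
    locus = pl$locus, h0 = h0, h1 = h1, h2 = h2,
    g1_star = g1, g2_star = g2, git_star = git
  )

  hbar <- c(
    h0 = mean(h0[usable]),
    h1 = mean(h1[usable]),
    h2 = if (single_deme) NA_real_ else mean(h2[usable])
  )
  hvec <- if (single_deme) hbar[1:2] else hbar
  if (any(hvec[-1] == 0)) {
    abort("combined h levels are zero: the data are monomorphic, G* undefined.")
  }
  gs <- g_statistics(hvec)
  structure(
    list(
      per_locus = per_locus,
      h = hbar,
      g_stats = gs,
      g1 = gs$per_level[1],
      g2 = if (single_deme) NA_real_ else gs$per_level[2],
      git = gs$total,
      identities = est,
      N = N, d = d,
      n_loci_used = sum(usable),
      dropped_loci = dropped
    ),
    class = "hierarchy_fit"
  )
}

#' @export
print.hierarchy_fit <- function(x, ...) {
  cat(sprintf(
    "IBS hierarchy from %d locus/loci (N = %g, d = %d)\n",
    x$n_loci_used, x$N, x$d
  ))
  cat("  combined h:", paste(signif(x$h, 6), collapse = ", "), "\n")
  cat(sprintf("  G_1* = %.6g, G_2* = %.6g, G_IT* = %.6g\n",
              x$g1, x$g2, x$git))
  if (length(x$dropped_loci)) {
    cat("  dropped loci:", paste(x$dropped_loci, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname estimate_hierarchy
#' @param x A `hierarchy_fit` object.
#' @param ... Unused.
#' @method tidy hierarchy_fit
#' @export
tidy.hierarchy_fit <- function(x, ...) x$per_locus

#' @rdname estimate_hierarchy
#' @method glance hierarchy_fit
#' @export
glance.hierarchy_fit <- function(x, ...) {
  tibble::tibble(
    h0 = x$h[["h0"]], h1 = x$h[["h1"]], h2 = x$h[["h2"]],
    g1_star = x$g1, g2_star = x$g2, git_star = x$git,
    n_loci = x$n_loci_used, n_dropped = length(x$dropped_loci),
    N = x$N, d = x$d
  )
}
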