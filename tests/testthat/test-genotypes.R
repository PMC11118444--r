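worked_table <- function() {
  tibble::tibble(
    id = c("i1", "i2", "i3", "i4"),
    deme = c("A", "A", "B", "B"),
    L1 = c("a/a", "a/b", "b/b", "b/b")
  )
}

test_that("genotype tables round-trip through write/read", {
  g <- worked_table()
  g$L2 <- c("0/1", NA, "2|0", "1/1")
  tf <- tempfile(fileext = ".tsv")
  write_genotypes(g, tf)
  g2 <- read_genotypes(tf)
  expect_equal(as.data.frame(g2), as.data.frame(g))
  expect_error(read_genotypes(tempfile(), "table"), "not found")
})

test_that("malformed tables are rejected with context", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tdeme\tL1", "i1\tA\ta/b", "i2\tA\tabc"), tf)
  expect_error(read_genotypes(tf), "malformed genotype 'abc'")
  writeLines(c("id\tL1", "i1\ta/b"), tf)
  expect_error(read_genotypes(tf), "'id' and 'deme'")
})

write_test_vcf <- function(path, gts) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", seq_along(gts[[1]]))), collapse = "\t")
  )
  rows <- vapply(seq_along(gts), function(i) {
    paste(c("chr1", i, paste0("site", i), "A", "C,T", ".", "PASS", ".",
            "GT", gts[[i]]), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
}

test_that("VCF input parses diploid GT with deme mapping; phase is ignored", {
  tf <- tempfile(fileext = ".vcf")
  write_test_vcf(tf, list(c("0|1", "0/1", "1/1", "./."),
                          c("0/0", "2/0", "1|2", "0/0")))
  dm <- tibble::tibble(sample = paste0("s", 1:4),
                       deme = c("A", "A", "B", "B"))
  g <- read_genotypes(tf, format = "vcf", deme_map = dm)
  expect_equal(nrow(g), 4)
  al <- estimate_identities(g)
  # phased 0|1 and unphased 0/1 give the same unordered pair
  pl <- tidy(al)
  expect_equal(pl$f_hat[1], 1 / 3)   # s4 missing; s3 homozygous of 3 callable
  # multiallelic site retained with index labels
  expect_true(any(grepl("2", g[[4]])))

  expect_error(read_genotypes(tf, format = "vcf"), "deme_map")
  dm_bad <- dm[1:3, ]
  expect_error(read_genotypes(tf, format = "vcf", deme_map = dm_bad),
               "absent from deme map")

  tf2 <- tempfile(fileext = ".vcf")
  write_test_vcf(tf2, list(c("0", "0/1", "1/1", "0/0")))
  expect_error(read_genotypes(tf2, format = "vcf", deme_map = dm),
               "non-diploid.*s1")
})

test_that("identity estimators reproduce full pair enumeration", {
  g <- worked_table()
  est <- glance(estimate_identities(g))
  expect_equal(est$f_hat, 0.75)
  expect_equal(est$g_w_hat, 0.75)
  expect_equal(est$g_b_hat, 0.25)

  # monomorphic data: all identities one
  mono <- tibble::tibble(id = c("a", "b", "c"), deme = c("X", "X", "Y"),
                         L1 = c("a/a", "a/a", "a/a"))
  em <- glance(estimate_identities(mono))
  expect_equal(c(em$f_hat, em$g_w_hat, em$g_b_hat), c(1, 1, 1))

  # randomised cross-check against the brute-force enumeration oracle,
  # including missing genotypes
  set.seed(17)
  for (rep in 1:10) {
    n <- 9
    g <- tibble::tibble(
      id = paste0("i", 1:n),
      deme = sample(c("A", "B", "C"), n, replace = TRUE),
      L1 = paste0(sample(letters[1:3], n, TRUE), "/",
                  sample(letters[1:3], n, TRUE))
    )
    g$L1[sample(n, 1)] <- NA
    if (length(unique(g$deme[!is.na(g$L1)])) < 2) next
    o <- enum_identities(g, "L1")
    e <- estimate_identities(g)$per_locus
    expect_equal(e$f_hat, o$f)
    expect_equal(e$g_w_hat, o$g_w)
    expect_equal(e$g_b_hat, o$g_b)
  }
})

test_that("hierarchy estimation assembles the printed h-levels and errors sanely", {
  fit <- estimate_hierarchy(worked_table())   # N defaults to 2, d to 2
  # h0 = 1 - 0.75; h1 = (0.25/2)/2 + 0.25 * (1/2); h2 = h1/2 + 0.75 * (1/2)
  expect_equal(unname(fit$h), c(0.25, 0.1875, 0.46875))
  expect_equal(fit$g1, (0.1875 - 0.25) / 0.1875)
  expect_equal(fit$git, 1 - 0.25 / 0.46875)

  mono <- tibble::tibble(id = c("a", "b", "c", "d"),
                         deme = c("X", "X", "Y", "Y"),
                         L1 = c("a/a", "a/a", "a/a", "a/a"))
  expect_error(estimate_hierarchy(mono), "monomorphic")

  single <- tibble::tibble(id = c("a", "b", "c"), deme = "X",
                           L1 = c("a/a", "a/b", "b/b"))
  sfit <- estimate_hierarchy(single)
  expect_true(is.na(sfit$g2))
  expect_false(is.na(sfit$g1))
})

test_that("estimates from simulated stationary data converge on analytic values", {
  p <- island_params(N = 20, d = 2, s = 0.5, u = 0.0125, m = 0.0125, K = 4)
  an <- island_steady_state(p)$identities
  sizes <- c(200, 800)
  errs <- numeric(2)
  ses <- numeric(2)
  for (i in 1:2) {
    g <- sim_genotypes(p, n_per_deme = 20, n_loci = sizes[i], seed = 40 + i,
                       n_samples = 2)
    est <- estimate_identities(g)
    errs[i] <- abs(est$combined$g_w_hat - an[["g_w"]])
    ses[i] <- sd(est$per_locus$g_w_hat) / sqrt(sizes[i])
    expect_lt(abs(est$combined$f_hat - an[["f"]]), 4 * sd(est$per_locus$f_hat) / sqrt(sizes[i]))
    expect_lt(errs[i], 4 * ses[i])
    expect_lt(abs(est$combined$g_b_hat - an[["g_b"]]),
              4 * sd(est$per_locus$g_b_hat) / sqrt(sizes[i]))
  }
  # quadrupling loci halves the standard error
  expect_gt(ses[1] / ses[2], 1.4)
  expect_lt(ses[1] / ses[2], 2.9)
})

test_that("a 10-fold mutation-rate contrast lowers G_2* at the diverse loci", {
  N <- 20
  base <- list(d = 2, s = 0, m = 0.0025)
  p_lo <- island_params(N = N, d = base$d, s = base$s, u = 0.00125,
                        m = base$m, K = Inf)
  p_hi <- island_params(N = N, d = base$d, s = base$s, u = 0.0125,
                        m = base$m, K = Inf)
  g_lo <- sim_genotypes(p_lo, n_per_deme = 20, n_loci = 200, seed = 51,
                        n_samples = 2)
  g_hi <- sim_genotypes(p_hi, n_per_deme = 20, n_loci = 200, seed = 52,
                        n_samples = 2)
  f_lo <- estimate_hierarchy(g_lo, N = N, d = 2)
  f_hi <- estimate_hierarchy(g_hi, N = N, d = 2)
  expect_gt(f_lo$g2, f_hi$g2)
})

test_that("permuting deme labels removes apparent between-deme structure", {
  p <- island_params(N = 20, d = 2, s = 0, u = 0.0125, m = 0.0025, K = Inf)
  g <- sim_genotypes(p, n_per_deme = 20, n_loci = 100, seed = 61, n_samples = 2)
  orig <- estimate_hierarchy(g, N = 20, d = 2)
  set.seed(62)
  g2s <- replicate(8, {
    gp <- g
    gp$deme <- sample(gp$deme)
    estimate_hierarchy(gp, N = 20, d = 2)$g2
  })
  expect_gt(orig$g2, mean(g2s) + 3 * sd(g2s))
  expect_lt(abs(mean(g2s)), 3 * sd(g2s) / sqrt(length(g2s)) + 0.02)
})
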