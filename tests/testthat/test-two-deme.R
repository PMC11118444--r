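test_that("raw-to-scaled parameter conversion follows the definitions", {
  sc <- scale_two_deme(two_deme_params(700, 300, 1e-3, 4e-4, 1e-4))
  expect_equal(sc$r, 0.7)
  expect_equal(sc$N, 500)
  expect_equal(sc$M0, 4 * 500 * 1e-3)
  expect_equal(sc$M1, 4 * 500 * 4e-4)
  expect_equal(sc$theta, 4 * 500 * 1e-4)
  expect_equal(scale_two_deme(two_deme_params(500, 500, 0, 0, 0))$r, 0.5)
  expect_warning(two_deme_params(1000, 1000, 0.2, 0.01, 1e-4), "scaling")
})

test_that("identity solver honours the mutation-free and symmetric limits", {
  expect_equal(
    unname(two_deme_identities(0.3, 2, 1, 0)), c(1, 1, 1)
  )
  sym <- two_deme_identities(0.5, 2, 2, 0.7)
  expect_equal(sym[["g_w0"]], sym[["g_w1"]])
  expect_warning(
    iso <- two_deme_identities(0.5, 0, 0, 1),
    "never coalesce"
  )
  expect_equal(unname(iso[["g_b"]]), 0)
})

test_that("the solved boundary case r = r_min gives g_w0 = g_b exactly", {
  # frozen from an independent solve of the three-equation system
  ids <- two_deme_identities(0.7, 4, 0.5, 0.5)
  expect_equal(ids[["g_w0"]], 0.5882352941, tolerance = 1e-9)
  expect_equal(ids[["g_w1"]], 0.7352941176, tolerance = 1e-9)
  expect_equal(ids[["g_b"]], 0.5882352941, tolerance = 1e-9)
  expect_equal(ids[["g_w0"]], ids[["g_b"]], tolerance = 1e-12)
  expect_equal(r_min(4, 0.5, 0.5), 0.7)
})

test_that("deme-specific indices: examples, sign agreement and dominance", {
  expect_equal(beta_wt(0.6, 0.5), 0.2)
  expect_equal(beta_wt(0.5, 0.6), -0.25)
  expect_equal(beta_wt(0.4, 0.4), 0)
  expect_equal(gst_deme(0.6, 0.5, 0.5), (0.5 * 0.1) / (0.5 * 0.4 + 0.5 * 0.5))
  expect_equal(gst_deme(0.4, 0.4, 0.3), 0)
  expect_error(beta_wt(0.5, 1), "undefined")
  expect_error(gst_deme(1, 1, 0.5), "undefined")

  set.seed(11)
  for (i in 1:300) {
    g_w0 <- runif(1, 0, 0.999)
    g_b <- runif(1, 0, 0.999)
    r <- runif(1, 0.01, 0.99)
    b <- beta_wt(g_w0, g_b)
    g <- gst_deme(g_w0, g_b, r)
    expect_equal(sign(b), sign(g))
    expect_gte(abs(b), abs(g))
    if (g_w0 != g_b) expect_gt(abs(b), abs(g))
    # printed closed form for the difference equals direct subtraction
    expect_lt(abs(index_difference(g_w0, g_b, r) - (b - g)), 1e-12)
  }
  # indices coincide as the focal deme's share vanishes
  expect_lt(abs(index_difference(0.6, 0.5, 1e-12)), 1e-11)
})

test_that("r_min matches its closed form, bounds and monotonicity", {
  expect_equal(r_min(4, 0.5, 0.5), 0.7)
  # M0 = 1 puts the threshold exactly at 1 for any M1, theta
  expect_equal(r_min(1, 0.3, 0.7), 1)
  expect_equal(r_min(1, 5, 0.01), 1)
  # M0 -> infinity approaches 1/2 from above
  expect_equal(r_min(1e9, 1, 1), 0.5, tolerance = 1e-8)
  expect_error(r_min(0, 0, 0), "> 0")
  # soft migration: threshold declines uniformly in M0
  for (M1 in c(0.1, 1)) {
    for (theta in c(0.1, 2)) {
      rm <- r_min(seq(1.1, 30, length.out = 40), M1, theta)
      expect_true(all(diff(rm) < 0))
      expect_true(all(rm > 0.5))
    }
  }
})

test_that("bisection boundary of the solver coincides with closed-form r_min", {
  bisect_boundary <- function(M0, M1, theta) {
    fn <- function(r) {
      ids <- two_deme_identities(r, M0, M1, theta)
      ids[["g_w0"]] - ids[["g_b"]]
    }
    lo <- 0.5; hi <- 1 - 1e-9
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (fn(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  grid <- expand.grid(M0 = c(1.5, 2, 4, 8), M1 = c(0.1, 0.5), theta = c(0.1, 1))
  for (i in seq_len(nrow(grid))) {
    rm <- r_min(grid$M0[i], grid$M1[i], grid$theta[i])
    if (rm < 1 - 1e-6) {
      expect_lt(abs(bisect_boundary(grid$M0[i], grid$M1[i], grid$theta[i]) - rm),
                1e-8)
    }
  }
})

test_that("hard migration keeps both deme-specific indices non-negative", {
  expect_equal(hard_migration_partner(0.5, 2), 2)
  expect_equal(hard_migration_partner(0.75, 1), 3)
  expect_true(is_hard_migration(0.75, 1, 3))
  expect_false(is_hard_migration(0.75, 1, 2))
  for (r in seq(0.1, 0.9, by = 0.2)) {
    for (M0 in c(0.5, 2, 8)) {
      for (theta in c(0.1, 1)) {
        M1 <- hard_migration_partner(r, M0)
        fit <- two_deme_steady_state(r, M0, M1, theta)
        expect_gte(fit$gst0_star, -1e-12)
        expect_gte(fit$beta_wt0, -1e-12)
      }
    }
  }
})

test_that("the diversity distance D* is positive at steady state, zero iff flat", {
  expect_equal(nei_distance(0.6, 0.6, 0.3), log(2))
  expect_equal(nei_distance(0.5, 0.5, 0.5), 0)
  expect_error(nei_distance(0.5, 0.5, 0), "positive")
  set.seed(5)
  for (i in 1:40) {
    fit <- two_deme_steady_state(
      runif(1, 0.05, 0.95), runif(1, 0.1, 8), runif(1, 0.1, 8),
      runif(1, 0.05, 4)
    )
    expect_gt(fit$d_star, 0)
  }
})

test_that("coalescence times solve the mutation-free chain; Slatkin's index follows", {
  ct <- coalescence_times(0.5, 1, 1)
  expect_equal(ct$E_W0, ct$E_W1)
  expect_equal(ct$E_Ts, ct$E_W0)
  fst <- slatkin_fst(ct)
  expect_gt(fst, 0)
  # residence-time identity: the within-deme equations can be verified
  # directly by substitution into the first-step system
  c0 <- 1 / (2 * 0.3); c1 <- 1 / (2 * 0.7)
  ct2 <- coalescence_times(0.3, 2, 0.6)
  expect_equal((1 + 2 * ct2$E_B) / (c0 + 2), ct2$E_W0, tolerance = 1e-12)
  expect_equal((1 + 0.6 * ct2$E_B) / (c1 + 0.6), ct2$E_W1, tolerance = 1e-12)
  expect_equal((1 + 1 * ct2$E_W1 + 0.3 * ct2$E_W0) / ((2 + 0.6) / 2),
               ct2$E_B, tolerance = 1e-12)
  expect_error(coalescence_times(0.5, 0, 0), "never coalesce")
})

test_that("the diversity index converges to Slatkin's F_ST* as mutation vanishes", {
  r <- 0.35; M0 <- 1.2; M1 <- 0.4
  fst <- slatkin_fst(coalescence_times(r, M0, M1))
  idx <- sapply(c(1e-2, 1e-3, 1e-4), function(theta) {
    ids <- two_deme_identities(r, M0, M1, theta)
    g_ws <- (r^2 * ids[["g_w0"]] + (1 - r)^2 * ids[["g_w1"]]) /
      (r^2 + (1 - r)^2)
    g_tot <- r^2 * ids[["g_w0"]] + (1 - r)^2 * ids[["g_w1"]] +
      2 * r * (1 - r) * ids[["g_b"]]
    1 - (1 - g_ws) / (1 - g_tot)
  })
  errs <- abs(idx - fst)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
  # error shrinks roughly linearly with theta
  expect_gt(errs[1] / errs[2], 5)
})

test_that("two_deme_steady_state assembles consistent summary components", {
  fit <- two_deme_steady_state(0.8, 6, 0.5, 0.5)
  expect_gt(fit$r, fit$r_min)       # in the negativity region
  expect_lt(fit$gst0_star, 0)
  expect_lt(fit$beta_wt0, 0)
  expect_gt(fit$d_star, 0)
  expect_false(fit$hard_migration)
  td <- tidy(fit)
  expect_true(all(c("beta_WT0", "GST0_star", "FST_slatkin") %in% td$quantity))
})
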