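test_that("DE matches hand-computed trapezoids", {
  ramp <- dissolution_profile(c(0, 240), c(0, 100))
  expect_equal(compute_de(ramp, 240), 50)

  flat <- dissolution_profile(c(0, 60, 120), c(100, 100, 100))
  expect_equal(compute_de(flat, 120), 100)
  expect_equal(compute_de(flat, 90), 100)

  p <- dissolution_profile(c(0, 60, 120, 240), c(0, 60, 90, 100))
  expect_equal(compute_de(p, 240), 73.75)

  # t_end between samples: linear interpolation, checked against the
  # loop-based trapezoid oracle on the augmented grid
  y180 <- approx(p$times, p$release, 180)$y
  expect_equal(compute_de(p, 180),
               100 * trapz_oracle(c(0, 60, 120, 180), c(0, 60, 90, y180)) /
                 (100 * 180))
})

test_that("DE rejects out-of-range horizons", {
  p <- dissolution_profile(c(0, 60, 120), c(0, 40, 70))
  expect_error(compute_de(p, 240), class = "dk_extrapolation_error")
  expect_error(compute_de(p, 0), class = "dk_domain_error")
  expect_error(compute_de(p, -10), class = "dk_domain_error")
})

test_that("MDT matches hand-computed increment-weighted midpoints", {
  uniform <- dissolution_profile(c(0, 60, 120, 180, 240), c(0, 25, 50, 75, 100))
  expect_equal(compute_mdt(uniform), 2.0)

  burst <- dissolution_profile(c(0, 60, 120), c(0, 100, 100))
  expect_equal(compute_mdt(burst), 0.5)

  p <- dissolution_profile(c(0, 60, 120, 240), c(0, 60, 90, 100))
  expect_equal(compute_mdt(p), 1.05)

  flatzero <- dissolution_profile(c(0, 60, 120), c(0, 0, 0))
  expect_error(compute_mdt(flatzero), class = "dk_undefined_statistic_error")
})

test_that("DE and MDT satisfy the Abel-summation consistency identity", {
  # for any monotone profile from (0,0): DE = y(T) * (1 - MDT_min / T)
  set.seed(101)
  for (i in 1:200) {
    p <- random_monotone_profile()
    T_ <- max(p$times)
    yT <- p$release[length(p$release)]
    de <- compute_de(p, T_)
    mdt_min <- compute_mdt(p) * 60
    expect_equal(de, yT * (1 - mdt_min / T_) / 100 * 100,
                 tolerance = 1e-11)
    # and both agree with the loop oracles
    expect_equal(de, 100 * trapz_oracle(p$times, p$release) / (100 * T_),
                 tolerance = 1e-12)
    expect_equal(mdt_min, mdt_oracle_min(p$times, p$release),
                 tolerance = 1e-12)
  }
})

test_that("DE is monotone under pointwise dominance and MDT stays in range", {
  set.seed(55)
  for (i in 1:30) {
    p <- random_monotone_profile()
    q <- p
    q$release <- pmin(100, q$release * runif(1, 1, 1.3))  # dominates p
    T_ <- max(p$times)
    expect_gte(compute_de(q, T_), compute_de(p, T_))
    mdt_min <- compute_mdt(p) * 60
    mids <- (p$times[-1] + p$times[-length(p$times)]) / 2
    expect_gte(mdt_min, min(mids))
    expect_lte(mdt_min, max(mids))
  }
})

test_that("f2 point selection excludes t=0 and truncates past 85%", {
  grid <- default_grid()
  slow <- dissolution_profile(grid, pmin(80, grid / 10))
  sel <- select_f2_points(slow, slow)
  expect_equal(sel$n_used, length(grid) - 1)  # only t=0 excluded
  expect_equal(sel$n_dropped, 0)

  fast <- dissolution_profile(grid, pmin(100, grid / 3))
  # both curves reach 85% at t = 255; the first such shared point is kept
  sel2 <- select_f2_points(fast, fast)
  expect_equal(max(sel2$times), 270)
  expect_true(all(sel2$times > 0))
  expect_equal(sel2$n_used + sel2$n_dropped, length(grid) - 1)

  a <- dissolution_profile(c(0, 60), c(0, 10))
  b <- dissolution_profile(c(0, 90), c(0, 10))
  expect_error(select_f2_points(a, b), class = "dk_insufficient_points_error")
})

test_that("f2 closed forms: identity, uniform 10% gap, exact-50 boundary", {
  grid <- default_grid()
  base <- dissolution_profile(grid, pmin(70, grid / 12))
  expect_equal(compute_f2(base, base)$f2, 100)
  expect_equal(as.character(compute_f2(base, base)$verdict), "similar")

  shift10 <- base; shift10$release <- base$release + 10
  r <- compute_f2(base, shift10)
  expect_equal(r$f2, 50 * log10(100 / sqrt(101)), tolerance = 1e-12)
  expect_equal(as.character(r$verdict), "dissimilar")

  shift99 <- base; shift99$release <- base$release + sqrt(99)
  r99 <- compute_f2(base, shift99)
  expect_equal(r99$f2, 50, tolerance = 1e-9)
  expect_equal(as.character(r99$verdict), "similar")
})

test_that("f2 is symmetric, agrees with the direct oracle, and decreases with offset", {
  set.seed(202)
  grid <- default_grid()
  for (i in 1:25) {
    r <- pmin(80, cumsum(runif(length(grid), 0, 4))); r[1] <- 0
    s <- pmin(80, r + runif(length(grid), -8, 8)); s[1] <- 0
    s <- pmax(0, s)
    pr <- dissolution_profile(grid, r)
    ps <- dissolution_profile(grid, s)
    expect_equal(compute_f2(pr, ps)$f2, compute_f2(ps, pr)$f2)
    expect_equal(compute_f2(pr, ps)$f2, f2_oracle(r[-1], s[-1]),
                 tolerance = 1e-12)
  }
  base <- dissolution_profile(grid, pmin(60, grid / 15))
  f2s <- sapply(c(2, 5, 10, 20), function(d) {
    q <- base; q$release <- base$release + d
    compute_f2(base, q)$f2
  })
  expect_true(all(diff(f2s) < 0))
  expect_true(all(f2s <= 100))
})

test_that("similarity verdict uses the inclusive [50, 100] band", {
  expect_equal(as.character(classify_similarity(76.3)), "similar")
  expect_equal(as.character(classify_similarity(45.5)), "dissimilar")
  expect_equal(as.character(classify_similarity(50.0)), "similar")
  expect_equal(as.character(classify_similarity(100)), "similar")
  expect_true(attr(classify_similarity(95), "near_identical"))
  expect_false(attr(classify_similarity(80), "near_identical"))
})
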