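test_that("grid construction satisfies the spacing identities", {
  g <- build_grid(Lx = 1, N = 3)
  expect_equal(g$hx, 1)
  expect_equal(g$x, c(-1, 0, 1))
  g2 <- build_grid(Lx = 5, N = 2)
  expect_equal(g2$hx, 10)
  for (N in c(3, 7, 51, 200)) {
    g <- build_grid(Lx = 2.5, N = N)
    expect_equal(g$x[1], -2.5)
    expect_equal(g$x[N], 2.5)
    expect_equal(g$hx * (N - 1), 2 * 2.5)
    expect_true(all(diff(g$x) > 0))
  }
  # odd N puts the center node exactly at 0
  g <- build_grid(3, 31)
  expect_equal(g$x[(31 + 1) %/% 2], 0)
  expect_error(build_grid(0, 5), "Lx")
  expect_error(build_grid(1, 1), "N")
})

test_that("interaction operator matches single-source and uniform oracles", {
  g <- build_grid(Lx = 12, N = 121)
  # single nonzero node: one-term quadrature
  rates <- numeric(g$N); m0 <- 40; rates[m0] <- 0.8
  out <- interaction(rates, g)
  expect_equal(out, g$hx * connectivity_kernel(g$x - g$x[m0]) * 0.8,
               tolerance = 1e-14)
  # uniform rate on a wide grid: interior approaches s * integral of kernel
  s <- 0.6
  out_u <- interaction(rep(s, g$N), g)
  interior <- out_u[(g$N %/% 2 - 5):(g$N %/% 2 + 5)]
  expect_equal(interior, rep(s * sqrt(pi) / 2, 11), tolerance = 1e-3)
  # mirror symmetry
  set.seed(3)
  r <- runif(g$N)
  sym <- (r + rev(r)) / 2
  expect_equal(interaction(sym, g), rev(interaction(sym, g)),
               tolerance = 1e-13)
})

test_that("interaction is linear and agrees with a brute-force double loop", {
  g <- build_grid(Lx = 2, N = 11)
  set.seed(5)
  r1 <- runif(11); r2 <- runif(11)
  expect_equal(interaction(0.3 * r1 + 1.7 * r2, g),
               0.3 * interaction(r1, g) + 1.7 * interaction(r2, g),
               tolerance = 1e-12)
  brute <- vapply(1:11, function(j)
    sum(vapply(1:11, function(m)
      g$hx * 0.5 * exp(-(g$x[j] - g$x[m])^2) * r1[m], numeric(1))),
    numeric(1))
  expect_equal(interaction(r1, g), brute, tolerance = 1e-12)
  expect_error(interaction(runif(7), g), "length")
})

test_that("laplacian is exact for low-order polynomials and conserves mass", {
  g <- build_grid(Lx = 4, N = 41)
  expect_equal(laplacian(rep(2.2, g$N), g), numeric(g$N))
  lin <- 0.7 * g$x
  expect_equal(laplacian(lin, g)[2:40], numeric(39), tolerance = 1e-12)
  quad <- g$x^2
  expect_equal(laplacian(quad, g)[2:40], rep(2, 39), tolerance = 1e-10)
  # Neumann closure conserves total content for arbitrary profiles
  set.seed(9)
  for (i in 1:10) {
    k <- runif(g$N, 0, 3)
    expect_lt(abs(sum(laplacian(k, g))) / max(abs(k)), 1e-10)
  }
  # quadratic profile: boundary rows are one-sided, interior exact
  expect_equal(laplacian(g$x^2, g)[2:40], rep(2, 39), tolerance = 1e-10)
  expect_error(laplacian(1:2, build_grid(1, 2)), "3 nodes")
})

test_that("stimulus is a windowed centered Gaussian bump", {
  g <- build_grid(10, 101)
  p <- stimulus_params(amplitude = 2, center = 0, width = 1.5,
                       onset = 1, duration = 0.5)
  expect_equal(stimulus_profile(g, 0.99, p), numeric(101))
  expect_equal(stimulus_profile(g, 1.5001, p), numeric(101))
  inside <- stimulus_profile(g, 1.2, p)
  expect_equal(max(inside), 2)                    # peak at the center node
  expect_equal(inside[which.max(inside)], inside[(101 + 1) %/% 2])
  expect_equal(inside, rev(inside))               # mirror symmetric
  expect_true(all(inside >= 0))
})

test_that("rhs vanishes at a constructed uniform fixed point", {
  # all couplings, production and diffusion off: v = gv(k) is stationary
  k0 <- 0.5
  cfg <- reference_config()
  params <- config_params(cfg)
  params <- update_params(params, c_ee = 0, c_ei = 0, c_ie = 0, c_ii = 0,
                          c1 = 0, c2 = 0, delta = 0)
  gv0 <- potassium_drive(0, k0, params$drive$beta_ve, params$drive$kv_star)
  g <- build_grid(5, 21)
  st <- field_state(rep(gv0, 21), rep(gv0, 21), rep(k0, 21))
  d <- field_rhs(st, 0, params, g, stimulus = NULL)
  expect_equal(d$dve, numeric(21), tolerance = 1e-12)
  expect_equal(d$dvi, numeric(21), tolerance = 1e-12)
  expect_equal(d$dk, numeric(21), tolerance = 1e-12)
})

test_that("rhs of a uniform state is uniform and symmetric states stay symmetric", {
  cfg <- reference_config()
  params <- config_params(cfg)
  g <- build_grid(8, 41)
  st <- field_state(rep(-4.9, 41), rep(-4.8, 41), rep(0.6, 41))
  d <- field_rhs(st, 0, params, g)
  # translation invariance holds away from the truncated-kernel boundaries
  interior <- abs(g$x) <= g$Lx - 6
  expect_lt(diff(range(d$dve[interior])), 1e-12)
  expect_lt(diff(range(d$dvi[interior])), 1e-12)
  # mirror-symmetric state + centered stimulus -> mirror-symmetric rhs
  set.seed(13)
  ve <- runif(41); ve <- (ve + rev(ve)) / 2
  vi <- runif(41); vi <- (vi + rev(vi)) / 2
  k <- runif(41, 0, 2); k <- (k + rev(k)) / 2
  stim <- stimulus_params(amplitude = 1, center = 0, width = 2,
                          onset = 0, duration = 1)
  d <- field_rhs(field_state(ve, vi, k), 0.5, params, g, stim)
  expect_equal(d$dve, rev(d$dve), tolerance = 1e-12)
  expect_equal(d$dvi, rev(d$dvi), tolerance = 1e-12)
  expect_equal(d$dk, rev(d$dk), tolerance = 1e-12)
})

test_that("rhs agrees with a naive reference implementation on a random state", {
  cfg <- reference_config()
  params <- config_params(cfg)
  g <- build_grid(2, 11)
  set.seed(21)
  ve <- runif(11, -6, 1); vi <- runif(11, -6, 1); k <- runif(11, 0, 2)
  d <- field_rhs(field_state(ve, vi, k), 0, params, g)

  # naive double-loop reference
  cp <- params$coupling; pr <- params$production; dr <- params$drive
  se <- firing_rate(ve, k, params$transfer_e)
  si <- firing_rate(vi, k, params$transfer_i)
  Se <- Si <- numeric(11)
  for (j in 1:11) for (m in 1:11) {
    w <- g$hx * 0.5 * exp(-(g$x[j] - g$x[m])^2)
    Se[j] <- Se[j] + w * se[m]
    Si[j] <- Si[j] + w * si[m]
  }
  lap <- numeric(11)
  for (j in 2:10) lap[j] <- (k[j - 1] - 2 * k[j] + k[j + 1]) / g$hx^2
  lap[1] <- (k[2] - k[1]) / g$hx^2
  lap[11] <- (k[10] - k[11]) / g$hx^2
  gv_e <- 1 / (1 + exp(-dr$beta_ve * (k - dr$kv_star)))
  gv_i <- 1 / (1 + exp(-dr$beta_vi * (k - dr$kv_star)))
  dve <- (-ve + cp$c_ee * Se - cp$c_ei * Si + gv_e) / cp$tau
  dvi <- (-vi + cp$c_ie * Se - cp$c_ii * Si + gv_i) / cp$tau
  dk <- (cp$delta * lap +
           cp$c1 * pr$a * cosh(pr$b * (se - pr$c * params$s_star_e)) +
           cp$c2 * pr$a * cosh(pr$b * (si - pr$c * params$s_star_i))) / cp$tau

  expect_equal(d$dve, dve, tolerance = 1e-12)
  expect_equal(d$dvi, dvi, tolerance = 1e-12)
  expect_equal(d$dk, dk, tolerance = 1e-12)
})

test_that("potassium derivative respects the production floor", {
  cfg <- reference_config()
  params <- config_params(cfg)
  cp <- params$coupling; pr <- params$production
  g <- build_grid(6, 31)
  set.seed(31)
  st <- field_state(runif(31, -6, 1), runif(31, -6, 1), runif(31, 0, 2))
  d <- field_rhs(st, 0, params, g)
  # diffusion sums to ~0, so the mean dk is bounded below by the floor
  floor_rate <- (cp$c1 * pr$a + cp$c2 * pr$a) / cp$tau
  expect_gte(mean(d$dk), floor_rate * (1 - 1e-10))
})
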