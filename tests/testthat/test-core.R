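test_that("monod factor matches closed-form arithmetic and rejects bad input", {
  expect_equal(monod_factor(0, 0.25), 0)
  expect_equal(monod_factor(0.25, 0.25), 0.5)
  # default initial DOC against the DOC half-saturation constant
  expect_equal(monod_factor(61.1, 0.25), 61.1 / 61.35)
  expect_true(all(monod_factor(c(0, 1, 100, 1e6), 0.25) >= 0))
  expect_true(all(monod_factor(c(0, 1, 100, 1e6), 0.25) < 1))
  expect_error(monod_factor(-1, 0.25), "negative")
  expect_error(monod_factor(1, 0), "positive")
  expect_error(monod_factor(NaN, 1), "non-finite")
})

test_that("unregulated rates follow the dual-substrate Monod product", {
  p <- rscm_params()
  # no electron donor: both pathways off
  r <- unregulated_rates(zero_state(xNO3 = 5, xNO2 = 5), p)
  expect_equal(unname(r), c(0, 0))
  # acceptor-specific: no nitrite, pathway 2 off only
  r <- unregulated_rates(zero_state(xDOC = 10, xNO3 = 5), p)
  expect_equal(r[["r2_kin"]], 0)
  expect_gt(r[["r1_kin"]], 0)
  # default initial state: direct hand arithmetic
  r <- unregulated_rates(rscm_init(), p)
  expect_equal(r[["r1_kin"]], 6.23 * (61.1 / 61.35) * (18.3 / 18.301))
  expect_equal(r[["r2_kin"]], 0)
})

test_that("matching law allocates in proportion to returns", {
  expect_equal(unname(cybernetic_u(1, 1)), c(0.5, 0.5))
  expect_equal(unname(cybernetic_u(3, 1)), c(0.75, 0.25))
  expect_equal(unname(cybernetic_u(0, 0)), c(0, 0))
  expect_error(cybernetic_u(-1, 1), "non-negative")
  for (i in 1:25) {
    p <- runif(2, 0, 10)
    u <- cybernetic_u(p[1], p[2])
    expect_equal(sum(u), 1)
    expect_true(all(u >= 0))
  }
})

test_that("cascade synthesis rates gate on their upstream pools", {
  p <- rscm_params()
  # no resource pool: neither transcription nor translation for pathway 1
  s <- synthesis_rates(zero_state(xDOC = 10, xNO3 = 5, tau1 = 0.5), p)
  expect_equal(s[["rT1"]], 0)
  expect_equal(s[["rE1"]], 0)
  # transcript absent but resource present: transcription on, translation off
  s <- synthesis_rates(zero_state(rho1 = 0.5), p)
  expect_equal(s[["rE1"]], 0)
  expect_gt(s[["rT1"]], 0)
  # default initial state: hand arithmetic for resource synthesis
  s <- synthesis_rates(rscm_init(), p)
  expect_equal(s[["rR1"]], 2.84 * (61.1 / 61.35) * (18.3 / 18.301))
})

test_that("derivative of biomass-only state reduces to turnover terms", {
  p <- rscm_params()
  d <- rscm_rhs(zero_state(xBM = 1), p)
  expect_equal(d[["xDOC"]], 5 * p$kdeg)
  expect_equal(d[["xBM"]], -p$kdeg)
  expect_equal(d[["rho1"]], p$alphaR1)
  expect_equal(d[["rho2"]], p$alphaR2)
  others <- setdiff(names(d), c("xDOC", "xBM", "rho1", "rho2"))
  expect_equal(unname(d[others]), rep(0, length(others)))
})

test_that("derivative at the default state matches hand stoichiometry", {
  p <- rscm_params()
  st <- rscm_init()
  d <- rscm_rhs(st, p)
  r1 <- st[["e1"]] * 6.23 * (61.1 / 61.35) * (18.3 / 18.301)
  expect_equal(d[["xNO3"]], -2 * 0.56 * r1)
  expect_equal(d[["xN2"]], 0)  # no nitrite yet
})

test_that("carbon and nitrogen are conserved at the derivative level", {
  p <- rscm_params()
  set.seed(42)
  for (i in 1:1000) {
    d <- rscm_rhs(random_state(), p)
    c_sum <- d[["xDOC"]] + d[["xDIC"]] + 5 * d[["xBM"]]
    n_sum <- d[["xNO3"]] + d[["xNO2"]] + 2 * d[["xN2"]]
    scale <- max(abs(d)) + 1
    expect_lt(abs(c_sum) / scale, 1e-13)
    expect_lt(abs(n_sum) / scale, 1e-13)
  }
})

test_that("regulated rates vanish without enzyme and rates are non-negative", {
  p <- rscm_params()
  set.seed(7)
  for (i in 1:50) {
    st <- random_state()
    # without enzyme there is no catalysis, whatever the substrate levels
    st0 <- st; st0[["e1"]] <- 0; st0[["e2"]] <- 0
    dr <- derived_rates(rscm_init(xDOC = st0[["xDOC"]], xNO3 = st0[["xNO3"]],
                                  xNO2 = st0[["xNO2"]], e1 = 0, e2 = 0), p)
    expect_equal(dr[["r1"]], 0)
    expect_equal(dr[["r2"]], 0)
    dr <- derived_rates(st, p)
    expect_true(all(dr[c("r1_kin", "r2_kin", "r1", "r2",
                         "rR1", "rR2", "rT1", "rT2", "rE1", "rE2")] >= 0))
    if (dr[["r1"]] + dr[["r2"]] > 0)
      expect_equal(dr[["u1"]] + dr[["u2"]], 1)
  }
})

test_that("rates are monotone non-decreasing in their substrates", {
  p <- rscm_params()
  doc <- seq(0, 80, length.out = 40)
  r <- vapply(doc, function(x)
    unregulated_rates(zero_state(xDOC = x, xNO3 = 5), p)[["r1_kin"]],
    numeric(1))
  expect_true(all(diff(r) >= 0))
  rho <- seq(0, 2, length.out = 40)
  s <- vapply(rho, function(x)
    synthesis_rates(zero_state(rho2 = x), p)[["rT2"]], numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("instantaneous yield interpolates the pathway stoichiometric yields", {
  p <- rscm_params()
  expect_equal(instantaneous_yield(1, 0, p), (1 - p$f1) / 5)
  expect_equal(instantaneous_yield(0, 1, p), (1 - p$f2) / 5)
  expect_equal(instantaneous_yield(0, 0, p), 0)
  expect_equal(instantaneous_yield(1, 1, p), (0.088 + 0.002) / 2)
  expect_error(instantaneous_yield(-1, 0, p), "negative")
})

test_that("parameter and state validation enforce the model's domain", {
  expect_error(rscm_params(f1 = 1.2), "f1")
  expect_error(rscm_params(k1 = 0), "positive")
  expect_error(rscm_params(alphaR1 = -0.1), "non-negative")
  expect_error(rscm_init(xDOC = -1), "non-negative")
  expect_s3_class(rscm_params(f1 = 0, f2 = 1), "rscm_params")
})
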