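test_that("warmup points span the feasible range and satisfy Sv = 0", {
  sys <- chain_system()
  W <- generate_warmup(sys, sampler_config(warmup_pull = 0.33))
  expect_equal(dim(W), c(3, 6))
  expect_lt(max(abs(sys$S %*% W)), 1e-9)
  # pulled vertices still reach near both ends of the through-flux range
  expect_lt(min(W["R1", ]), 2.5)
  expect_gt(max(W["R1", ]), 7.5)
  expect_true(all(W >= matrix(sys$lb, 3, 6) - 1e-9))
  expect_true(all(W <= matrix(sys$ub, 3, 6) + 1e-9))
})

test_that("the chain polytope samples uniformly on the through-flux", {
  ss <- achr_sample(chain_system(), sampler_config(n_samples = 10000,
                                                   seed = 42))
  v <- ss$samples[, "R1"]
  # uniform(0, 10): mean 5, variance 100/12
  expect_lt(abs(mean(v) - 5), 0.15)
  expect_lt(abs(stats::var(v) - 100 / 12), 0.5)
  expect_gt(stats::ks.test(v, "punif", 0, 10)$p.value, 0.01)
  expect_samples_valid(ss, chain_system())
})

test_that("sampling is bit-reproducible for a fixed seed", {
  cfg <- sampler_config(n_samples = 500, seed = 7)
  s1 <- achr_sample(chain_system(), cfg)
  s2 <- achr_sample(chain_system(), cfg)
  expect_identical(s1$samples, s2$samples)
  s3 <- achr_sample(chain_system(), sampler_config(n_samples = 500,
                                                   seed = 8))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("fixed reactions have zero sample variance", {
  ss <- achr_sample(simplex_system(), sampler_config(n_samples = 2000,
                                                     seed = 1))
  expect_equal(stats::var(ss$samples[, "IN"]), 0)
  ss2 <- achr_sample(chain_system(), sampler_config(n_samples = 1000,
                                                    seed = 1))
  # EX_A = -R1 exactly (mass balance), so their sum is constant zero
  expect_lt(max(abs(ss2$samples[, "EX_A"] + ss2$samples[, "R1"])), 1e-9)
})

test_that("a fully fixed polytope degenerates to its unique point", {
  expect_warning(
    ss <- achr_sample(fixed_system(), sampler_config(n_samples = 50,
                                                     seed = 1)),
    "degenerate")
  expect_equal(nrow(ss$samples), 50)
  expect_equal(unname(ss$samples[1, ]), c(-4, 4, 4))
  expect_equal(max(apply(ss$samples, 2, stats::var)), 0)

  rj <- rejection_sample(fixed_system(), n = 20, seed = 1)
  expect_equal(unname(rj$samples[5, ]), c(-4, 4, 4))
})

test_that("rejection oracle reproduces analytic uniform marginals", {
  rj <- rejection_sample(chain_system(), n = 10000, seed = 11)
  expect_gt(stats::ks.test(rj$samples[, "R1"], "punif", 0, 10)$p.value,
            0.01)
  sx <- rejection_sample(simplex_system(), n = 10000, seed = 12)
  for (b in c("B1", "B2", "B3")) {
    expect_lt(abs(mean(sx$samples[, b]) - 10 / 3), 0.15)
  }
})

test_that("rejection sampling guards its free-dimension budget", {
  sys <- build_stoichiometric_system(build_toy_wine_network())
  expect_error(rejection_sample(sys, n = 10, seed = 1),
               "free dimensions")
})

test_that("ACHR matches the rejection oracle on a 2-free-dimension polytope", {
  n <- 10000
  a <- achr_sample(simplex_system(), sampler_config(n_samples = n,
                                                    seed = 5))
  r <- rejection_sample(simplex_system(), n = n, seed = 6)
  for (b in c("B1", "B2", "B3")) {
    va <- a$samples[, b]; vr <- r$samples[, b]
    # 5 Monte-Carlo standard errors on the mean and the variance
    se_mean <- sqrt(stats::var(vr) / n)
    expect_lt(abs(mean(va) - mean(vr)), 5 * se_mean)
    se_var <- sqrt(stats::var((vr - mean(vr))^2) / n)
    expect_lt(abs(stats::var(va) - stats::var(vr)), 5 * se_var)
  }
  # exchangeable branches: symmetric means
  expect_lt(diff(range(colMeans(a$samples[, c("B1", "B2", "B3")]))), 0.3)
})

test_that("sample validity reporting counts violations and empties", {
  sys <- chain_system()
  ss <- achr_sample(sys, sampler_config(n_samples = 200, seed = 3))
  rep0 <- check_sample_validity(ss, sys)
  expect_equal(rep0$n_bound_violations, 0L)
  expect_false(rep0$empty)

  tampered <- ss
  tampered$samples[7, "R1"] <- 12  # above the upper bound
  rep1 <- check_sample_validity(tampered, sys)
  expect_equal(rep1$n_bound_violations, 1L)

  empty <- ss
  empty$samples <- ss$samples[0, , drop = FALSE]
  rep2 <- check_sample_validity(empty, sys)
  expect_true(rep2$empty)
  expect_equal(rep2$n_bound_violations, 0L)

  wrong <- ss
  colnames(wrong$samples) <- rev(colnames(wrong$samples))
  wrong$reaction_ids <- rev(wrong$reaction_ids)
  expect_error(check_sample_validity(wrong, sys), "disagree")
})

test_that("mean-split diagnostics flag nothing on a mixed chain", {
  ss <- achr_sample(chain_system(), sampler_config(n_samples = 5000,
                                                   seed = 13))
  d <- sampling_diagnostics(ss)
  expect_equal(nrow(d), 3)
  expect_true(all(is.finite(d$z)))
  # a well-mixed uniform chain: no gross first/second-half mean shift
  expect_lt(max(abs(d$z)), 5)

  # fixed reactions report exactly zero
  sfix <- achr_sample(simplex_system(), sampler_config(n_samples = 500,
                                                       seed = 14))
  dfix <- sampling_diagnostics(sfix)
  expect_equal(dfix$z[dfix$reaction_id == "IN"], 0)

  tiny <- sfix
  tiny$samples <- tiny$samples[1:3, , drop = FALSE]
  expect_error(sampling_diagnostics(tiny), "at least 4")
})

test_that("tidy() flattens a sample set to a long tibble", {
  ss <- achr_sample(chain_system(), sampler_config(n_samples = 20,
                                                   seed = 2),
                    strain = "s1", time_h = 24)
  td <- tidy(ss)
  expect_equal(nrow(td), 20 * 3)
  expect_setequal(unique(td$reaction_id), c("EX_A", "R1", "EX_B"))
  expect_equal(unique(td$strain), "s1")
})
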