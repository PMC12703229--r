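test_that("Dirichlet measure draws have the right marginals", {
  # m = 1 is the degenerate point mass
  one <- by_baseline_measure(1)
  set.seed(1)
  expect_equal(sample_dirichlet_measure(one, 0.5)$mass, 1)

  # symmetric Dirichlet(1, 1): first coordinate is Beta(1, 1) = uniform
  base <- binned_measure(c(0.5, 0.5))
  set.seed(2)
  first <- replicate(5000, sample_dirichlet_measure(base, 2)$mass[1])
  ks <- suppressWarnings(ks.test(first, "punif"))
  expect_gt(ks$p.value, 0.01)

  # huge mass concentrates the draw at the baseline (E[nu] = nu0)
  nu0 <- by_baseline_measure(50)
  set.seed(3)
  l1 <- replicate(50, sum(abs(sample_dirichlet_measure(nu0, 1e6)$mass -
                                nu0$mass)))
  expect_lt(max(l1), 0.01)

  expect_error(sample_dirichlet_measure(nu0, 0), "positive")
  expect_error(sample_dirichlet_measure(nu0, -1), "positive")
})

test_that("degenerate families pin the prior predictive", {
  ones <- pvalue_family(rep(1, 8))
  fit1 <- dpmtp(ones, n_draws = 50, seed = 4)
  expect_true(all(fit1$R_draws == 0L))
  expect_true(all(fit1$sig_prob == 0))

  zeros <- pvalue_family(rep(0, 8))
  fit0 <- dpmtp(zeros, n_draws = 50, seed = 4)
  expect_true(all(fit0$R_draws == 8L))
  expect_true(all(fit0$sig_prob == 1))
})

test_that("a near-degenerate DP reproduces the BY decision", {
  fam <- simulate_pvalues(200, pi0 = 0.7, effect = 3, rho = 0.3, seed = 6)
  fit <- dpmtp(fam, n_draws = 200, mass = 1e6, seed = 7)
  expect_gte(mean(fit$R_draws == mtp(fam, "by")$R), 0.95)
})

test_that("significance probabilities are rank-monotone and vanish above alpha", {
  fam <- simulate_pvalues(150, pi0 = 0.6, effect = 2.5, rho = 0.5, seed = 8)
  fit <- dpmtp(fam, n_draws = 300, seed = 9)

  by_rank <- fit$sig_prob[fam$order]
  expect_true(!is.unsorted(rev(by_rank)))          # non-increasing in rank
  expect_true(all(fit$sig_prob[fam$values > fit$alpha] == 0))

  # sig_prob of the rank-r hypothesis is the proportion of draws with R >= r
  r_probe <- c(1L, 10L, 75L, 150L)
  for (r in r_probe) {
    expect_equal(by_rank[r], mean(fit$R_draws >= r))
  }
  expect_equal(fit$mean_R, mean(fit$R_draws))
})

test_that("dpmtp is reproducible and validates its inputs", {
  fam <- simulate_pvalues(60, pi0 = 0.5, effect = 2, seed = 10)
  a <- dpmtp(fam, n_draws = 100, seed = 11)
  b <- dpmtp(fam, n_draws = 100, seed = 11)
  expect_identical(a$R_draws, b$R_draws)
  expect_identical(a$M_draws, b$M_draws)
  expect_identical(a$sig_prob, b$sig_prob)

  expect_error(dpmtp(fam, alpha = 1.2), "alpha")
  expect_error(dpmtp(fam, n_draws = 0), "n_draws")
  expect_error(dpmtp(fam, mass = -2), "positive")
  expect_error(dpmtp(fam, mass = "gaussian"), "mass")
  expect_error(dpmtp(fam, baseline = by_baseline_measure(10)), "bins")
})

test_that("per-hypothesis table and histogram export are consistent", {
  fam <- simulate_pvalues(40, pi0 = 0.5, effect = 3, seed = 12)
  fit <- dpmtp(fam, n_draws = 100, seed = 13)
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 40L)
  expect_equal(df$p, fam$values)
  expect_equal(sort(df$rank), 1:40)
  expect_equal(df$sig_prob, fit$sig_prob)

  h <- dpmtp_histogram(fit)
  expect_equal(sum(h$count), 100L)
  expect_true(all(h$upper > h$lower))
})

test_that("expected cluster count matches closed form, bounds and the CRP", {
  expect_equal(expected_clusters(0.7, 1), 1)
  expect_equal(expected_clusters(1, 3), 11 / 6)
  # at M = 1 the sum telescopes to the harmonic number
  for (m in c(5, 50, 500)) {
    expect_equal(expected_clusters(1, m), sum(1 / seq_len(m)))
  }
  for (M in c(0.1, 1, 20)) {
    ec <- expected_clusters(M, 100)
    expect_gte(ec, max(1, M * log((M + 100) / M)) - 1e-12)
    expect_lte(ec, 1 + M * log((M + 101) / M) + 1e-12)
  }

  set.seed(14)
  sims <- replicate(10000, crp_clusters(5, 100))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected_clusters(5, 100)), 4 * se)

  expect_error(expected_clusters(0, 10), "positive")
})

test_that("a single random DP draw yields a valid rejection decision", {
  fam <- simulate_pvalues(80, pi0 = 0.7, effect = 3, seed = 15)
  dec <- dp_mtp_decision(fam, seed = 16)
  expect_s3_class(dec, "mtp_decision")
  expect_equal(sum(dec$rejected), dec$R)
  # rejected set is the R smallest p-values
  if (dec$R > 0) {
    expect_true(max(fam$values[dec$rejected]) <=
                  min(fam$values[!dec$rejected]))
  }
})
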