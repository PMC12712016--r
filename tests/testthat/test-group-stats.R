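test_that("pearson matches the closed-form oracle on random vectors", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    got <- pearson_cor(x, y)
    ref <- pearson_oracle(x, y)
    expect_equal(got$r, ref$r, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
    expect_equal(got$n, n)
  }
})

test_that("pearson edge behavior: identity and degenerate inputs", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  got <- pearson_cor(x, x)
  expect_equal(got$r, 1)
  expect_lt(got$p, 1e-10)
  expect_error(pearson_cor(x, rep(2, 4)), class = "cpnquant_value_error")
  expect_error(pearson_cor(x[1:2], x[1:2] + 1), class = "cpnquant_value_error")
  expect_error(pearson_cor(x, x[1:3]), class = "cpnquant_value_error")
})

test_that("BH adjustment matches the step-up oracle on all permutations", {
  set.seed(9)
  p5 <- round(runif(5), 3)
  perms <- asplit(rbind(expand.grid(rep(list(1:5), 5))), 1)
  perms <- Filter(function(ix) length(unique(ix)) == 5, perms)
  expect_length(perms, 120)
  for (ix in perms) {
    p <- p5[unlist(ix)]
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-15)
  }
  expect_equal(bh_adjust(0.01), 0.01)             # single test unchanged
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.2, 1.4)), class = "cpnquant_value_error")
  # order of the raw p-values is preserved in the adjusted vector
  p <- c(0.04, 0.001, 0.7, 0.02)
  expect_equal(order(bh_adjust(p)), order(bh_oracle(p)))
})

test_that("NB regression: symmetry, label exchange, and input checks", {
  set.seed(21)
  tot <- rep(1000L, 8)
  cnt <- c(rpois(4, 100), rpois(4, 100))
  # two groups drawn from the same law, then literally identical data
  g <- rep(c("A", "B"), each = 4)
  same <- nb_rate_regression(rep(cnt[1:4], 2), tot, g)
  expect_equal(unname(same$rate_ratios["B_vs_A"]), 1, tolerance = 1e-9)

  cnt2 <- c(rpois(4, 120), rpois(4, 60))
  f1 <- nb_rate_regression(cnt2, tot, factor(g, levels = c("A", "B")))
  f2 <- nb_rate_regression(cnt2, tot, factor(g, levels = c("B", "A")))
  expect_equal(unname(f1$rate_ratios["B_vs_A"] * f2$rate_ratios["A_vs_B"]), 1,
               tolerance = 1e-9)

  expect_error(nb_rate_regression(cnt2, rep(0L, 8), g),
               class = "cpnquant_value_error")
  expect_error(nb_rate_regression(cnt2[1:5], tot[1:5], c("A", "A", "A", "A", "B")),
               class = "cpnquant_value_error")
})

test_that("the NB2 family collapses to Poisson as dispersion vanishes", {
  set.seed(5)
  tot <- as.integer(round(runif(12, 500, 5000)))
  g <- rep(c("A", "B", "C"), each = 4)
  cnt <- rpois(12, tot * c(0.1, 0.05, 0.08)[as.integer(factor(g))])
  f_nb <- nb_rate_regression(cnt, tot, g, dispersion = 1e-10)
  f_po <- nb_rate_regression(cnt, tot, g, dispersion = 0)
  expect_equal(f_nb$rate_ratios, f_po$rate_ratios, tolerance = 1e-6)
  expect_equal(f_po$dispersion, 0)
})

test_that("fitted NB log-likelihood agrees with the density-based oracle", {
  fix <- load_table2_fixture()
  sub <- fix[fix$region %in% c("prefrontal", "premotor", "parietal"), ]
  fit <- nb_rate_regression(sub$contra, sub$total, sub$region)
  mu <- fitted(fit$model)
  expect_equal(as.numeric(stats::logLik(fit$model)),
               nb2_loglik(sub$contra, mu, fit$theta), tolerance = 1e-6)
})

test_that("a designed rate ratio of 0.5 is recovered across replicates", {
  set.seed(31)
  n_rep <- 200
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    tot <- as.integer(round(runif(24, 2000, 30000)))
    g <- rep(c("ref", "half"), each = 12)
    mu <- tot * ifelse(g == "ref", 0.10, 0.05)
    cnt <- rnbinom(24, mu = mu, size = 1 / 0.3)
    est[r] <- nb_rate_regression(cnt, tot, factor(g, levels = c("ref", "half")))$
      rate_ratios[["half_vs_ref"]]
  }
  expect_gt(median(est), 0.45)
  expect_lt(median(est), 0.55)
})

test_that("region summaries reproduce the published group means", {
  fix <- load_table2_fixture()
  prem <- region_summary(fix, "premotor")
  expect_equal(prem$n_cases, 10)
  expect_equal(round_half_up(prem$mean_pct_cpn, 0), 14)
  par <- region_summary(fix, "parietal", exclude_areas = "PF")
  expect_equal(par$n_cases, 10)
  expect_equal(round_half_up(par$mean_pct_cpn, 0), 9)
  expect_true(par$min_pct_cpn <= par$mean_pct_cpn &
                par$mean_pct_cpn <= par$max_pct_cpn)
  one <- region_summary(fix[fix$case_id == "30FB", ], "prefrontal")
  expect_equal(one$mean_pct_cpn, one$min_pct_cpn)
  expect_equal(one$mean_pct_cpn, one$max_pct_cpn)
  expect_error(region_summary(fix, "cerebellar"), class = "cpnquant_value_error")
})
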