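test_that("percentage agreement is the diagonal share, high only above 70", {
  expect_equal(as.numeric(percent_agreement(matrix(c(1, 0, 1, 1), 2))),
               100 * 2/3, tolerance = 1e-12)
  d <- diag(c(4, 5, 6))
  expect_equal(as.numeric(percent_agreement(d)), 100)
  m <- matrix(c(20, 10, 5, 15), 2)       # trace 35 of 50
  pa <- percent_agreement(m)
  expect_equal(as.numeric(pa), 70)
  expect_false(attr(pa, "high"))
  expect_true(attr(percent_agreement(matrix(c(8, 1, 1, 4), 2)), "high"))
  expect_error(percent_agreement(matrix(0, 2, 2)), "empty")
})

test_that("Cohen's kappa reproduces hand-computed values", {
  # p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  m <- matrix(c(20, 10, 5, 15), 2)
  r <- cohens_kappa(m)
  expect_equal(r$estimate, 0.4, tolerance = 1e-12)
  expect_equal(r$status, "ok")
  expect_equal(r$interpretation, "fair")
  d <- diag(c(10, 7, 3))
  expect_equal(cohens_kappa(d)$estimate, 1.0)
})

test_that("kappa SE, null SE and p match the large-sample reference", {
  # reference values computed independently with the Fleiss-Cohen-Everitt
  # variance formulas (statsmodels implementation) for this 3x3 table
  m <- matrix(c(20, 5, 3, 4, 15, 6, 2, 3, 12), 3, byrow = TRUE)
  r <- cohens_kappa(m)
  expect_equal(r$estimate, 0.5030864197530863, tolerance = 1e-12)
  expect_equal(r$se, 0.08419018148519773, tolerance = 1e-9)
  rw <- weighted_kappa(m)
  expect_equal(rw$estimate, 0.540983606557377, tolerance = 1e-12)
  expect_equal(rw$se, 0.08497220999520338, tolerance = 1e-9)
  r2 <- cohens_kappa(matrix(c(20, 5, 10, 15), 2, byrow = TRUE))
  # one-sided p from the null SE 0.138564... at kappa = 0.4
  expect_equal(r2$p_value, stats::pnorm(0.4 / 0.13856406460551018,
                                        lower.tail = FALSE),
               tolerance = 1e-9)
  # CI is Wald, truncated into [-1, 1]
  expect_equal(r$ci_low, r$estimate - 1.96 * r$se)
  expect_lte(cohens_kappa(diag(c(1, 1)) * 5 + 0)$ci_high, 1)
})

test_that("constant one- or two-sided ratings yield typed degeneracy", {
  one <- matrix(c(30, 0, 5, 0), 2)       # side B all first category
  r <- cohens_kappa(one)
  expect_equal(r$status, "undefined_constant_one_side")
  expect_true(is.na(r$estimate))
  expect_equal(as.numeric(percent_agreement(one)), 100 * 30 / 35)

  both <- matrix(c(12, 0, 0, 0), 2)
  expect_equal(cohens_kappa(both)$status,
               "undefined_constant_both_sides")
  expect_equal(weighted_kappa(both)$status,
               "undefined_constant_both_sides")
  expect_equal(as.numeric(percent_agreement(both)), 100)
})

test_that("kappa and weighted kappa match brute-force oracles", {
  set.seed(20240501)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    m <- random_table_nondeg(k, sample(10:50, 1))
    expect_equal(cohens_kappa(m)$estimate, oracle_kappa(m),
                 tolerance = 1e-12)
    expect_equal(weighted_kappa(m)$estimate,
                 oracle_kappa(m, weighted = TRUE), tolerance = 1e-12)
  }
})

test_that("linear weights reduce to unweighted kappa on any 2x2 table", {
  set.seed(7)
  for (rep in 1:50) {
    m <- random_table_nondeg(2, sample(5:60, 1))
    expect_equal(weighted_kappa(m)$estimate, cohens_kappa(m)$estimate,
                 tolerance = 1e-14)
    expect_equal(weighted_kappa(m)$se, cohens_kappa(m)$se,
                 tolerance = 1e-14)
  }
  expect_equal(weighted_kappa(diag(c(5, 5)) + 0)$estimate, 1)
})

test_that("kappa statistics are symmetric in the two sides", {
  set.seed(8)
  for (rep in 1:25) {
    m <- random_table_nondeg(3, 40)
    expect_equal(cohens_kappa(t(m))$estimate, cohens_kappa(m)$estimate,
                 tolerance = 1e-12)
    expect_equal(weighted_kappa(t(m))$estimate,
                 weighted_kappa(m)$estimate, tolerance = 1e-12)
    expect_equal(as.numeric(percent_agreement(t(m))),
                 as.numeric(percent_agreement(m)))
  }
})

test_that("a hand-checked near-diagonal ordinal table matches its oracle", {
  m <- matrix(c(10, 2, 0, 2, 10, 2, 0, 2, 10), 3, byrow = TRUE)
  expect_equal(weighted_kappa(m)$estimate, oracle_kappa(m, TRUE),
               tolerance = 1e-14)
  expect_gt(weighted_kappa(m)$estimate, cohens_kappa(m)$estimate)
})

test_that("ICC definitions behave definitionally and match references", {
  x <- c(0.2, 0.5, 0.7, 0.9, 0.4, 0.65)
  dup <- cbind(x, x)
  expect_equal(icc(dup, "consistency")$estimate, 1.0)
  shifted <- cbind(x, x + 0.2)
  expect_equal(icc(shifted, "consistency")$estimate, 1.0)
  expect_lt(icc(shifted, "agreement")$estimate, 1.0)

  # 10x2 fixture with reference values from an independent two-way
  # random-effects implementation (pingouin ICC(C,1)/ICC(A,1))
  a <- c(1.0061378682077773, 0.3166502453028727, 0.7627148270088668,
         0.6148345590808105, 0.6321026061834331, 0.667660425536535,
         0.3970020806279123, 0.6652101433533716, 0.5702180385587587,
         1.1984499274967324)
  b <- c(1.074200797266011, 0.33843978175554507, 0.7902118335567588,
         0.6113908513920946, 0.5976905620870234, 0.6863963473577627,
         0.4855577117084552, 0.6961258548275023, 0.6968387347955399,
         1.232465757171406)
  rc <- icc(cbind(a, b), "consistency")
  ra <- icc(cbind(a, b), "agreement")
  expect_equal(rc$estimate, 0.984554, tolerance = 1e-5)
  expect_equal(ra$estimate, 0.975886, tolerance = 1e-5)
  expect_equal(round(c(rc$ci_low, rc$ci_high), 2), c(0.94, 1.00))
  expect_equal(round(c(ra$ci_low, ra$ci_high), 2), c(0.84, 0.99))
  expect_equal(ra$p_value, 2.025238e-08, tolerance = 1e-3)
})

test_that("ICC matches an explicit ANOVA mean-squares oracle", {
  set.seed(321)
  for (rep in 1:100) {
    n <- sample(5:20, 1)
    x <- matrix(stats::rnorm(n * 2, 0.7, 0.2), n, 2) +
      stats::rnorm(n, 0, 0.25)          # unit effect
    expect_equal(icc(x, "consistency")$estimate,
                 oracle_icc(x, "consistency"), tolerance = 1e-10)
    expect_equal(icc(x, "agreement")$estimate,
                 oracle_icc(x, "agreement"), tolerance = 1e-10)
  }
})

test_that("ICC handles degenerate and incomplete input", {
  flat <- cbind(rep(0.5, 6), rep(0.7, 6))   # zero between-row variance
  expect_equal(icc(flat)$status, "undefined")
  x <- matrix(stats::rnorm(20), 10, 2)
  x[3, 2] <- NA
  r <- icc(x)
  expect_equal(r$n, 9L)
  expect_equal(attr(r, "n_dropped"), 1L)
  expect_error(icc(x[1:2, 1, drop = FALSE]), "at least 2 raters")
})

test_that("Landis-Koch bands reproduce the printed interpretation scale", {
  expect_equal(interpret_landis_koch(-0.1), "poor")
  expect_equal(interpret_landis_koch(0.0), "slight")
  expect_equal(interpret_landis_koch(0.20), "slight")
  expect_equal(interpret_landis_koch(0.21), "fair")
  expect_equal(interpret_landis_koch(0.40), "fair")
  expect_equal(interpret_landis_koch(0.41), "moderate")
  expect_equal(interpret_landis_koch(0.55), "moderate")
  expect_equal(interpret_landis_koch(0.60), "moderate")
  expect_equal(interpret_landis_koch(0.61), "substantial")
  expect_equal(interpret_landis_koch(0.80), "substantial")
  expect_equal(interpret_landis_koch(0.81), "almost_perfect")
  expect_equal(interpret_landis_koch(1.0), "almost_perfect")
  # gap values round to two decimals before banding
  expect_equal(interpret_landis_koch(0.205), "slight")
  expect_equal(interpret_landis_koch(0.404), "fair")
  expect_error(interpret_landis_koch(1.2), "exceed 1")
})
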