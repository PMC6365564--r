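test_that("alcohol derivation sums grams times frequency over beverages", {
  expect_equal(derive_alcohol(NULL), 0)
  expect_equal(derive_alcohol(data.frame(grams = numeric(0), freq = numeric(0))), 0)
  expect_equal(derive_alcohol(data.frame(grams = 10, freq = 4)), 40)
  expect_equal(derive_alcohol(data.frame(grams = c(10, 20), freq = c(4, 2))), 80)
  expect_error(derive_alcohol(data.frame(grams = -1, freq = 2)), "nonnegative")
})

test_that("smoking exposure is years times cigarettes per day", {
  expect_equal(derive_pack_years(0, 20), 0)
  expect_equal(derive_pack_years(10, 0), 0)
  expect_equal(derive_pack_years(2, 5), 10)
  expect_equal(cigyears_to_packs(derive_pack_years(2, 20)), 2)
  expect_error(derive_pack_years(-1, 5), ">= 0")
})

test_that("social integration index sums marital, close-ties and membership domains", {
  expect_equal(derive_social_index(FALSE, 0, 0, 0, 0), 0)
  expect_equal(derive_social_index(TRUE, 3, 2, 4, 2), 13)
  expect_equal(derive_social_index(TRUE, 0, 0, 0, 0), 2)
  expect_error(derive_social_index(TRUE, -1, 0, 0, 0), ">= 0")
})

test_that("MET totals multiply activity value by hours, capped at four per type", {
  expect_equal(derive_met(NULL), 0)
  expect_equal(derive_met(data.frame(met = 6, hours = 3)), 18)
  five_sport <- data.frame(met = rep(6, 5), hours = 1, type = "sport")
  expect_error(derive_met(five_sport), "four")
  expect_error(derive_met(data.frame(met = -1, hours = 1)), "nonnegative")
})

test_that("z-transform standardizes with the n-1 denominator", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  z <- z_transform(rnorm(50))
  expect_equal(z_transform(z), z, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(z_transform(c(5, 5, 5)), "constant")
  expect_error(z_transform(3), "two values")
})

test_that("combined score matches the hand-computed min-shift example", {
  z <- data.frame(ACT = c(-1, 0, 1), ALC = c(1, 0, -1))
  rs <- combine_risk_score(z, pair_spec(c("ACT", "ALC")))
  expect_equal(rs$score, c(2, 0, -2))
  # protective contributions <= 0, risk contributions >= 0
  expect_true(all(rs$contributions[, "ACT"] <= 0))
  expect_true(all(rs$contributions[, "ALC"] >= 0))
})

test_that("score is zero at joint sample minima and monotone in risk variables", {
  set.seed(41)
  n <- 40
  z <- data.frame(ACT = z_transform(rnorm(n)), ALC = z_transform(rnorm(n)),
                  SOC = z_transform(rnorm(n)), SMO = z_transform(rnorm(n)))
  rs <- combine_risk_score(z)
  # a participant sitting at the sample minimum of every variable scores 0:
  # both shifted contributions vanish there
  z0 <- z
  z0[1, ] <- vapply(z, min, numeric(1))
  rs0 <- combine_risk_score(z0)
  expect_equal(rs0$score[1], 0, tolerance = 1e-12)
  # increasing any risk z strictly increases the score (others fixed)
  for (v in c("ALC", "SMO")) {
    zz <- z
    zz[[v]][5] <- zz[[v]][5] + 0.5
    expect_gt(combine_risk_score(zz)$score[5], rs$score[5])
  }
  # increasing a protective z never increases the score
  for (v in c("ACT", "SOC")) {
    zz <- z
    zz[[v]][5] <- zz[[v]][5] + 0.5
    expect_lt(combine_risk_score(zz)$score[5], rs$score[5])
  }
})

test_that("combined score decomposes over sub-model partitions", {
  set.seed(17)
  z <- data.frame(ACT = z_transform(rnorm(30)), ALC = z_transform(rnorm(30)),
                  SOC = z_transform(rnorm(30)), SMO = z_transform(rnorm(30)))
  full <- combine_risk_score(z)$score
  part1 <- combine_risk_score(z, pair_spec(c("ACT", "ALC")))$score
  part2 <- combine_risk_score(z, pair_spec(c("SOC", "SMO")))$score
  expect_equal(full, part1 + part2, tolerance = 1e-12)
})

test_that("combined score is invariant to affine rescaling of a raw variable", {
  set.seed(23)
  raw <- data.frame(a = rgamma(40, 2), b = rgamma(40, 2),
                    c = rgamma(40, 2), d = rgamma(40, 2))
  z1 <- data.frame(ACT = z_transform(raw$a), ALC = z_transform(raw$b),
                   SOC = z_transform(raw$c), SMO = z_transform(raw$d))
  z2 <- data.frame(ACT = z_transform(raw$a * 7 + 3), ALC = z_transform(raw$b),
                   SOC = z_transform(raw$c), SMO = z_transform(raw$d / 10 - 2))
  expect_equal(combine_risk_score(z1)$score, combine_risk_score(z2)$score,
               tolerance = 1e-10)
})

test_that("single-pass SD rule flags extreme scores only", {
  expect_equal(exclude_outliers(rep(1, 10)), rep(FALSE, 10))
  scores <- c(rep(0, 99), 10)
  expect_equal(which(exclude_outliers(scores)), 100L)
  expect_false(any(exclude_outliers(scores, k = Inf)))
})

test_that("model family enumerates 13 specs with the pair constraint", {
  fam <- enumerate_models()
  labels <- vapply(fam, `[[`, character(1), "label")
  sizes <- vapply(fam, function(m) length(m$included), integer(1))
  expect_length(fam, 13L)
  expect_equal(anyDuplicated(labels), 0L)
  expect_equal(sum(sizes %in% c(2L, 3L)), 8L)  # reduced multi-variable models
  expect_equal(sum(sizes == 4L), 1L)
  expect_equal(sum(sizes == 1L), 4L)
  pairs <- fam[sizes == 2L]
  for (m in pairs) {
    expect_length(intersect(m$included, c("ACT", "SOC")), 1L)
    expect_length(intersect(m$included, c("ALC", "SMO")), 1L)
  }
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("sensitivity residualization returns OLS residuals on the other three", {
  set.seed(5)
  n <- 200
  # mutually uncorrelated -> residuals ~ centered originals
  d <- data.frame(alcohol_g = rnorm(n), pack_years = rnorm(n),
                  social_index = rnorm(n), met_total = rnorm(n))
  res <- sensitivity_residualize(d)
  for (v in names(d)) {
    expect_equal(mean(res[[v]]), 0, tolerance = 1e-10)
    expect_gt(cor(res[[v]], d[[v]] - mean(d[[v]])), 0.97)
    # residual orthogonal to the other three predictors
    others <- setdiff(names(d), v)
    fit <- lm(res[[v]] ~ ., data = d[others])
    expect_true(all(abs(coef(fit)[-1]) < 1e-10))
  }
  # exact linear dependence -> residuals all ~ 0
  d2 <- d
  d2$met_total <- 2 * d$alcohol_g - d$pack_years + 0.5 * d$social_index
  res2 <- sensitivity_residualize(d2)
  expect_lt(max(abs(res2$met_total)), 1e-10)
})
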