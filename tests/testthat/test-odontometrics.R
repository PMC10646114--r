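test_that("median of triplicates and the cut-off rule behave as specified", {
  expect_equal(medianDiameter(c(7.5, 7.6, 7.4)), 7.5)
  expect_equal(medianDiameter(c(7.7, 7.7, 7.7)), 7.7)
  expect_equal(medianDiameter(c(8.0, 7.0, 7.6)), 7.6)
  expect_error(medianDiameter(c(7.5, 7.6)), "three")

  expect_identical(classifyByCutoff(7.90), "male")
  expect_identical(classifyByCutoff(7.50), "female")
  # ties classify female: the rule is strictly-greater-than
  expect_identical(classifyByCutoff(7.73), "female")
  expect_error(classifyByCutoff(-1), "positive")

  # monotone: growing a diameter never flips male back to female
  d <- seq(6, 9, by = 0.01)
  cls <- classifyByCutoff(d)
  expect_true(all(diff(cls == "male") >= 0))
})

test_that("sample-specific cut-off candidates match hand arithmetic", {
  res <- sampleSpecificCutoffs(c(8, 8, 7, 7, 7, 7),
                               c("male", "male", rep("female", 4)))
  expect_equal(res$pooled_mean, 7.3333, tolerance = 1e-4)
  expect_equal(res$sex_weighted_mean, 7.5)
  expect_true(res$small_sample_warning)

  expect_error(sampleSpecificCutoffs(rep(7.5, 5), rep("female", 5)),
               "both male and female")
  big <- sampleSpecificCutoffs(rep(7.5, 40))
  expect_false(big$small_sample_warning)
})

test_that("TEM, %TEM and reliability match the classical formulas", {
  same <- temStats(c(7.1, 7.5, 8.0), c(7.1, 7.5, 8.0))
  expect_equal(same$tem_mm, 0)
  expect_equal(same$percent_tem, 0)
  expect_equal(same$reliability_R, 1)

  r <- temStats(c(10.0, 10.2), c(10.2, 10.0))
  expect_equal(r$tem_mm, sqrt(0.08 / 4), tolerance = 1e-9)
  expect_equal(r$percent_tem, 100 * sqrt(0.02) / 10.1, tolerance = 1e-9)
  expect_equal(r$n_pairs, 2L)

  expect_error(temStats(1:3, 1:4), "equal length")
  expect_error(temStats(1, 2), "two pairs")
})

test_that("TEM is symmetric and scale-equivariant; %TEM scale-invariant", {
  set.seed(99)
  a <- rnorm(25, 7.5, 0.3)
  b <- a + rnorm(25, 0, 0.05)
  expect_equal(temStats(a, b)$tem_mm, temStats(b, a)$tem_mm)
  expect_equal(temStats(3 * a, 3 * b)$tem_mm, 3 * temStats(a, b)$tem_mm,
               tolerance = 1e-12)
  expect_equal(temStats(3 * a, 3 * b)$percent_tem, temStats(a, b)$percent_tem,
               tolerance = 1e-12)
})

test_that("repeat noise of 0.05 mm keeps %TEM under 2% and R above 0.93", {
  ok <- 0L
  for (seed in 1:100) {
    sim <- simulateOdontometry(rep(c("male", "female"), c(12, 13)),
                               specimen_ids = sprintf("P%02d", 1:25),
                               seed = seed)
    m <- sim$measurements
    s1 <- medianDiameters(m, observer = "RG", session = 1)
    s2 <- medianDiameters(m, observer = "RG", session = 2)
    r <- temStats(s1$diameter_mm, s2$diameter_mm)
    if (r$percent_tem < 2 && r$reliability_R >= 0.93) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("agreement reproduces the worked confusion-matrix example", {
  # 21 + 2 peptide females, 5 + 7 peptide males; odontometric calls laid out
  # to give the matrix [[21, 2], [5, 7]]
  ids <- sprintf("I%02d", 1:35)
  pep <- calls_df(ids, rep(c("female", "male"), c(23, 12)))
  odo <- calls_df(ids, c(rep("female", 21), rep("male", 2),
                         rep("female", 5), rep("male", 7)))
  set.seed(1)
  res <- sexAgreement(pep, odo)
  expect_identical(unclass(res$matrix),
                   matrix(c(21L, 5L, 2L, 7L), 2,
                          dimnames = dimnames(res$matrix)))
  expect_equal(res$accuracy, 0.80)
  expect_equal(res$per_class[["female"]], 21 / 23)
  expect_equal(res$per_class[["male"]], 7 / 12)
  expect_equal(res$kappa, 0.528, tolerance = 1e-3)
  expect_lt(res$kappa_p, 0.05)
  # cross-check kappa against an independent implementation
  skip_if_not_installed("e1071")
  expect_equal(res$kappa,
               e1071::classAgreement(res$matrix)$kappa, tolerance = 1e-12)
})

test_that("non-confident peptide calls are excluded with a count", {
  ids <- sprintf("I%02d", 1:6)
  pep <- calls_df(ids, c("female", "female", "male", "male",
                         "probable_female", "undetermined"))
  odo <- calls_df(ids, rep(c("female", "male"), 3))
  set.seed(1)
  expect_message(res <- sexAgreement(pep, odo, n_perm = 100), "excluded")
  expect_identical(res$excluded_n, 2L)
  expect_identical(res$n, 4L)
  expect_error(sexAgreement(pep, calls_df("ZZZ", "male")), "no shared")
})

test_that("kappa obeys its structural identities", {
  set.seed(7)
  ids <- sprintf("I%02d", 1:40)
  # perfect agreement
  v <- rep(c("female", "male"), 20)
  res <- suppressMessages(sexAgreement(calls_df(ids, v), calls_df(ids, v),
                                       n_perm = 200))
  expect_equal(res$kappa, 1)
  expect_equal(res$accuracy, 1)
  # chance-level agreement: independent margins give kappa 0
  # table [[16, 4], [16, 4]]: p_o = 0.5, p_e = 0.5
  pep <- calls_df(ids, rep(c("female", "male"), each = 20))
  odo <- calls_df(ids, rep(c(rep("female", 16), rep("male", 4)), 2))
  res0 <- suppressMessages(sexAgreement(pep, odo, n_perm = 200))
  expect_equal(res0$kappa, 0, tolerance = 1e-12)
  # kappa stays within [-1, 1] on random call sets
  for (i in 1:20) {
    pep <- calls_df(ids, sample(c("female", "male"), 40, replace = TRUE))
    odo <- calls_df(ids, sample(c("female", "male"), 40, replace = TRUE))
    k <- suppressMessages(sexAgreement(pep, odo, n_perm = 10))$kappa
    expect_gte(k, -1)
    expect_lte(k, 1)
  }
})

test_that("generator-matched cutoffs separate synthetic sexes sensibly", {
  sim <- simulateOdontometry(rep(c("male", "female"), c(18, 18)), seed = 5)
  d <- medianDiameters(sim$measurements, observer = "RG", session = 1)
  truth <- sim$truth$sex[match(d$specimen_id, sim$truth$specimen_id)]
  acc_at <- function(cut) mean(classifyByCutoff(d$diameter_mm, cut) == truth)
  # the midpoint of the generator means should beat grossly shifted cutoffs
  mid <- (7.30 + 7.95) / 2
  expect_gte(acc_at(mid), acc_at(mid - 0.5))
  expect_gte(acc_at(mid), acc_at(mid + 0.5))
})
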