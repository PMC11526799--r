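test_that("mean squares match brute-force and aov decompositions", {
  # rows (0,0,0),(1,1,1),(2,2,2): all variance between subjects
  m <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, byrow = TRUE)
  a <- anova_mean_squares(m)
  expect_equal(a$MSR, 3)
  expect_equal(a$MSC, 0)
  expect_equal(a$MSE, 0)
  expect_equal(a$SSR, 6)

  expect_equal(anova_mean_squares(matrix(5, 3, 3))[c("MSR", "MSC", "MSE")],
               list(MSR = 0, MSC = 0, MSE = 0))

  set.seed(11)
  for (rep in 1:10) {
    m <- matrix(rnorm(15, 1, 0.6), 5, 3)
    a <- anova_mean_squares(m)
    o <- oracle_ss(m)
    expect_equal(a$SSR + a$SSC + a$SSE, o$SST, tolerance = 1e-12)
    expect_equal(a$MSR, o$MSR, tolerance = 1e-12)
    expect_equal(a$MSC, o$MSC, tolerance = 1e-12)
    expect_equal(a$MSE, o$MSE, tolerance = 1e-12)
    ms <- oracle_ms_aov(m)
    expect_equal(a$MSR, ms$MSR, tolerance = 1e-10)
    expect_equal(a$MSC, ms$MSC, tolerance = 1e-10)
    expect_equal(a$MSE, ms$MSE, tolerance = 1e-10)
  }
})

test_that("agreement ICC matches the variance-component oracle on small matrices", {
  m6 <- matrix(c(2, 2, 1, 1, 0, 1, 2, 1, 2, 0, 1, 0, 2, 2, 2, 1, 1, 2),
               6, 3, byrow = TRUE)
  expect_equal(icc_agreement(m6)$estimate, oracle_icc_vc(m6),
               tolerance = 1e-10)
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 4), n, 4)
    expect_equal(icc_agreement(m)$estimate, oracle_icc_vc(m),
                 tolerance = 1e-10)
  }
})

test_that("estimate, CI, F and p agree with an independent ICC(A,1)/ICC(A,k) implementation", {
  # 6 subjects x 4 raters benchmark; expected values computed with
  # pingouin.intraclass_corr (two-way random effects, absolute agreement).
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), 6, 4, byrow = TRUE)
  single <- icc_agreement(m, "single")
  expect_equal(single$estimate, 0.28976377952755916, tolerance = 1e-12)
  expect_equal(round(single$lower, 2), 0.02)
  expect_equal(round(single$upper, 2), 0.76)
  expect_equal(single$F, 11.027247956403299, tolerance = 1e-12)
  expect_equal(single$p, 0.000134566516484335, tolerance = 1e-9)
  avg <- icc_agreement(m, "average")
  expect_equal(avg$estimate, 0.6200505475989893, tolerance = 1e-12)
  expect_equal(round(avg$lower, 2), 0.07)
  expect_equal(round(avg$upper, 2), 0.93)
})

test_that("perfect agreement gives ICC 1 with a collapsed interval", {
  m <- matrix(c(0, 0, 2, 2, 1, 1), 3, 2, byrow = TRUE)
  r <- icc_agreement(m)
  expect_equal(r$estimate, 1)
  expect_equal(c(r$lower, r$upper), c(1, 1))
  expect_equal(r$band, "excellent")
})

test_that("degenerate and malformed matrices are rejected explicitly", {
  expect_error(icc_agreement(matrix(1, 4, 3)), "undefined",
               class = "ewat_degenerate_error")
  expect_error(ratings_matrix(matrix(c(1, NA, 2, 3), 2)),
               "missing", class = "ewat_validation_error")
  expect_error(ratings_matrix(matrix(1:3, 3, 1)), class = "ewat_validation_error")
  expect_error(ratings_matrix(matrix(1:3, 1, 3)), class = "ewat_validation_error")
})

test_that("absolute agreement penalises rater level shifts; consistency does not", {
  set.seed(5)
  base <- rnorm(8, 1, 0.7)
  m <- cbind(base + rnorm(8, 0, 0.1), base + rnorm(8, 0, 0.1))
  shifted <- m; shifted[, 2] <- shifted[, 2] + 0.8
  agree <- icc_agreement(shifted)$estimate
  a <- anova_mean_squares(shifted)
  consistency <- (a$MSR - a$MSE) / (a$MSR + (a$k - 1) * a$MSE)
  expect_lt(agree, consistency)
  # and strictly less than the unshifted agreement ICC
  expect_lt(agree, icc_agreement(m)$estimate)
})

test_that("agreement ICC is invariant to global shift and positive scaling", {
  set.seed(9)
  for (rep in 1:10) {
    m <- matrix(rnorm(12, 1, 0.5), 6, 2)
    base <- icc_agreement(m)$estimate
    expect_equal(icc_agreement(m + 3.7)$estimate, base, tolerance = 1e-10)
    expect_equal(icc_agreement(m * 2.4)$estimate, base, tolerance = 1e-10)
  }
})

test_that("average-rating ICC dominates single-rating ICC when positive", {
  set.seed(31)
  for (rep in 1:10) {
    m <- simulate_two_way(n = 8, k = 3, sigma2_subject = 1, sigma2_rater = 0.2,
                          sigma2_error = 0.4, seed = rep)
    s <- icc_agreement(m, "single")$estimate
    a <- icc_agreement(m, "average")$estimate
    if (s > 0) expect_gte(a, s)
  }
})

test_that("interpretation bands follow the conventional cut-points", {
  expect_equal(classify_icc(c(0.3, 0.6, 0.82, 0.95)),
               c("poor", "moderate", "good", "excellent"))
  # boundary values fall in the upper band by default
  expect_equal(classify_icc(c(0.5, 0.75, 0.9)),
               c("moderate", "good", "excellent"))
  expect_equal(classify_icc(c(0.5, 0.75, 0.9), right_closed = TRUE),
               c("poor", "moderate", "good"))
  expect_equal(classify_icc(-0.2), "poor")
  expect_error(classify_icc(NaN), class = "ewat_usage_error")
})

test_that("the pooled report reproduces hand-computed summaries", {
  mats <- lapply(c(0.78, 0.80, 0.82, 0.90),
                 function(r) ewat:::make_icc_matrix(10, 3, r))
  names(mats) <- paste0("set", 1:4)
  rep4 <- reliability_report(mats, "inter_rater")
  expect_equal(rep4$mean, 0.825, tolerance = 1e-9)
  expect_equal(rep4$range, c(0.78, 0.90), tolerance = 1e-9)
  expect_equal(rep4$se, sd(rep4$results$estimate) / 2, tolerance = 1e-12)

  # identical matrices: SE 0, collapsed range
  same <- list(a = mats[[1]], b = mats[[1]], c = mats[[1]])
  rs <- reliability_report(same, "inter_rater")
  expect_equal(rs$se, 0)
  expect_equal(rs$range[1], rs$range[2])

  # single matrix: mean is that ICC, SE defined as 0
  r1 <- reliability_report(mats[1], "inter_rater")
  expect_equal(r1$mean, 0.78, tolerance = 1e-9)
  expect_equal(r1$se, 0)
})

test_that("report validates design constraints", {
  m3 <- ewat:::make_icc_matrix(10, 3, 0.8)
  expect_error(reliability_report(list(a = m3), "test_retest"),
               "2 occasions", class = "ewat_validation_error")
  m2 <- ewat:::make_icc_matrix(10, 2, 0.8)
  other <- m2; rownames(other) <- rev(rownames(other))
  expect_error(reliability_report(list(a = m2, b = other), "test_retest"),
               "same subjects", class = "ewat_validation_error")
})

test_that("rating matrices assemble from sheets by rater and occasion", {
  cb <- load_codebook()
  sheets <- c(
    lapply(1:3, function(r) constant_sheet(cb, 2, elephant_id = "e1",
                                           rater_id = paste0("r", r))),
    lapply(1:3, function(r) constant_sheet(cb, 1, elephant_id = "e2",
                                           rater_id = paste0("r", r))),
    lapply(1:3, function(r) constant_sheet(cb, 0, elephant_id = "e3",
                                           rater_id = paste0("r", r)))
  )
  mats <- assemble_ratings(sheets, cb)
  expect_named(mats, c("Nutrition", "Environment", "Health", "BehaviorMental",
                       "overall"))
  expect_equal(dim(mats$overall), c(3L, 3L))
  expect_equal(unname(mats$overall["e1", ]), rep(2, 3))

  # occasions as columns
  occ <- list(constant_sheet(cb, 2, elephant_id = "e1", occasion = 1),
              constant_sheet(cb, 1, elephant_id = "e1", occasion = 2),
              constant_sheet(cb, 2, elephant_id = "e2", occasion = 1),
              constant_sheet(cb, 2, elephant_id = "e2", occasion = 2))
  m <- assemble_ratings(occ, cb, level = "overall", by = "occasion")$overall
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m["e1", ]), c(2, 1))

  # incomplete coverage errors unless listwise deletion is requested
  expect_error(assemble_ratings(sheets[-1], cb), "listwise",
               class = "ewat_validation_error")
  dropped <- assemble_ratings(sheets[-1], cb, level = "overall",
                              drop_incomplete = TRUE)$overall
  expect_equal(rownames(dropped), c("e2", "e3"))
})
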