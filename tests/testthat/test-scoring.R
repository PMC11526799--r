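test_that("uniform sheets score at the common value under both weightings", {
  cb <- load_codebook()
  s2 <- constant_sheet(cb, 2)
  expect_equal(elephant_score(s2, cb, "per_item")$value, 2)
  expect_equal(elephant_score(s2, cb, "per_measure")$value, 2)
  # half 0s, half 2s -> 1.0 per item
  keys <- cb$items$key
  mixed <- new_sheet("e1", cb, scores = stats::setNames(
    rep(c(0, 2), each = 21), keys))
  expect_equal(elephant_score(mixed, cb, "per_item")$value, 1)
})

test_that("dual-condition measures separate the two weightings as hand arithmetic says", {
  cb <- toy_cb4()  # env.chain day+night, env.bath, hlt.skin
  sc <- c("env.chain:daytime" = 2, "env.chain:nighttime" = 2,
          "env.bath:none" = 1)
  sheet <- new_sheet("e1", cb, scores = sc)
  # 3 of 4 items scored = 0.75 completeness
  expect_equal(completeness(sheet, cb), 0.75)
  expect_equal(elephant_score(sheet, cb, "per_item", 0.5)$value, 5 / 3)
  expect_equal(elephant_score(sheet, cb, "per_measure", 0.5)$value, 1.5)
})

test_that("weightings agree exactly when every measure has one condition", {
  cb <- toy_codebook(list(list(id = "a"), list(id = "b"), list(id = "c")))
  sc <- stats::setNames(c(0, 1, 2), cb$items$key)
  sheet <- new_sheet("e1", cb, scores = sc)
  expect_equal(elephant_score(sheet, cb, "per_item")$value,
               elephant_score(sheet, cb, "per_measure")$value)
})

test_that("low completeness blocks the overall score", {
  cb <- load_codebook()
  thin <- new_sheet("e1", cb, scores = stats::setNames(rep(2, 10),
                                                       cb$items$key[1:10]))
  expect_error(elephant_score(thin, cb), "insufficient",
               class = "ewat_insufficient_data_error")
  expect_silent(elephant_score(thin, cb, min_completeness = 0.2))
})

test_that("domain scores match the final tool's per-domain item counts", {
  cb <- load_codebook()
  tab <- table(cb$items$domain)
  expect_equal(tab[["Nutrition"]], 5L)
  expect_equal(tab[["Environment"]], 17L)  # 6 dual measures doubled
  expect_equal(tab[["Health"]], 10L)
  expect_equal(tab[["BehaviorMental"]], 10L)

  keys <- cb$items$key
  sc <- stats::setNames(rep(2, length(keys)), keys)
  sc[cb$items$key[cb$items$domain == "Health"]] <- 1
  ds <- domain_scores(new_sheet("e1", cb, scores = sc), cb)
  expect_equal(ds$value[ds$domain == "Health"], 1)
  expect_equal(ds$value[ds$domain != "Health"], rep(2, 3))
  # item-count-weighted recombination of domain means = per_item overall
  overall <- sum(ds$value * ds$n_items) / sum(ds$n_items)
  expect_equal(overall,
               elephant_score(new_sheet("e1", cb, scores = sc), cb)$value)
})

test_that("an unscored domain is reported missing, not zero", {
  cb <- load_codebook()
  keys_not_nut <- cb$items$key[cb$items$domain != "Nutrition"]
  sheet <- new_sheet("e1", cb, scores = stats::setNames(
    rep(1, length(keys_not_nut)), keys_not_nut))
  ds <- domain_scores(sheet, cb)
  expect_true(is.na(ds$value[ds$domain == "Nutrition"]))
  expect_equal(ds$n_items[ds$domain == "Nutrition"], 0L)
})

test_that("camp score is the unweighted mean over elephants", {
  cb <- load_codebook()
  a <- constant_sheet(cb, 1, elephant_id = "eA")
  b <- constant_sheet(cb, 2, elephant_id = "eB")
  expect_equal(camp_score(list(a, b), cb)$value, 1.5)
  expect_equal(camp_score(list(a), cb)$value, 1)
  expect_equal(camp_score(list(b, a), cb)$value,
               camp_score(list(a, b), cb)$value)
  expect_equal(camp_score(list(a, b), cb)$n, 2L)
  expect_error(camp_score(list(), cb), class = "ewat_insufficient_data_error")
  # two sheets for one elephant count once
  expect_equal(camp_score(list(a, constant_sheet(cb, 2, elephant_id = "eA"),
                               b), cb)$value, (1.5 + 2) / 2)
})

test_that("aggregation is bounded and mean-stable", {
  cb <- load_codebook()
  for (seed in 1:5) {
    sheets <- simulate_camp(cb, n_elephants = 4, quality = 1.2, noise = 0.5,
                            seed = seed)
    for (s in sheets) {
      v <- elephant_score(s, cb)$value
      expect_gte(v, min(s$scores, na.rm = TRUE))
      expect_lte(v, max(s$scores, na.rm = TRUE))
    }
  }
  # adding an item equal to the current mean leaves the mean unchanged
  cb3 <- toy_codebook(list(list(id = "a"), list(id = "b"), list(id = "c")))
  partial <- new_sheet("e1", cb3, scores = c("a:none" = 0, "b:none" = 2))
  full <- new_sheet("e1", cb3, scores = c("a:none" = 0, "b:none" = 2,
                                          "c:none" = 1))
  expect_equal(elephant_score(partial, cb3, min_completeness = 0.5)$value,
               elephant_score(full, cb3)$value)
})

test_that("concern flags carry the basis-appropriate semantics", {
  cb <- load_codebook()
  expect_equal(nrow(flag_concerns(constant_sheet(cb, 2), cb)), 0L)

  keys <- cb$items$key
  sc <- stats::setNames(rep(2, length(keys)), keys)
  sc["env.bathing:none"] <- 0          # resource-based
  sc["hlt.wounds:none"] <- 0           # animal-based
  sc["beh.rest_sleep:none"] <- 1
  fl <- flag_concerns(new_sheet("e1", cb, scores = sc), cb)
  expect_equal(nrow(fl), 2L)
  expect_equal(fl$label[fl$measure_id == "env.bathing"], "High-risk")
  expect_equal(fl$label[fl$measure_id == "hlt.wounds"],
               "Welfare concern (Not adequate)")
  fl1 <- flag_concerns(new_sheet("e1", cb, scores = sc), cb,
                       include_potential = TRUE)
  expect_equal(nrow(fl1), 3L)
  expect_equal(fl1$label[fl1$measure_id == "beh.rest_sleep"],
               "Potential welfare concern (Needs improvement)")
})

test_that("reports tabulate elephants and camps", {
  cb <- load_codebook()
  sheets <- list(constant_sheet(cb, 2, elephant_id = "e1"),
                 constant_sheet(cb, 1, elephant_id = "e2"))
  er <- elephant_report(sheets, cb)
  expect_equal(nrow(er), 2L)
  expect_equal(er$overall, c(2, 1))
  expect_equal(er$n_concerns, c(0L, 0L))
  cr <- camp_report(sheets, cb)
  expect_equal(cr$camp_score, 1.5)
  expect_equal(cr$n_elephants, 2L)
})
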