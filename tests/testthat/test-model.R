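# Ensemble model: feature encoding, training contracts, percentile bands,
# confidence tiers, ranking, class aggregation.

# A stub member whose predict() returns a constant lets band arithmetic be
# checked exactly.
const_fit <- function(v) structure(list(v = v), class = "htnrec_constfit")
predict.htnrec_constfit <- function(object, newdata, ...) {
  rep(object$v, nrow(newdata))
}
.S3method("predict", "htnrec_constfit", predict.htnrec_constfit)

stub_ensemble <- function(values, support = NULL, cuts = NULL) {
  scaling <- list(center = c(age = 50, pre_sbp = 140, pre_dbp = 85,
                             creatinine = 1),
                  scale = c(age = 10, pre_sbp = 15, pre_dbp = 10,
                            creatinine = 0.5))
  support <- support %||% tibble::tibble(
    treatment_id = character(), race = character(),
    age_band = factor(character(), levels = c("18-39", "40-59", "60-79",
                                              "80+")),
    support_count = integer()
  )
  structure(
    list(
      members = purrr::map(values, ~ list(fit = const_fit(.x), idx = 1:2,
                                          seed = 1L)),
      scaling = scaling, config = ensemble_config(),
      support = support, n_train = 100, seed = 1,
      tier_cuts = cuts %||% list(s_medium = 5, s_high = 20, d_cap = 0.5)
    ),
    class = "htn_ensemble"
  )
}

test_that("featurize is deterministic and rejects incomplete records", {
  p <- ref_patient()
  f1 <- featurize(p, "lisinopril:10")
  f2 <- featurize(p, "lisinopril:10")
  expect_identical(f1, f2)

  # same patient, two candidate treatments: only the treatment field differs
  fa <- featurize(p, "lisinopril:10")
  fb <- featurize(p, "amlodipine:5")
  expect_identical(dplyr::select(fa, -"treatment_id"),
                   dplyr::select(fb, -"treatment_id"))

  p_missing <- dplyr::select(p, -"creatinine")
  expect_error(featurize(p_missing, "lisinopril:10"),
               class = "htnrec_feature_error")
  p_na <- p; p_na$creatinine <- NA_real_
  expect_error(featurize(p_na, "lisinopril:10"),
               class = "htnrec_feature_error")
  expect_error(featurize(p, "aspirin:81"), class = "htnrec_domain_error")
})

test_that("training is reproducible and members see 80% subsamples", {
  run <- small_model_fixture()
  ens <- run$ensemble
  expect_length(ens$members, run$config$members)
  n <- ens$n_train
  for (m in ens$members) expect_length(m$idx, floor(0.8 * n))
  expect_length(unique(purrr::map_int(ens$members, "seed")),
                run$config$members)
  # distinct member subsamples
  expect_gt(length(unique(purrr::map_chr(
    ens$members, ~ paste(sort(.x$idx), collapse = ",")))), 1)

  ens2 <- train_ensemble(run$features, run$labels, run$config, seed = 101)
  expect_equal(predict_success(ens, run$features[1:5, ]),
               predict_success(ens2, run$features[1:5, ]))
})

test_that("degenerate labels refuse to train", {
  run <- small_model_fixture()
  all_fail <- dplyr::mutate(run$labels, status = "failure")
  expect_error(train_ensemble(run$features, all_fail, run$config, seed = 1),
               class = "htnrec_training_error")
})

test_that("percentile bands follow the member score distribution", {
  feats <- featurize(ref_patient(), "lisinopril:10")
  # all members at 0.4: zero-width bands
  ens <- stub_ensemble(rep(0.4, 20))
  pred <- predict_success(ens, feats)
  expect_equal(pred$median, 0.4)
  expect_equal(pred$p10, 0.4)
  expect_equal(pred$p90, 0.4)
  # 19 members low, one high: the median stays with the majority
  ens2 <- stub_ensemble(c(rep(0.1, 19), 0.9))
  pred2 <- predict_success(ens2, feats)
  expect_equal(pred2$median, 0.1)
  expect_lt(pred2$p75, 0.2)
})

test_that("band ordering holds for every prediction", {
  run <- small_model_fixture()
  pred <- predict_success(run$ensemble, run$features)
  expect_true(all(pred$p10 <= pred$p25 + 1e-12))
  expect_true(all(pred$p25 <= pred$median + 1e-12))
  expect_true(all(pred$median <= pred$p75 + 1e-12))
  expect_true(all(pred$p75 <= pred$p90 + 1e-12))
})

test_that("confidence tiers implement the positivity filter", {
  feats <- featurize(ref_patient(age = 50), "lisinopril:10")
  # zero support is always low, whatever the dispersion
  ens <- stub_ensemble(rep(0.4, 20))
  expect_equal(confidence_tier(ens, feats)$confidence_tier, "low")
  expect_equal(confidence_tier(ens, feats)$support_count, 0L)
  # zero dispersion with large support is high
  supp <- tibble::tibble(
    treatment_id = "lisinopril:10", race = "White",
    age_band = factor("40-59", levels = c("18-39", "40-59", "60-79", "80+")),
    support_count = 500L
  )
  ens2 <- stub_ensemble(rep(0.4, 20), support = supp)
  expect_equal(confidence_tier(ens2, feats)$confidence_tier, "high")
  # middling support lands in medium
  supp$support_count <- 10L
  ens3 <- stub_ensemble(rep(0.4, 20), support = supp)
  expect_equal(confidence_tier(ens3, feats)$confidence_tier, "medium")
})

test_that("ranking is deterministic with the declared tie-breaks", {
  supp <- tibble::tibble(
    treatment_id = c("lisinopril:10", "losartan:50", "amlodipine:5"),
    race = "White",
    age_band = factor("40-59", levels = c("18-39", "40-59", "60-79", "80+")),
    support_count = c(50L, 80L, 50L)
  )
  ens <- stub_ensemble(rep(0.4, 20), support = supp)
  r <- recommend(ens, ref_patient(age = 50),
                 candidates = c("amlodipine:5", "losartan:50",
                                "lisinopril:10"))
  # equal medians everywhere: support breaks the tie, then treatment id
  expect_equal(r$treatment_id[1], "losartan:50")
  expect_equal(r$treatment_id[2:3], c("amlodipine:5", "lisinopril:10"))
  expect_equal(r$rank, 1:3)

  # min_tier filters: only the supported candidates survive medium
  r2 <- recommend(ens, ref_patient(age = 50),
                  candidates = c("amlodipine:5", "valsartan:80"),
                  min_tier = "medium")
  expect_equal(r2$treatment_id, "amlodipine:5")
  expect_warning(
    r3 <- recommend(ens, ref_patient(age = 50),
                    candidates = "valsartan:80", min_tier = "high"),
    "No candidate"
  )
  expect_equal(nrow(r3), 0)
})

test_that("class aggregation is the weighted mean of pair medians", {
  pred <- tibble::tibble(
    treatment_id = c("a", "b", "c"),
    median = c(0.3, 0.5, 0.4)
  )
  w <- tibble::tibble(treatment_id = c("a", "b", "c"),
                      class_label = c("X", "X", "Y"),
                      weight = c(0.5, 0.5, 1))
  agg <- aggregate_to_class(pred, w)
  expect_equal(agg$score[agg$class_label == "X"], 0.4)
  expect_equal(agg$score[agg$class_label == "Y"], 0.4)

  w2 <- tibble::tibble(treatment_id = c("a", "b"), class_label = "X",
                       weight = c(0.9, 0.1))
  agg2 <- aggregate_to_class(pred[1:2, ], w2)
  expect_equal(agg2$score, 0.9 * 0.3 + 0.1 * 0.5)  # 0.44

  w_bad <- tibble::tibble(treatment_id = c("a", "b"), class_label = "X",
                          weight = c(0.5, 0.3))
  expect_error(aggregate_to_class(pred[1:2, ], w_bad),
               class = "htnrec_validation_error")
})

test_that("predicting with an untrained object is a state error", {
  expect_error(predict_success(list(), featurize(ref_patient(), "lisinopril:10")),
               class = "htnrec_state_error")
})

test_that("shuffling a zero-coefficient feature barely moves predictions", {
  run <- acceptance_fixture()
  val_feats <- dplyr::filter(run$features,
                             .data$patient_id %in% run$split$validation)
  base <- predict_success(run$ensemble, val_feats)
  shuffled <- val_feats
  shuffled$creatinine <- withr::with_seed(4, sample(shuffled$creatinine))
  after <- predict_success(run$ensemble, shuffled)
  # creatinine has a zero planted coefficient; cell-level predictions may
  # move only within estimation noise
  menu <- treatment_menu()$menu
  cls <- menu$class_label[match(base$treatment_id, menu$treatment_id)]
  delta <- tapply(after$median - base$median, cls, mean)
  expect_lt(max(abs(delta)), 0.02)
  expect_lt(mean(abs(after$median - base$median)), 0.02)
})
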