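test_that("stratified folds preserve class ratios within one participant", {
  participants <- data.frame(
    participant_id = sprintf("P%02d", 1:62),
    group = rep(c("ASD", "TD"), c(39, 23)), stringsAsFactors = FALSE)
  folds <- stratified_folds(participants, k = 5, seed = 1)
  expect_setequal(names(folds), participants$participant_id)
  per_fold <- table(participants$group, folds)
  expect_true(all(per_fold["ASD", ] %in% 7:8))
  expect_true(all(per_fold["TD", ] %in% 4:5))
  expect_equal(sum(per_fold["ASD", ]), 39)
  # determinism and seed sensitivity
  expect_identical(folds, stratified_folds(participants, 5, 1))
  folds2 <- stratified_folds(participants, 5, 2)
  expect_false(identical(folds, folds2))
  per_fold2 <- table(participants$group, folds2)
  expect_true(all(per_fold2["ASD", ] %in% 7:8)) # same margins, new split
  expect_error(stratified_folds(participants, 24, 1), "configuration error")
  expect_warning(stratified_folds(participants, 1, 1), "degenerate")
})

test_that("metric formulas reproduce hand-computed confusion tables", {
  m1 <- classification_metrics(c(TP = 8, FP = 2, TN = 3, FN = 0))
  expect_equal(unname(m1["precision"]), 0.80)
  expect_equal(unname(m1["recall"]), 1.00)
  expect_equal(unname(m1["specificity"]), 0.60)
  expect_equal(unname(m1["mcc"]), 24 / sqrt(10 * 8 * 5 * 3))
  expect_equal(unname(m1["f1"]), 2 * 0.8 / 1.8)
  perfect <- classification_metrics(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unname(perfect), rep(1, 5))
  # 0/0 conventions
  degenerate <- classification_metrics(c(TP = 0, FP = 0, TN = 3, FN = 0))
  expect_equal(unname(degenerate["precision"]), 0)
  expect_equal(unname(degenerate["mcc"]), 0)
})

test_that("MCC matches its correlation definition and swap symmetry", {
  set.seed(20)
  for (i in 1:50) {
    ct <- c(TP = rpois(1, 5), FP = rpois(1, 3), TN = rpois(1, 5),
            FN = rpois(1, 3))
    truth <- rep(c(1, 0, 0, 1), ct)
    pred <- rep(c(1, 1, 0, 0), ct)
    mcc <- unname(classification_metrics(ct)["mcc"])
    # brute force: MCC is the Pearson correlation of the binary vectors
    oracle <- suppressWarnings(cor(truth, pred))
    if (!is.na(oracle)) expect_equal(mcc, oracle, tolerance = 1e-12)
    # symmetry under simultaneous TP<->TN, FP<->FN swap
    swapped <- c(TP = ct[["TN"]], FP = ct[["FN"]], TN = ct[["TP"]],
                 FN = ct[["FP"]])
    expect_equal(unname(classification_metrics(swapped)["mcc"]), mcc)
  }
})

test_that("x-y projection drops exactly the 20 joint depth channels", {
  rec <- toy_recording(T = 30)
  proj <- project_xy(rec)
  expect_equal(ncol(proj$data), 42)
  expect_true(all(c("board:x", "board:y") %in% colnames(proj$data)))
  expect_false(any(grepl(":z$", colnames(proj$data))))
  fm <- featurize_recording(proj)
  expect_equal(ncol(fm), 84)
  # list form
  expect_equal(ncol(project_xy(list(rec))[[1]]$data), 42)
})

test_that("balanced subsampling keeps all TD and a seeded ASD subset", {
  fx <- toy_features(n_per = 8)
  # pretend unbalanced: drop 2 TD participants
  fx <- filter_participants(fx, setdiff(fx$participants$participant_id,
                                        c("T07", "T08")))
  bal <- balance_groups(fx, 6, seed = 1)
  expect_equal(sum(bal$participants$group == "ASD"), 6)
  expect_equal(sum(bal$participants$group == "TD"), 6)
  expect_true(all(c("T01", "T06") %in% bal$participants$participant_id))
  # full-size request is the identity
  full <- toy_features(n_per = 8)
  expect_setequal(balance_groups(full, 8, 1)$participants$participant_id,
                  full$participants$participant_id)
  bal2 <- balance_groups(fx, 6, seed = 2)
  expect_false(setequal(
    bal$participants$participant_id[bal$participants$group == "ASD"],
    bal2$participants$participant_id[bal2$participants$group == "ASD"]))
  expect_error(balance_groups(fx, 7, 1), "configuration error")
})

test_that("cross-validation partitions participants without leakage", {
  fx <- toy_features(n_per = 8, n_vec = 4, poses = 1:2, delta = 3)
  cv <- run_cv(fx, k = 4, seed = 3, top_k = 5)
  expect_s3_class(cv, "movement_cv")
  expect_length(cv$per_fold, 4)
  # every participant predicted exactly once, in their assigned fold
  expect_setequal(cv$predictions$participant_id,
                  fx$participants$participant_id)
  expect_equal(cv$fold_assignments[cv$predictions$participant_id],
               setNames(cv$predictions$fold,
                        cv$predictions$participant_id))
  # fold count sums reconstruct the cohort
  counts <- Reduce(`+`, lapply(cv$per_fold, `[[`, "counts"))
  expect_equal(unname(counts[["TP"]] + counts[["FN"]]), 8)
  expect_equal(unname(counts[["TN"]] + counts[["FP"]]), 8)
  # averages are unweighted fold means
  expect_equal(cv$averages,
               colMeans(do.call(rbind,
                                lapply(cv$per_fold, `[[`, "metrics"))))
  # strong toy signal: good held-out accuracy
  expect_gte(unname(cv$averages["mcc"]), 0.5)
  # determinism
  cv2 <- run_cv(fx, k = 4, seed = 3, top_k = 5)
  expect_equal(cv$averages, cv2$averages)
  expect_equal(cv$predictions, cv2$predictions)
})
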