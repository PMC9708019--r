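make_xy <- function(n, seed = 1, p_signal = 2) {
  # two informative gaussians + noise columns, balanced classes
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- cbind(matrix(rnorm(n * p_signal, mean = y), n, p_signal),
             matrix(rnorm(n * 2), n, 2))
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  list(X = X, y = y)
}

test_that("preprocessing one-hot encodes devices and scales on training rows only", {
  co <- toy_cohort(60, seed = 2)
  tr <- 1:40
  fm <- preprocess(co, tr)
  expect_s3_class(fm, "feature_matrix")
  oh <- fm$X[, c("device_CV", "device_EREPRO", "device_LT")]
  expect_true(all(rowSums(oh) == 1))
  i_lt <- which(co$device_type == "LT")[1]
  expect_equal(unname(fm$X[i_lt, c("device_CV", "device_EREPRO", "device_LT")]),
               c(0, 0, 1))
  num <- fm$X[tr, fm$numeric_columns]
  expect_true(all(num >= 0 & num <= 1))
  # scaling learned on train rows: value halfway between min and max -> 0.5
  lo <- min(co$doi[tr]); hi <- max(co$doi[tr])
  co2 <- co; co2$doi[41] <- (lo + hi) / 2; co2$doi[42] <- hi + 1
  fm2 <- preprocess(co2, tr)
  expect_equal(unname(fm2$X[41, "doi"]), 0.5)
  expect_gt(fm2$X[42, "doi"], 1)          # no clipping outside the train range
  co3 <- co; co3$cpi <- 7
  expect_warning(preprocess(co3, tr), "constant")
})

test_that("correlation screening drops only redundant numeric features", {
  co <- toy_cohort(1000, seed = 3)
  fm <- preprocess(co, 1:700)
  kept <- correlation_screen(fm)
  expect_setequal(kept, fm$columns)       # independent features all retained
  co$cpi <- co$cpmax * 100                # plant a duplicated feature
  fm2 <- preprocess(co, 1:700)
  kept2 <- correlation_screen(fm2)
  expect_length(setdiff(fm2$columns, kept2), 1)
  expect_true("cpmax" %in% kept2)         # the later pair member is dropped
})

test_that("the stratified split respects sizes, devices and determinism", {
  co <- toy_cohort(151, seed = 5)
  sp <- split_cohort(co, seed = 7)
  expect_length(sp$train_ids, 106)        # round(0.7 * 151)
  expect_length(sp$validation_ids, 45)
  expect_setequal(c(sp$train_ids, sp$validation_ids), 1:151)
  for (ids in sp)
    expect_setequal(unique(co$device_type[ids]), c("CV", "ER/EPRO", "LT"))
  # outcome stratification: training prevalence close to cohort prevalence
  expect_equal(mean(co$ca[sp$train_ids]), mean(co$ca), tolerance = 0.02)
  expect_identical(split_cohort(co, seed = 7), sp)
  co_bad <- co; co_bad$device_type <- c("LT", rep("CV", 150))
  expect_error(split_cohort(co_bad, seed = 1), "at least 2")
})

test_that("all eight base algorithms separate an easy problem", {
  expect_length(ml_algorithms(), 8)
  d <- make_xy(60, seed = 4)
  d$X[, 1] <- ifelse(d$y == 1, 10, -10)   # make it trivially separable
  for (id in ml_algorithms()) {
    m <- train_base(d$X, d$y, id, seed = 1, folds = 3)
    acc <- mean((predict(m, d$X) >= 0.5) == d$y)
    expect_gte(acc, 0.95)
  }
  expect_error(train_base(d$X, d$y, "mlp", seed = 1), "unknown algorithm")
})

test_that("cross-validated accuracy is at chance on label-shuffled data", {
  set.seed(10)
  d <- make_xy(400, seed = 10)
  y_perm <- sample(d$y)
  for (id in c("knn", "logreg", "dtree")) {
    m <- train_base(d$X, y_perm, id, seed = 2)
    expect_equal(m$cv_accuracy, 0.5, tolerance = 0.2)
  }
})

test_that("bagging degenerates to the base classifier and averages scores", {
  d <- make_xy(80, seed = 6)
  base <- train_base(d$X, d$y, "logreg", seed = 3)
  bag1 <- ensemble_bagging(d$X, d$y, "logreg", seed = 3, B = 1,
                           bootstrap = FALSE)
  expect_equal(predict(bag1, d$X), predict(base, d$X), tolerance = 1e-12)
  # ensemble score is the mean of member scores
  bag <- ensemble_bagging(d$X, d$y, "logreg", seed = 3, B = 5)
  s_members <- vapply(bag$members, function(m)
    bag$score_fun(m, d$X), numeric(nrow(d$X)))
  expect_equal(predict(bag, d$X), rowMeans(s_members), tolerance = 1e-12)
})

test_that("bagging reduces the variance of the ensemble score", {
  # averaging inequality checked by simulation over bootstrap worlds
  d <- make_xy(120, seed = 8)
  x_new <- matrix(0.5, 1, ncol(d$X), dimnames = list(NULL, colnames(d$X)))
  single <- numeric(30); bagged <- numeric(30)
  for (r in 1:30) {
    b1 <- ensemble_bagging(d$X, d$y, "dtree", seed = 100 + r, B = 1)
    b10 <- ensemble_bagging(d$X, d$y, "dtree", seed = 100 + r, B = 10)
    single[r] <- predict(b1, x_new)
    bagged[r] <- predict(b10, x_new)
  }
  expect_lte(var(bagged), var(single) + 1e-12)
})

test_that("voting takes the majority with ties toward the positive class", {
  fixed <- function(s) structure(list(score = s),
                                 class = "tavicap_fixed_clf")
  assign("predict.tavicap_fixed_clf",
         function(object, newdata, ...) rep(object$score, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.tavicap_fixed_clf", envir = globalenv()))
  X1 <- matrix(0, 1, 2)
  v <- ensemble_voting(list(fixed(1), fixed(1), fixed(0)))
  expect_gte(predict(v, X1), 0.5)
  v2 <- ensemble_voting(list(fixed(1), fixed(0)))
  expect_gte(predict(v2, X1), 0.5)        # tie -> positive
  v3 <- ensemble_voting(list(fixed(0), fixed(0), fixed(1)))
  expect_lt(predict(v3, X1), 0.5)
  expect_error(ensemble_voting(list(fixed(1))), "at least 2")
})

test_that("evaluation metrics satisfy their identities", {
  set.seed(12)
  d <- make_xy(300, seed = 12)
  m <- train_base(d$X, d$y, "logreg", seed = 1)
  rep <- evaluate(m, d$X, d$y, n_boot = 200, seed = 1)
  with(rep, {
    expect_equal(accuracy, (tp + tn) / (tp + tn + fp + fn), tolerance = 1e-12)
    expect_equal(f1, 2 * ppv * sensitivity / (ppv + sensitivity),
                 tolerance = 1e-12)
    expect_equal(ppv, tp / (tp + fp), tolerance = 1e-12)
    expect_equal(npv, tn / (tn + fn), tolerance = 1e-12)
  })
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
  expect_error(evaluate(m, d$X, rep(1, nrow(d$X))), "both classes")
})

test_that("the published worked example: F1 from sensitivity 1.00 and PPV 0.71", {
  expect_equal(round(f1_score(ppv = 0.71, sensitivity = 1.00), 2), 0.83)
})

test_that("AUC equals the Mann-Whitney normalisation, 1 for a perfect model", {
  y <- c(0, 0, 1, 1, 0, 1)
  s <- c(0.1, 0.4, 0.35, 0.8, 0.2, 0.9)
  roc <- roc_curve(s, y)
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  expect_identical(trap, auc_mann_whitney(s, y))
  # ties handled identically (counted one half)
  s2 <- c(0.5, 0.5, 0.5, 0.8, 0.2, 0.9)
  roc2 <- roc_curve(s2, y)
  expect_equal(sum(diff(roc2$fpr) * (head(roc2$tpr, -1) + roc2$tpr[-1]) / 2),
               auc_mann_whitney(s2, y), tolerance = 1e-15)
  # perfect separation
  expect_equal(auc_mann_whitney(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  # random scores at large n
  set.seed(14)
  expect_equal(auc_mann_whitney(runif(4000), rbinom(4000, 1, 0.5)), 0.5,
               tolerance = 0.05)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(200, 1, 0.5)
  s <- y * 0.6 + runif(200)
  ours <- auc_mann_whitney(s, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("model selection follows accuracy with documented tie-breaks", {
  mk <- function(acc, auc, cva = NA_real_)
    structure(list(accuracy = acc, auc = auc, cv_accuracy = cva),
              class = "evaluation_report")
  expect_equal(select_best(list(a = mk(0.83, 0.8), b = mk(0.80, 0.9),
                                c = mk(0.78, 0.95))), "a")
  expect_equal(select_best(list(a = mk(0.80, 0.84), b = mk(0.80, 0.80))), "a")
  expect_equal(select_best(list(zz = mk(0.80, 0.84))), "zz")
  # CV accuracy breaks ties before AUC
  expect_equal(select_best(list(a = mk(0.8, 0.9, cva = 0.7),
                                b = mk(0.8, 0.8, cva = 0.75))), "b")
})

test_that("training is leakage-free: validation permutation cannot change models", {
  co <- toy_cohort(300, seed = 16)
  sp <- split_cohort(co, seed = 16)
  co_perm <- co
  perm <- sample(sp$validation_ids)
  co_perm[sp$validation_ids, ] <- co[perm, ]
  an1 <- run_primary(co, seed = 16,
                     control = list(B = 2, n_boot = 0, split = sp))
  an2 <- run_primary(co_perm, seed = 16,
                     control = list(B = 2, n_boot = 0, split = sp))
  expect_identical(an1$selected, an2$selected)
  # per-model validation scores are the same multiset
  expect_equal(sort(an1$selected_report$scores),
               sort(an2$selected_report$scores), tolerance = 1e-9)
  expect_equal(an1$selected_report$accuracy, an2$selected_report$accuracy)
})

test_that("the sub-cohort analysis filters PPI and switches the outcome", {
  co <- toy_cohort(400, seed = 18)
  an <- run_subcohort_lbbb(co, seed = 18, control = list(B = 2, n_boot = 0))
  expect_equal(an$n, sum(co$ppi == 0))
  expect_equal(an$outcome, "lbbb_rbbb")
  # without any PPI patients the sub-cohort equals the full cohort
  co2 <- co[co$ppi == 0, ]; rownames(co2) <- NULL
  an2 <- run_subcohort_lbbb(co2, seed = 18, control = list(B = 2, n_boot = 0))
  expect_equal(an2$n, nrow(co2))
})

test_that("the ablation removes exactly the two mechanistic features", {
  co <- toy_cohort(300, seed = 19)
  an <- run_ablation(co, seed = 19, control = list(B = 2, n_boot = 0))
  expect_false(any(c("cpmax", "cpi") %in% an$retained_features))
  expect_length(setdiff(an$retained_features,
                        c("device_CV", "device_EREPRO", "device_LT")), 5)
})

test_that("the protocol is deterministic given the seed and null-calibrated on noise", {
  co <- toy_cohort(240, seed = 20, signal = FALSE)
  ctl <- list(B = 2, n_boot = 0)
  an1 <- run_primary(co, seed = 3, control = ctl)
  an2 <- run_primary(co, seed = 3, control = ctl)
  expect_identical(an1$selected, an2$selected)
  expect_equal(an1$all_models$accuracy, an2$all_models$accuracy)
  # with outcome independent of features, accuracy ~ majority-class rate
  prev <- max(mean(co$ca), 1 - mean(co$ca))
  expect_equal(an1$selected_report$accuracy, prev, tolerance = 0.2)
})

test_that("selected models consistently beat the mechanistic ablation across seeds", {
  # reduced protocol (n = 600, B = 5) to keep 20 replicates desk-scale
  aucs <- numeric(20); abls <- numeric(20)
  for (s in 1:20) {
    co <- sample_cohort_statistical(600, seed = 5000 + s)
    an <- run_primary(co, seed = s, control = list(B = 5, n_boot = 0))
    ab <- run_ablation(co, seed = s,
                       control = list(B = 5, n_boot = 0, split = an$split))
    aucs[s] <- an$selected_report$auc
    abls[s] <- ab$selected_report$auc
  }
  expect_gte(mean(aucs), 0.80)
  expect_true(all(aucs > abls))
})
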