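# Supervised-learning protocol: preprocessing, stratified split, eight base
# classifiers tuned by five-fold CV, bagging/voting ensembles,
# accuracy-based selection and full evaluation reports.

.ml_numeric_features <- c("ibms_length", "ibms_angle", "d3", "sizing_index",
                          "doi", "cpmax", "cpi")
.ml_device_levels <- c("CV", "ER/EPRO", "LT")

#' Preprocess a cohort into a feature matrix
#'
#' One-hot encodes the device type (three indicator columns) and min-max
#' scales the numeric features, with scaling parameters learned on the
#' training rows only and applied to all rows (validation values outside
#' the training range are not clipped). A constant training column is
#' scaled to zero with a warning.
#'
#' @param cohort cohort data frame.
#' @param train_ids integer row indices of the training partition.
#' @param numeric_features numeric feature columns to include.
#' @return Object of class `feature_matrix`: numeric matrix `X`, the
#'   scaling table, column names and the training ids.
#' @export
preprocess <- function(cohort, train_ids,
                       numeric_features = .ml_numeric_features) {
  stopifnot(all(numeric_features %in% names(cohort)),
            "device_type" %in% names(cohort),
            all(train_ids >= 1), all(train_ids <= nrow(cohort)))
  dev <- factor(cohort$device_type, levels = .ml_device_levels)
  if (any(is.na(dev))) stop("unknown device type in cohort")
  onehot <- sapply(.ml_device_levels, function(l) as.numeric(dev == l))
  colnames(onehot) <- paste0("device_", c("CV", "EREPRO", "LT"))
  scaling <- data.frame(column = numeric_features,
                        min = NA_real_, max = NA_real_)
  num <- matrix(NA_real_, nrow(cohort), length(numeric_features),
                dimnames = list(NULL, numeric_features))
  for (k in seq_along(numeric_features)) {
    x <- cohort[[numeric_features[k]]]
    lo <- min(x[train_ids]); hi <- max(x[train_ids])
    scaling$min[k] <- lo; scaling$max[k] <- hi
    if (hi - lo < .Machine$double.eps) {
      warning("constant training column '", numeric_features[k],
              "' scaled to 0")
      num[, k] <- 0
    } else num[, k] <- (x - lo) / (hi - lo)
  }
  X <- cbind(onehot, num)
  structure(list(X = X, scaling = scaling,
                 columns = colnames(X), numeric_columns = numeric_features,
                 train_ids = sort(unique(as.integer(train_ids)))),
            class = "feature_matrix")
}

#' Correlation screen for redundant numeric features
#'
#' Greedily drops one member of any numeric feature pair whose absolute
#' Pearson correlation (computed on training rows) exceeds the threshold.
#' One-hot indicator columns are always retained.
#'
#' @param fm a [preprocess()] feature matrix.
#' @param threshold absolute correlation above which a pair is redundant.
#' @return Character vector of retained column names.
#' @export
correlation_screen <- function(fm, threshold = 0.9) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- fm$numeric_columns
  Xtr <- fm$X[fm$train_ids, , drop = FALSE]
  repeat {
    if (length(keep) < 2L) break
    cm <- suppressWarnings(stats::cor(Xtr[, keep, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    mx <- max(abs(cm))
    if (mx <= threshold) break
    ij <- which(abs(cm) == mx, arr.ind = TRUE)[1, ]
    keep <- keep[-max(ij)]  # drop the later column of the worst pair
  }
  c(setdiff(fm$columns, fm$numeric_columns), keep)
}

#' Stratified train/validation split
#'
#' Splits the cohort 70/30 (by default), stratified by the outcome, and
#' redraws until each of the three device categories is present in both
#' partitions.
#'
#' @param cohort cohort data frame.
#' @param ratio training fraction; `|train| = round(ratio * n)`.
#' @param seed RNG seed.
#' @param outcome outcome column used for stratification.
#' @param max_tries redraw budget for the device-presence constraint.
#' @return List with integer vectors `train_ids` and `validation_ids`.
#' @export
split_cohort <- function(cohort, ratio = 0.7, seed = 1, outcome = "ca",
                         max_tries = 1000) {
  n <- nrow(cohort)
  y <- cohort[[outcome]]
  devs <- unique(cohort$device_type)
  if (any(table(cohort$device_type) < 2))
    stop("every device category needs at least 2 members to split")
  n_train <- round(ratio * n)
  .with_seed(.derive_seed(seed, 11L), {
    for (try in seq_len(max_tries)) {
      # stratified by outcome: proportional allocation, largest remainder
      idx1 <- which(y == 1); idx0 <- which(y == 0)
      k1 <- round(n_train * length(idx1) / n)
      k1 <- min(max(k1, 0), length(idx1))
      k0 <- n_train - k1
      if (k0 < 0 || k0 > length(idx0)) stop("infeasible split sizes")
      tr <- sort(c(sample(idx1, k1), sample(idx0, k0)))
      va <- setdiff(seq_len(n), tr)
      ok <- all(devs %in% cohort$device_type[tr]) &&
        all(devs %in% cohort$device_type[va])
      if (ok) return(list(train_ids = tr, validation_ids = va))
    }
    stop("could not satisfy the device-presence constraint in ", max_tries,
         " draws")
  })
}

# ---------------------------------------------------------------- registry

.gnb_floor_sd <- function(model, floor = 1e-3) {
  model$tables <- lapply(model$tables, function(tb) {
    if (is.matrix(tb) && ncol(tb) == 2L) tb[, 2] <- pmax(tb[, 2], floor)
    tb
  })
  model
}

.svm_score <- function(model, X) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- if (first == "1") 1 else -1
  plogis(s * as.numeric(dv))
}

.fit_sgd_svm <- function(X, y, lambda, epochs = 5, seed = 1) {
  # Pegasos-style stochastic sub-gradient descent on the hinge loss
  yy <- ifelse(y == 1, 1, -1)
  p <- ncol(X); n <- nrow(X)
  w <- numeric(p); b <- 0; t <- 0
  .with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (lambda * t)
        marg <- yy[i] * (sum(w * X[i, ]) + b)
        w <- (1 - eta * lambda) * w
        if (marg < 1) {
          w <- w + eta * yy[i] * X[i, ]
          b <- b + eta * yy[i]
        }
      }
    }
  })
  list(w = w, b = b, lambda = lambda)
}

# Each algorithm: a small documented hyperparameter grid, a fit and a score
# (probability-like, in [0, 1], threshold 0.5 for labels).
.ml_registry <- function() {
  list(
    knn = list(
      label = "K-Nearest Neighbours",
      grid = lapply(c(3, 5, 7, 9, 11), function(k) list(k = k)),
      fit = function(X, y, h, seed) list(X = X, y = as.integer(y), k = h$k),
      score = function(m, X) .knn_score_cpp(m$X, m$y, X, m$k)),
    logreg = list(
      label = "Logistic Regression",
      grid = list(list()),
      fit = function(X, y, h, seed) {
        df <- data.frame(y = y, X)
        suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      },
      score = function(m, X) {
        cf <- coef(m); cf[is.na(cf)] <- 0
        as.numeric(plogis(cbind(1, X) %*% cf))
      }),
    svc = list(
      label = "C-Support Vector Classification",
      grid = lapply(c(0.5, 2), function(C) list(cost = C)),
      fit = function(X, y, h, seed)
        e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = h$cost, scale = FALSE),
      score = function(m, X) .svm_score(m, X)),
    gnb = list(
      label = "Gaussian Naive-Bayes",
      grid = list(list()),
      fit = function(X, y, h, seed)
        .gnb_floor_sd(e1071::naiveBayes(x = as.data.frame(X),
                                        y = factor(y, levels = c(0, 1)))),
      score = function(m, X)
        predict(m, as.data.frame(X), type = "raw")[, "1"]),
    sgd_svm = list(
      label = "Support Vector Machine + SGD",
      grid = lapply(c(1e-3, 1e-2, 1e-1), function(l) list(lambda = l)),
      fit = function(X, y, h, seed) .fit_sgd_svm(X, y, h$lambda, seed = seed),
      score = function(m, X) plogis(as.numeric(X %*% m$w + m$b))),
    xgb = list(
      label = "Extreme Gradient Boosting",
      grid = lapply(c(2, 4), function(d) list(max_depth = d)),
      fit = function(X, y, h, seed)
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = h$max_depth, eta = 0.1,
                                         nthread = 1, seed = seed),
                           data = xgboost::xgb.DMatrix(X, label = y,
                                                       nthread = 1),
                           nrounds = 60, verbose = 0),
      score = function(m, X) predict(m, X)),
    dtree = list(
      label = "Decision Tree",
      grid = lapply(c(0.001, 0.01), function(cp) list(cp = cp)),
      fit = function(X, y, h, seed)
        rpart::rpart(y ~ ., data = data.frame(y = factor(y, levels = c(0, 1)), X),
                     method = "class", cp = h$cp),
      score = function(m, X) predict(m, data.frame(X), type = "prob")[, "1"]),
    rf = list(
      label = "Random Forest",
      grid = lapply(c(2, 3), function(m) list(mtry = m)),
      fit = function(X, y, h, seed)
        ranger::ranger(y = factor(y, levels = c(0, 1)), x = data.frame(X),
                       probability = TRUE, num.trees = 100,
                       mtry = min(h$mtry, ncol(X)), num.threads = 1,
                       seed = seed),
      score = function(m, X) predict(m, data.frame(X),
                                     num.threads = 1)$predictions[, "1"])
  )
}

#' Names of the eight base classification algorithms
#' @return Character vector of registry ids.
#' @export
ml_algorithms <- function() names(.ml_registry())

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train a tuned base classifier
#'
#' Fits one of the eight base algorithms, choosing its hyperparameters by
#' stratified five-fold cross-validated accuracy over a small grid, then
#' refits on the full training set. All fitted models expose a continuous
#' score in `[0, 1]` via [predict()]; labels use a 0.5 threshold.
#'
#' @param X training feature matrix (rows = patients).
#' @param y binary outcome vector (0/1).
#' @param algorithm_id one of [ml_algorithms()].
#' @param seed RNG seed (folds, stochastic learners).
#' @param folds number of CV folds.
#' @return Object of class `tavicap_model` with elements `algorithm_id`,
#'   `hyper`, `cv_accuracy` and the fitted learner.
#' @export
train_base <- function(X, y, algorithm_id, seed = 1, folds = 5) {
  reg <- .ml_registry()
  if (!algorithm_id %in% names(reg))
    stop("unknown algorithm id: ", algorithm_id)
  alg <- reg[[algorithm_id]]
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  .with_seed(.derive_seed(seed, 21L), {
    fold <- .stratified_folds(y, folds)
    acc <- vapply(alg$grid, function(h) {
      mean(vapply(seq_len(folds), function(f) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) return(NA_real_)
        m <- alg$fit(X[tr, , drop = FALSE], y[tr], h, seed)
        s <- alg$score(m, X[!tr, , drop = FALSE])
        mean((s >= 0.5) == y[!tr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best <- which.max(acc)  # first grid point wins ties
    fit <- alg$fit(X, y, alg$grid[[best]], seed)
    structure(list(algorithm_id = algorithm_id, label = alg$label,
                   hyper = alg$grid[[best]], cv_accuracy = acc[best],
                   fit = fit, score_fun = alg$score),
              class = "tavicap_model")
  })
}

#' @export
predict.tavicap_model <- function(object, newdata, ...) {
  as.numeric(object$score_fun(object$fit, newdata))
}

#' Homogeneous bagging ensemble
#'
#' Bootstrap aggregation of one base algorithm: hyperparameters are tuned
#' once by cross-validation on the training set, then `B` members are
#' fitted on bootstrap resamples (resampled if single-class). The ensemble
#' score is the mean of member scores; labels use the 0.5 threshold.
#'
#' @inheritParams train_base
#' @param B number of bootstrap members.
#' @param bootstrap set to FALSE (with `B = 1`) to recover the plain base
#'   classifier (degenerate ensemble).
#' @return Object of class `tavicap_ensemble`.
#' @export
ensemble_bagging <- function(X, y, algorithm_id, seed = 1, B = 50,
                             folds = 5, bootstrap = TRUE) {
  base <- train_base(X, y, algorithm_id, seed = seed, folds = folds)
  reg <- .ml_registry()[[algorithm_id]]
  n <- nrow(X)
  .with_seed(.derive_seed(seed, 31L), {
    members <- lapply(seq_len(B), function(b) {
      idx <- if (bootstrap) {
        repeat {
          i <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[i])) == 2L) break
        }
        i
      } else seq_len(n)
      reg$fit(X[idx, , drop = FALSE], y[idx], base$hyper, seed + b)
    })
    structure(list(algorithm_id = algorithm_id,
                   label = paste("Bagging:", base$label),
                   hyper = base$hyper, cv_accuracy = base$cv_accuracy,
                   members = members, score_fun = reg$score),
              class = "tavicap_ensemble")
  })
}

#' @export
predict.tavicap_ensemble <- function(object, newdata, ...) {
  s <- vapply(object$members, function(m)
    as.numeric(object$score_fun(m, newdata)), numeric(nrow(newdata)))
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  rowMeans(s)
}

#' Mixed voting ensemble
#'
#' Unweighted majority vote over the labels of two or more fitted
#' classifiers; ties are broken toward the positive (CA) class. The
#' continuous score is the fraction of positive votes.
#'
#' @param models list of fitted classifiers (>= 2).
#' @return Object of class `tavicap_voting`.
#' @export
ensemble_voting <- function(models) {
  if (length(models) < 2L) stop("voting needs at least 2 fitted classifiers")
  structure(list(models = models, label = "Voting ensemble",
                 cv_accuracy = NA_real_),
            class = "tavicap_voting")
}

#' @export
predict.tavicap_voting <- function(object, newdata, ...) {
  v <- vapply(object$models, function(m)
    as.numeric(predict(m, newdata) >= 0.5), numeric(nrow(newdata)))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  rowMeans(v)  # score >= 0.5 iff at least half vote positive (tie -> positive)
}

# ------------------------------------------------------------- evaluation

#' AUC by the Mann--Whitney normalisation
#'
#' @param scores numeric scores.
#' @param y binary labels.
#' @return AUC in `[0, 1]` (ties counted 1/2).
#' @export
auc_mann_whitney <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve over score thresholds
#'
#' @inheritParams auc_mann_whitney
#' @return Data frame with `threshold`, `fpr`, `tpr` (including the (0,0)
#'   and (1,1) endpoints).
#' @export
roc_curve <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yy == 1); fp <- cumsum(yy == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / max(1, sum(y == 0))),
             tpr = c(0, tp[last] / max(1, sum(y == 1))))
}

.auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' F1 score as the harmonic mean of PPV and sensitivity
#'
#' @param ppv positive predictive value.
#' @param sensitivity sensitivity (recall).
#' @return F1 score (NA when undefined).
#' @export
f1_score <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity) || ppv + sensitivity == 0)
    return(NA_real_)
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' Classification metrics from confusion counts
#'
#' @param tp,fp,tn,fn confusion counts at the 0.5 label threshold.
#' @return Named list: counts plus accuracy, sensitivity, specificity, PPV,
#'   NPV and F1 (NA where the denominator is zero).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); ppv <- div(tp, tp + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = div(tp + tn, tp + fp + tn + fn),
       sensitivity = sens, specificity = div(tn, tn + fp),
       ppv = ppv, npv = div(tn, tn + fn),
       f1 = f1_score(ppv, sens))
}

#' Evaluate a fitted classifier on a validation set
#'
#' Computes confusion counts at the 0.5 score threshold, the derived
#' metrics, the ROC curve, the trapezoid AUC, and a stratified percentile
#' bootstrap 95\% CI for the AUC.
#'
#' @param model fitted classifier (base, bagging or voting).
#' @param X validation feature matrix.
#' @param y validation labels (both classes must be present).
#' @param n_boot bootstrap resamples for the AUC CI (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `evaluation_report`.
#' @export
evaluate <- function(model, X, y, n_boot = 2000, seed = 1) {
  if (length(unique(y)) < 2L)
    stop("validation set must contain both classes; metrics undefined")
  scores <- predict(model, X)
  pred <- as.integer(scores >= 0.5)
  cm <- confusion_metrics(tp = sum(pred == 1 & y == 1),
                          fp = sum(pred == 1 & y == 0),
                          tn = sum(pred == 0 & y == 0),
                          fn = sum(pred == 0 & y == 1))
  roc <- roc_curve(scores, y)
  auc <- .auc_trapezoid(roc)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    i1 <- which(y == 1); i0 <- which(y == 0)
    ci <- .with_seed(.derive_seed(seed, 41L), {
      b <- vapply(seq_len(n_boot), function(k) {
        ii <- c(sample(i1, length(i1), replace = TRUE),
                sample(i0, length(i0), replace = TRUE))
        auc_mann_whitney(scores[ii], y[ii])
      }, numeric(1))
      unname(quantile(b, c(0.025, 0.975)))
    })
  }
  structure(c(cm, list(auc = auc, auc_ci = ci, roc = roc, scores = scores,
                       cv_accuracy = if (!is.null(model$cv_accuracy))
                         model$cv_accuracy else NA_real_,
                       label = if (!is.null(model$label)) model$label else NA)),
            class = "evaluation_report")
}

#' Select the best model by accuracy
#'
#' Highest validation accuracy wins; ties are broken by higher
#' cross-validated training accuracy, then higher AUC, then lexicographic
#' model id.
#'
#' @param reports named list of [evaluate()] reports.
#' @return The id (name) of the selected report.
#' @export
select_best <- function(reports) {
  stopifnot(length(reports) >= 1L)
  ids <- names(reports)
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  cva <- vapply(reports, function(r)
    if (is.null(r$cv_accuracy) || is.na(r$cv_accuracy)) -Inf else r$cv_accuracy,
    numeric(1))
  auc <- vapply(reports, function(r) r$auc, numeric(1))
  ids[order(-acc, -cva, -auc, ids)][1]
}

# ------------------------------------------------------------ full protocol

.report_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(model = id, label = r$label, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               ppv = r$ppv, npv = r$npv, f1 = r$f1, auc = r$auc,
               auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2])
  }))
}

.run_protocol <- function(cohort, outcome, seed, control) {
  ctl <- modifyList(list(B = 50, n_boot = 2000, folds = 5, ratio = 0.7,
                         screen_threshold = 0.9,
                         numeric_features = .ml_numeric_features,
                         split = NULL), control)
  sp <- if (is.null(ctl$split))
    split_cohort(cohort, ratio = ctl$ratio, seed = seed, outcome = outcome)
  else ctl$split
  fm <- preprocess(cohort, sp$train_ids,
                   numeric_features = ctl$numeric_features)
  retained <- correlation_screen(fm, threshold = ctl$screen_threshold)
  X <- fm$X[, retained, drop = FALSE]
  y <- cohort[[outcome]]
  Xtr <- X[sp$train_ids, , drop = FALSE]; ytr <- y[sp$train_ids]
  Xva <- X[sp$validation_ids, , drop = FALSE]; yva <- y[sp$validation_ids]

  algs <- ml_algorithms()
  bases <- list(); reports <- list()
  for (i in seq_along(algs)) {
    id <- algs[i]
    bases[[id]] <- train_base(Xtr, ytr, id, seed = .derive_seed(seed, 50 + i),
                              folds = ctl$folds)
    reports[[paste0("base_", id)]] <-
      evaluate(bases[[id]], Xva, yva, n_boot = ctl$n_boot, seed = seed)
  }
  for (i in seq_along(algs)) {
    id <- algs[i]
    bag <- ensemble_bagging(Xtr, ytr, id, seed = .derive_seed(seed, 70 + i),
                            B = ctl$B, folds = ctl$folds)
    reports[[paste0("bagging_", id)]] <-
      evaluate(bag, Xva, yva, n_boot = ctl$n_boot, seed = seed)
  }
  vote <- ensemble_voting(bases)
  reports[["voting"]] <- evaluate(vote, Xva, yva, n_boot = ctl$n_boot,
                                  seed = seed)
  best <- select_best(reports)
  tab <- .report_table(reports)
  tab <- tab[order(-tab$accuracy, -tab$auc), ]
  structure(list(selected = best, selected_report = reports[[best]],
                 reports = reports, top_models = head(tab, 4),
                 all_models = tab, retained_features = retained,
                 split = sp, outcome = outcome, seed = seed,
                 n = nrow(cohort)),
            class = "tavicap_analysis")
}

#' @export
print.tavicap_analysis <- function(x, ...) {
  cat("TAVI conduction-abnormality prediction protocol\n")
  cat(sprintf("  outcome: %s   n = %d (train %d / validation %d)\n",
              x$outcome, x$n, length(x$split$train_ids),
              length(x$split$validation_ids)))
  cat(sprintf("  selected model: %s (accuracy %.3f, AUC %.3f)\n",
              x$selected, x$selected_report$accuracy, x$selected_report$auc))
  cat("  top models:\n")
  tab <- x$top_models
  tab[, sapply(tab, is.numeric)] <- round(tab[, sapply(tab, is.numeric)], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the full prediction protocol on the composite CA outcome
#'
#' Preprocess, screen, split 70/30, train the eight tuned base classifiers,
#' their bagging ensembles and the mixed voting ensemble, evaluate all on
#' the held-out validation set, and select the most accurate model.
#'
#' @param cohort cohort data frame with the 8 model features and outcomes.
#' @param seed master RNG seed.
#' @param control optional list overriding protocol settings (`B`,
#'   `n_boot`, `folds`, `ratio`, `screen_threshold`).
#' @return Object of class `tavicap_analysis`: all evaluation reports, the
#'   selected model id and a publication-style table of the top 4 models.
#' @export
run_primary <- function(cohort, seed = 1, control = list()) {
  .run_protocol(cohort, outcome = "ca", seed = seed, control = control)
}

#' Ablation: drop the mechanistic features
#'
#' Re-runs the identical protocol with Cpmax and CPI removed (six features).
#' When `split` is supplied in `control`, the same train/validation
#' partition as the primary analysis is reused so the AUC difference is a
#' paired comparison.
#'
#' @inheritParams run_primary
#' @export
run_ablation <- function(cohort, seed = 1, control = list()) {
  control$numeric_features <- setdiff(.ml_numeric_features, c("cpmax", "cpi"))
  .run_protocol(cohort, outcome = "ca", seed = seed, control = control)
}

#' Sub-cohort analysis: L/RBBB only, PPI patients excluded
#'
#' Removes patients who received a permanent pacemaker, switches the
#' outcome to new L/RBBB, and re-runs the full protocol (models re-trained).
#'
#' @inheritParams run_primary
#' @export
run_subcohort_lbbb <- function(cohort, seed = 1, control = list()) {
  sub <- cohort[cohort$ppi == 0, , drop = FALSE]
  rownames(sub) <- NULL
  .run_protocol(sub, outcome = "lbbb_rbbb", seed = seed, control = control)
}
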