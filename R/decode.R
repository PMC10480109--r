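#' SVM configuration
#'
#' Radial-kernel soft-margin SVM with the study's fixed hyperparameters
#' `C = 1`, `gamma = 0.01`. Probability outputs (Platt sigmoid fitted on the
#' training decision values) are required by the online fusion engine.
#'
#' @param C soft-margin cost, > 0.
#' @param gamma RBF kernel width, > 0.
#' @param probability fit Platt probability calibration (default `TRUE`).
#' @param tol SMO stopping tolerance.
#' @param max_iter SMO iteration cap.
#' @export
svm_config <- function(C = 1, gamma = 0.01, probability = TRUE,
                       tol = 1e-3, max_iter = 200000L) {
  if (C <= 0 || gamma <= 0)
    abort_painbci("need C > 0 and gamma > 0", "painbci_validation_error")
  structure(list(C = C, gamma = gamma, probability = probability,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "bci_svm_config")
}

# Platt sigmoid fit, Lin & Weng's numerically stable Newton iteration.
# Targets are the usual (N+ + 1)/(N+ + 2), 1/(N- + 2) smoothing.
platt_fit <- function(f, y_pos) {
  prior1 <- sum(y_pos); prior0 <- length(y_pos) - prior1
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t_ <- ifelse(y_pos, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t_ * fApB + log1p(exp(-fApB)),
               (t_ - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(A, B)
  for (it in 1:100) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t_ - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= 1e-10) {
      nA <- A + step * dA; nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) {
        A <- nA; B <- nB; fv <- nf; break
      }
      step <- step / 2
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

platt_prob <- function(f, ab) {
  fApB <- ab[1] * f + ab[2]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Train a radial-kernel SVM
#'
#' One-vs-one machines over the observed classes, each solved by an SMO
#' dual solver; probability outputs via a Platt sigmoid per machine. The
#' fit is deterministic for fixed input order (no internal randomness), so
#' the `seed` is recorded only for provenance.
#'
#' @param x numeric feature matrix (rows = observations), already
#'   standardized.
#' @param y character/factor labels, at least two classes.
#' @param cfg an [svm_config()].
#' @param seed integer recorded in the model.
#' @return An object of class `rbf_svm`.
#' @export
train_svm <- function(x, y, cfg = svm_config(), seed = 0L) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    abort_painbci("need at least two classes to train",
                  "painbci_validation_error")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    xs <- x[sel, , drop = FALSE]
    yy <- ifelse(y[sel] == pr[1], 1L, -1L)  # first class of the pair is +1
    K <- .rbf_kernel_cpp(xs, xs, cfg$gamma)
    fit <- .svm_smo_cpp(K, yy, cfg$C, cfg$tol, cfg$max_iter)
    alpha <- fit$alpha
    svi <- which(alpha > 1e-8)
    coef <- alpha[svi] * yy[svi]
    m <- list(pos = pr[1], neg = pr[2], sv = xs[svi, , drop = FALSE],
              coef = coef, b = fit$b, platt = c(A = 0, B = 0))
    if (cfg$probability) {
      dec <- .rbf_decision_cpp(m$sv, m$coef, m$b, xs, cfg$gamma)
      m$platt <- platt_fit(dec, yy == 1L)
    }
    m
  })
  structure(list(machines = machines, classes = classes,
                 gamma = cfg$gamma, C = cfg$C,
                 probability = cfg$probability, seed = seed),
            class = "rbf_svm")
}

#' Predict from a trained RBF-SVM
#'
#' `type = "class"` returns labels (pairwise vote, ties broken by the
#' larger mean pairwise probability); `type = "prob"` returns a matrix of
#' class probabilities (Platt sigmoid for two classes; averaged pairwise
#' coupling, renormalized, for three).
#'
#' @param object an `rbf_svm`.
#' @param newdata feature matrix on the training standardization scale.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.rbf_svm <- function(object, newdata, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  k <- length(object$classes)
  n <- nrow(newdata)
  rsum <- matrix(0, n, k, dimnames = list(NULL, object$classes))
  votes <- matrix(0, n, k, dimnames = list(NULL, object$classes))
  for (m in object$machines) {
    dec <- .rbf_decision_cpp(m$sv, m$coef, m$b, newdata, object$gamma)
    pr <- platt_prob(dec, m$platt)
    rsum[, m$pos] <- rsum[, m$pos] + pr
    rsum[, m$neg] <- rsum[, m$neg] + (1 - pr)
    votes[, m$pos] <- votes[, m$pos] + (dec > 0)
    votes[, m$neg] <- votes[, m$neg] + (dec <= 0)
  }
  prob <- rsum / rowSums(rsum)
  if (type == "prob") return(prob)
  lab <- vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1) top <- top[which.max(prob[i, top])]
    object$classes[top]
  }, "")
  lab
}

#' Fit a per-column z-scaler on training rows
#'
#' Mean and SD per feature column, estimated on the training table only.
#' Constant columns (SD below 1e-12) get SD set to 1 with a warning, so
#' they standardize to zero rather than NaN.
#'
#' @param train a `bci_features` table (or plain feature matrix).
#' @export
zscore_fit <- function(train) {
  x <- if (inherits(train, "bci_features")) feature_matrix(train)
       else as.matrix(train)
  if (nrow(x) == 0)
    abort_painbci("training table is empty", "painbci_validation_error")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  const <- sdev < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant feature column(s); SD set to 1",
                    sum(const)))
    sdev[const] <- 1
  }
  list(mean = mu, sd = sdev, feature_names = colnames(x))
}

#' Apply a fitted z-scaler
#' @param scaler from [zscore_fit()].
#' @param tbl feature table or matrix with the same columns.
#' @return Standardized numeric matrix.
#' @export
zscore_apply <- function(scaler, tbl) {
  x <- if (inherits(tbl, "bci_features")) feature_matrix(tbl)
       else as.matrix(tbl)
  if (!identical(colnames(x), scaler$feature_names))
    abort_painbci("feature columns do not match the scaler",
                  "painbci_validation_error")
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Fit on train, standardize both tables
#' @param train,apply_to feature tables sharing the same columns.
#' @return `list(scaler, train, applied)` with standardized matrices.
#' @export
zscore_fit_apply <- function(train, apply_to = train) {
  scaler <- zscore_fit(train)
  list(scaler = scaler, train = zscore_apply(scaler, train),
       applied = zscore_apply(scaler, apply_to))
}

#' Stimulus-grouped k-fold assignment
#'
#' Groups (stimulus event ids), not windows, are shuffled with the seed and
#' dealt round-robin into `k` folds, so every window cut from one stimulus
#' shares a fold and overlapping windows never straddle the train/test
#' split.
#'
#' @param groups vector of group ids, one per observation window.
#' @param k number of folds.
#' @param seed integer shuffle seed.
#' @return Integer fold id (1..k) per observation; the group-level map is in
#'   attribute `group_folds`.
#' @export
grouped_kfold <- function(groups, k = 4, seed = 0L) {
  ug <- unique(groups)
  if (length(ug) < k)
    abort_painbci(sprintf("%d groups < %d folds", length(ug), k),
                  "painbci_validation_error")
  shuffled <- withr::with_seed(seed, sample(ug))
  gf <- rep_len(seq_len(k), length(shuffled))
  names(gf) <- as.character(shuffled)
  folds <- gf[as.character(groups)]
  attr(folds, "group_folds") <- gf
  folds
}

#' Classification metrics report
#'
#' Confusion counts (rows = true class), accuracy = trace/total, per-class
#' recall (row-wise) and precision (column-wise), and the row-normalized
#' confusion matrix. Pain recall is the ratio of correctly classified pain
#' samples to all pain samples; pain precision the ratio of correctly
#' classified pain to all pain classifications.
#'
#' @param y_true,y_pred label vectors.
#' @param class_set ordered class labels for the matrix layout.
#' @return A `bci_metrics` object.
#' @export
classification_metrics <- function(y_true, y_pred,
                                   class_set = sort(unique(c(y_true, y_pred)))) {
  y_true <- factor(y_true, levels = class_set)
  y_pred <- factor(y_pred, levels = class_set)
  confusion <- table(true = y_true, predicted = y_pred)
  total <- sum(confusion)
  acc <- if (total > 0) sum(diag(confusion)) / total else NA_real_
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / colSums(confusion)
  rn <- sweep(confusion, 1, rowSums(confusion), "/")
  structure(list(confusion = unclass(confusion), accuracy = acc,
                 recall = recall, precision = precision,
                 row_normalized = unclass(rn), classes = class_set),
            class = "bci_metrics")
}

#' @export
print.bci_metrics <- function(x, ...) {
  cat(sprintf("<bci_metrics> accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  cat("recall:   ", paste(sprintf("%s %.3f", x$classes, x$recall),
                          collapse = "  "), "\n")
  cat("precision:", paste(sprintf("%s %.3f", x$classes, x$precision),
                          collapse = "  "), "\n")
  invisible(x)
}

#' Cross-validation plan
#' @param k folds (default 4).
#' @param seed fold shuffle seed.
#' @param classes class set: `c("P","R")` or `c("P","NP","R")`.
#' @export
cv_plan <- function(k = 4, seed = 0L, classes = c("P", "R")) {
  structure(list(k = k, seed = seed, classes = classes), class = "bci_cv_plan")
}

#' Stimulus-grouped cross-validation of an SVM decoder
#'
#' Restricts the feature table to the plan's classes, assigns stimulus
#' groups to folds with [grouped_kfold()], and per fold standardizes on the
#' training split, trains the SVM and predicts the held-out windows.
#' Confusion counts are summed over folds.
#'
#' @param ft a `bci_features` table.
#' @param plan a [cv_plan()].
#' @param cfg an [svm_config()].
#' @param grouped set `FALSE` to fold at window level (leaks overlapping
#'   windows across the split; provided to demonstrate the inflation).
#' @return A `bci_metrics` report; per-fold reports in `$folds`.
#' @export
cross_validate <- function(ft, plan = cv_plan(), cfg = svm_config(),
                           grouped = TRUE) {
  keep <- ft$label %in% plan$classes
  ft <- ft[keep, , drop = FALSE]
  attr(ft, "feature_names") <- feature_names(ft) %||%
    setdiff(names(ft), c("window_id", "event_id", "label"))
  x <- feature_matrix(ft)
  y <- ft$label
  folds <- if (grouped) grouped_kfold(ft$event_id, plan$k, plan$seed)
           else withr::with_seed(plan$seed,
                                 sample(rep_len(seq_len(plan$k), nrow(ft))))
  y_pred <- character(length(y))
  fold_reports <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    tr <- folds != f
    sc <- zscore_fit(x[tr, , drop = FALSE])
    xtr <- zscore_apply(sc, x[tr, , drop = FALSE])
    xte <- zscore_apply(sc, x[!tr, , drop = FALSE])
    model <- train_svm(xtr, y[tr], cfg, seed = plan$seed)
    y_pred[!tr] <- predict(model, xte, type = "class")
    fold_reports[[f]] <- classification_metrics(y[!tr], y_pred[!tr],
                                                plan$classes)
  }
  rep_ <- classification_metrics(y, y_pred, plan$classes)
  rep_$folds <- fold_reports
  rep_
}

#' Train a deployable decoder from a feature table
#'
#' Fits the z-scaler on all rows of the given classes, trains the SVM on
#' the standardized features, and bundles everything the online engine
#' needs: scaler, model, class set, modality, feature names and the window
#' spec the decoder expects.
#'
#' @param ft a `bci_features` table.
#' @param classes class set to train on.
#' @param cfg an [svm_config()].
#' @param modality `"EEG"` or `"SC"`.
#' @param wspec the [window_spec()] the features were extracted with.
#' @param fspec the [filter_spec()] of the preprocessing path.
#' @param fs sampling rate of the decoder's input chunks.
#' @param seed provenance seed.
#' @return A `bci_decoder`.
#' @export
train_decoder <- function(ft, classes = c("P", "R"), cfg = svm_config(),
                          modality = c("EEG", "SC"), wspec = NULL,
                          fspec = NULL, fs = NULL, seed = 0L) {
  modality <- match.arg(modality)
  wspec <- wspec %||%
    if (modality == "EEG") eeg_window_spec() else sc_window_spec()
  fspec <- fspec %||%
    if (modality == "EEG") eeg_filter_spec() else sc_filter_spec()
  fs <- fs %||% if (modality == "EEG") 500 else 5
  keep <- ft$label %in% classes
  ft <- ft[keep, , drop = FALSE]
  attr(ft, "feature_names") <- feature_names(ft) %||%
    setdiff(names(ft), c("window_id", "event_id", "label"))
  z <- zscore_fit_apply(ft)
  model <- train_svm(z$train, ft$label, cfg, seed = seed)
  structure(list(scaler = z$scaler, svm = model, classes = model$classes,
                 modality = modality, feature_names = z$scaler$feature_names,
                 window_spec = unclass(wspec), filter_spec = unclass(fspec),
                 fs = fs,
                 meta = list(svm_config = unclass(cfg), seed = seed)),
            class = "bci_decoder")
}
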