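# Classifier heads on the selected features, confusion-matrix metrics,
# and stratified k-fold cross-validation with per-fold refitting of the
# entropy selector (no train/test leakage).

.LEVELS <- c("melanoma", "non_melanoma")

#' Classifier head specification
#'
#' The default head is L2-regularized (ridge) logistic regression
#' (\pkg{glmnet}): deterministic, fast at the 1280-feature width, and the
#' L2 penalty controls overfitting on desk-scale sample sizes. Pluggable
#' alternatives: a single-hidden-layer dense network (\code{"mlp"},
#' \pkg{nnet}, practical only at modest feature widths since its BFGS
#' optimizer is quadratic in the weight count), decision tree, random
#' forest, k-nearest-neighbors and SVM.
#'
#' @param type one of \code{"glmnet"}, \code{"mlp"}, \code{"dt"},
#'   \code{"rf"}, \code{"knn"}, \code{"svm"}.
#' @param lambda ridge penalty (glmnet).
#' @param hidden hidden units (mlp).
#' @param decay L2 weight decay (mlp).
#' @param maxit training iterations (mlp).
#' @param kNeighbors neighbors (knn).
#' @return a \code{headSpec} list.
#' @export
headSpec <- function(type = c("glmnet", "mlp", "dt", "rf", "knn", "svm"),
                     lambda = 0.01, hidden = 8L, decay = 1e-2,
                     maxit = 200L, kNeighbors = 5L) {
  type <- match.arg(type)
  structure(list(type = type, lambda = lambda, hidden = as.integer(hidden),
                 decay = decay, maxit = as.integer(maxit),
                 kNeighbors = as.integer(kNeighbors)),
            class = "headSpec")
}

needsPkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("head requires the '", pkg, "' package")
}

#' Train a classifier head
#'
#' Standardizes features with training-set center/scale and fits the head
#' described by \code{spec}; training is deterministic under \code{seed}.
#'
#' @param features numeric matrix (samples x features), >= 10 rows.
#' @param labels character/factor labels in \code{melanoma},
#'   \code{non_melanoma}; both classes must be present.
#' @param spec a [headSpec].
#' @param seed integer training seed.
#' @return a [DermoHead-class].
#' @export
trainHead <- function(features, labels, spec = headSpec(), seed = 1L) {
  if (!is.matrix(features) || nrow(features) < 10L)
    stop("need a feature matrix with at least 10 samples")
  labels <- as.character(labels)
  if (!all(labels %in% .LEVELS))
    stop("labels must be 'melanoma' or 'non_melanoma'")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training data")
  if (length(labels) != nrow(features))
    stop("labels and features disagree in length")
  ctr <- colMeans(features)
  scl <- apply(features, 2L, sd)
  scl[scl < 1e-12] <- 1
  xs <- scale(features, center = ctr, scale = scl)
  y <- factor(labels, levels = .LEVELS)
  fit <- withSeed(seed, switch(spec$type,
    glmnet = glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                            lambda = spec$lambda),
    mlp = {
      needsPkg("nnet")
      nw <- (ncol(xs) + 1L) * spec$hidden + (spec$hidden + 1L)
      nnet::nnet(xs, as.integer(y == "melanoma"), size = spec$hidden,
                 decay = spec$decay, maxit = spec$maxit, entropy = TRUE,
                 MaxNWts = nw + 10L, trace = FALSE)
    },
    dt = {
      needsPkg("rpart")
      df <- cbind(data.frame(y = y), as.data.frame(xs))
      rpart::rpart(y ~ ., data = df, method = "class")
    },
    rf = {
      needsPkg("randomForest")
      randomForest::randomForest(xs, y, ntree = 200L)
    },
    knn = {
      needsPkg("class")
      list(train = xs, y = y, k = spec$kNeighbors)
    },
    svm = {
      needsPkg("e1071")
      e1071::svm(xs, y, kernel = "radial")
    }))
  new("DermoHead", type = spec$type, fit = fit, levels = .LEVELS,
      center = ctr, scale = scl, seed = as.integer(seed))
}

#' @describeIn trainHead predict labels for new samples; applies the
#'   stored training standardization first.
#' @param x a trained [DermoHead-class].
#' @param m feature matrix with the training dimensionality.
#' @export
setMethod("predictHead", "DermoHead", function(x, m) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  if (ncol(m) != length(x@center)) stop("feature dimension mismatch")
  xs <- scale(m, center = x@center, scale = x@scale)
  pred <- switch(x@type,
    glmnet = as.character(predict(x@fit, xs, type = "class")),
    mlp = ifelse(as.numeric(predict(x@fit, xs)) >= 0.5,
                 "melanoma", "non_melanoma"),
    dt = as.character(predict(x@fit, as.data.frame(xs), type = "class")),
    rf = as.character(predict(x@fit, xs)),
    knn = as.character(class::knn(x@fit$train, xs, x@fit$y, k = x@fit$k)),
    svm = as.character(predict(x@fit, xs)))
  factor(pred, levels = x@levels)
})

#' Confusion matrix with melanoma as the positive class
#'
#' @param predictions,labels vectors over \code{melanoma},
#'   \code{non_melanoma}, equal length.
#' @return a [ConfusionMatrix-class].
#' @export
confusionCounts <- function(predictions, labels) {
  p <- as.character(predictions); t <- as.character(labels)
  if (length(p) != length(t)) stop("predictions and labels differ in length")
  if (!all(c(p, t) %in% .LEVELS))
    stop("labels must be 'melanoma' or 'non_melanoma'")
  new("ConfusionMatrix",
      tp = sum(p == "melanoma" & t == "melanoma"),
      fn = sum(p == "non_melanoma" & t == "melanoma"),
      fp = sum(p == "melanoma" & t == "non_melanoma"),
      tn = sum(p == "non_melanoma" & t == "non_melanoma"))
}

#' @describeIn confusionCounts build a [ConfusionMatrix-class] directly
#'   from the four counts.
#' @param tp,fn,fp,tn nonnegative integer counts.
#' @export
confusionFromCounts <- function(tp, fn, fp, tn) {
  new("ConfusionMatrix", tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Accuracy, sensitivity, specificity and precision
#'
#' \code{ACC = (TP+TN)/(TP+TN+FP+FN)}, \code{SEN = TP/(TP+FN)},
#' \code{SPEC = TN/(TN+FP)}, \code{PREC = TP/(TP+FP)}. A metric whose
#' denominator is zero is reported as \code{NA} (undefined); an all-zero
#' matrix is an error.
#'
#' @param x a [ConfusionMatrix-class].
#' @param ... unused.
#' @return named numeric vector \code{accuracy, sensitivity, specificity,
#'   precision}.
#' @export
setMethod("classMetrics", "ConfusionMatrix", function(x, ...) {
  tot <- x@tp + x@fn + x@fp + x@tn
  if (tot == 0) stop("empty confusion matrix")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = (x@tp + x@tn) / tot,
    sensitivity = rat(x@tp, x@tp + x@fn),
    specificity = rat(x@tn, x@tn + x@fp),
    precision = rat(x@tp, x@tp + x@fp))
})

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..k) per sample; each class is spread as
#'   evenly as possible across folds.
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < k) stop("need at least k samples")
  fold <- integer(n)
  withSeed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' Stratified k-fold cross-validation of the select-then-classify stage
#'
#' For each fold the entropy selector is refitted on the training portion
#' only, the head is trained on the selected training features, and the
#' held-out fold is predicted — every sample is tested exactly once and
#' nothing from a test fold influences its fold's selector or head.
#'
#' @param features fused feature matrix (samples x features, typically
#'   7948 columns).
#' @param labels class labels, both classes present.
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment and head training).
#' @param kSelect selector size (default 1280; capped at the dimension).
#' @param nBins selector histogram bins.
#' @param head a [headSpec].
#' @return list with \code{folds} (assignment), \code{perFold}
#'   (data.frame of per-fold metrics), \code{mean} (mean of the per-fold
#'   metrics), \code{confusion} (pooled [ConfusionMatrix-class]),
#'   \code{selectorChecksums} (per-fold sum of selected indices, a
#'   leakage witness).
#' @export
kfoldCV <- function(features, labels, k = 5L, seed = 1L, kSelect = 1280L,
                    nBins = 10L, head = headSpec()) {
  labels <- as.character(labels)
  if (nrow(features) < k) stop("need at least k samples")
  kSelect <- min(kSelect, ncol(features))
  fold <- stratifiedFolds(labels, k, seed)
  perFold <- vector("list", k)
  pooled <- factor(rep(NA_character_, length(labels)), levels = .LEVELS)
  checks <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L)
      stop("fold ", f, " lost a class; reduce k or add samples")
    sel <- fitEntropySelector(features[tr, , drop = FALSE], k = kSelect,
                              nBins = nBins)
    model <- trainHead(applySelector(sel, features[tr, , drop = FALSE]),
                       labels[tr], spec = head,
                       seed = deriveSeed(seed, 300L + f))
    pred <- predictHead(model, applySelector(sel,
                                             features[!tr, , drop = FALSE]))
    pooled[!tr] <- pred
    cm <- confusionCounts(pred, labels[!tr])
    perFold[[f]] <- data.frame(fold = f, t(classMetrics(cm)))
    checks[f] <- sum(selectedIndices(sel))
  }
  perFold <- do.call(rbind, perFold)
  list(folds = fold, perFold = perFold,
       mean = colMeans(perFold[, -1L, drop = FALSE]),
       confusion = confusionCounts(pooled, labels),
       selectorChecksums = checks)
}

#' Stratified train/test split
#'
#' @param labels class labels.
#' @param trainFraction fraction per class assigned to training
#'   (default 0.7, the conventional 70/30 split).
#' @param seed integer seed.
#' @return logical vector, \code{TRUE} for training samples.
#' @export
trainTestSplit <- function(labels, trainFraction = 0.7, seed = 1L) {
  labels <- as.character(labels)
  tr <- logical(length(labels))
  withSeed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    tr[idx[seq_len(ceiling(length(idx) * trainFraction))]] <- TRUE
  })
  tr
}
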