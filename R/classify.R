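## Class-weighted linear SVM, confusion metrics, the sensitivity x
## specificity balance metric, repeated stratified k-fold cross-validation,
## the class-weight sweep and the hyperparameter grid search.

# run expr with a private RNG stream; the caller's .Random.seed is untouched
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Fit a class-weighted linear SVM
#'
#' Linear decision function minimising the L2-regularised hinge loss with
#' per-class misclassification penalties \code{weights[y] * cost} (libsvm
#' C-classification via \pkg{e1071}). The orientation of the decision
#' values relative to the two labels is recorded at fit time so prediction
#' is unambiguous.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels binary labels in \{0, 1\} (1 = abnormal = positive class).
#' @param weights named numeric vector of per-class weights, names "0" and
#'   "1"; both > 0.
#' @param cost SVM cost parameter C.
#' @return an object of class \code{"weightedLinearSVM"}.
#' @export
fitWeightedLinearSvm <- function(features, labels,
                                 weights = c("0" = 1, "1" = 1), cost = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training labels")
  if (nrow(features) != length(labels))
    stop("feature rows and labels differ in length")
  if (any(weights <= 0)) stop("class weights must be > 0")
  y <- factor(labels, levels = c(0L, 1L))
  m <- e1071::svm(x = features, y = y, kernel = "linear", cost = cost,
                  class.weights = weights[levels(y)], scale = FALSE)
  # libsvm's decision value is positive for the first internally ordered
  # class; read that orientation off a training prediction, then collapse
  # the support-vector expansion to an explicit weight vector oriented so
  # that a positive decision value means the abnormal class (label 1)
  dv <- attr(stats::predict(m, features[1L, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  posLabel <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  w <- as.numeric(crossprod(m$coefs, m$SV))
  b <- -m$rho
  if (posLabel != "1") { w <- -w; b <- -b }
  structure(list(svm = m, w = w, b = b, dim = ncol(features)),
            class = "weightedLinearSVM")
}

#' Predict binary labels from a fitted weighted linear SVM
#'
#' Maps the sign of the decision function to \{0, 1\}; a decision value of
#' exactly 0 is assigned to the positive (abnormal, label 1) class.
#'
#' @param object a \code{"weightedLinearSVM"} fit.
#' @param newdata numeric matrix with the training dimensionality.
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
predict.weightedLinearSVM <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$dim)
    stop("feature dimension does not match the trained model")
  d <- as.numeric(newdata %*% object$w) + object$b
  as.integer(d >= 0)
}

#' Write / read a fitted linear SVM as flat text
#'
#' One metadata line (feature dimension and bias) followed by the weight
#' vector, one entry per line. The stored decision function is already
#' oriented so that positive values mean the abnormal class.
#'
#' @param model a \code{"weightedLinearSVM"} fit.
#' @param path output text file.
#' @return \code{writeSvmModel} returns \code{path} invisibly;
#'   \code{readSvmModel} returns a \code{"weightedLinearSVM"} usable with
#'   \code{predict}.
#' @export
writeSvmModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# weightedLinearSVM dim=%d", model$dim),
               sprintf("bias %s", format(model$b, digits = 17)),
               format(model$w, digits = 17)), con)
  invisible(path)
}

#' @rdname writeSvmModel
#' @export
readSvmModel <- function(path) {
  lines <- readLines(path)
  dim <- as.integer(sub(".*dim=", "", lines[1L]))
  b <- as.numeric(sub("^bias ", "", lines[2L]))
  w <- as.numeric(lines[-(1:2)])
  if (length(w) != dim) stop("corrupt model file: ", path)
  structure(list(svm = NULL, w = w, b = b, dim = dim),
            class = "weightedLinearSVM")
}

#' Confusion counts for binary predictions
#'
#' @param yTrue,yPred equal-length binary label vectors.
#' @param positive the positive-class label (default 1 = abnormal).
#' @return named list with TP, TN, FP, FN and the positive label.
#' @export
confusionCounts <- function(yTrue, yPred, positive = 1L) {
  if (length(yTrue) != length(yPred))
    stop("label vectors differ in length")
  p <- yTrue == positive
  list(TP = sum(p & yPred == positive),
       TN = sum(!p & yPred != positive),
       FP = sum(!p & yPred == positive),
       FN = sum(p & yPred != positive),
       positive = positive)
}

#' Confusion-derived performance metrics
#'
#' ACC = (TP+TN)/(TP+FN+FP+TN), SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), F1 = 2TP/(2TP+FP+FN), and the
#' balance metric g of SEN and SPE. A metric whose denominator is zero is
#' reported as NA, never silently 0.
#'
#' @param counts value of \code{\link{confusionCounts}}.
#' @param gMode balance-metric mode, \code{"product"} (default) or
#'   \code{"sqrt"}; see \code{\link{balanceMetric}}.
#' @return one-row data.frame with columns acc, sen, spe, ppv, npv, f1, g
#'   and the four counts.
#' @export
computeMetrics <- function(counts, gMode = "product") {
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, {
    acc <- sdiv(TP + TN, TP + FN + FP + TN)
    sen <- sdiv(TP, TP + FN)
    spe <- sdiv(TN, TN + FP)
    ppv <- sdiv(TP, TP + FP)
    npv <- sdiv(TN, TN + FN)
    f1  <- sdiv(2 * TP, 2 * TP + FP + FN)
    g <- if (is.na(sen) || is.na(spe)) NA_real_
         else balanceMetric(sen, spe, mode = gMode)
    data.frame(acc = acc, sen = sen, spe = spe, ppv = ppv, npv = npv,
               f1 = f1, g = g, TP = TP, TN = TN, FP = FP, FN = FN)
  })
}

#' Balance metric of sensitivity and specificity
#'
#' Combines the two class recalls of an imbalanced problem into one score.
#' Mode \code{"product"} returns sen * spe; mode \code{"sqrt"} returns
#' sqrt(sen * spe), the usual g-mean. Product is the default because it is
#' what the reference class-weight tables tabulate under that name.
#'
#' @param sen,spe fractions in [0, 1].
#' @param mode \code{"product"} or \code{"sqrt"}.
#' @return a fraction in [0, 1].
#' @export
#' @examples
#' balanceMetric(0.9426, 0.7540)           # 0.7107...
#' balanceMetric(0.9426, 0.7540, "sqrt")
balanceMetric <- function(sen, spe, mode = c("product", "sqrt")) {
  mode <- match.arg(mode)
  if (any(c(sen, spe) < 0) || any(c(sen, spe) > 1))
    stop("'sen' and 'spe' must lie in [0, 1]")
  if (mode == "product") sen * spe else sqrt(sen * spe)
}

# fold ids for one repeat: per-class seeded shuffle, remainders assigned
# to the currently lightest folds so total fold sizes stay balanced
makeFolds <- function(labels, k, stratified, seed) {
  n <- length(labels)
  fold <- integer(n)
  withSeed(seed, {
    if (stratified) {
      load <- integer(k)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k)
          stop("class ", cl, " has fewer members (", length(idx),
               ") than folds (", k, ")")
        idx <- sample(idx)
        sizes <- rep.int(length(idx) %/% k, k)
        extra <- length(idx) - sum(sizes)
        if (extra > 0) {
          lightest <- order(load, seq_len(k))[seq_len(extra)]
          sizes[lightest] <- sizes[lightest] + 1L
        }
        fold[idx] <- rep.int(seq_len(k), sizes)
        load <- load + sizes
      }
    } else {
      if (n < k) stop("fewer samples than folds")
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation of the weighted SVM
#'
#' For each repeat, samples are shuffled (seeded) and split into k
#' stratified folds; the SVM is fit on k-1 folds with the configured class
#' weights and evaluated on the held-out fold. Metrics are averaged over
#' all k * repeats fold evaluations (undefined fold metrics are dropped
#' from their average).
#'
#' @param features numeric matrix, one row per sample.
#' @param labels binary labels in \{0, 1\}.
#' @param config a \code{\linkS4class{CVConfig}}.
#' @param gMode balance-metric mode passed to \code{\link{computeMetrics}}.
#' @return list with \code{average} (one-row data.frame) and \code{folds}
#'   (one row per fold evaluation, with repeat/fold provenance).
#' @export
crossValidate <- function(features, labels, config = cvConfig(),
                          gMode = "product") {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  minority <- as.integer(names(tab)[which.min(tab)])
  w <- c("0" = config@wMajority, "1" = config@wMajority)
  w[as.character(minority)] <- config@wMinority
  rows <- vector("list", config@k * config@repeats)
  i <- 0L
  for (r in seq_len(config@repeats)) {
    fold <- makeFolds(labels, config@k, config@stratified,
                      seed = config@seed + 1000L * (r - 1L))
    for (f in seq_len(config@k)) {
      test <- fold == f
      fit <- fitWeightedLinearSvm(features[!test, , drop = FALSE],
                                  labels[!test], weights = w,
                                  cost = config@cost)
      pred <- predict(fit, features[test, , drop = FALSE])
      mr <- computeMetrics(confusionCounts(labels[test], pred),
                           gMode = gMode)
      i <- i + 1L
      rows[[i]] <- cbind(data.frame(repeatIdx = r, fold = f), mr)
    }
  }
  folds <- do.call(rbind, rows)
  metricCols <- c("acc", "sen", "spe", "ppv", "npv", "f1", "g")
  avg <- as.data.frame(lapply(folds[metricCols], mean, na.rm = TRUE))
  avg$wMinority <- config@wMinority
  avg$wMajority <- config@wMajority
  list(average = avg, folds = folds)
}

#' Class-weight sweep
#'
#' Re-runs the cross-validation with the minority-class weight set to each
#' value in \code{weights} (majority weight fixed at 1) and tabulates the
#' averaged ACC / SEN / SPE / g per weight. The row with the best balance
#' metric is flagged.
#'
#' @param features,labels as in \code{\link{crossValidate}}.
#' @param weights integer minority-class weights to try (default 1:9).
#' @param config a \code{\linkS4class{CVConfig}}; its \code{wMinority} is
#'   overridden by the sweep.
#' @param gMode balance-metric mode.
#' @return data.frame with one row per weight and a logical \code{best}
#'   column.
#' @export
weightSweep <- function(features, labels, weights = 1:9,
                        config = cvConfig(), gMode = "product") {
  rows <- lapply(weights, function(w) {
    cfg <- config
    cfg@wMinority <- as.numeric(w)
    cfg@wMajority <- 1
    cbind(data.frame(weight = w),
          crossValidate(features, labels, cfg, gMode = gMode)$average)
  })
  out <- do.call(rbind, rows)
  out$best <- FALSE
  out$best[which.max(out$g)] <- TRUE
  out
}

#' Default hyperparameter grids
#'
#' The printed search ranges: eps over decades 1e-10..1, a in \{0, 1\},
#' gamma 0..10 step 2, alpha over decades 1e-6..1e2, beta 0..1 step 0.25,
#' sigma = 315 t / 84 for t in \{0.59, 0.60\}, and the LRN window n on an
#' integer grid (1..9 here; only the step, not the range, is prescribed).
#'
#' @return named list of numeric grids.
#' @export
defaultHyperGrids <- function() {
  list(eps = 10^seq(-10, 0), a = c(0, 1), gamma = seq(0, 10, by = 2),
       alpha = 10^seq(-6, 2), beta = seq(0, 1, by = 0.25),
       sigma = 315 * c(0.59, 0.60) / 84, nLrn = 1:9)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every point of the Cartesian grid on a stratified validation
#' split of the supplied training subset: features are recomputed per
#' point by \code{trainFeaturesFn}, a weighted linear SVM is fit on the
#' training part and the objective is measured on the validation part.
#' Ties keep the first point in grid order (grids expand with the first
#' named grid varying fastest).
#'
#' @param trainFeaturesFn function(params) returning the feature matrix of
#'   the training subset under hyperparameters \code{params}.
#' @param trainLabels binary labels of that subset.
#' @param grids named list of grids over any of eps, a, gamma, alpha,
#'   beta, sigma, nLrn (missing ones stay at the \code{baseParams} value).
#' @param baseParams \code{\linkS4class{NetParams}} supplying every field
#'   not in \code{grids}.
#' @param objective function(metricsRow) returning the score to maximise;
#'   default is the balance metric g (NA scored as -Inf).
#' @param weights,cost SVM weighting and cost used during the search.
#' @param valFraction fraction of the subset held out for validation.
#' @param seed seed of the stratified split.
#' @return list with \code{params} (the winning \code{NetParams}) and
#'   \code{scores} (data.frame of all grid points and their objectives).
#' @export
gridSearchHyperParams <- function(trainFeaturesFn, trainLabels,
                                  grids = defaultHyperGrids(),
                                  baseParams = netParams(),
                                  objective = function(m) m$g,
                                  weights = c("0" = 1, "1" = 1), cost = 1,
                                  valFraction = 0.25, seed = 1) {
  if (length(grids) == 0L || any(lengths(grids) == 0L))
    stop("empty hyperparameter grid")
  bad <- setdiff(names(grids),
                 c("eps", "a", "gamma", "alpha", "beta", "sigma", "nLrn"))
  if (length(bad)) stop("unknown grid dimensions: ",
                        paste(bad, collapse = ", "))
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  trainLabels <- as.integer(trainLabels)
  # one stratified validation split shared by every grid point
  val <- logical(length(trainLabels))
  withSeed(seed, for (cl in unique(trainLabels)) {
    idx <- which(trainLabels == cl)
    nv <- max(1L, round(valFraction * length(idx)))
    if (nv >= length(idx))
      stop("class ", cl, " too small for a validation split")
    val[sample(idx, nv)] <- TRUE
  })
  setHp <- function(params, row) {
    for (nm in names(grids)) {
      val <- grid[[nm]][row]
      if (nm %in% c("a", "nLrn")) val <- as.integer(val)
      slot(params, nm) <- val
    }
    validObject(params)
    params
  }
  best <- -Inf; bestRow <- 1L
  scores <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- setHp(baseParams, r)
    X <- trainFeaturesFn(p)
    fit <- fitWeightedLinearSvm(X[!val, , drop = FALSE], trainLabels[!val],
                                weights = weights, cost = cost)
    mr <- computeMetrics(confusionCounts(trainLabels[val],
                                         predict(fit, X[val, , drop = FALSE])))
    sc <- objective(mr)
    scores[r] <- if (is.na(sc)) -Inf else sc
    if (scores[r] > best) { best <- scores[r]; bestRow <- r }
  }
  list(params = setHp(baseParams, bestRow),
       scores = cbind(grid, objective = scores))
}
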