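# Classifier discovery: balanced accuracy, univariate threshold classifiers,
# cross-validation, and exact binomial cross-validated p-values.

#' Balanced accuracy
#'
#' The arithmetic mean of sensitivity (how well positives are predicted) and
#' specificity (how well negatives are predicted):
#' \code{BACC = (sensitivity + specificity) / 2}.
#'
#' @param sensitivity,specificity values in \[0, 1\].
#' @return Balanced accuracy in \[0, 1\].
#' @examples
#' bacc(0.7920, 0.5742)  # 0.6831
#' @export
bacc <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  (sensitivity + specificity) / 2
}

#' Remove uninformative variables
#'
#' Data cleaning: drops protein columns with zero variance across the pooled
#' cohorts (constant columns carry no classification signal, whatever the
#' constant). Column order of the survivors is preserved.
#'
#' @param data a [CohortData-class].
#' @return The cleaned [CohortData-class]; an error if every column is
#'   dropped.
#' @export
cleanVariables <- function(data) {
  pooled <- rbind(data@positive, data@negative)
  if (ncol(pooled) < 1) stop("no protein columns")
  keep <- apply(pooled, 2, function(v) max(v) > min(v))
  if (!any(keep)) stop("all variables are uninformative (zero variance)")
  new("CohortData", positive = data@positive[, keep, drop = FALSE],
      negative = data@negative[, keep, drop = FALSE])
}

# linear threshold scan: all midpoints between adjacent sorted distinct
# pooled values; both directions; ties -> smaller threshold, then ">".
.fitLinear <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  if (length(v) < 2)
    return(list(form = "linear", threshold = v[1], direction = "gt",
                bacc = 0.5))
  cuts <- (v[-1] + v[-length(v)]) / 2
  sp <- sort(pos); sn <- sort(neg)
  npos <- length(pos); nneg <- length(neg)
  posLE <- findInterval(cuts, sp)        # pos values <= cut
  negLE <- findInterval(cuts, sn)
  baccGT <- ((npos - posLE) / npos + negLE / nneg) / 2
  baccLT <- 1 - baccGT
  best <- max(baccGT, baccLT)
  cand <- which(pmax(baccGT, baccLT) >= best - 1e-12)
  i <- cand[1]                            # smallest threshold
  dir <- if (baccGT[i] >= baccLT[i]) "gt" else "lt"
  list(form = "linear", threshold = cuts[i], direction = dir,
       bacc = if (dir == "gt") baccGT[i] else baccLT[i])
}

# quadratic (two-cut interval) scan; sentinels allow degenerate intervals
.fitQuadratic <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cuts <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + 1)
  sp <- sort(pos); sn <- sort(neg)
  npos <- length(pos); nneg <- length(neg)
  posLE <- findInterval(cuts, sp)
  negLE <- findInterval(cuts, sn)
  m <- length(cuts)
  # inside rule: positive iff t1 < x <= t2 for cut pair (t1, t2), t1 < t2
  sensIn <- (outer(rep(1, m), posLE) - outer(posLE, rep(1, m))) / npos
  specIn <- 1 - (outer(rep(1, m), negLE) - outer(negLE, rep(1, m))) / nneg
  baccIn <- (sensIn + specIn) / 2
  baccIn[lower.tri(baccIn, diag = TRUE)] <- -Inf
  baccOut <- 1 - baccIn
  baccOut[lower.tri(baccOut, diag = TRUE)] <- -Inf
  best <- max(baccIn, baccOut)
  pick <- function(b) which(b >= best - 1e-12, arr.ind = TRUE)
  ci <- pick(baccIn); co <- pick(baccOut)
  ord <- function(idx) idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  insideBest <- nrow(ci) > 0 &&
    (nrow(co) == 0 ||
       {a <- ord(ci)[1, ]; b <- ord(co)[1, ]
        a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])})
  idx <- if (insideBest) ord(ci)[1, ] else ord(co)[1, ]
  list(form = "quadratic",
       threshold = c(cuts[idx[1]], cuts[idx[2]]),
       direction = if (insideBest) "inside" else "outside",
       bacc = best)
}

#' Fit an optimal univariate threshold classifier
#'
#' For one variable, finds the cut(s) maximizing training balanced accuracy
#' by exhaustive scan over all midpoints between adjacent sorted
#' observations. The linear form is a single cut with automatically chosen
#' direction; the quadratic form is a pair of cuts defining an
#' inside/outside-interval rule. Ties break towards the smaller
#' threshold(s).
#'
#' @param pos,neg numeric activity values of the positive and negative
#'   class (each at least 2 values).
#' @param form \code{"linear"} or \code{"quadratic"}.
#' @return List with \code{form}, \code{threshold} (one or two cuts),
#'   \code{direction} (\code{"gt"}/\code{"lt"} or
#'   \code{"inside"}/\code{"outside"}) and training \code{bacc}.
#' @examples
#' fitThresholdClassifier(c(2, 3), c(0, 1))$bacc            # 1
#' fitThresholdClassifier(c(0, 3), c(1, 2), "quadratic")$bacc  # 1
#' @export
fitThresholdClassifier <- function(pos, neg,
                                   form = c("linear", "quadratic")) {
  form <- match.arg(form)
  if (length(pos) < 2 || length(neg) < 2)
    stop("both classes need at least 2 values")
  if (form == "linear") .fitLinear(pos, neg) else .fitQuadratic(pos, neg)
}

#' Predict with a fitted threshold classifier
#' @param fit result of [fitThresholdClassifier()].
#' @param x numeric values.
#' @return Logical vector: predicted positive class membership.
#' @export
predictThreshold <- function(fit, x) {
  switch(fit$direction,
         gt = x > fit$threshold,
         lt = x <= fit$threshold,
         inside = x > fit$threshold[1] & x <= fit$threshold[2],
         outside = !(x > fit$threshold[1] & x <= fit$threshold[2]),
         stop("unknown direction: ", fit$direction))
}

#' Leave-one-out averaged linear threshold
#'
#' Fits the optimal linear threshold \code{n} times, each time keeping a
#' different sample out of the analysis, and returns the average of the
#' \code{n} thresholds. This is the validated threshold estimate used for
#' univariate biomarker evaluation.
#'
#' @param pos,neg numeric values per class (at least 3 samples in total,
#'   and at least 2 per class so each leave-one-out fit keeps both classes
#'   populated).
#' @return List with \code{threshold} (the LOO average), \code{direction}
#'   (majority direction across folds) and \code{thresholds} (all LOO
#'   cuts).
#' @export
looThreshold <- function(pos, neg) {
  n <- length(pos) + length(neg)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  if (length(pos) < 2 || length(neg) < 2)
    stop("both classes need at least 2 values")
  fits <- c(
    lapply(seq_along(pos), function(i) .fitLinear(pos[-i], neg)),
    lapply(seq_along(neg), function(i) .fitLinear(pos, neg[-i])))
  th <- vapply(fits, `[[`, numeric(1), "threshold")
  dirs <- vapply(fits, `[[`, character(1), "direction")
  list(threshold = mean(th),
       direction = names(sort(table(dirs), decreasing = TRUE))[1],
       thresholds = th)
}

#' Exact binomial cross-validated p-value
#'
#' One-sided probability of observing at least the given number of correct
#' pooled out-of-fold predictions under chance, where chance is the larger
#' class prior (the accuracy of always predicting the majority class):
#' \code{P(X >= correct)}, \code{X ~ Binomial(n, max prior)}.
#'
#' @param labels true class labels (logical or two-level).
#' @param predictions predicted labels, same coding.
#' @param method \code{"binomial"} (default; the exact tail above) or
#'   \code{"permutation"}: label-permutation null of the pooled accuracy,
#'   an assumption-lighter alternative that absorbs the dependence between
#'   out-of-fold predictions.
#' @param B permutation count (permutation method only).
#' @return p-value in (0, 1\].
#' @examples
#' cvPValue(rep(c(TRUE, FALSE), 10), rep(c(TRUE, FALSE), 10))  # 0.5^20
#' @export
cvPValue <- function(labels, predictions,
                     method = c("binomial", "permutation"), B = 1000) {
  method <- match.arg(method)
  if (!length(labels)) stop("no predictions to test")
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  n <- length(labels)
  correct <- sum(labels == predictions)
  if (method == "binomial") {
    p0 <- max(table(labels)) / n
    return(pbinom(correct - 1, n, p0, lower.tail = FALSE))
  }
  perm <- vapply(seq_len(B), function(b)
    sum(sample(labels) == predictions), numeric(1))
  (1 + sum(perm >= correct)) / (B + 1)
}

.cvMetrics <- function(labels, predictions) {
  tp <- sum(labels & predictions)
  tn <- sum(!labels & !predictions)
  fp <- sum(!labels & predictions)
  fn <- sum(labels & !predictions)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0  # no positive calls
  list(bacc = (sens + spec) / 2, sensitivity = sens, specificity = spec,
       precision = prec, cv_p = cvPValue(labels, predictions))
}

.fitPredict <- function(kind, xtr, ytr, xte, foldSeed) {
  if (kind %in% c("linear_threshold", "quadratic_threshold")) {
    if (ncol(xtr) != 1)
      stop("threshold classifiers are univariate")
    fit <- fitThresholdClassifier(
      xtr[ytr, 1], xtr[!ytr, 1],
      if (kind == "linear_threshold") "linear" else "quadratic")
    return(predictThreshold(fit, xte[, 1]))
  }
  dtr <- data.frame(.y = factor(ifelse(ytr, "pos", "neg"),
                                levels = c("neg", "pos")), xtr,
                    check.names = TRUE)
  dte <- data.frame(xte, check.names = TRUE)
  names(dte) <- names(dtr)[-1]
  if (kind == "logistic") {
    fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
    return(suppressWarnings(
      predict(fit, newdata = dte, type = "response")) > 0.5)
  }
  if (kind == "naive_bayes") {
    fit <- e1071::naiveBayes(.y ~ ., data = dtr)
    return(predict(fit, newdata = dte) == "pos")
  }
  if (kind == "small_mlp") {
    set.seed(foldSeed)  # fixed-seed weight initialization
    fit <- nnet::nnet(.y ~ ., data = dtr, size = 4, decay = 0.01,
                      maxit = 200, trace = FALSE)
    return(as.vector(predict(fit, newdata = dte, type = "class")) == "pos")
  }
  stop("unknown model kind: ", kind)
}

#' Cross-validate a candidate protein tuple
#'
#' Stratified k-fold cross-validation of a 1-3 protein classifier:
#' out-of-fold predictions are pooled and sensitivity, specificity,
#' precision, balanced accuracy and the exact binomial p-value (see
#' [cvPValue()]) are computed on the pool. Reproducible given \code{seed}.
#'
#' @param data a [CohortData-class] (cleaned; see [cleanVariables()]).
#' @param proteins character vector of 1-3 gene names.
#' @param modelKind \code{"linear_threshold"} or
#'   \code{"quadratic_threshold"} (univariate), or \code{"logistic"},
#'   \code{"naive_bayes"}, \code{"small_mlp"} (multivariate).
#' @param k number of folds (default 10); each class must have at least
#'   \code{k} members.
#' @param seed fold-assignment seed.
#' @return Named list: \code{proteins}, \code{model_kind}, \code{bacc},
#'   \code{sensitivity}, \code{specificity}, \code{precision}, \code{cv_p},
#'   \code{n}.
#' @export
crossValidateCandidate <- function(data, proteins, modelKind, k = 10,
                                   seed = 1) {
  miss <- setdiff(proteins, colnames(data@positive))
  if (length(miss))
    stop("protein(s) absent from cohort data: ",
         paste(miss, collapse = ", "))
  npos <- nrow(data@positive); nneg <- nrow(data@negative)
  if (npos < k || nneg < k)
    stop(sprintf("each class needs >= k members (have %d/%d, k = %d); %s",
                 npos, nneg, k, "use a smaller k"))
  X <- rbind(data@positive[, proteins, drop = FALSE],
             data@negative[, proteins, drop = FALSE])
  y <- rep(c(TRUE, FALSE), c(npos, nneg))
  set.seed(seed)
  folds <- integer(npos + nneg)
  folds[y] <- sample(rep(seq_len(k), length.out = npos))
  folds[!y] <- sample(rep(seq_len(k), length.out = nneg))
  pred <- logical(length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    pred[te] <- .fitPredict(modelKind, X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE],
                            foldSeed = (seed * 131 + f) %% 2147483647)
  }
  m <- .cvMetrics(y, pred)
  c(list(proteins = proteins, model_kind = modelKind), m,
    list(n = length(y)))
}
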