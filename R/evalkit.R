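# evalkit: confusion metrics, ROC AUC, n-fold CV, SVM baseline

#' Confusion counts of binary predictions
#' @param truth,pred 0/1 vectors.
#' @return Named integer vector TP, FP, TN, FN.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == 1 & pred == 1), FP = sum(truth == 0 & pred == 1),
    TN = sum(truth == 0 & pred == 0), FN = sum(truth == 1 & pred == 0))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Acc = (TP+TN)/(TP+TN+FP+FN), Sen = TP/(TP+FN), Spe = TN/(TN+FP).
#' A metric whose denominator is zero is reported as NA (undefined), not 0.
#'
#' @param counts Named vector/list with TP, FP, TN, FN.
#' @return Named numeric vector (Acc, Sen, Spe).
#' @export
metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  div <- function(a, b) if (b > 0) a / b else NA_real_
  c(Acc = div(tp + tn, tp + tn + fp + fn),
    Sen = div(tp, tp + fn),
    Spe = div(tn, tn + fp))
}

#' Area under the ROC curve
#'
#' Area under the (1-specificity, sensitivity) curve over all score
#' thresholds, computed by the rank (Mann-Whitney) equivalence; tied scores
#' count one half.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores Real-valued scores, larger = more positive.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  np <- sum(labels == 1)
  nm <- sum(labels == 0)
  if (np == 0 || nm == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nm)
}

#' ADtree learner specification for cross_validate
#' @param n_iterations,smoothing Passed to \code{\link{train_adtree}}.
#' @return A learner (list with \code{train} and \code{score} functions).
#' @export
adtree_learner <- function(n_iterations = 15, smoothing = NULL) {
  list(name = "adtree",
       train = function(X, y) train_adtree(X, y, n_iterations, smoothing),
       score = function(model, X) predict_margin(model, X))
}

#' SVM learner specification for cross_validate
#' @param config An \code{\link{svm_config}}.
#' @return A learner (list with \code{train} and \code{score} functions).
#' @export
svm_learner <- function(config = svm_config()) {
  list(name = "svm",
       train = function(X, y) list(X = X, y = y, config = config),
       score = function(model, X)
         train_svm(model$X, model$y, newX = X, config = model$config))
}

#' n-fold cross-validation
#'
#' Randomly divides the instances into n near-equal bins (seeded); each
#' learner is trained n times on n-1 bins and scores the held-out bin, so
#' every instance is predicted exactly once. Metrics are pooled (micro-
#' averaged) over all held-out predictions. If a training split lacks one
#' class, the partition is reshuffled once with seed+1, then it is an error.
#'
#' @param X n x d feature matrix.
#' @param y 0/1 labels.
#' @param learner A learner spec (\code{\link{adtree_learner}},
#'   \code{\link{svm_learner}}, or any list with train/score functions whose
#'   scores are positive for the positive class).
#' @param n_folds Number of folds (default 20).
#' @param seed RNG seed for the partition.
#' @param stratify Stratify folds by class (default FALSE: plain random
#'   division).
#' @return An \code{EvalReport}: per-fold and pooled confusion counts,
#'   pooled Acc/Sen/Spe, AUC, best-threshold accuracy, held-out scores and
#'   the fold assignment.
#' @export
cross_validate <- function(X, y, learner, n_folds = 20, seed = 1,
                           stratify = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(n >= n_folds, all(y %in% 0:1))
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")

  assign_folds <- function(s) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(s)
    fold <- integer(n)
    if (stratify) {
      for (cls in 0:1) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
    fold
  }
  fold <- assign_folds(seed)
  ok <- all(vapply(seq_len(n_folds), function(k) {
    ytr <- y[fold != k]
    any(ytr == 1) && any(ytr == 0)
  }, logical(1)))
  if (!ok) {
    fold <- assign_folds(seed + 1)
    ok <- all(vapply(seq_len(n_folds), function(k) {
      ytr <- y[fold != k]
      any(ytr == 1) && any(ytr == 0)
    }, logical(1)))
    if (!ok) stop("a training split contains a single class")
  }

  scores <- numeric(n)
  fold_counts <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    te <- fold == k
    model <- learner$train(X[!te, , drop = FALSE], y[!te])
    scores[te] <- learner$score(model, X[te, , drop = FALSE])
    fold_counts[[k]] <- confusion_counts(y[te], as.integer(scores[te] > 0))
  }
  pooled <- Reduce(`+`, fold_counts)
  # accuracy at the best class-separation threshold (margin cutpoint)
  thr_cand <- sort(unique(scores))
  thr_cand <- c(thr_cand[1] - 1, (thr_cand[-1] + thr_cand[-length(thr_cand)]) / 2,
                thr_cand[length(thr_cand)] + 1)
  best_acc <- max(vapply(thr_cand, function(th)
    mean((scores > th) == (y == 1)), numeric(1)))

  structure(list(
    fold_counts = fold_counts, pooled_counts = pooled,
    metrics = metrics(pooled), auc = roc_auc(y, scores),
    best_threshold_acc = best_acc,
    scores = scores, fold_assignment = fold, n_folds = n_folds,
    seed = seed, learner = learner$name
  ), class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "EvalReport (%s, %d-fold CV, seed %d)\n  pooled: TP=%d FP=%d TN=%d FN=%d\n  Acc=%.3f Sen=%.3f Spe=%.3f AUC=%.3f (best-threshold Acc=%.3f)\n",
    x$learner, x$n_folds, x$seed,
    x$pooled_counts["TP"], x$pooled_counts["FP"], x$pooled_counts["TN"],
    x$pooled_counts["FN"], m["Acc"], m["Sen"], m["Spe"], x$auc,
    x$best_threshold_acc))
  invisible(x)
}

#' Gaussian-kernel SVM configuration
#' @param gamma Kernel width; default 1/d at fit time (features are
#'   standardized internally, so this matches the common "scale" heuristic).
#' @param cost Soft-margin cost C (default 1).
#' @return An \code{SVMConfig}.
#' @export
svm_config <- function(gamma = NULL, cost = 1) {
  stopifnot(is.null(gamma) || gamma > 0, cost > 0)
  structure(list(gamma = gamma, cost = cost), class = "SVMConfig")
}

#' Train a Gaussian-kernel SVM and score new instances
#'
#' Delegates to scikit-learn's SVC through the system \code{python} (an
#' established solver; no SVM implementation ships with this package).
#' Features are z-scored with parameters learned from the training rows only.
#' Returns decision-function scores (positive = positive class), usable by
#' \code{\link{roc_auc}}.
#'
#' @param X,y Training matrix and 0/1 labels.
#' @param newX Instances to score (default: the training matrix).
#' @param config An \code{\link{svm_config}}.
#' @return Numeric decision scores for \code{newX}.
#' @export
train_svm <- function(X, y, newX = X, config = svm_config()) {
  X <- as.matrix(X)
  newX <- as.matrix(newX)
  y <- as.integer(y)
  if (!any(y == 1) || !any(y == 0)) stop("single-class training labels")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Ns <- sweep(sweep(newX, 2, mu), 2, sdv, "/")
  gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma

  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("SVM delegation requires a python interpreter on PATH")
  dir <- tempfile("svm")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fx <- file.path(dir, "xtr.csv"); fy <- file.path(dir, "ytr.csv")
  fn <- file.path(dir, "xte.csv"); fo <- file.path(dir, "scores.csv")
  write.table(Xs, fx, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(y, fy, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(Ns, fn, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import sys, numpy as np",
    "from sklearn.svm import SVC",
    "xtr = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    "ytr = np.loadtxt(sys.argv[2], delimiter=',').astype(int)",
    "xte = np.loadtxt(sys.argv[3], delimiter=',', ndmin=2)",
    "m = SVC(kernel='rbf', gamma=float(sys.argv[5]), C=float(sys.argv[6]))",
    "m.fit(xtr, ytr)",
    "np.savetxt(sys.argv[4], m.decision_function(xte))",
    sep = "; ")
  status <- system2(py, c("-c", shQuote(script), shQuote(fx), shQuote(fy),
                          shQuote(fn), shQuote(fo), gamma, config$cost),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fo))
    stop("python/scikit-learn SVM call failed (status ", status, ")")
  as.numeric(readLines(fo))
}
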