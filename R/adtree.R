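# adtree: alternating decision tree training, prediction, export

#' Train an alternating decision tree
#'
#' Real-valued boosting of threshold rules. Instance weights start uniform
#' and the root prediction node carries the precondition score
#' 0.5 ln(W+/W-). Each iteration exhaustively scans every existing prediction
#' node c1, feature f and threshold between consecutive distinct sorted
#' values of f among the instances reaching c1, and picks the rule minimizing
#'
#'   Z = 2 [ sqrt(W+(c1,c2) W-(c1,c2)) + sqrt(W+(c1,!c2) W-(c1,!c2)) ] + W(!c1)
#'
#' where c2 is "f <= threshold". The new splitter's children score
#' a = 0.5 ln((W+(c1,c2)+eps)/(W-(c1,c2)+eps)) and likewise b for !c2, with
#' smoothing eps. Weights update w <- w exp(-y r(x)) and are renormalized to
#' sum to 1, so the per-iteration normalizers z (stored in the model) satisfy
#' training error <= prod(z). Ties in Z break to the lower feature index,
#' then lower threshold, then earlier node.
#'
#' @param X n x d numeric matrix (no NA/NaN).
#' @param y Binary labels: 0/1 or -1/+1.
#' @param n_iterations Number of boosting rounds (default 15; the tree then
#'   has at most 1 + 2 * n_iterations prediction nodes, typically "fewer than
#'   20" informative ones).
#' @param smoothing Score smoothing eps; default 0.5 * (1/n).
#' @return An \code{ADTreeModel} with the root score, the ordered rule list
#'   and per-iteration normalizers \code{z}.
#' @export
train_adtree <- function(X, y, n_iterations = 15, smoothing = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("NaN or non-finite feature values")
  y <- normalize_labels(y)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2) stop("need at least 2 instances")
  if (length(y) != n) stop("label length mismatch")
  if (all(y > 0) || all(y < 0)) stop("single-class labels")
  if (is.null(smoothing)) smoothing <- 0.5 / n
  pos <- y > 0

  w <- rep(1 / n, n)
  root_score <- 0.5 * log(sum(w[pos]) / sum(w[!pos]))
  w <- w * exp(-y * root_score)
  z <- sum(w)                      # root normalizer 2 sqrt(W+ W-)
  w <- w / sum(w)

  reach <- matrix(TRUE, n, 1)      # instances reaching each prediction node
  node_score <- root_score
  splitters <- list()

  for (iter in seq_len(n_iterations)) {
    best <- NULL
    for (p in seq_len(ncol(reach))) {
      idx <- which(reach[, p])
      if (length(idx) < 2) next
      w_not_c1 <- 1 - sum(w[idx])
      wp <- w[idx] * pos[idx]
      wm <- w[idx] * !pos[idx]
      tot_p <- sum(wp)
      tot_m <- sum(wm)
      for (f in seq_len(d)) {
        xv <- X[idx, f]
        ord <- order(xv)
        xs <- xv[ord]
        cut <- which(xs[-length(xs)] < xs[-1])
        if (!length(cut)) next
        cp <- cumsum(wp[ord])[cut]
        cm <- cumsum(wm[ord])[cut]
        Z <- 2 * (sqrt(cp * cm) + sqrt((tot_p - cp) * (tot_m - cm))) + w_not_c1
        thr <- (xs[cut] + xs[cut + 1]) / 2
        k <- which.min(Z)
        # candidates tie-break: lower feature, lower threshold, earlier node;
        # within a feature/node scan, the lowest threshold attaining min wins
        kk <- which(Z == Z[k])
        k <- kk[which.min(thr[kk])]
        cand <- list(Z = Z[k], f = f, thr = thr[k], p = p,
                     wp_le = cp[k], wm_le = cm[k],
                     wp_gt = tot_p - cp[k], wm_gt = tot_m - cm[k])
        if (is.null(best) || cand$Z < best$Z ||
            (cand$Z == best$Z && (cand$f < best$f ||
              (cand$f == best$f && (cand$thr < best$thr ||
                (cand$thr == best$thr && cand$p < best$p))))))
          best <- cand
      }
    }
    if (is.null(best)) break       # no admissible split remains
    a <- 0.5 * log((best$wp_le + smoothing) / (best$wm_le + smoothing))
    b <- 0.5 * log((best$wp_gt + smoothing) / (best$wm_gt + smoothing))
    left_id <- length(node_score) + 1L
    right_id <- length(node_score) + 2L
    node_score <- c(node_score, a, b)
    splitters[[iter]] <- list(feature = best$f, threshold = best$thr,
                              precondition = best$p,
                              left = left_id, right = right_id, order = iter)
    in_node <- reach[, best$p]
    go_left <- in_node & X[, best$f] <= best$thr
    r <- ifelse(go_left, a, ifelse(in_node, b, 0))
    w <- w * exp(-y * r)
    z <- c(z, sum(w))
    w <- w / sum(w)
    reach <- cbind(reach, go_left, in_node & !go_left)
  }
  structure(list(root_score = root_score, node_score = node_score,
                 splitters = splitters, d = d, z = z,
                 n_iterations = length(splitters), smoothing = smoothing),
            class = "ADTreeModel")
}

normalize_labels <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be 0/1 or -1/+1")
  y
}

#' Additive margin score of instances under an ADtree
#'
#' Traverses every splitter whose precondition node is reached (multi-path
#' evaluation) and sums the scores of all reached prediction nodes, starting
#' from the root precondition score. The magnitude of the margin is a
#' confidence measure.
#'
#' @param model An \code{ADTreeModel}.
#' @param X A numeric vector (one instance) or an n x d matrix.
#' @return Numeric vector of margins.
#' @export
predict_margin <- function(model, X) {
  stopifnot(inherits(model, "ADTreeModel"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("dimension mismatch: model expects ", model$d, " features")
  n <- nrow(X)
  reach <- matrix(FALSE, n, length(model$node_score))
  reach[, 1] <- TRUE
  margin <- rep(model$root_score, n)
  for (sp in model$splitters) {
    at <- reach[, sp$precondition]
    go_left <- at & X[, sp$feature] <= sp$threshold
    go_right <- at & !go_left
    reach[go_left, sp$left] <- TRUE
    reach[go_right, sp$right] <- TRUE
    margin[go_left] <- margin[go_left] + model$node_score[sp$left]
    margin[go_right] <- margin[go_right] + model$node_score[sp$right]
  }
  margin
}

#' Classify instances with an ADtree
#'
#' Positive class iff the margin is strictly greater than zero.
#'
#' @inheritParams predict_margin
#' @return Integer vector of 0/1 predictions.
#' @export
classify <- function(model, X) {
  as.integer(predict_margin(model, X) > 0)
}

#' @export
print.ADTreeModel <- function(x, ...) {
  cat("ADTreeModel:", x$n_iterations, "rules,",
      length(x$node_score), "prediction nodes, root score",
      sprintf("%+.4f", x$root_score), "\n")
  invisible(x)
}

#' Export an ADtree as indented text and DOT
#'
#' Splitter labels carry the rule-addition order in parentheses - an
#' importance ranking of the rules.
#'
#' @param model An \code{ADTreeModel}.
#' @param feature_names Character vector of length d.
#' @return List with \code{text} (character vector of lines) and \code{dot}
#'   (a single DOT digraph string).
#' @export
export_tree <- function(model, feature_names = NULL) {
  stopifnot(inherits(model, "ADTreeModel"))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(model$d))
  if (length(feature_names) != model$d)
    stop("feature_names must have length ", model$d)
  kids <- function(p) Filter(function(s) s$precondition == p, model$splitters)

  lines <- character(0)
  emit_node <- function(id, depth) {
    lines <<- c(lines, sprintf("%s[%+.4f]", strrep("  ", depth),
                               model$node_score[id]))
    for (s in kids(id)) {
      lines <<- c(lines, sprintf("%s%s(%d) <= %.6g ?", strrep("  ", depth + 1),
                                 feature_names[s$feature], s$order,
                                 s$threshold))
      emit_node(s$left, depth + 2)
      emit_node(s$right, depth + 2)
    }
  }
  emit_node(1L, 0)

  q <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
  dot <- c("digraph adtree {",
           sprintf("  p1 [shape=ellipse, label=%s];",
                   q(sprintf("%+.4f", model$root_score))))
  for (s in model$splitters) {
    sid <- sprintf("s%d", s$order)
    dot <- c(dot,
      sprintf("  %s [shape=box, label=%s];", sid,
              q(sprintf("%s(%d) <= %.6g", feature_names[s$feature], s$order,
                        s$threshold))),
      sprintf("  p%d -> %s;", s$precondition, sid),
      sprintf("  p%d [shape=ellipse, label=%s];", s$left,
              q(sprintf("%+.4f", model$node_score[s$left]))),
      sprintf("  p%d [shape=ellipse, label=%s];", s$right,
              q(sprintf("%+.4f", model$node_score[s$right]))),
      sprintf("  %s -> p%d [label=\"y\"];", sid, s$left),
      sprintf("  %s -> p%d [label=\"n\"];", sid, s$right))
  }
  dot <- c(dot, "}")
  list(text = lines, dot = paste(dot, collapse = "\n"))
}

#' Save an ADtree as JSON
#' @param model An \code{ADTreeModel}.
#' @param path Output path.
#' @export
adtree_save <- function(model, path) {
  stopifnot(inherits(model, "ADTreeModel"))
  obj <- list(root_score = model$root_score, node_score = model$node_score,
              splitters = lapply(model$splitters, function(s)
                list(feature = s$feature, threshold = s$threshold,
                     precondition = s$precondition, left = s$left,
                     right = s$right, order = s$order)),
              d = model$d, z = model$z, n_iterations = model$n_iterations,
              smoothing = model$smoothing)
  # digits = I(17): full significant digits so margins round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load an ADtree from JSON
#' @param path Path written by \code{\link{adtree_save}}.
#' @return An \code{ADTreeModel}.
#' @export
adtree_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  splitters <- if (is.data.frame(obj$splitters)) {
    lapply(seq_len(nrow(obj$splitters)), function(i)
      list(feature = as.integer(obj$splitters$feature[i]),
           threshold = obj$splitters$threshold[i],
           precondition = as.integer(obj$splitters$precondition[i]),
           left = as.integer(obj$splitters$left[i]),
           right = as.integer(obj$splitters$right[i]),
           order = as.integer(obj$splitters$order[i])))
  } else {
    lapply(obj$splitters, function(s)
      list(feature = as.integer(s$feature), threshold = s$threshold,
           precondition = as.integer(s$precondition),
           left = as.integer(s$left), right = as.integer(s$right),
           order = as.integer(s$order)))
  }
  structure(list(root_score = obj$root_score,
                 node_score = as.numeric(obj$node_score),
                 splitters = splitters, d = as.integer(obj$d),
                 z = as.numeric(obj$z),
                 n_iterations = as.integer(obj$n_iterations),
                 smoothing = obj$smoothing),
            class = "ADTreeModel")
}
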