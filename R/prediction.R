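#' Random-hidden-layer network classifier specification
#'
#' A feed-forward network with one hidden layer whose input weights are
#' drawn once from a seeded standard normal and kept fixed; only the output
#' layer is trained, by ridge-regularized least squares against +/-1
#' targets on sigmoid hidden activations of z-scored features.  Training is
#' deterministic given the seed and takes one linear solve.
#'
#' @param hidden_nodes hidden-layer width (800 by default; 100 is used for
#'   forward feature selection).
#' @param ridge per-row ridge penalty on the output weights (intercept
#'   unpenalized); the total penalty scales with the number of training
#'   rows, so duplicating the training set leaves the solution unchanged.
#' @param seed seed for the fixed hidden weights.
#' @return object of class `rnn_spec`.
#' @export
rnn_spec <- function(hidden_nodes = 800, ridge = 1e-3, seed = 1) {
  if (hidden_nodes < 1) stop("hidden_nodes must be >= 1", call. = FALSE)
  structure(list(hidden_nodes = as.integer(hidden_nodes), ridge = ridge,
                 seed = as.integer(seed)),
            class = "rnn_spec")
}

# Coerce labels to logical (TRUE = positive class).  The class names of
# the co-expression labeling ("strong" vs "none") are recognized; for any
# other factor the first level is the positive class.
as_binary_labels <- function(y) {
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    y <- droplevels(y)
    lev <- levels(y)
    if (length(lev) > 2) stop("more than two label values", call. = FALSE)
    pos <- if ("strong" %in% lev) "strong" else lev[1L]
    y <- y == pos
  }
  as.logical(y)
}

# Sigmoid hidden activations of z-scored features.  The z-scoring is folded
# into the hidden weights (sigmoid(((X - ctr)/scl) W + b) ==
# sigmoid(X (W/scl) + b - ctr (W/scl))) so no scaled copy of X is made.
hidden_activations <- function(X, ctr, scl, W, b) {
  Ws <- W / scl
  A <- X %*% Ws
  A <- A + rep(b - drop(ctr %*% Ws), each = nrow(A))
  1 / (1 + exp(-A))
}

#' Fit the random-hidden-layer classifier
#'
#' @param spec an [rnn_spec()].
#' @param X numeric feature matrix (rows = gene pairs), finite values only.
#' @param y binary labels (logical, 0/1, or two-level factor with the
#'   positive class first).
#' @return object of class `rnn_model`.
#' @export
fit_rnn <- function(spec, X, y) {
  stopifnot(inherits(spec, "rnn_spec"))
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)", call. = FALSE)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  if (length(unique(y)) < 2) stop("training labels contain a single class",
                                  call. = FALSE)
  p <- ncol(X)
  h <- spec$hidden_nodes
  ctr <- colMeans(X)
  # population variance (invariant under row duplication); cancellation
  # can push near-constant columns fractionally below zero
  v <- colMeans(X^2) - ctr^2
  v[!is.finite(v) | v < .Machine$double.eps] <- 1
  scl <- sqrt(v)
  wb <- with_seed(spec$seed, list(W = matrix(stats::rnorm(p * h), p, h),
                                  b = stats::rnorm(h)))
  H <- hidden_activations(X, ctr, scl, wb$W, wb$b)
  Hb <- cbind(1, H)
  A <- crossprod(Hb)
  diag(A) <- diag(A) + nrow(X) * c(0, rep(spec$ridge, h))
  beta <- solve(A, crossprod(Hb, ifelse(y, 1, -1)))
  structure(list(spec = spec, columns = colnames(X), center = ctr,
                 scale = scl, W = wb$W, b = wb$b, beta = drop(beta)),
            class = "rnn_model")
}

#' Decision scores of a fitted classifier
#'
#' Continuous scores; larger means more likely positive (strong
#' co-expression).
#'
#' @param model an `rnn_model` from [fit_rnn()].
#' @param X feature matrix with the same columns as at training.
#' @return numeric score vector.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "rnn_model"))
  X <- as.matrix(X)
  if (!is.null(model$columns) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$columns)) {
    stop("feature columns do not match the training columns", call. = FALSE)
  }
  if (ncol(X) != nrow(model$W)) {
    stop("feature columns do not match the training columns", call. = FALSE)
  }
  H <- hidden_activations(X, model$center, model$scale, model$W, model$b)
  drop(cbind(1, H) %*% model$beta)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with average-rank tie correction: the
#' probability that a random positive outscores a random negative, counting
#' ties as one half.
#'
#' @param scores numeric decision scores.
#' @param labels binary labels (TRUE/1 = positive).
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

# Seeded stratified fold assignment: a partition with near-equal class
# balance in every fold.
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' Cross-validated AUC of the classifier
#'
#' Stratified, seeded k-fold cross-validation.  Feature z-scoring is fit on
#' the training folds only; each fold's AUC is computed on its held-out
#' rows.
#'
#' @param spec an [rnn_spec()].
#' @param X feature matrix.
#' @param y binary labels.
#' @param folds number of folds.
#' @param seed seed for the fold assignment.
#' @return object of class `cv_result`: `per_fold_auc`, `mean_auc`,
#'   `median_auc`, `fold` (assignment vector), `seed`.
#' @export
cross_validate <- function(spec, X, y, folds = 10, seed = 1) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (min(table(y)) < folds) stop("need at least `folds` rows per class",
                                  call. = FALSE)
  fold <- stratified_folds(y, folds, seed)
  per_fold <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    model <- fit_rnn(spec, X[tr, , drop = FALSE], y[tr])
    auc(predict_scores(model, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  structure(list(per_fold_auc = per_fold, mean_auc = mean(per_fold),
                 median_auc = stats::median(per_fold), fold = fold,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: mean AUC %.3f, median %.3f\n",
              length(x$per_fold_auc), x$mean_auc, x$median_auc))
  invisible(x)
}

#' Greedy forward feature selection under the classifier
#'
#' Within each outer training fold, candidate feature sets are scored by
#' their mean AUC over `n_reps` seeded stratified validation splits
#' (fraction `val_frac` each); features are added greedily, one at a time,
#' as long as the best addition improves that validation AUC by at least
#' `min_gain`.  The margin matters: every candidate evaluation refits the
#' random hidden projection, whose sampling noise on a small validation
#' split would otherwise let pure-noise features "improve" the score.  The
#' selected set is then scored on the outer test fold.
#'
#' @param spec an [rnn_spec()] (conventionally with 100 hidden nodes).
#' @param X feature matrix with at least 2 columns.
#' @param y binary labels.
#' @param folds outer folds (5 by default).
#' @param seed seed for folds and validation splits.
#' @param val_frac fraction of each training fold held out per validation
#'   split.
#' @param n_reps validation splits averaged per candidate evaluation.
#' @param min_gain smallest mean validation-AUC improvement that justifies
#'   adding a feature.
#' @param max_features optional cap on the selected-set size.
#' @return list: `per_fold` (ordered selected column names per fold),
#'   `union`, `top5` (first five per fold), `per_fold_auc` on outer test
#'   folds, `mean_auc`.
#' @export
forward_select <- function(spec, X, y, folds = 5, seed = 1,
                           val_frac = 0.25, n_reps = 3, min_gain = 0.01,
                           max_features = Inf) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 features", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as_binary_labels(y)
  fold <- stratified_folds(y, folds, seed)
  sel_by_fold <- vector("list", folds)
  auc_by_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    # n_reps stratified validation splits of the training fold
    splits <- lapply(seq_len(n_reps), function(r) {
      val <- integer(0)
      with_seed(seed * 1000L + f * 31L + r, {
        for (cls in c(TRUE, FALSE)) {
          idx <- tr[y[tr] == cls]
          val <- c(val, sample(idx, max(1L, round(val_frac * length(idx)))))
        }
      })
      list(inner = setdiff(tr, val), val = val)
    })
    score_cols <- function(cols) {
      mean(vapply(splits, function(sp) {
        m <- fit_rnn(spec, X[sp$inner, cols, drop = FALSE], y[sp$inner])
        auc(predict_scores(m, X[sp$val, cols, drop = FALSE]), y[sp$val])
      }, numeric(1)))
    }
    selected <- character(0)
    best <- -Inf
    repeat {
      if (length(selected) >= min(max_features, ncol(X))) break
      cand <- setdiff(colnames(X), selected)
      cand_auc <- vapply(cand, function(cn)
        score_cols(c(selected, cn)), numeric(1))
      j <- which.max(cand_auc)
      gain <- cand_auc[j] - max(best, 0.5)
      if (length(selected) == 0L || gain >= min_gain) {
        best <- max(cand_auc[j], best)
        selected <- c(selected, cand[j])
        if (length(selected) == 1L && cand_auc[j] < 0.5 + min_gain) break
      } else break
    }
    sel_by_fold[[f]] <- selected
    m <- fit_rnn(spec, X[tr, selected, drop = FALSE], y[tr])
    auc_by_fold[f] <- auc(predict_scores(m, X[fold == f, selected, drop = FALSE]),
                          y[fold == f])
  }
  list(per_fold = sel_by_fold,
       union = Reduce(union, sel_by_fold),
       top5 = lapply(sel_by_fold, utils::head, 5L),
       per_fold_auc = auc_by_fold,
       mean_auc = mean(auc_by_fold))
}

#' Leave-one-chromosome-out evaluation
#'
#' Trains one model per held-out chromosome on the pooled rows of all
#' other chromosomes and reports the AUC on the held-out chromosome.  All
#' chromosomes must share an identical feature-column set.
#'
#' @param X_list named list of per-chromosome feature matrices.
#' @param y_list matching list of binary label vectors.
#' @param spec an [rnn_spec()].
#' @return named numeric vector of held-out AUCs.
#' @export
leave_one_chromosome_out <- function(X_list, y_list, spec = rnn_spec()) {
  stopifnot(length(X_list) == length(y_list), length(X_list) >= 2)
  cols <- lapply(X_list, colnames)
  if (!all(vapply(cols, identical, logical(1), cols[[1]]))) {
    stop("chromosomes must share identical feature columns", call. = FALSE)
  }
  out <- vapply(seq_along(X_list), function(i) {
    Xtr <- do.call(rbind, X_list[-i])
    ytr <- unlist(lapply(y_list[-i], as_binary_labels))
    m <- fit_rnn(spec, Xtr, ytr)
    auc(predict_scores(m, X_list[[i]]), y_list[[i]])
  }, numeric(1))
  names(out) <- names(X_list)
  out
}
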