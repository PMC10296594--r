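# Stacked ensemble classifier over the 39-feature descriptor: quantile
# normalization, ANOVA-F best-k feature selection, four base learners
# (random forest, k-nearest-neighbor, one-hidden-layer MLP, gradient
# boosting; optionally a fifth, multinomial logistic regression), and a
# logistic-regression meta-learner fed the base models' out-of-fold class
# probabilities.

#' Ensemble configuration
#'
#' Defaults follow the tuned values of the reference pipeline: RF with
#' 1500 trees and 5 candidate features per split, one 50-unit MLP hidden
#' layer, gradient boosting with eta 0.2, depth 6, 300 rounds, 200
#' quantile bins, all 39 features, 10-fold stacking.  KNN's `k = 5` and
#' the MLP iteration cap are library-style defaults recorded here.
#'
#' @param rf_trees,rf_mtry Random-forest size and per-split features.
#' @param knn_k Neighbors for the KNN base model.
#' @param mlp_size,mlp_maxit Hidden units / iteration cap of the MLP.
#' @param xgb_eta,xgb_depth,xgb_rounds Gradient-boosting parameters.
#' @param n_bins Quantile-transform bins.
#' @param k_features ANOVA-selected feature count (1-39).
#' @param cv_folds Stratified folds for out-of-fold stacking.
#' @param include_lr Keep logistic regression as a fifth base model
#'   (it is trained for comparison, then dropped, by default).
#' @param balance Downsample classes to the minority class before
#'   training.
#' @return An `eml_config` list.
#' @export
eml_config <- function(rf_trees = 1500, rf_mtry = 5, knn_k = 5,
                       mlp_size = 50, mlp_maxit = 200,
                       xgb_eta = 0.2, xgb_depth = 6, xgb_rounds = 300,
                       n_bins = 200, k_features = 39, cv_folds = 10,
                       include_lr = FALSE, balance = TRUE) {
  stopifnot(k_features >= 1, k_features <= 39, cv_folds >= 2)
  structure(as.list(environment()), class = "eml_config")
}

#' Quantile transform to a standard normal
#'
#' Maps each feature through its empirical CDF (estimated on `n_bins`
#' training quantiles) and then through the normal quantile function, so
#' every transformed feature is approximately standard normal on the
#' training set regardless of its original (possibly skewed)
#' distribution.  Constant features pass through unchanged with a
#' warning.
#'
#' @param X Numeric matrix or data frame, samples in rows.
#' @param n_bins Number of quantile landmarks per feature.
#' @return A `quantile_transformer`; apply with `predict()`.
#' @export
fit_quantile_standardizer <- function(X, n_bins = 200) {
  X <- as.matrix(X)
  maps <- lapply(seq_len(ncol(X)), function(jc) {
    x <- X[, jc]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2) {
      warning(sprintf("feature %d is constant; passing through", jc),
              call. = FALSE)
      return(NULL)
    }
    probs <- seq(0, 1, length.out = min(n_bins, length(x)))
    q <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
    p <- tapply(probs, q, mean)                  # collapse duplicate knots
    list(q = as.numeric(names(p)), p = as.numeric(p))
  })
  structure(list(maps = maps, n_bins = n_bins, p = ncol(X)),
            class = "quantile_transformer")
}

#' @export
predict.quantile_transformer <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == object$p)
  eps <- 1e-7
  for (jc in seq_len(ncol(X))) {
    m <- object$maps[[jc]]
    if (is.null(m)) next
    pr <- stats::approx(m$q, m$p, xout = X[, jc], rule = 2)$y
    X[, jc] <- stats::qnorm(pmin(1 - eps, pmax(eps, pr)))
  }
  X
}

#' Select the k features with the largest ANOVA F statistics
#'
#' Classic one-way (equal-variance) ANOVA of each feature against the
#' class labels; the `k` features with the largest F values are kept.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Class labels.
#' @param k Number of features to keep.
#' @return Sorted column indices, with the F statistics as attribute
#'   `"f_stat"`.
#' @export
select_k_best_anova <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (k < 1 || k > ncol(X)) stop("k out of range", call. = FALSE)
  f <- vapply(seq_len(ncol(X)), function(jc) {
    tryCatch(unname(stats::oneway.test(X[, jc] ~ y,
                                       var.equal = TRUE)$statistic),
             error = function(e) 0)
  }, numeric(1))
  f[!is.finite(f)] <- 0
  idx <- sort(order(-f, seq_along(f))[seq_len(k)])
  structure(idx, f_stat = f)
}

eml_base_names <- function(cfg) {
  c("rf", "knn", "mlp", "xgb", if (cfg$include_lr) "lr")
}

fit_base_model <- function(name, X, y, cfg) {
  switch(name,
    rf = ranger::ranger(x = X, y = y, num.trees = cfg$rf_trees,
                        mtry = min(cfg$rf_mtry, ncol(X)),
                        probability = TRUE, num.threads = 1,
                        seed = sample.int(.Machine$integer.max, 1)),
    knn = caret::knn3(X, y, k = cfg$knn_k),
    mlp = nnet::nnet(X, nnet::class.ind(y), size = cfg$mlp_size,
                     softmax = TRUE, maxit = cfg$mlp_maxit,
                     MaxNWts = 100000, trace = FALSE),
    xgb = xgboost::xgboost(X, y, objective = "multi:softprob",
                           nrounds = cfg$xgb_rounds,
                           learning_rate = cfg$xgb_eta,
                           max_depth = cfg$xgb_depth,
                           nthreads = 1, verbosity = 0),
    lr = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      df$.y <- y
      nnet::multinom(.y ~ ., df, trace = FALSE, maxit = 200, MaxNWts = 10000)
    },
    stop("unknown base model ", name, call. = FALSE))
}

predict_base_model <- function(name, fit, X, classes) {
  P <- switch(name,
    rf = stats::predict(fit, data = X, num.threads = 1)$predictions,
    knn = stats::predict(fit, X, type = "prob"),
    mlp = stats::predict(fit, X),
    xgb = stats::predict(fit, X, type = "response"),
    lr = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      p <- stats::predict(fit, df, type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(X), byrow = TRUE,
                                       dimnames = list(NULL, fit$lev))
      p
    })
  P <- as.matrix(P)
  P[, classes, drop = FALSE]
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the stacked ensemble
#'
#' Quantile-normalizes the descriptors, selects features by ANOVA F,
#' trains the base models, collects their stratified out-of-fold class
#' probabilities, and fits a multinomial logistic meta-learner on them.
#' Deterministic given `seed`.
#'
#' @param X Descriptor matrix or [ca_features()]-style tibble (the 39
#'   descriptor columns are used); rows with missing values are dropped.
#' @param y Labels over `c("H","E","L")` (taken from `X$label` when
#'   omitted and `X` is a features tibble).
#' @param cfg An [eml_config()].
#' @param seed Seed fixing all randomness.
#' @return An `eml_model`.
#' @export
train_eml <- function(X, y = NULL, cfg = eml_config(), seed = 1) {
  if (is.data.frame(X) && all(feature_names() %in% names(X))) {
    if (is.null(y)) y <- X$label
    X <- as.matrix(X[, feature_names()])
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(as.character(y), levels = SSE_CLASSES)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  if (nlevels(y) < 2) stop("need at least two classes in y", call. = FALSE)
  y <- factor(as.character(y), levels = SSE_CLASSES[SSE_CLASSES %in% levels(y)])
  with_seed(seed, {
    if (cfg$balance) {
      m <- min(table(y))
      idx <- unlist(lapply(levels(y), function(cl) {
        sample(which(y == cl), m)
      }))
      idx <- sort(idx)
      X <- X[idx, , drop = FALSE]
      y <- y[idx]
    }
    transformer <- fit_quantile_standardizer(X, cfg$n_bins)
    Xt <- stats::predict(transformer, X)
    sel <- select_k_best_anova(Xt, y, min(cfg$k_features, ncol(Xt)))
    Xs <- Xt[, sel, drop = FALSE]
    bases <- eml_base_names(cfg)
    k <- min(cfg$cv_folds, min(table(y)))
    fold <- stratified_folds(y, k)
    meta_X <- matrix(NA_real_, nrow(Xs), 0)
    for (b in bases) {
      P <- matrix(NA_real_, nrow(Xs), nlevels(y))
      for (fd in seq_len(k)) {
        tr <- fold != fd
        fit <- fit_base_model(b, Xs[tr, , drop = FALSE], y[tr], cfg)
        P[!tr, ] <- predict_base_model(b, fit, Xs[!tr, , drop = FALSE],
                                       levels(y))
      }
      colnames(P) <- paste(b, levels(y), sep = "_")
      meta_X <- cbind(meta_X, P)
    }
    meta_df <- as.data.frame(meta_X)
    meta_df$.y <- y
    meta <- nnet::multinom(.y ~ ., meta_df, trace = FALSE, maxit = 300,
                           MaxNWts = 10000)
    base_fits <- lapply(stats::setNames(bases, bases), function(b) {
      fit_base_model(b, Xs, y, cfg)
    })
    structure(list(transformer = transformer, selected = as.integer(sel),
                   base = base_fits, meta = meta, cfg = cfg,
                   classes = levels(y), colnames = colnames(X),
                   n_train = nrow(Xs)),
              class = "eml_model")
  })
}

#' @export
print.eml_model <- function(x, ...) {
  cat(sprintf("# Stacked SSE ensemble: %s -> multinom meta, %d features, %d training rows\n",
              paste(names(x$base), collapse = "+"), length(x$selected),
              x$n_train))
  invisible(x)
}

#' Predict classes or probabilities from a stacked ensemble
#'
#' @param object An `eml_model`.
#' @param newdata Descriptor matrix (39 columns) or features tibble.
#' @param type `"label"` or `"prob"`.
#' @param ... Unused.
#' @return Character labels, or a probability matrix with one column per
#'   class.
#' @export
predict.eml_model <- function(object, newdata, type = c("label", "prob"),
                              ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata) && all(feature_names() %in% names(newdata))) {
    newdata <- as.matrix(newdata[, feature_names()])
  }
  X <- as.matrix(newdata)
  colnames(X) <- object$colnames
  Xt <- stats::predict(object$transformer, X)
  Xs <- Xt[, object$selected, drop = FALSE]
  meta_X <- do.call(cbind, lapply(names(object$base), function(b) {
    P <- predict_base_model(b, object$base[[b]], Xs, object$classes)
    colnames(P) <- paste(b, object$classes, sep = "_")
    P
  }))
  probs <- stats::predict(object$meta, as.data.frame(meta_X), type = "probs")
  if (is.null(dim(probs))) {
    probs <- matrix(probs, nrow = nrow(X), byrow = FALSE)
    # multinom collapses to a vector for 2-class models
    probs <- cbind(1 - probs, probs)
  }
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

# per-residue EML classification of one trace; incomplete descriptors -> U
classify_eml <- function(trace, model) {
  stopifnot(inherits(model, "eml_model"))
  feats <- ca_features(trace)
  X <- as.matrix(feats[, feature_names()])
  ok <- stats::complete.cases(X)
  labels <- rep("U", nrow(trace))
  P <- matrix(NA_real_, nrow(trace), 3,
              dimnames = list(NULL, paste0("p_", SSE_CLASSES)))
  if (any(ok)) {
    probs <- stats::predict(model, X[ok, , drop = FALSE], type = "prob")
    P[ok, paste0("p_", colnames(probs))] <- probs
    labels[ok] <- stats::predict(model, X[ok, , drop = FALSE])
  }
  prediction_tibble(trace, labels, P, "eml")
}
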