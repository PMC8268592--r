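#' Train the two-level stacked classifier for one step
#'
#' Level 1 fits four heterogeneous base learners on the first labelled
#' feature matrix: a random-forest regressor and a shallow (single hidden
#' layer, logistic-output) neural-network regressor, both targeting the
#' 0/1 label, plus a k-nearest-neighbour classifier and a linear
#' discriminant classifier. Level 2 computes the four base outputs on the
#' second, independent feature matrix and fits another linear discriminant
#' classifier (the metamodel) on those 4-vectors. Regressor outputs are
#' clipped to \[0, 1\] before entering the metamodel; features are
#' standardized with level-1 statistics everywhere (no leakage from
#' level 2 or test data).
#'
#' @param level1,level2 data.frames sharing a feature schema plus a binary
#'   `label` column; the two sets must be disjoint draws.
#' @param ntree random-forest trees (default 200).
#' @param knn_k neighbours for the kNN base classifier (default 5).
#' @param nnet_size hidden units of the shallow network (default 10).
#' @param seed optional integer seed for the stochastic learners.
#' @return An object of class `scour_stack` with a [predict.scour_stack]
#'   method; its `report` element records per-learner and metamodel
#'   training accuracy, sizes and the seed.
#' @export
train_stack <- function(level1, level2, ntree = 200L, knn_k = 5L,
                        nnet_size = 10L, seed = NULL) {
  if (!identical(sort(names(level1)), sort(names(level2)))) {
    stop("level1 and level2 must share a feature schema", call. = FALSE)
  }
  if (!"label" %in% names(level1)) stop("missing 'label' column", call. = FALSE)
  feats <- setdiff(names(level1), "label")
  y1 <- level1$label
  y2 <- level2$label
  if (length(unique(y1)) < 2 || length(unique(y2)) < 2) {
    stop("training sets must contain both classes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x1 <- as.matrix(level1[feats])
  x2 <- as.matrix(level2[feats])
  center <- colMeans(x1)
  scale_ <- apply(x1, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  z1 <- scale(x1, center, scale_)
  z2 <- scale(x2, center, scale_)

  rf <- suppressWarnings(randomForest::randomForest(z1, y1, ntree = ntree))
  nn <- nnet::nnet(z1, y1, size = nnet_size, linout = FALSE, trace = FALSE,
                   maxit = 500, decay = 1e-3)
  lda1 <- fit_lda(z1, y1)

  base_outputs <- function(z) {
    cbind(
      rf   = pmin(pmax(stats::predict(rf, z), 0), 1),
      knn  = as.numeric(as.character(class::knn(z1, z, factor(y1), k = knn_k))),
      nnet = pmin(pmax(as.vector(stats::predict(nn, z)), 0), 1),
      lda  = as.numeric(as.character(predict_lda(lda1, z)$class))
    )
  }
  b2 <- base_outputs(z2)
  meta <- fit_lda(b2, y2)

  b1 <- base_outputs(z1)
  acc <- function(pred, y) mean((pred > 0.5) == (y > 0.5))
  report <- list(
    base_train_accuracy = apply(b1, 2, acc, y = y1),
    meta_train_accuracy = acc(predict_lda(meta, b2)$posterior, y2),
    n_level1 = nrow(z1), n_level2 = nrow(z2),
    hyperparameters = list(ntree = ntree, knn_k = knn_k,
                           nnet_size = nnet_size),
    seed = seed
  )
  structure(list(features = feats, center = center, scale = scale_,
                 rf = rf, nn = nn, lda = lda1, knn_train = z1,
                 knn_labels = factor(y1), knn_k = knn_k, meta = meta,
                 base_outputs = base_outputs, report = report),
            class = "scour_stack")
}

## LDA wrapper tolerant of within-group constant columns (e.g. a base
## classifier that is unanimous on the level-2 set): such columns carry no
## discriminant information and are dropped before fitting.
fit_lda <- function(x, y) {
  x <- as.matrix(x)
  grp <- factor(y)
  wsd <- sapply(seq_len(ncol(x)), function(j) {
    max(tapply(x[, j], grp, stats::sd))
  })
  keep <- which(wsd > 1e-10)
  if (length(keep) == 0) {
    # no informative column: fall back to majority class
    maj <- names(which.max(table(grp)))
    return(structure(list(majority = maj, keep = integer(),
                          levels = levels(grp)), class = "scour_lda"))
  }
  fit <- MASS::lda(x[, keep, drop = FALSE], grp)
  structure(list(fit = fit, keep = keep, levels = levels(grp)),
            class = "scour_lda")
}

predict_lda <- function(object, x) {
  x <- as.matrix(x)
  if (length(object$keep) == 0) {
    cls <- factor(rep(object$majority, nrow(x)), levels = object$levels)
    return(list(class = cls,
                posterior = as.numeric(object$majority == "1") + numeric(nrow(x))))
  }
  p <- stats::predict(object$fit, x[, object$keep, drop = FALSE])
  pos <- if ("1" %in% colnames(p$posterior)) p$posterior[, "1"] else
    1 - p$posterior[, 1]
  list(class = p$class, posterior = pos)
}

#' Predict candidate labels with a trained stack
#'
#' Deterministic for a frozen stack: computes the four base-learner
#' outputs on the standardized features and applies the discriminant
#' metamodel.
#'
#' @param object a `scour_stack` from [train_stack].
#' @param newdata data.frame (or matrix) of features matching the
#'   training schema; a `label` column, if present, is ignored.
#' @param ... unused.
#' @return data.frame with `label` (0/1 metamodel class) and `score`
#'   (metamodel posterior probability of the positive class).
#' @export
predict.scour_stack <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!all(object$features %in% names(newdata))) {
    stop("newdata does not match the training feature schema", call. = FALSE)
  }
  if (nrow(newdata) == 0) {
    return(data.frame(label = integer(), score = numeric()))
  }
  z <- scale(as.matrix(newdata[object$features]), object$center, object$scale)
  b <- object$base_outputs(z)
  p <- predict_lda(object$meta, b)
  data.frame(label = as.integer(as.character(p$class)),
             score = as.numeric(p$posterior))
}

#' @export
print.scour_stack <- function(x, ...) {
  cat(sprintf("<scour_stack> %d features, level-1 n=%d, level-2 n=%d\n",
              length(x$features), x$report$n_level1, x$report$n_level2))
  cat("  base training accuracy:",
      paste(sprintf("%s=%.3f", names(x$report$base_train_accuracy),
                    x$report$base_train_accuracy), collapse = " "), "\n")
  cat(sprintf("  metamodel training accuracy: %.3f\n",
              x$report$meta_train_accuracy))
  invisible(x)
}
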