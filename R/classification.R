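## Multi-fold discrimination between groups in DSM mode-score space using
## closest-mean, linear-discriminant and linear max-margin classifiers, with
## the DSM rebuilt on every training fold so no test information leaks into
## the model.

#' Closest-mean classification
#'
#' Assigns a test score vector to the group whose mean training score vector
#' is nearest in Euclidean distance; ties go to the first group in sorted
#' label order.
#'
#' @param train_scores_by_group Named list of score matrices (rows =
#'   training faces).
#' @param test_score Numeric score vector.
#' @return List: `label`, `distances` (named, sorted label order).
#' @export
closest_mean_classify <- function(train_scores_by_group, test_score) {
  if (length(train_scores_by_group) < 2L) stop("need >= 2 groups")
  labels <- sort(names(train_scores_by_group))
  p <- length(test_score)
  d <- vapply(labels, function(g) {
    m <- train_scores_by_group[[g]]
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    if (ncol(m) != p) stop("dimension mismatch: group ", g, " scores have ",
                           ncol(m), " modes, test has ", p)
    sqrt(sum((colMeans(m) - test_score)^2))
  }, numeric(1))
  list(label = labels[which.min(d)], distances = d)
}

make_folds <- function(groups, folds, seed) {
  # stratified fold assignment; deterministic given seed
  idx <- integer(length(groups))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    idx[sel] <- sample(rep_len(seq_len(folds), length(sel)))
  }
  idx
}

#' Multi-fold discrimination test in shape space
#'
#' Stratified cross-validated discrimination between groups: within each
#' fold a DSM is rebuilt from the training faces only, all faces are
#' projected into its retained mode space, and three classifiers are trained
#' and applied -- closest mean, linear discriminant analysis and a linear
#' max-margin classifier (SVM, C = 1). Leave-one-out is used when the
#' smallest group has fewer than 15 members, else `folds`-fold (default 10).
#'
#' LDA uses at most `n_train - n_groups - 1` leading modes (it is singular
#' when the mode count approaches the training count); the other classifiers
#' use all retained modes.
#'
#' @param cc A `corresponded_cohort`.
#' @param groups Optional group labels (default `cc$meta$group`).
#' @param folds `"auto"` (leave-one-out when the smallest group has < 15
#'   members, else 10-fold), `"loo"`, or an integer fold count.
#' @param seed Integer seed controlling fold assignment.
#' @param variance_target DSM variance target per fold.
#' @param classifiers Subset of `c("closest_mean", "lda", "svm")`.
#' @return A `discrimination_result`: per-classifier mean/per-fold
#'   accuracies, macro-averaged per-class accuracy and confusion tables.
#' @export
discriminate <- function(cc, groups = NULL, folds = "auto", seed = 1,
                         variance_target = 0.99,
                         classifiers = c("closest_mean", "lda", "svm")) {
  groups <- groups %||% cc$meta$group
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups")
  if (any(tab < 2L)) stop("every group needs n >= 2, got: ",
                          paste(names(tab)[tab < 2], collapse = ", "))
  n <- length(groups)
  loo <- identical(folds, "loo") ||
    (identical(folds, "auto") && min(tab) < 15L)
  if (identical(folds, "auto")) folds <- 10L
  scheme <- if (loo) "leave-one-out" else sprintf("stratified %d-fold", folds)
  fold_id <- if (loo) seq_len(n) else make_folds(groups, as.integer(folds), seed)
  nf <- max(fold_id)

  preds <- matrix(NA_character_, n, length(classifiers),
                  dimnames = list(NULL, classifiers))
  fold_model_digest <- vector("list", nf)
  for (f in seq_len(nf)) {
    test <- which(fold_id == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(groups[train])) < 2L) next
    model <- dsm(cc$points[train], variance_target = variance_target)
    fold_model_digest[[f]] <- c(mean = sum(model$mean_points),
                                var = sum(model$variances),
                                retained = model$retained)
    tr_scores <- predict(model, cc$points[train])
    te_scores <- predict(model, cc$points[test])
    by_group <- split.data.frame(tr_scores, groups[train])
    by_group <- lapply(by_group, as.matrix)
    if ("closest_mean" %in% classifiers) {
      preds[test, "closest_mean"] <- vapply(seq_along(test), function(j)
        closest_mean_classify(by_group, te_scores[j, ])$label, character(1))
    }
    if ("lda" %in% classifiers) {
      p_lda <- max(1L, min(ncol(tr_scores),
                           length(train) - length(unique(groups[train])) - 1L))
      fit <- MASS::lda(tr_scores[, seq_len(p_lda), drop = FALSE],
                       grouping = factor(groups[train]))
      preds[test, "lda"] <- as.character(
        stats::predict(fit, te_scores[, seq_len(p_lda), drop = FALSE])$class)
    }
    if ("svm" %in% classifiers) {
      fit <- e1071::svm(tr_scores, factor(groups[train]), kernel = "linear",
                        cost = 1, scale = FALSE)
      preds[test, "svm"] <- as.character(stats::predict(fit, te_scores))
    }
  }

  labels <- sort(unique(groups))
  per_classifier <- lapply(classifiers, function(cl) {
    ok <- !is.na(preds[, cl])
    conf <- table(truth = factor(groups[ok], labels),
                  predicted = factor(preds[ok, cl], labels))
    per_class <- diag(conf) / pmax(rowSums(conf), 1L)
    fold_acc <- vapply(seq_len(nf), function(f) {
      sel <- which(fold_id == f & ok)
      if (!length(sel)) return(NA_real_)
      mean(preds[sel, cl] == groups[sel])
    }, numeric(1))
    list(confusion = conf,
         accuracy = mean(preds[ok, cl] == groups[ok]),
         macro_accuracy = mean(per_class),
         per_class = per_class,
         fold_accuracies = fold_acc[!is.na(fold_acc)])
  })
  names(per_classifier) <- classifiers
  structure(list(classifiers = per_classifier, scheme = scheme,
                 folds = nf, seed = seed, fold_id = fold_id,
                 fold_model_digest = fold_model_digest,
                 n = n, groups = groups),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Discrimination (%s, %d faces):\n", x$scheme, x$n))
  for (cl in names(x$classifiers)) {
    r <- x$classifiers[[cl]]
    cat(sprintf("  %-12s accuracy %.3f (macro %.3f)\n", cl, r$accuracy,
                r$macro_accuracy))
  }
  invisible(x)
}

#' Project a face onto inter-group-mean axes
#'
#' For each pair of group mean surfaces (A, B), returns the signed position
#' of the face along the unit axis from A to B, measured from the pair
#' midpoint: A maps to `-|B - A| / 2`, the midpoint to 0, and B to
#' `+|B - A| / 2`. Used for simultaneous comparison of a face along several
#' syndrome-to-syndrome axes.
#'
#' @param mean_pairs List of pairs; each element a list/with elements `a`
#'   and `b`, both N x 3 mean surfaces (optionally named).
#' @param face N x 3 corresponded point matrix.
#' @return Named numeric vector, one coordinate per axis.
#' @export
axis_projection <- function(mean_pairs, face) {
  f <- as.vector(as.matrix(face))
  out <- vapply(mean_pairs, function(p) {
    a <- as.vector(as.matrix(p$a)); b <- as.vector(as.matrix(p$b))
    u <- b - a
    len <- sqrt(sum(u^2))
    if (len < 1e-12) stop("degenerate axis: coincident group means")
    sum((f - (a + b) / 2) * (u / len))
  }, numeric(1))
  names(out) <- names(mean_pairs) %||%
    paste0("axis", seq_along(mean_pairs))
  out
}
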