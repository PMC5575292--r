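CLASS_LEVELS <- c("benign", "recessive", "dominant")

#' Fit the class-mean imputation model
#'
#' Missing values are replaced with the weighted average of the per-class
#' training means of the column: with `weights = "equal"` (default) the
#' plain mean of the three class means, with `weights = "prior"` the
#' class-frequency-weighted mean. Columns that are entirely missing in the
#' training data are dropped with a warning. Binary columns are imputed the
#' same way and then thresholded to \{-1, +1\} (at 0, ties to -1) so the
#' encoded matrix stays strictly binary.
#'
#' @param features data frame of registry features (training rows).
#' @param labels class labels aligned with `features`.
#' @param weights `"equal"` or `"prior"`.
#' @return an imputation model: list with `columns`, `impute` (named
#'   vector), `binary` (logical per column), `dropped`.
#' @export
fit_imputation <- function(features, labels, weights = c("equal", "prior")) {
  weights <- match.arg(weights)
  labels <- factor(labels, levels = CLASS_LEVELS)
  reg <- feature_registry()
  binary <- stats::setNames(reg$type == "binary", reg$name)
  w <- if (weights == "equal") rep(1 / 3, 3) else
    as.numeric(table(labels)[CLASS_LEVELS] / length(labels))
  impute <- numeric(0); keep <- character(0); dropped <- character(0)
  for (col in names(features)) {
    cm <- vapply(CLASS_LEVELS, function(k) {
      v <- features[[col]][labels == k]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(cm))) {
      dropped <- c(dropped, col)
      next
    }
    # a class with no observed values contributes the overall observed mean
    cm[is.na(cm)] <- mean(features[[col]], na.rm = TRUE)
    val <- sum(w * cm)
    if (isTRUE(binary[[col]])) val <- if (val >= 0) 1 else -1
    impute[col] <- val
    keep <- c(keep, col)
  }
  if (length(dropped))
    warning("dropping entirely-missing feature column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  structure(list(columns = keep, impute = impute,
                 binary = binary[keep], dropped = dropped),
            class = "plof_imputation")
}

#' Encode a feature table into a complete numeric matrix
#'
#' Applies an imputation model fitted on training data: retained columns
#' are selected, and every missing entry is replaced by the model's
#' imputation constant for that column. The result contains no missing
#' entries; binary columns are in \{-1, +1\}.
#'
#' @param features data frame of registry features.
#' @param imputation a model from [fit_imputation()].
#' @return numeric matrix (rows = examples).
#' @export
encode_features <- function(features, imputation) {
  stopifnot(inherits(imputation, "plof_imputation"))
  m <- as.matrix(features[, imputation$columns, drop = FALSE])
  for (col in imputation$columns) {
    miss <- is.na(m[, col])
    if (any(miss)) m[miss, col] <- imputation$impute[[col]]
  }
  storage.mode(m) <- "double"
  m
}

#' Build one class-balanced training replicate
#'
#' Subsamples a labeled corpus to reduce per-gene redundancy: at most one
#' variant per gene for the benign and recessive classes, at most three per
#' gene for the dominant class, chosen uniformly at random under `seed`.
#' When a gene is represented on several transcripts, variants on its
#' longest transcript (largest `cds_length` feature) are preferred.
#'
#' @param corpus a training corpus data frame: columns `label`, `gene_id`,
#'   `transcript_id`, then the registry features.
#' @param seed integer RNG seed.
#' @return subsampled corpus data frame.
#' @export
build_training_replicate <- function(corpus, seed) {
  set.seed(seed)
  caps <- c(benign = 1L, recessive = 1L, dominant = 3L)
  keep <- integer(0)
  for (k in CLASS_LEVELS) {
    rows <- which(corpus$label == k)
    if (!length(rows)) stop("training corpus has no examples of class ", k)
    for (g in unique(corpus$gene_id[rows])) {
      gr <- rows[corpus$gene_id[rows] == g]
      lens <- corpus$cds_length[gr]
      pref <- if (all(is.na(lens))) gr else
        gr[which(lens == max(lens, na.rm = TRUE))]
      n <- min(caps[[k]], length(pref))
      keep <- c(keep, if (length(pref) == 1L) pref else sample(pref, n))
    }
  }
  corpus[sort(keep), , drop = FALSE]
}

balanced_forest <- function(x, y, ntree) {
  y <- droplevels(y)
  n_min <- min(table(y))
  randomForest::randomForest(
    x = x, y = y, ntree = ntree, replace = TRUE,
    strata = y, sampsize = rep(n_min, nlevels(y)))
}

# Gene-grouped, class-stratified fold assignment: every variant of a gene
# lands in the same fold, genes spread round-robin within their class.
gene_grouped_folds <- function(labels, genes, n_folds) {
  gene_class <- tapply(as.character(labels), genes, function(v) v[1L])
  fold_of_gene <- stats::setNames(integer(length(gene_class)), names(gene_class))
  for (k in unique(gene_class)) {
    gk <- sample(names(gene_class)[gene_class == k])
    fold_of_gene[gk] <- rep_len(seq_len(n_folds), length(gk))
  }
  unname(fold_of_gene[as.character(genes)])
}

#' Train the replicated stratified random-forest ensemble
#'
#' For each replicate: a fresh per-gene subsample
#' ([build_training_replicate()]), class-mean imputation fitted on that
#' subsample, a random forest grown with class-balanced (stratified)
#' bootstrap sampling, and a gene-grouped class-stratified k-fold
#' cross-validated multiclass AUC ([hand_till_auc()]). The default of 40
#' replicates with 10-fold cross-validation follows the published training
#' scheme; replicate seeds are derived from `base_seed` and recorded in the
#' model so the whole procedure is reproducible byte-for-byte.
#'
#' @param corpus training corpus data frame (`label`, `gene_id`,
#'   `transcript_id`, registry features).
#' @param n_replicates number of forest replicates (default 40).
#' @param n_folds cross-validation folds (default 10); reduced with a
#'   warning when a class has fewer genes than folds.
#' @param ntree trees per forest (default 500).
#' @param base_seed integer seed from which replicate seeds are derived.
#' @param weights imputation weighting, see [fit_imputation()].
#' @param feature_subset optional character vector restricting the feature
#'   columns used (e.g. to ablate a feature family).
#' @param cv logical: compute per-replicate cross-validated AUC.
#' @return an `EnsembleModel`: replicates (each with forest, imputation,
#'   seed), per-replicate `cv_auc`, configuration, and the feature-name
#'   fingerprint.
#' @export
train_ensemble <- function(corpus, n_replicates = 40L, n_folds = 10L,
                           ntree = 500L, base_seed = 1L,
                           weights = "equal", feature_subset = NULL,
                           cv = TRUE) {
  feat_cols <- intersect(feature_registry()$name, names(corpus))
  if (!is.null(feature_subset)) feat_cols <- intersect(feat_cols, feature_subset)
  if (!length(feat_cols)) stop("no feature columns in corpus")
  labels <- factor(corpus$label, levels = CLASS_LEVELS)
  if (any(is.na(labels))) stop("labels outside {benign, recessive, dominant}")

  replicates <- vector("list", n_replicates)
  cv_auc <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    seed_r <- base_seed + r
    sub <- build_training_replicate(corpus, seed_r)
    y <- factor(sub$label, levels = CLASS_LEVELS)
    feats <- sub[, feat_cols, drop = FALSE]
    if (cv) {
      genes_per_class <- tapply(sub$gene_id, y, function(g) length(unique(g)))
      k <- min(n_folds, min(genes_per_class))
      if (k < n_folds)
        warning("reducing folds to ", k, " (smallest class has ", k,
                " genes)", call. = FALSE)
      set.seed(seed_r)
      fold <- gene_grouped_folds(y, sub$gene_id, k)
      prob <- matrix(NA_real_, nrow(sub), 3,
                     dimnames = list(NULL, CLASS_LEVELS))
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 3L) next
        imp_f <- suppressWarnings(fit_imputation(feats[tr, , drop = FALSE],
                                                 y[tr], weights))
        set.seed(seed_r * 131L + f)
        rf <- balanced_forest(encode_features(feats[tr, , drop = FALSE], imp_f),
                              y[tr], ntree)
        prob[!tr, ] <- stats::predict(
          rf, encode_features(feats[!tr, , drop = FALSE], imp_f),
          type = "prob")[, CLASS_LEVELS]
      }
      ok <- stats::complete.cases(prob)
      cv_auc[r] <- hand_till_auc(y[ok], prob[ok, , drop = FALSE])
    }
    imp <- suppressWarnings(fit_imputation(feats, y, weights))
    set.seed(seed_r * 131L)
    forest <- balanced_forest(encode_features(feats, imp), y, ntree)
    replicates[[r]] <- list(forest = forest, imputation = imp, seed = seed_r)
  }
  structure(list(
    replicates = replicates, cv_auc = cv_auc,
    config = list(n_replicates = n_replicates, n_folds = n_folds,
                  ntree = ntree, base_seed = base_seed, weights = weights),
    feature_names = feat_cols
  ), class = "EnsembleModel")
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat(sprintf("<EnsembleModel: %d replicates, %d features, mean CV AUC %.3f>\n",
              length(x$replicates), length(x$feature_names),
              mean(x$cv_auc, na.rm = TRUE)))
  invisible(x)
}

#' Predict class probabilities with the ensemble
#'
#' Each replicate encodes the features with its own training-time
#' imputation model and votes a probability triple; the reported
#' probabilities are the across-replicate means (renormalized to sum to 1)
#' and the dispersion is the per-class across-replicate standard deviation.
#' The predicted class is the probability argmax; exact ties resolve to the
#' least pathogenic class (benign, then recessive, then dominant). A
#' High/Low confidence label is attached via [confidence_label()].
#'
#' @param object an `EnsembleModel`.
#' @param features data frame of registry feature columns (raw, un-encoded;
#'   missing values allowed).
#' @param ... unused.
#' @return data frame with `p_benign`, `p_recessive`, `p_dominant`,
#'   `sd_benign`, `sd_recessive`, `sd_dominant`, `predicted_class`,
#'   `confidence`.
#' @export
predict.EnsembleModel <- function(object, features, ...) {
  missing_cols <- setdiff(object$feature_names, names(features))
  if (length(missing_cols))
    stop("feature columns absent from input: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  n <- nrow(features)
  probs <- array(NA_real_, c(n, 3, length(object$replicates)),
                 dimnames = list(NULL, CLASS_LEVELS, NULL))
  for (r in seq_along(object$replicates)) {
    rep_r <- object$replicates[[r]]
    enc <- encode_features(features[, object$feature_names, drop = FALSE],
                           rep_r$imputation)
    probs[, , r] <- stats::predict(rep_r$forest, enc,
                                   type = "prob")[, CLASS_LEVELS, drop = FALSE]
  }
  summarize_ensemble_probs(probs)
}

#' Aggregate per-replicate class probabilities into predictions
#'
#' Means are taken across replicates and renormalized to sum to 1; the
#' per-class across-replicate standard deviation quantifies ensemble
#' dispersion; the predicted class is the argmax with ties resolved to the
#' least pathogenic class (benign, then recessive, then dominant); the
#' High/Low label follows [confidence_label()].
#'
#' @param probs array `n x 3 x n_replicates` of class probabilities
#'   (columns in `benign, recessive, dominant` order).
#' @return prediction data frame (see [predict.EnsembleModel()]).
#' @export
summarize_ensemble_probs <- function(probs) {
  means <- apply(probs, c(1, 2), mean)
  sds <- apply(probs, c(1, 2), stats::sd)
  means <- means / rowSums(means)
  pred <- CLASS_LEVELS[max.col(means, ties.method = "first")]
  conf <- confidence_label(means, sds, dim(probs)[3])
  out <- data.frame(means, sds, predicted_class = pred, confidence = conf,
                    stringsAsFactors = FALSE)
  names(out)[1:6] <- c(paste0("p_", CLASS_LEVELS), paste0("sd_", CLASS_LEVELS))
  rownames(out) <- NULL
  out
}

#' High/Low confidence labels from cross-replicate dispersion
#'
#' For each class, a 95\% confidence interval
#' `mean +/- 1.96 * SD / sqrt(n_replicates)` is formed from the
#' across-replicate dispersion. The prediction is labeled `"Low"` when the
#' lower bound of the predicted (argmax) class overlaps the upper bound of
#' either less likely class, and `"High"` otherwise.
#'
#' @param means,sds numeric matrices (rows = predictions, columns = the
#'   three classes in `benign, recessive, dominant` order).
#' @param n_replicates ensemble size used for the standard error.
#' @return character vector of `"High"`/`"Low"`.
#' @export
confidence_label <- function(means, sds, n_replicates) {
  means <- rbind(means); sds <- rbind(sds)
  if (n_replicates < 2L) {
    warning("fewer than 2 replicates: confidence is Low by definition",
            call. = FALSE)
    return(rep("Low", nrow(means)))
  }
  se <- sds / sqrt(n_replicates)
  lower <- means - 1.96 * se
  upper <- means + 1.96 * se
  vapply(seq_len(nrow(means)), function(i) {
    k <- which.max(means[i, ])
    if (lower[i, k] <= max(upper[i, -k])) "Low" else "High"
  }, character(1))
}

#' Hand-and-Till multiclass AUC
#'
#' The multiclass generalization `M` of the ROC AUC: for every unordered
#' class pair (i, j), the two-class ranking probability `A(i|j)` is computed
#' from the class-i scores of the class-i and class-j examples (ties count
#' 0.5), symmetrized as `A(i,j) = (A(i|j) + A(j|i)) / 2`, and `M` is the
#' mean of `A(i,j)` over all pairs, i.e.
#' `M = 2 / (c (c - 1)) * sum_{i<j} A(i,j)`. Classes with no examples are
#' excluded from the pairing with a warning.
#'
#' @param labels class labels.
#' @param probs numeric matrix of class scores, columns named by class.
#' @return AUC in \[0, 1\].
#' @export
hand_till_auc <- function(labels, probs) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(probs))
  classes <- intersect(colnames(probs), unique(labels))
  empty <- setdiff(colnames(probs), classes)
  if (length(empty))
    warning("class(es) with no examples excluded from AUC: ",
            paste(empty, collapse = ", "), call. = FALSE)
  if (length(classes) < 2L) stop("need at least 2 classes with examples")
  a_cond <- function(i, j) {
    # P(score_i of a class-i example > score_i of a class-j example)
    sel <- labels %in% c(i, j)
    s <- probs[sel, i]
    is_i <- labels[sel] == i
    r <- rank(s)                              # midranks handle ties as 0.5
    n_i <- sum(is_i); n_j <- sum(!is_i)
    (sum(r[is_i]) - n_i * (n_i + 1) / 2) / (n_i * n_j)
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  mean(vapply(pairs, function(p)
    (a_cond(p[1], p[2]) + a_cond(p[2], p[1])) / 2, numeric(1)))
}

#' Per-class precision and recall
#'
#' Precision = TP / (TP + FP); recall = TP / (TP + FN), per class;
#' undefined (0/0) values are reported as `NA`.
#'
#' @param labels true class labels.
#' @param predicted predicted class labels (same length).
#' @return data frame with columns `class`, `precision`, `recall`.
#' @export
precision_recall <- function(labels, predicted) {
  if (length(labels) != length(predicted))
    stop("labels and predictions have different lengths")
  labels <- as.character(labels); predicted <- as.character(predicted)
  classes <- sort(unique(c(labels, predicted)))
  res <- lapply(classes, function(k) {
    tp <- sum(labels == k & predicted == k)
    fp <- sum(labels != k & predicted == k)
    fn <- sum(labels == k & predicted != k)
    data.frame(class = k,
               precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
               recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  })
  do.call(rbind, res)
}

#' Mean feature importance across ensemble replicates
#'
#' @param model an `EnsembleModel`.
#' @return data frame `feature`, `importance` (mean decrease in Gini
#'   impurity averaged over replicates), sorted decreasing.
#' @export
feature_importance <- function(model) {
  imp <- lapply(model$replicates, function(r)
    randomForest::importance(r$forest)[, 1])
  all_feats <- unique(unlist(lapply(imp, names)))
  m <- vapply(imp, function(v) v[all_feats], numeric(length(all_feats)))
  out <- data.frame(feature = all_feats,
                    importance = rowMeans(m, na.rm = TRUE))
  out[order(-out$importance), ]
}

#' Save / load a trained ensemble archive
#'
#' The archive records the feature-name fingerprint, seeds, and replicates;
#' loading verifies the fingerprint against the current feature registry.
#'
#' @param model an `EnsembleModel`.
#' @param path archive path (RDS).
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "EnsembleModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @return `load_ensemble()` returns the `EnsembleModel`.
#' @export
load_ensemble <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "EnsembleModel")) stop("not an ensemble archive")
  unknown <- setdiff(model$feature_names, feature_registry()$name)
  if (length(unknown))
    stop("archive features not in the current registry: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  model
}
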