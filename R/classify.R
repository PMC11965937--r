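#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param TP,TN,FP,FN non-negative counts; their sum must be positive.
#' @return Accuracy as a fraction in [0, 1].
#' @export
accuracy_from_counts <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  if (total <= 0) stop("no evaluated cases", call. = FALSE)
  (TP + TN) / total
}

#' Fit a fatigue classifier
#'
#' Trains one of three conventional classifiers on (already standardised)
#' features:
#' * `"svm"` -- RBF-kernel support vector machine (`e1071::svm`), cost 10,
#'   kernel bandwidth `1 / (d * var(X))` (the "scale" convention);
#' * `"knn"` -- k-nearest neighbours, k = 5, Euclidean distance (prediction
#'   defers to `class::knn`; with an odd k and binary labels votes cannot
#'   tie);
#' * `"ann"` -- single-hidden-layer neural network (`nnet::nnet`), 16 units,
#'   weight decay for regularisation.
#'
#' @param X numeric feature matrix (rows = cases), standardised by the caller.
#' @param y factor or character labels; at least two classes.
#' @param kind `"svm"`, `"knn"` or `"ann"`.
#' @param hyper optional named list overriding hyperparameters
#'   (`cost`, `gamma`, `k`, `size`, `decay`, `maxit`).
#' @param seed integer seed (ANN weight initialisation).
#' @return An object of class `emg_classifier` with a `predict` method.
#' @export
fit_classifier <- function(X, y, kind = c("svm", "knn", "ann"),
                           hyper = list(), seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("training set contains a single class", call. = FALSE)
  stopifnot(all(is.finite(X)))
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  model <- switch(kind,
    svm = {
      gamma <- hyper$gamma %||% (1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12)))
      e1071::svm(X, y, kernel = "radial", cost = hyper$cost %||% 10,
                 gamma = gamma, scale = FALSE)
    },
    knn = list(train = X, cl = y, k = hyper$k %||% 5L),
    ann = {
      nnet::nnet(X, nnet::class.ind(y), size = hyper$size %||% 16L,
                 decay = hyper$decay %||% 1e-2, maxit = hyper$maxit %||% 200L,
                 softmax = TRUE, trace = FALSE)
    }
  )
  structure(list(kind = kind, model = model, levels = levels(y), seed = seed),
            class = "emg_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.emg_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- switch(object$kind,
    svm = as.character(stats::predict(object$model, newdata)),
    knn = {
      old <- .Random.seed_store()
      on.exit(.Random.seed_restore(old))
      set.seed(object$seed)        # distance ties in class::knn draw randomly
      as.character(class::knn(object$model$train, newdata,
                              object$model$cl, k = object$model$k))
    },
    ann = {
      pr <- stats::predict(object$model, newdata)
      object$levels[max.col(pr, ties.method = "first")]
    }
  )
  factor(out, levels = object$levels)
}

confusion_counts <- function(truth, pred, positive = "difficult") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  c(TP = sum(truth == positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    FN = sum(truth == positive & pred != positive))
}

## Fold assignment. Stratified: rows grouped by class, shuffled, dealt
## cyclically so per-class and total fold sizes differ by at most one.
## Grouped: subjects are dealt to folds whole, never split across train/test.
assign_folds <- function(table, scheme, k_folds, seed) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(table)
  fold <- integer(n)
  if (scheme == "stratified-window") {
    ord <- order(table$label, stats::runif(n))
    fold[ord] <- rep_len(seq_len(k_folds), n)
  } else if (scheme == "grouped-by-subject") {
    subjects <- unique(table$subject)
    if (length(subjects) < k_folds)
      stop("fewer subjects than folds in grouped scheme", call. = FALSE)
    sf <- rep_len(seq_len(k_folds), length(subjects))[order(stats::runif(length(subjects)))]
    fold <- sf[match(table$subject, subjects)]
  } else stop("unknown scheme: ", scheme, call. = FALSE)
  fold
}

#' Cross-validated evaluation of a classifier on a feature table
#'
#' Two protocols are offered: `"stratified-window"` (label-stratified folds
#' over windows -- optimistic when adjacent windows of one trial are
#' correlated) and `"grouped-by-subject"` (all of a subject's windows stay in
#' the same fold -- the honest generalisation estimate). Feature
#' standardisation uses train-fold statistics only.
#'
#' @param wide a wide feature data frame ([feature_table_wide()] or an
#'   embedding with `y1..y3` columns); must contain `subject` and `label`.
#' @param scheme `"stratified-window"` or `"grouped-by-subject"`.
#' @param k_folds number of folds (>= 2).
#' @param kind classifier kind for [fit_classifier()].
#' @param hyper hyperparameter overrides.
#' @param seed integer seed controlling folds and classifier initialisation.
#' @param feature_cols columns to use as features (default: every numeric
#'   non-key column).
#' @return An `eval_report`: list with `folds` (per-fold TP/TN/FP/FN and
#'   accuracy), `mean_accuracy`, pooled `counts`, `fold_assignment`, `scheme`,
#'   `kind`, `seed`.
#' @export
cross_validate <- function(wide, scheme = "stratified-window", k_folds = 5,
                           kind = "svm", hyper = list(), seed = 1L,
                           feature_cols = NULL) {
  stopifnot(k_folds >= 2, all(c("subject", "label") %in% names(wide)))
  keycols <- c("subject", "trial", "channel", "window", "label")
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(wide), keycols)
  X <- as.matrix(wide[, feature_cols, drop = FALSE])
  y <- factor(wide$label)
  fold <- assign_folds(wide, scheme, k_folds, seed)
  folds <- lapply(seq_len(k_folds), function(f) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    model <- fit_classifier(Xs[tr, , drop = FALSE], y[tr], kind,
                            hyper = hyper, seed = seed + f)
    pred <- predict(model, Xs[!tr, , drop = FALSE])
    cc <- confusion_counts(y[!tr], pred)
    c(cc, accuracy = accuracy_from_counts(cc["TP"], cc["TN"], cc["FP"], cc["FN"]))
  })
  folds_df <- as.data.frame(do.call(rbind, folds))
  folds_df$fold <- seq_len(k_folds)
  counts <- colSums(folds_df[, c("TP", "TN", "FP", "FN")])
  structure(list(folds = folds_df,
                 mean_accuracy = mean(folds_df$accuracy),
                 pooled_accuracy = accuracy_from_counts(
                   counts["TP"], counts["TN"], counts["FP"], counts["FN"]),
                 counts = counts, fold_assignment = fold,
                 scheme = scheme, kind = kind, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s / %s: mean CV accuracy %.3f over %d folds\n",
              x$kind, x$scheme, x$mean_accuracy, nrow(x$folds)))
  invisible(x)
}

#' Accuracy as a function of the number of IMFs kept
#'
#' For each `k = 1..max_k` the classifier is cross-validated on the raw
#' features combined with the first `k` IMF sources; optionally the same is
#' done on the 3-D t-SNE reduction of those features (embedded once over all
#' rows, then cross-validated -- the transductive protocol, which shares the
#' embedding between train and test folds).
#'
#' @param table a long `feature_table` containing `imf1..imfK` sources.
#' @param kind classifier kind.
#' @param max_k largest number of IMFs to include.
#' @param representation `"features"`, `"tsne"` or `"both"`.
#' @param scheme,k_folds,seed,hyper passed to [cross_validate()].
#' @param tsne_args named list of overrides for [embed_feature_table()].
#' @return Data frame with `n_imfs`, `accuracy_features` and (if requested)
#'   `accuracy_tsne`.
#' @export
imf_sweep <- function(table, kind = "svm", max_k = 5,
                      representation = c("both", "features", "tsne"),
                      scheme = "stratified-window", k_folds = 5, seed = 1L,
                      hyper = list(), tsne_args = list()) {
  representation <- match.arg(representation)
  rows <- lapply(seq_len(max_k), function(k) {
    wide <- feature_table_wide(table, k)
    out <- list(n_imfs = k)
    if (representation %in% c("features", "both")) {
      out$accuracy_features <- cross_validate(
        wide, scheme, k_folds, kind, hyper, seed)$mean_accuracy
    }
    if (representation %in% c("tsne", "both")) {
      emb <- do.call(embed_feature_table,
                     c(list(wide = wide, seed = seed), tsne_args))
      out$accuracy_tsne <- cross_validate(
        emb, scheme, k_folds, kind, hyper, seed,
        feature_cols = grep("^y[0-9]+$", names(emb), value = TRUE))$mean_accuracy
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' Accuracy matrix across decomposition variants and classifiers
#'
#' Decomposes every record with each requested EMD-family variant, extracts
#' the feature table (raw + `k_keep` IMFs) and cross-validates each
#' classifier under one common protocol and seed policy.
#'
#' @param records named list of `emg_record` objects (preprocessed).
#' @param variants character vector of decomposition variants.
#' @param classifiers character vector of classifier kinds.
#' @param params a [decomp_params()] template (variant field is overridden).
#' @param config a [window_config()].
#' @param k_keep IMFs retained as feature sources.
#' @param scheme,k_folds,seed passed to [cross_validate()].
#' @return A list with `accuracy` (variants x classifiers matrix), `ranking`
#'   (data frame sorted by accuracy) and the per-cell `eval_report`s.
#' @export
method_comparison <- function(records,
                              variants = c("EMD", "EEMD", "CEEMD", "CEEMDAN",
                                           "ICEEMDAN"),
                              classifiers = c("svm", "knn", "ann"),
                              params = decomp_params(),
                              config = window_config(), k_keep = 4,
                              scheme = "stratified-window", k_folds = 5,
                              seed = 1L) {
  acc <- matrix(NA_real_, length(variants), length(classifiers),
                dimnames = list(variants, classifiers))
  reports <- list()
  for (v in variants) {
    p <- params
    p$variant <- v
    decomps <- lapply(records, function(r) decompose(r$samples, p))
    tab <- extract_feature_table(records, decomps, config, k_keep)
    wide <- feature_table_wide(tab, k_keep)
    for (cl in classifiers) {
      rep_ <- cross_validate(wide, scheme, k_folds, cl, seed = seed)
      acc[v, cl] <- rep_$mean_accuracy
      reports[[paste(v, cl, sep = "_")]] <- rep_
    }
  }
  ranking <- data.frame(
    variant = rep(variants, times = length(classifiers)),
    classifier = rep(classifiers, each = length(variants)),
    accuracy = as.vector(acc))
  ranking <- ranking[order(-ranking$accuracy), ]
  rownames(ranking) <- NULL
  list(accuracy = acc, ranking = ranking, reports = reports)
}
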