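#' Vote-based training labels from external IR predictions
#'
#' Training labels are derived by agreement among three external
#' IR-prediction interval sets: introns hit by at least two of the three
#' sets become positives (`yes`), introns hit by none form the negative
#' pool, and introns hit by exactly one set are excluded from both classes.
#' Negatives are sampled uniformly without replacement from the pool.
#'
#' @param catalog Intron catalog from [derive_introns()].
#' @param preds A list of three interval tables (tibbles with `chrom`,
#'   `start`, `end`, 0-based half-open), e.g. from [read_bed_intervals()].
#' @param neg_ratio Negatives sampled per positive (default 4.757, i.e.
#'   3525/741).
#' @param seed Integer seed for the negative sampling (required).
#' @param match `"exact"` requires identical coordinates; `"overlap"`
#'   accepts reciprocal overlap of at least `min_overlap`.
#' @param min_overlap Reciprocal-overlap threshold for `match = "overlap"`.
#' @return An `ir_labeling` list with `positive_ids`, `negative_ids`,
#'   `pool_size`, `n_excluded` (hit by exactly one set), `neg_ratio`,
#'   `seed`. `tidy()` returns a tibble of `intron_id`, `label`.
#' @export
label_training_set <- function(catalog, preds, neg_ratio = 3525 / 741,
                               seed, match = c("exact", "overlap"),
                               min_overlap = 0.9) {
  match <- match.arg(match)
  if (missing(seed)) abort("a seed is required for negative sampling")
  if (length(preds) != 3) abort("exactly three prediction sets are required")
  hits <- vapply(preds, function(p) {
    intron_hit(catalog, p, match = match, min_overlap = min_overlap)
  }, logical(nrow(catalog)))
  if (nrow(catalog) == 1) hits <- matrix(hits, nrow = 1)
  n_hits <- rowSums(hits)
  positives <- catalog$intron_id[n_hits >= 2]
  pool <- catalog$intron_id[n_hits == 0]
  if (length(positives) == 0) {
    abort(paste0("no intron is hit by two or more prediction sets; ",
                 "larger prediction sets are needed for vote labeling"))
  }
  n_neg <- min(round(neg_ratio * length(positives)), length(pool))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  negatives <- sort(sample(sort(pool), n_neg, replace = FALSE))
  structure(list(
    positive_ids = sort(positives),
    negative_ids = negatives,
    pool_size = length(pool),
    n_excluded = sum(n_hits == 1),
    neg_ratio = neg_ratio,
    seed = seed
  ), class = "ir_labeling")
}

# logical: is each catalog intron hit by the prediction set?
intron_hit <- function(catalog, pred, match = "exact", min_overlap = 0.9) {
  if (match == "exact") {
    key <- paste(pred$chrom, pred$start, pred$end)
    paste(catalog$chrom, catalog$start, catalog$end) %in% key
  } else {
    a <- .catalog_granges(catalog)
    b <- GenomicRanges::GRanges(pred$chrom,
                                IRanges::IRanges(pred$start + 1L, pred$end))
    h <- GenomicRanges::findOverlaps(a, b)
    if (length(h) == 0) return(logical(nrow(catalog)))
    ov <- BiocGenerics::width(IRanges::pintersect(
      a[S4Vectors::queryHits(h)], b[S4Vectors::subjectHits(h)]))
    wa <- BiocGenerics::width(a[S4Vectors::queryHits(h)])
    wb <- BiocGenerics::width(b[S4Vectors::subjectHits(h)])
    ok <- ov / wa >= min_overlap & ov / wb >= min_overlap
    seq_len(nrow(catalog)) %in% S4Vectors::queryHits(h)[ok]
  }
}

#' @export
print.ir_labeling <- function(x, ...) {
  cat(sprintf("vote labeling: %d positives, %d sampled negatives (pool %d), %d excluded\n",
              length(x$positive_ids), length(x$negative_ids), x$pool_size,
              x$n_excluded))
  invisible(x)
}

#' @describeIn label_training_set Labels as a tibble of `intron_id`,
#'   `label` (`"yes"`/`"no"`).
#' @param x An `ir_labeling` object.
#' @param ... Unused.
#' @export
tidy.ir_labeling <- function(x, ...) {
  bind_rows(
    tibble(intron_id = x$positive_ids, label = "yes"),
    tibble(intron_id = x$negative_ids, label = "no")
  )
}

#' Build the 17-feature labeled matrix
#'
#' Joins labels onto the feature table and appends the three delta features
#' (DIE, DIJ, DIC), computed with the same pseudo-count policy as the
#' caller but without the positivity noise filter — negative examples
#' legitimately have non-positive deltas. Rows are ordered by `intron_id`
#' and columns follow the fixed canonical order, so the matrix is
#' byte-stable across runs.
#'
#' @param labeling An `ir_labeling` object or a tibble with `intron_id` and
#'   `label` columns.
#' @param features A feature table from [build_feature_table()].
#' @param pseudo Pseudo-count for the delta features (default 1).
#' @return A tibble with `intron_id`, the 17 feature columns and a `label`
#'   factor with levels `no`, `yes`. Labeled introns missing from the
#'   feature table, or with undefined feature values, are excluded with a
#'   warning; the count is available as `attr(x, "n_excluded")`.
#' @export
build_matrix <- function(labeling, features, pseudo = 1) {
  labels <- if (inherits(labeling, "ir_labeling")) tidy(labeling)
            else as_tibble(labeling)
  stopifnot(all(c("intron_id", "label") %in% names(labels)))
  with_deltas <- compute_deltas(features, pseudo = pseudo) |>
    rename(DIE = die, DIJ = dij, DIC = dic)
  mat <- labels |>
    inner_join(with_deltas, by = "intron_id") |>
    select(intron_id, all_of(ir_feature_columns()), label)
  complete <- rowSums(!is.finite(as.matrix(mat[ir_feature_columns()]))) == 0
  n_excluded <- nrow(labels) - sum(complete)
  if (n_excluded > 0) {
    warn(sprintf("%d labeled intron(s) lacked complete features and were excluded",
                 n_excluded))
  }
  out <- mat[complete, , drop = FALSE] |>
    arrange(intron_id) |>
    mutate(label = factor(label, levels = c("no", "yes")))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Train an IR classifier
#'
#' Two classifier families are supported: a single pruned decision tree with
#' information-gain splits (pruned by cost-complexity at the
#' cross-validation-optimal strength) and a bagged random forest of 10 trees
#' each drawing 5 candidate features per split, aggregated by majority vote.
#'
#' @param matrix A labeled matrix from [build_matrix()].
#' @param kind `"tree"` or `"forest"`.
#' @param seed Integer seed controlling tree/forest randomness.
#' @param prune For `kind = "tree"`, whether to prune (default `TRUE`).
#' @param ntree,mtry Forest size and features tried per split
#'   (defaults 10 and 5).
#' @param control An [rpart::rpart.control()] list for the tree.
#' @return An `ir_classifier` object; use [predict()] on new feature rows.
#' @export
train_ir_classifier <- function(matrix, kind = c("tree", "forest"), seed = 1,
                                prune = TRUE, ntree = 10, mtry = 5,
                                control = NULL) {
  kind <- match.arg(kind)
  dat <- as_tibble(matrix)
  if (!"label" %in% names(dat)) abort("matrix must carry a `label` column")
  dat$label <- factor(dat$label, levels = c("no", "yes"))
  counts <- table(dat$label)
  if (any(counts < 2) || length(unique(dat$label)) < 2) {
    abort("training requires at least two examples of each class")
  }
  x <- dat[ir_feature_columns()]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  if (kind == "tree") {
    ctl <- control %||% rpart::rpart.control(minsplit = 4, minbucket = 2,
                                             cp = 0, xval = 10)
    fit <- rpart::rpart(label ~ ., data = bind_cols(x, label = dat$label),
                        method = "class",
                        parms = list(split = "information"), control = ctl)
    if (prune && !is.null(fit$cptable) && nrow(fit$cptable) > 1) {
      best <- fit$cptable[which.min(fit$cptable[, "xerror"]), "CP"]
      fit <- rpart::prune(fit, cp = best)
    }
  } else {
    fit <- randomForest::randomForest(
      x = as.data.frame(x), y = dat$label,
      ntree = ntree, mtry = min(mtry, ncol(x)))
  }
  structure(list(kind = kind, model = fit, seed = seed,
                 feature_columns = ir_feature_columns()),
            class = "ir_classifier")
}

#' Predict IR events with a trained classifier
#'
#' @param object An `ir_classifier`.
#' @param newdata A tibble carrying the 17 canonical feature columns (an
#'   `intron_id` column, if present, is passed through).
#' @param ... Unused.
#' @return A tibble with `label` (`"yes"`/`"no"`) and `score`, the
#'   yes-probability: the fraction of forest trees voting yes, or the
#'   tree-leaf class frequency.
#' @export
predict.ir_classifier <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  missing_cols <- setdiff(object$feature_columns, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata is missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ids <- if ("intron_id" %in% names(newdata)) newdata$intron_id else NULL
  x <- as.data.frame(newdata[object$feature_columns])
  if (nrow(x) == 0) {
    out <- tibble(label = character(0), score = numeric(0))
    if (!is.null(ids)) out <- bind_cols(tibble(intron_id = ids), out)
    return(out)
  }
  prob <- as.numeric(predict(object$model, x, type = "prob")[, "yes"])
  out <- tibble(label = ifelse(prob > 0.5, "yes", "no"), score = prob)
  if (!is.null(ids)) out <- bind_cols(tibble(intron_id = ids), out)
  out
}

#' @export
print.ir_classifier <- function(x, ...) {
  cat(sprintf("IR classifier (%s), seed %d\n", x$kind, x$seed))
  invisible(x)
}

#' @describeIn train_ir_classifier Variable importance as a tibble.
#' @param x An `ir_classifier`.
#' @export
tidy.ir_classifier <- function(x, ...) {
  if (x$kind == "forest") {
    imp <- randomForest::importance(x$model)
    out <- tibble(feature = rownames(imp), importance = as.numeric(imp[, 1]))
  } else {
    imp <- x$model$variable.importance
    out <- if (is.null(imp)) {
      tibble(feature = character(0), importance = numeric(0))
    } else {
      tibble(feature = names(imp), importance = as.numeric(imp))
    }
  }
  arrange(out, desc(importance))
}

#' @describeIn train_ir_classifier One-row model summary.
#' @export
glance.ir_classifier <- function(x, ...) {
  tibble(kind = x$kind, seed = x$seed,
         n_features = length(x$feature_columns))
}

#' Stratified k-fold cross-validation of an IR classifier
#'
#' Folds are stratified by class so every fold's class balance matches the
#' global balance to within one example. Metrics are pooled over the
#' held-out predictions of all folds: accuracy, specificity (true-negative
#' rate), sensitivity (true-positive rate), and AUC computed from the
#' continuous yes-scores.
#'
#' @inheritParams train_ir_classifier
#' @param folds Number of folds (default 10).
#' @param ... Passed on to [train_ir_classifier()].
#' @return An `ir_cv` object with `metrics` (one-row tibble: `kind`, `acc`,
#'   `sp`, `sn`, `auc`) and `predictions` (per-row held-out label, score
#'   and fold).
#' @export
cross_validate <- function(matrix, kind = c("tree", "forest"), folds = 10,
                           seed = 1, ...) {
  kind <- match.arg(kind)
  dat <- as_tibble(matrix)
  dat$label <- factor(dat$label, levels = c("no", "yes"))
  counts <- table(dat$label)
  if (any(counts < folds)) {
    abort(sprintf(
      "smallest class has %d examples, fewer than %d folds; use fewer folds",
      min(counts), folds))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  fold_of <- integer(nrow(dat))
  for (cl in levels(dat$label)) {
    idx <- which(dat$label == cl)
    fold_of[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- dat[fold_of != f, , drop = FALSE]
    test <- dat[fold_of == f, , drop = FALSE]
    model <- train_ir_classifier(train, kind = kind, seed = seed + f, ...)
    p <- predict(model, test)
    preds[[f]] <- tibble(fold = f, truth = as.character(test$label),
                         label = p$label, score = p$score)
  }
  pooled <- bind_rows(preds)
  tp <- sum(pooled$truth == "yes" & pooled$label == "yes")
  tn <- sum(pooled$truth == "no" & pooled$label == "no")
  fp <- sum(pooled$truth == "no" & pooled$label == "yes")
  fn <- sum(pooled$truth == "yes" & pooled$label == "no")
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = pooled$truth, predictor = pooled$score,
    levels = c("no", "yes"), direction = "<", quiet = TRUE)))
  structure(list(
    metrics = tibble(kind = kind,
                     acc = (tp + tn) / nrow(pooled),
                     sp = tn / (tn + fp),
                     sn = tp / (tp + fn),
                     auc = auc),
    predictions = pooled,
    folds = folds,
    seed = seed
  ), class = "ir_cv")
}

#' @export
print.ir_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%d-fold CV (%s): acc %.3f, sp %.3f, sn %.3f, auc %.3f\n",
              x$folds, m$kind, m$acc, m$sp, m$sn, m$auc))
  invisible(x)
}

#' @describeIn cross_validate Metrics in long form (`metric`, `value`).
#' @param x An `ir_cv` object.
#' @export
tidy.ir_cv <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_longer(c(acc, sp, sn, auc), names_to = "metric",
                        values_to = "value")
}

#' @describeIn cross_validate One-row metric summary.
#' @export
glance.ir_cv <- function(x, ...) {
  x$metrics
}

#' @describeIn cross_validate ROC curve of the pooled held-out scores.
#' @param object An `ir_cv` object.
#' @export
autoplot.ir_cv <- function(object, ...) {
  r <- pROC::roc(response = object$predictions$truth,
                 predictor = object$predictions$score,
                 levels = c("no", "yes"), direction = "<", quiet = TRUE)
  df <- tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  ggplot(df, aes(x = fpr, y = tpr)) +
    geom_step() +
    geom_abline(linetype = "dashed", colour = "grey50") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("%s, AUC %.3f", object$metrics$kind,
                         object$metrics$auc)) +
    theme_bw()
}
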