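# Feed-forward neural-network organelle classifier.
#
# Inputs are residue compositions of six fixed sequence regions around and
# within the aligned TMD; the network has one hidden layer and is trained
# by plain stochastic error back-propagation (logistic activations, one-hot
# targets, squared-error loss). The architecture and training schedule (120
# inputs, 7 hidden nodes, learning rate 0.01, 100 cycles) are the package
# defaults.

#' Input regions for the classifier encoding
#'
#' Six position intervals in aligned coordinates (cytosolic core edge at
#' position 1, flank at 0 and below): the last four cytosolic-flank
#' residues, then five windows through the core and into the exoplasmic
#' flank. Positions 5-8 are deliberately not encoded.
#'
#' @return A tibble with columns `region`, `from`, `to`.
#' @export
tmd_regions <- function() {
  tibble(region = 1:6,
         from = c(-3L, 1L, 9L, 12L, 16L, 18L),
         to = c(0L, 4L, 11L, 15L, 17L, 24L))
}

#' Encode aligned TMDs as region compositions
#'
#' For every protein, the relative abundance of each of the 20 residues in
#' each of the six regions of [tmd_regions()], giving a 120-entry vector
#' (6 regions x 20 residues). Each populated region's block sums to one;
#' positions missing from a region (short flanks) shrink its denominator,
#' and an entirely absent region yields a zero block with a warning.
#'
#' @param aligned A `tmd_aligned` tibble.
#' @param regions Region definition tibble; default [tmd_regions()].
#' @return A tibble with column `id` followed by 120 numeric columns named
#'   `r<region>_<residue>` in region-major, alphabetical-residue order.
#' @export
encode_regions <- function(aligned, regions = tmd_regions()) {
  region_of <- function(pos) {
    idx <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(regions))) {
      hit <- pos >= regions$from[i] & pos <= regions$to[i]
      idx[hit] <- regions$region[i]
    }
    idx
  }
  ids <- unique(aligned$id)
  fracs <- aligned %>%
    mutate(region = region_of(.data$position)) %>%
    filter(!is.na(.data$region)) %>%
    count(.data$id, .data$region, .data$residue, name = "k") %>%
    group_by(.data$id, .data$region) %>%
    mutate(frac = .data$k / sum(.data$k)) %>%
    ungroup()
  n_missing <- length(ids) * nrow(regions) -
    nrow(distinct(fracs, .data$id, .data$region))
  if (n_missing > 0) {
    warn(sprintf("encode_regions: %d empty region block(s) encoded as zeros", n_missing))
  }
  grid <- tidyr::expand_grid(id = ids, region = regions$region,
                             residue = AA_ALPHABET)
  wide <- grid %>%
    left_join(select(fracs, "id", "region", "residue", "frac"),
              by = c("id", "region", "residue")) %>%
    mutate(frac = tidyr::replace_na(.data$frac, 0),
           col = paste0("r", .data$region, "_", .data$residue)) %>%
    select("id", "col", "frac") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "frac")
  wide[match(ids, wide$id), , drop = FALSE]
}

encoding_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  ids <- x$id
  m <- as.matrix(x[, setdiff(names(x), "id"), drop = FALSE])
  rownames(m) <- ids
  m
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_forward <- function(x_mat, w_in, w_out) {
  h <- sigmoid(cbind(1, x_mat) %*% w_in)
  sigmoid(cbind(1, h) %*% w_out)
}

#' Train the feed-forward organelle classifier
#'
#' One hidden layer, logistic activations on hidden and output nodes,
#' one-hot targets, per-sample error back-propagation in a seeded random
#' order for a fixed number of cycles. The default loss is per-output
#' Bernoulli cross-entropy, the natural pairing for logistic outputs
#' (its output gradient is simply `o - t`); plain squared error is
#' available but trains markedly more slowly at this learning rate and
#' cycle budget because its gradient carries an extra `o(1 - o)` factor.
#' Weights start uniform in `[-0.5, 0.5]` (seeded), so training is
#' deterministic given the seed. With `restarts > 1`, several networks are
#' trained from different seeded initializations and the one with the best
#' mean one-vs-rest training MCC at the training threshold (0.67) is kept
#' -- the MCC-based weight selection used with this architecture.
#'
#' @param x Encoding tibble from [encode_regions()] (or a plain numeric
#'   matrix, one row per protein).
#' @param labels Class (organelle) label per row of `x`; at least two
#'   distinct classes are required.
#' @param hidden Hidden-layer size (default 7).
#' @param rate Learning rate (default 0.01).
#' @param epochs Training cycles through the data (default 100).
#' @param seed Integer seed for weight initialization and sample order.
#' @param loss `"cross-entropy"` (default) or `"squared"`.
#' @param restarts Number of seeded restarts to select among (default 3).
#' @param train_threshold Threshold for the restart-selection MCC
#'   (default 0.67).
#' @return An object of class `tmd_ann`: weights (`w_in` with the bias as
#'   first row, `w_out` likewise), `classes`, the training configuration,
#'   and `loss` (mean training loss after each epoch).
#' @export
ann_train <- function(x, labels, hidden = 7, rate = 0.01, epochs = 100,
                      seed = NULL, loss = c("cross-entropy", "squared"),
                      restarts = 3, train_threshold = 0.67) {
  loss <- match.arg(loss)
  x_mat <- encoding_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x_mat)) abort("labels must match rows of x")
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("ann_train: need at least two classes")
  t_mat <- outer(labels, classes, `==`) * 1
  d <- ncol(x_mat); n <- nrow(x_mat); n_c <- length(classes)
  loss_fun <- function(o) {
    if (loss == "squared") mean((o - t_mat)^2)
    else -mean(t_mat * log(pmax(o, 1e-12)) +
                 (1 - t_mat) * log(pmax(1 - o, 1e-12)))
  }
  run <- function() {
    w_in <- matrix(runif((d + 1) * hidden, -0.5, 0.5), d + 1, hidden)
    w_out <- matrix(runif((hidden + 1) * n_c, -0.5, 0.5), hidden + 1, n_c)
    loss_hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        xi <- c(1, x_mat[i, ])
        h <- sigmoid(drop(xi %*% w_in))
        hb <- c(1, h)
        o <- sigmoid(drop(hb %*% w_out))
        delta_o <- o - t_mat[i, ]
        if (loss == "squared") delta_o <- delta_o * o * (1 - o)
        delta_h <- drop(w_out[-1, , drop = FALSE] %*% delta_o) * h * (1 - h)
        w_out <- w_out - rate * tcrossprod(hb, delta_o)
        w_in <- w_in - rate * tcrossprod(xi, delta_h)
      }
      loss_hist[ep] <- loss_fun(ann_forward(x_mat, w_in, w_out))
    }
    list(w_in = w_in, w_out = w_out, loss = loss_hist)
  }
  train_mcc <- function(fit) {
    o <- ann_forward(x_mat, fit$w_in, fit$w_out)
    mean(vapply(seq_len(n_c), function(j) {
      pos <- o[, j] >= train_threshold
      truth <- t_mat[, j] == 1
      confusion_stats(sum(pos & truth), sum(!pos & !truth),
                      sum(pos & !truth), sum(!pos & truth))$mcc
    }, numeric(1)))
  }
  seed0 <- if (is.null(seed)) sample.int(.Machine$integer.max - restarts, 1) else as.integer(seed)
  fits <- lapply(seq_len(restarts) - 1L,
                 function(k) withr::with_seed(seed0 + k, run()))
  best <- which.max(vapply(fits, train_mcc, numeric(1)))
  fit <- fits[[best]]
  structure(
    list(w_in = fit$w_in, w_out = fit$w_out, classes = classes,
         features = colnames(x_mat), regions = tmd_regions(),
         residues = AA_ALPHABET, hidden = hidden, rate = rate,
         epochs = epochs, seed = seed, loss_type = loss,
         restarts = restarts, loss = fit$loss, n_train = n),
    class = "tmd_ann"
  )
}

#' @export
print.tmd_ann <- function(x, ...) {
  cat(sprintf("<tmd_ann> %d -> %d -> %d network; %d classes: %s\n",
              nrow(x$w_in) - 1, x$hidden, length(x$classes),
              length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epochs at rate %g on %d proteins; final MSE %.4g\n",
              x$epochs, x$rate, x$n_train, x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict from encodings
#'
#' Output scores lie in `(0, 1)`; the predicted class is the one with the
#' highest score.
#'
#' @param object A `tmd_ann` model.
#' @param newdata Encoding tibble or matrix with the model's feature
#'   columns.
#' @param ... Unused.
#' @return Tibble with `id` (when available), one score column per class,
#'   and `.pred`, the argmax class.
#' @export
predict.tmd_ann <- function(object, newdata, ...) {
  x_mat <- encoding_matrix(newdata)
  x_mat <- x_mat[, object$features, drop = FALSE]
  scores <- ann_forward(x_mat, object$w_in, object$w_out)
  colnames(scores) <- object$classes
  out <- as_tibble(scores)
  out$.pred <- object$classes[max.col(scores, ties.method = "first")]
  if (!is.null(rownames(x_mat))) out <- tibble(id = rownames(x_mat)) %>% dplyr::bind_cols(out)
  out
}

#' Confusion-matrix statistics
#'
#' Matthews correlation coefficient, sensitivity and specificity from
#' true/false positive/negative counts:
#' `MCC = (Tp*Tn - Fp*Fn) / sqrt((Tp+Fn)(Tp+Fp)(Tn+Fp)(Tn+Fn))`,
#' `sensitivity = Tp/(Tp+Fn)`, `specificity = Tp/(Tp+Fp)`. MCC is defined
#' as 0 when any factor of the denominator is 0. Note that this
#' "specificity" is the positive predictive value (precision), kept under
#' its historical name; it is not Tn/(Tn+Fp).
#'
#' @param tp,tn,fp,fn Non-negative counts, not all zero.
#' @param threshold Optional classification threshold to record.
#' @return One-row tibble with the counts, `mcc`, `sensitivity`,
#'   `specificity` and `threshold`.
#' @export
confusion_stats <- function(tp, tn, fp, fn, threshold = NA_real_) {
  if (any(c(tp, tn, fp, fn) < 0)) abort("confusion_stats: negative count")
  if (tp + tn + fp + fn == 0) abort("confusion_stats: all counts zero")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn, mcc = mcc,
         sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
         specificity = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         threshold = threshold)
}

#' Scan classification thresholds for the best MCC
#'
#' Evaluates the Matthews correlation coefficient of score >= threshold
#' predictions on a fixed grid of thresholds over `[0, 1]` and returns the
#' full curve and the (lowest) threshold achieving the maximum.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Logical (or 0/1) true-positive indicator per score.
#' @param step Grid step (default 0.01).
#' @return List of class `tmd_threshold_scan` with elements `threshold`,
#'   `mcc`, and `curve` (tibble of `threshold`, `mcc`, `sensitivity`,
#'   `specificity`).
#' @export
threshold_scan <- function(scores, labels, step = 0.01) {
  labels <- as.logical(labels)
  grid <- seq(0, 1, by = step)
  curve <- bind_rows(lapply(grid, function(th) {
    pos <- scores >= th
    confusion_stats(sum(pos & labels), sum(!pos & !labels),
                    sum(pos & !labels), sum(!pos & labels),
                    threshold = th)
  })) %>% select("threshold", "mcc", "sensitivity", "specificity")
  best <- which.max(curve$mcc)
  structure(list(threshold = curve$threshold[best], mcc = curve$mcc[best],
                 curve = curve),
            class = "tmd_threshold_scan")
}

#' @export
print.tmd_threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold scan> best MCC %.3f at threshold %.2f (%d grid points)\n",
              x$mcc, x$threshold, nrow(x$curve)))
  invisible(x)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Partitions each class into `k` seeded folds, trains on `k - 1` and
#' scores the held-out fold, then pools the held-out scores. Mean accuracy
#' is the fraction of proteins whose highest-scoring class is their true
#' class. One-vs-rest confusion counts per class are evaluated at
#' `threshold`; when `threshold` is `NULL` the threshold with the highest
#' pooled one-vs-rest MCC is found by [threshold_scan()].
#'
#' @inheritParams ann_train
#' @param k Number of folds (default 5); every class must have at least
#'   `k` members.
#' @param threshold Classification threshold for the per-class statistics,
#'   or `NULL` to pick the best-MCC threshold from the pooled held-out
#'   scores.
#' @return An object of class `tmd_cv`: per-class `stats`, `accuracy`,
#'   `threshold`, the threshold `scan`, pooled held-out `scores` and the
#'   fold assignment.
#' @export
cross_validate <- function(x, labels, k = 5, hidden = 7, rate = 0.01,
                           epochs = 100, seed = NULL, threshold = NULL) {
  x_mat <- encoding_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x_mat)) abort("labels must match rows of x")
  sizes <- table(labels)
  if (any(sizes < k)) {
    abort(sprintf("every class needs at least k = %d members (smallest has %d)",
                  k, min(sizes)))
  }
  seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else as.integer(seed)
  folds <- withr::with_seed(seed, {
    f <- integer(length(labels))
    for (cl in names(sizes)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  classes <- sort(unique(labels))
  scores <- matrix(NA_real_, nrow(x_mat), length(classes),
                   dimnames = list(rownames(x_mat), classes))
  for (fold in seq_len(k)) {
    tr <- folds != fold
    fit <- ann_train(x_mat[tr, , drop = FALSE], labels[tr], hidden = hidden,
                     rate = rate, epochs = epochs, seed = seed + fold)
    scores[!tr, ] <- ann_forward(x_mat[!tr, , drop = FALSE], fit$w_in, fit$w_out)
  }
  pred <- classes[max.col(scores, ties.method = "first")]
  accuracy <- mean(pred == labels)
  onehot <- outer(labels, classes, `==`)
  scan <- threshold_scan(as.vector(scores), as.vector(onehot))
  if (is.null(threshold)) threshold <- scan$threshold
  stats_tbl <- bind_rows(lapply(seq_along(classes), function(j) {
    pos <- scores[, j] >= threshold
    truth <- onehot[, j]
    cbind(tibble(class = classes[j]),
          confusion_stats(sum(pos & truth), sum(!pos & !truth),
                          sum(pos & !truth), sum(!pos & truth),
                          threshold = threshold))
  }))
  score_tbl <- as_tibble(scores)
  score_tbl <- tibble(id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
                      label = labels, fold = folds, .pred = pred) %>%
    dplyr::bind_cols(score_tbl)
  structure(list(stats = stats_tbl, accuracy = accuracy, threshold = threshold,
                 scan = scan, scores = score_tbl, k = k, classes = classes,
                 config = list(hidden = hidden, rate = rate, epochs = epochs,
                               seed = seed)),
            class = "tmd_cv")
}

#' @export
print.tmd_cv <- function(x, ...) {
  cat(sprintf("<tmd_cv> %d-fold cross-validation, %d classes, %d proteins\n",
              x$k, length(x$classes), nrow(x$scores)))
  cat(sprintf("  mean accuracy %.1f%%; mean per-class MCC %.3f at threshold %.2f\n",
              100 * x$accuracy, mean(x$stats$mcc), x$threshold))
  print(x$stats)
  invisible(x)
}

#' Serialize / restore a trained network as JSON
#'
#' @param model A `tmd_ann` object.
#' @param path Output (input) JSON path.
#' @return `write_ann` invisibly returns `path`; `read_ann` a `tmd_ann`.
#' @export
write_ann <- function(model, path) {
  payload <- list(
    w_in = unclass(model$w_in), w_out = unclass(model$w_out),
    classes = model$classes, features = model$features,
    regions = model$regions, residues = model$residues,
    hidden = model$hidden, rate = model$rate, epochs = model$epochs,
    seed = model$seed, loss = model$loss, n_train = model$n_train
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(w_in = as.matrix(p$w_in), w_out = as.matrix(p$w_out),
         classes = p$classes, features = p$features,
         regions = as_tibble(p$regions), residues = p$residues,
         hidden = p$hidden, rate = p$rate, epochs = p$epochs,
         seed = p$seed, loss = p$loss, n_train = p$n_train),
    class = "tmd_ann"
  )
}
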