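# Random-forest false-positive filter for inter-alignment (split-read)
# signatures, applied before clustering.  The extraction rules are
# deliberately lenient, so this classifier carries the burden of
# separating true split-read evidence from alignment noise; it also
# resolves fuzzy type boundaries (notably INS vs DUP) by relabeling.

RF_CLASSES <- c("DEL", "INS", "DUP", "INV", "TRA", "false")

#' Per-feature min-max normalization bounds
#'
#' @param x Numeric feature matrix (rows = items).
#' @return List with `min` and `max` vectors (one per column).
#' @export
feature_bounds <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' Apply min-max normalization with stored bounds
#'
#' Values are scaled by `(x - min) / (max - min)` and clipped to `[0, 1]`;
#' constant features map to 0.
#'
#' @param x Feature matrix.
#' @param bounds From [feature_bounds()] (computed on training data).
#' @return Normalized matrix of the same shape.
#' @export
normalize_features <- function(x, bounds) {
  rng <- bounds$max - bounds$min
  rng[rng == 0] <- 1
  out <- sweep(sweep(x, 2, bounds$min, "-"), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

macro_f1 <- function(pred, truth, classes) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp + fn == 0) return(NA_real_)   # class absent from truth
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 1)
  mean(f1, na.rm = TRUE)
}

#' Train the split-read signature filter (random forest)
#'
#' Features are min-max normalized (bounds frozen into the bundle) and a
#' grid search over tree depth (2-10), forest size (10-100) and minimum
#' node size for splitting (10-100) selects the model with the highest
#' macro-F1 on a held-out fold.
#'
#' @param features Numeric matrix with the 22 inter-signature feature
#'   columns (named as in the extractor schema).
#' @param labels Character vector over
#'   `DEL, INS, DUP, INV, TRA, false`.
#' @param seed Integer seed (grid search and forests are deterministic
#'   under it).
#' @param holdout_frac Held-out fraction for model selection
#'   (default 0.25).
#' @return The `rf` half of a filter bundle: `model`, `bounds`,
#'   `features` (schema), `classes`, `macro_f1` (held-out),
#'   `best_params`.
#' @importFrom ranger ranger
#' @export
train_rf <- function(features, labels, seed = 1, holdout_frac = 0.25) {
  stopifnot(nrow(features) == length(labels))
  if (!all(colnames(features) == INTER_FEATURES)) {
    stop("feature schema mismatch: expected the 22 inter-signature features")
  }
  missing_cl <- setdiff(RF_CLASSES, unique(labels))
  if (length(missing_cl)) {
    warning("classes absent from training labels: ",
            paste(missing_cl, collapse = ", "))
  }
  set.seed(seed)
  bounds <- feature_bounds(features)
  xn <- normalize_features(features, bounds)
  df <- as.data.frame(xn)
  df$.label <- factor(labels, levels = intersect(RF_CLASSES, unique(labels)))
  n <- nrow(df)
  hold <- sample.int(n, max(1L, round(n * holdout_frac)))
  train <- df[-hold, , drop = FALSE]
  test <- df[hold, , drop = FALSE]
  grid <- expand.grid(depth = c(2, 4, 6, 8, 10),
                      trees = c(10, 25, 50, 75, 100),
                      min_node = c(10, 25, 50, 75, 100))
  best <- NULL; best_f1 <- -Inf
  for (g in seq_len(nrow(grid))) {
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = train,
      num.trees = grid$trees[g], max.depth = grid$depth[g],
      min.node.size = grid$min_node[g],
      num.threads = 1, seed = seed, verbose = FALSE)
    pred <- stats::predict(fit, test, num.threads = 1)$predictions
    f1 <- macro_f1(as.character(pred), as.character(test$.label),
                   levels(df$.label))
    if (f1 > best_f1) {
      best_f1 <- f1
      best <- list(model = fit, params = grid[g, ])
    }
  }
  list(model = best$model, bounds = bounds, features = INTER_FEATURES,
       classes = levels(df$.label), macro_f1 = best_f1,
       best_params = best$params)
}

rf_predict <- function(rf, features) {
  if (!all(colnames(features) == rf$features)) {
    stop("bundle schema does not match the extractor feature schema")
  }
  xn <- as.data.frame(normalize_features(features, rf$bounds))
  as.character(stats::predict(rf$model, xn, num.threads = 1)$predictions)
}

#' Filter inter-alignment signatures with a trained random forest
#'
#' Signatures predicted `false` are removed before clustering.
#' Predictions may also relabel a signature, but only across the
#' insertion/duplication boundary: a tandem duplication is an insertion
#' of its own copy, so the two rule types genuinely overlap, whereas
#' the other rule types (DEL vs INS by gap sign, INV by strand, TRA by
#' contig) are fixed by the observed alignment geometry and a model
#' vote cannot overturn them.
#'
#' @param sigs Inter-signature data frame from
#'   [extract_inter_signatures()].
#' @param rf The `rf` half of a filter bundle from [train_rf()].
#' @return The filtered (and possibly relabeled) signature frame.
#' @export
rf_filter <- function(sigs, rf) {
  if (nrow(sigs) == 0L) return(sigs)
  pred <- rf_predict(rf, as.matrix(sigs[, INTER_FEATURES, drop = FALSE]))
  keep <- pred != "false"
  out <- sigs[keep, , drop = FALSE]
  pred <- pred[keep]
  relabel <- pred != out$type & pred %in% c("INS", "DUP") &
    out$type %in% c("INS", "DUP")
  out$type[relabel] <- pred[relabel]
  rownames(out) <- NULL
  out
}

#' Label signatures or clusters against a truth set
#'
#' An item is labeled with a truth SV's type when it lies on the same
#' contig, its breakpoint distance is at most `tol_bp` and its length is
#' within `tol_frac` of the truth length (span types only); otherwise it
#' is labeled `false`.  The label is the truth type, so a
#' rule-misclassified item (e.g. a duplication collected as an
#' insertion) trains the filter to correct the type.
#'
#' @param items Data frame with `type`, `contig`, `start`, `end`,
#'   `length` (signature frame or cluster summary).
#' @param truth Truth data frame from [generate_truth()] (or parsed
#'   truth VCF records).
#' @param tol_bp Maximum breakpoint distance (default 500).
#' @param tol_frac Two-sided length-ratio window (default
#'   `c(0.7, 1.43)`).
#' @return Character vector of labels over `DEL, INS, DUP, INV, TRA,
#'   false`.
#' @export
generate_labels <- function(items, truth, tol_bp = 500,
                            tol_frac = c(0.7, 1.43)) {
  n <- nrow(items)
  if (n == 0L) return(character(0))
  if (nrow(truth) == 0L) {
    warning("empty truth set: labeling everything false")
    return(rep("false", n))
  }
  labels <- rep("false", n)
  for (i in seq_len(n)) {
    cand <- truth[truth$contig == items$contig[i], , drop = FALSE]
    if (!nrow(cand)) next
    d_start <- abs(cand$start - items$start[i])
    span <- cand$type %in% c("DEL", "DUP", "INV")
    d_end <- ifelse(span, abs(cand$end - items$end[i]), d_start)
    dist <- pmax(d_start, d_end)
    ratio <- items$length[i] / pmax(1, cand$length)
    ok <- dist <= tol_bp &
      (cand$type == "TRA" | (ratio >= tol_frac[1] & ratio <= tol_frac[2]))
    if (any(ok)) {
      labels[i] <- cand$type[ok][which.min(dist[ok])]
    }
  }
  labels
}
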