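#' Build a per-flower feature table for syndrome classification
#'
#' Features are the Procrustes shape coordinates plus centroid size and
#' corolla tube length (measured on the raw configurations when supplied).
#'
#' @param aligned an `aligned_set`.
#' @param specimens optional matching [specimen_set()]; when given, tube
#'   length is measured in raw scanner units, otherwise on the aligned
#'   shapes.
#' @param tube_base,tube_mouth landmark indices for the tube length.
#' @return data.frame with feature columns, plus `species` and `syndrome`
#'   (`"unknown"` marks flowers to be predicted) as attributes-free columns.
#' @export
feature_table <- function(aligned, specimens = NULL, tube_base = 1,
                          tube_mouth = 2) {
  X <- aligned$shape_coords
  colnames(X) <- paste0(rep(aligned$landmark_labels, each = 3),
                        c("_x", "_y", "_z"))
  tl <- vapply(seq_len(nrow(X)), function(i) {
    cfg <- if (!is.null(specimens)) specimens$coords[, , i]
           else unflatten_config(X[i, ])
    tube_length(cfg, tube_base, tube_mouth)
  }, numeric(1))
  df <- data.frame(X, check.names = FALSE)
  df$centroid_size <- aligned$centroid_sizes
  df$tube_length <- tl
  map <- aligned$syndrome_map
  df$species <- aligned$species
  df$syndrome <- map$syndrome[match(aligned$species, map$species)]
  df$syndrome[is.na(df$syndrome)] <- "unknown"
  df
}

#' Random-forest pollination-syndrome prediction
#'
#' Trains a random forest on the labelled flowers (stratified bootstrap per
#' class) and predicts class votes for every flower.  Importance is the
#' permutation-based mean decrease in out-of-bag accuracy per feature.
#'
#' @param features data.frame from [feature_table()] (columns `species` and
#'   `syndrome` are metadata, the rest are predictors).
#' @param n_trees number of trees (>= 100; default 500).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param mtry number of variables tried per split (default
#'   `floor(sqrt(p))`).
#' @return object of class `syndrome_prediction`: `predictions` data.frame
#'   (specimen-wise class + vote fractions), `oob_accuracy`, `importance`
#'   (sorted decreasing), `forest`.
#' @export
train_and_predict <- function(features, n_trees = 500, seed = 1, mtry = NULL) {
  if (n_trees < 100) stop("n_trees must be >= 100")
  meta <- c("species", "syndrome")
  predictors <- setdiff(names(features), meta)
  lab <- features$syndrome
  labelled <- lab != "unknown"
  classes <- unique(lab[labelled])
  if (length(classes) < 2) stop("need >= 2 labelled classes for training")
  Xtr <- features[labelled, predictors, drop = FALSE]
  ytr <- factor(lab[labelled])
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(predictors))))
  set.seed(seed)
  counts <- table(ytr)
  rf <- randomForest::randomForest(
    x = Xtr, y = ytr, ntree = n_trees, mtry = mtry, importance = TRUE,
    strata = ytr, sampsize = as.vector(counts))
  oob <- mean(rf$predicted == ytr)
  imp <- rf$importance[, "MeanDecreaseAccuracy"]
  imp <- sort(imp, decreasing = TRUE)
  votes <- matrix(NA_real_, nrow(features), nlevels(ytr),
                  dimnames = list(NULL, levels(ytr)))
  votes[labelled, ] <- rf$votes[, levels(ytr)]
  if (any(!labelled)) {
    pv <- stats::predict(rf, features[!labelled, predictors, drop = FALSE],
                         type = "vote", norm.votes = TRUE)
    votes[!labelled, ] <- pv[, levels(ytr)]
  }
  pred_class <- levels(ytr)[max.col(votes, ties.method = "first")]
  predictions <- data.frame(species = features$species,
                            known_syndrome = lab,
                            predicted = pred_class,
                            stringsAsFactors = FALSE)
  predictions <- cbind(predictions, as.data.frame(votes))
  structure(list(predictions = predictions,
                 oob_accuracy = oob,
                 importance = imp,
                 classes = levels(ytr),
                 n_trees = n_trees,
                 seed = seed,
                 forest = rf),
            class = "syndrome_prediction")
}

#' @export
print.syndrome_prediction <- function(x, ...) {
  cat(sprintf("syndrome_prediction: OOB accuracy %.3f (%d trees); top feature: %s\n",
              x$oob_accuracy, x$n_trees, names(x$importance)[1]))
  invisible(x)
}

#' Aggregate per-flower predictions to species-level syndromes
#'
#' Majority vote across a species' flowers.  A species is flagged
#' `ambiguous` when the top class is tied or carries at most half of the
#' flowers; the full vote table is always returned.
#'
#' @param prediction a `syndrome_prediction` (or its `predictions`
#'   data.frame).
#' @return data.frame with one row per species: `species`, `syndrome`,
#'   `support` (fraction of flowers voting for the top class), `ambiguous`,
#'   and per-class flower counts.
#' @export
species_assignment <- function(prediction) {
  df <- if (inherits(prediction, "syndrome_prediction")) prediction$predictions
        else prediction
  species <- unique(df$species)
  classes <- sort(unique(df$predicted))
  rows <- lapply(species, function(sp) {
    p <- df$predicted[df$species == sp]
    tab <- table(factor(p, levels = classes))
    top <- which.max(tab)
    support <- as.numeric(tab[top]) / length(p)
    tie <- sum(tab == max(tab)) > 1
    out <- data.frame(species = sp, syndrome = names(tab)[top],
                      support = support,
                      ambiguous = tie || support <= 0.5,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(t(as.matrix(tab))))
  })
  do.call(rbind, rows)
}
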