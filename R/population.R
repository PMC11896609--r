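#' Mean-impute and average a population response table
#'
#' Missing cells are replaced by the feature mean over individuals with
#' data (mean-imputation), then trials are averaged within individual so
#' each individual contributes one row.
#'
#' @param table tibble with columns `individual`, optionally `trial` and
#'   `hemisphere`, and one numeric column per (glomerulus, odor) feature;
#'   `NA` = missing.
#' @return Tibble: one row per individual, imputed and trial-averaged
#'   feature columns.
#' @export
impute_and_average <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot("individual" %in% names(table))
  meta <- intersect(c("individual", "trial", "hemisphere"), names(table))
  feats <- setdiff(names(table), meta)
  if (length(unique(table$individual)) < 2) {
    abort("need at least 2 individuals")
  }
  all_missing <- vapply(table[feats], function(x) all(is.na(x)), logical(1))
  if (any(all_missing)) {
    abort(paste0("feature missing for all individuals: ",
                 paste(feats[all_missing], collapse = ", ")))
  }
  imputed <- dplyr::mutate(table, dplyr::across(
    dplyr::all_of(feats),
    function(x) ifelse(is.na(x), mean(x, na.rm = TRUE), x)))
  dplyr::summarise(dplyr::group_by(imputed, .data$individual),
                   dplyr::across(dplyr::all_of(feats), mean),
                   .groups = "drop")
}

#' PCA of glomerulus-odor response features
#'
#' Principal components of mean-centered features with a deterministic sign
#' convention: within each component, the largest-magnitude loading is made
#' positive. Observations are individuals (or trials); features are
#' (glomerulus, odor) response pairs.
#'
#' @param features numeric matrix or all-numeric data frame (observations x
#'   features), or the output of [impute_and_average()] (metadata columns
#'   are dropped).
#' @return An `al_pca`: list with `loadings` (features x PCs), `scores`
#'   (observations x PCs), `variance_fraction`, `center`,
#'   `feature_names`, and `observations` (ids, when available).
#' @export
pca_responses <- function(features) {
  obs_ids <- NULL
  if (is.data.frame(features)) {
    meta <- intersect(c("individual", "trial", "hemisphere"),
                      names(features))
    if ("individual" %in% meta) obs_ids <- as.character(features$individual)
    features <- as.matrix(features[setdiff(names(features), meta)])
  }
  storage.mode(features) <- "double"
  if (nrow(features) < 2) abort("need at least 2 observations")
  if (all(abs(sweep(features, 2, colMeans(features))) < 1e-12)) {
    abort("constant feature matrix has no principal components")
  }
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = vf, center = pc$center,
                 feature_names = colnames(features),
                 observations = obs_ids),
            class = "al_pca")
}

#' @export
print.al_pca <- function(x, ...) {
  cat("<al_pca> ", nrow(x$scores), " observations x ",
      nrow(x$loadings), " features; PC1 ",
      round(100 * x$variance_fraction[1], 1), "% variance\n", sep = "")
  invisible(x)
}

#' Glomerular organization index of PCA loadings
#'
#' Quantifies how much of the loading energy of the top principal
#' components is organized by glomerulus rather than by odor. For PC k
#' with loadings l(g, o) over glomerulus-odor features,
#' `GOI_k = sum_g n_g * mean_o(l)^2 / sum(l^2)` - the between-glomerulus
#' share of loading energy: 1 when loadings are constant within every
#' glomerulus, 0 when they sum to zero within every glomerulus, about
#' 1/n_odors for unstructured loadings. The index is the
#' variance-fraction-weighted mean over the top `K` PCs.
#'
#' @param pca an `al_pca`.
#' @param blocks factor/character: the glomerulus of each feature. If
#'   `NULL`, parsed from feature names of the form `"glom:odor"`.
#' @param K number of leading PCs to average (default 5).
#' @return Index in \[0, 1\].
#' @export
glomerular_organization_index <- function(pca, blocks = NULL, K = 5) {
  if (is.null(blocks)) {
    blocks <- sub(":.*$", "", pca$feature_names)
  }
  blocks <- as.character(blocks)
  stopifnot(length(blocks) == nrow(pca$loadings))
  if (any(table(blocks) == 0)) abort("empty glomerulus block")
  K <- min(K, ncol(pca$loadings))
  goi_k <- vapply(seq_len(K), function(k) {
    l <- pca$loadings[, k]
    between <- tapply(l, blocks, function(v) length(v) * mean(v)^2)
    sum(between) / sum(l^2)
  }, numeric(1))
  w <- pca$variance_fraction[seq_len(K)]
  sum(goi_k * w) / sum(w)
}

#' Linear preference model
#'
#' An affine map from a named neural predictor to a behavioral preference
#' score: `preference = beta0 + beta1 * predictor`. Predictors are either a
#' principal-component score of a stated feature space (e.g. PC 2 of PN
#' calcium responses, the odor-vs-odor model with beta0 = -0.058,
#' beta1 = -0.081) or a named feature contrast such as DM2 - DC2.
#'
#' @param beta0 intercept.
#' @param beta1 slope.
#' @param predictor predictor name, e.g. `"PC2"` or `"DM2-DC2"`.
#' @return A `preference_model`.
#' @export
preference_model <- function(beta0, beta1, predictor = "PC2") {
  structure(list(beta0 = beta0, beta1 = beta1, predictor = predictor),
            class = "preference_model")
}

#' Read / write a preference model as JSON
#'
#' @param path JSON file with fields `beta0`, `beta1`, `predictor`.
#' @return A [preference_model()].
#' @export
read_preference_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  preference_model(j$beta0, j$beta1, j$predictor %||% "PC2")
}

#' @rdname read_preference_model
#' @param model a [preference_model()].
#' @export
write_preference_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' Apply a linear preference model
#'
#' Resolves the model's predictor against per-individual scores or
#' features and returns `beta0 + beta1 * predictor`. A `"PC<k>"` predictor
#' resolves against a score matrix/tibble with a matching column; a
#' `"A-B"` contrast resolves as the difference of the mean response across
#' the features of glomerulus A and glomerulus B.
#'
#' @param model a [preference_model()].
#' @param scores named vector, matrix or tibble of per-individual predictor
#'   values: either PC scores (column `PC2` etc.) or glomerulus-odor
#'   features named `"glom:odor"`.
#' @return Numeric vector of predicted preferences.
#' @export
apply_preference_model <- function(model, scores) {
  pred <- model$predictor
  val <- if (is.numeric(scores) && is.null(dim(scores))) {
    scores
  } else {
    m <- if (is.data.frame(scores)) {
      as.matrix(scores[vapply(scores, is.numeric, logical(1))])
    } else as.matrix(scores)
    if (pred %in% colnames(m)) {
      m[, pred]
    } else if (grepl("-", pred, fixed = TRUE)) {
      parts <- strsplit(pred, "-", fixed = TRUE)[[1]]
      gl <- sub(":.*$", "", colnames(m))
      if (!all(parts %in% gl)) {
        abort(paste0("cannot resolve predictor '", pred, "'"))
      }
      rowMeans(m[, gl == parts[1], drop = FALSE]) -
        rowMeans(m[, gl == parts[2], drop = FALSE])
    } else {
      abort(paste0("cannot resolve predictor '", pred, "'"))
    }
  }
  model$beta0 + model$beta1 * val
}

#' Linear-logistic classification with twofold cross-validation
#'
#' Trains a linear logistic classifier on half the observations, evaluates
#' on the other half, then swaps the folds; accuracy is the fraction of
#' observations classified correctly across both folds. Folds are
#' stratified by class and differ in size by at most one.
#'
#' @param scores numeric matrix/data frame of predictors (e.g. the first
#'   `n_pcs` PC scores per individual).
#' @param labels two-level factor (or coercible) of class labels.
#' @param n_pcs use only the first `n_pcs` columns (default: all).
#' @param seed integer seed for the fold split.
#' @return Classification accuracy in \[0, 1\].
#' @export
classify_individuals <- function(scores, labels, n_pcs = NULL, seed = 1) {
  m <- as.matrix(scores)
  if (!is.null(n_pcs)) m <- m[, seq_len(n_pcs), drop = FALSE]
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("need at least 2 classes")
  if (any(table(labels) < 2)) abort("each class needs at least 2 members")
  df <- data.frame(y = labels, m)
  fold <- integer(nrow(df))
  withr::with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep(1:2, length.out = length(idx))
    }
  })
  correct <- logical(nrow(df))
  for (f in 1:2) {
    train <- df[fold != f, , drop = FALSE]
    test <- df[fold == f, , drop = FALSE]
    fit <- suppressWarnings(glm(y ~ ., data = train, family = binomial()))
    p <- predict(fit, newdata = test, type = "response")
    correct[fold == f] <- (p > 0.5) == (test$y == levels(labels)[2])
  }
  mean(correct)
}

#' Within- and across-individual response distances
#'
#' Distances between trial-level response projections. For each
#' individual, the within distance averages the mean pairwise distance
#' among left-hemisphere trials, among right-hemisphere trials, and
#' between left and right trials; the across distance is computed
#' identically against the trials of every other individual.
#'
#' @param projections numeric matrix of trial projections (rows align with
#'   `individual` / `hemisphere`).
#' @param individual individual id per row.
#' @param hemisphere optional hemisphere label per row (`"L"`/`"R"`); when
#'   absent all trials are pooled in one category.
#' @return Tibble `individual`, `within`, `across`. Individuals with no
#'   valid within comparison are dropped with a warning.
#' @export
response_distances <- function(projections, individual, hemisphere = NULL) {
  m <- as.matrix(projections)
  individual <- as.character(individual)
  hemisphere <- if (is.null(hemisphere)) rep("L", nrow(m)) else
    as.character(hemisphere)
  stopifnot(nrow(m) == length(individual), length(individual) ==
              length(hemisphere))
  D <- as.matrix(stats::dist(m))
  inds <- unique(individual)
  if (length(inds) < 2) abort("need at least 2 individuals")

  mean_between <- function(rows_a, rows_b, exclude_self = FALSE) {
    if (!length(rows_a) || !length(rows_b)) return(NA_real_)
    sub <- D[rows_a, rows_b, drop = FALSE]
    if (exclude_self) {
      pairs <- sub[upper.tri(sub)]
      if (!length(pairs)) return(NA_real_)
      mean(pairs)
    } else mean(sub)
  }

  res <- purrr::map_dfr(inds, function(i) {
    mine <- which(individual == i)
    theirs <- which(individual != i)
    L <- mine[hemisphere[mine] == "L"]; R <- mine[hemisphere[mine] == "R"]
    within <- mean(c(mean_between(L, L, TRUE), mean_between(R, R, TRUE),
                     mean_between(L, R)), na.rm = TRUE)
    oL <- theirs[hemisphere[theirs] == "L"]
    oR <- theirs[hemisphere[theirs] == "R"]
    across_lr <- mean(c(mean_between(L, oR), mean_between(R, oL)),
                      na.rm = TRUE)
    across <- mean(c(mean_between(L, oL), mean_between(R, oR), across_lr),
                   na.rm = TRUE)
    tibble::tibble(individual = i, within = within, across = across)
  })
  bad <- is.nan(res$within)
  if (any(bad)) {
    warn(paste0("excluding individuals with no within-fly comparison: ",
                paste(res$individual[bad], collapse = ", ")))
    res <- res[!bad, , drop = FALSE]
  }
  res
}
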