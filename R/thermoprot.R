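#' Map an optimal growth temperature to a thermal class
#'
#' Banding used throughout: psychrophilic (<15), mesophilic (25-37),
#' thermophilic (45-70), hyperthermophilic (>80), all in degrees C.
#' Temperatures falling between bands return `NA` (unlabeled) rather than
#' being snapped to the nearest band.
#'
#' @param ogt Numeric vector of temperatures in degrees C.
#' @return Character vector of class names or `NA`.
#' @export
band_ogt_to_class <- function(ogt) {
  out <- rep(NA_character_, length(ogt))
  out[ogt < 15] <- "psychrophilic"
  out[ogt >= 25 & ogt <= 37] <- "mesophilic"
  out[ogt >= 45 & ogt <= 70] <- "thermophilic"
  out[ogt > 80] <- "hyperthermophilic"
  out
}

# Maximum number of identically matched residue pairs over any global
# alignment of a and b = length of their longest common subsequence.
lcs_length <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0L)
  m <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = lcs_submat(), gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE)
  as.integer(round(m))
}

lcs_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- Biostrings::AA_ALPHABET
      m <- matrix(0, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1
      cache <<- m
    }
    cache
  }
})

#' Pairwise sequence identity
#'
#' Identity between two sequences under the clustering convention:
#' maximum number of matched identical residues over a global alignment,
#' divided by the length of the shorter sequence.
#'
#' @param a,b Residue strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pair_identity <- function(a, b) {
  lcs_length(a, b) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering
#'
#' CD-HIT-style greedy incremental clustering: records are sorted by
#' decreasing length (ties by id); each record joins the first existing
#' cluster whose representative shares [pair_identity()] at or above the
#' threshold, otherwise it founds a new cluster. Exact global-alignment
#' identities are used throughout (no word-filter heuristics), which is
#' appropriate at desk scale.
#'
#' @param records A `seq_records` tibble.
#' @param threshold Identity threshold in (0, 1\]; joining is inclusive
#'   (identity equal to the threshold joins).
#' @param seed Unused (the ordering rule makes the procedure
#'   deterministic); kept for interface stability.
#' @return Integer cluster ids named by record id, in input order.
#' @export
cluster_identity <- function(records, threshold = 0.4, seed = NULL) {
  stopifnot(nrow(records) >= 1, threshold > 0, threshold <= 1)
  ord <- order(-nchar(records$residues), records$id)
  reps <- integer(0)   # indices (into records) of cluster representatives
  assign <- integer(nrow(records))
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pair_identity(records$residues[reps[ci]],
                        records$residues[i]) >= threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  stats::setNames(assign, records$id)
}

#' Partition clusters into train/tune/validation sets
#'
#' Whole clusters are assigned to a single partition so that no pair of
#' similar sequences straddles a partition boundary. Clusters are visited
#' in seeded random order and each is given to the partition with the
#' largest remaining deficit relative to the requested fractions.
#'
#' @param assignment Named integer cluster vector from
#'   [cluster_identity()].
#' @param fractions Named numeric vector of target fractions (must sum
#'   to 1), e.g. `c(train = .8, tune = .1, validation = .1)`.
#' @param labels Optional class labels (same order as `assignment`); when
#'   given, every class must end up present in every partition, otherwise
#'   an error is raised.
#' @param seed Integer seed.
#' @return Named character vector: record id -> partition name.
#' @export
split_by_cluster <- function(assignment,
                             fractions = c(train = .8, tune = .1,
                                           validation = .1),
                             labels = NULL, seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  n <- length(assignment)
  cl_ids <- unique(assignment)
  if (length(cl_ids) == 1) {
    warning("all records fall in a single cluster; ",
            "everything goes to one partition")
  }
  sizes <- table(assignment)
  out <- rep(NA_character_, n)
  withr::with_seed(seed, {
    visit <- sample(cl_ids)
    got <- stats::setNames(numeric(length(fractions)), names(fractions))
    for (cl in visit) {
      deficit <- fractions - got / max(sum(got), 1)
      pick <- names(fractions)[which.max(deficit)]
      out[assignment == cl] <- pick
      got[pick] <- got[pick] + sizes[as.character(cl)]
    }
  })
  if (!is.null(labels)) {
    tab <- table(labels, out)
    if (any(tab == 0)) {
      stop("class balance error: some class is absent from a partition",
           call. = FALSE)
    }
  }
  stats::setNames(out, names(assignment))
}

#' Select g-gap dipeptide features by Gini importance
#'
#' Fits a random forest on the candidate g-gap compositions alone and
#' returns the top `k` descriptors by mean impurity-decrease (Gini)
#' importance, ties broken lexicographically by descriptor name.
#'
#' @param ggap_matrix Numeric matrix of candidate compositions (rows =
#'   sequences, columns = descriptors), e.g. from the internal candidate
#'   enumeration; see [enumerate_ggap_candidates()].
#' @param labels Binary class labels (factor or character), one per row.
#' @param k Number of descriptors to retain (default 10).
#' @param seed Integer seed for the forest.
#' @param num_trees Trees in the forest.
#' @return Character vector of `k` descriptor names, ordered by decreasing
#'   importance.
#' @export
select_ggap_features <- function(ggap_matrix, labels, k = 10, seed = 1,
                                 num_trees = 300) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    stop("feature selection needs two classes", call. = FALSE)
  }
  stopifnot(k <= ncol(ggap_matrix))
  df <- as.data.frame(ggap_matrix)
  names(df) <- make.names(colnames(ggap_matrix))
  fit <- ranger::ranger(x = df, y = labels, num.trees = num_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  ord <- order(-imp, colnames(ggap_matrix))
  colnames(ggap_matrix)[ord][seq_len(k)]
}

#' Declare a classifier specification
#'
#' @param scheme Binary scheme: `"PM"` (psychrophilic vs mesophilic),
#'   `"MT"`, `"TH"`, or `"MTH"` (mesophilic vs thermophilic +
#'   hyperthermophilic). The second-listed group is the positive class.
#' @param method One of `"random_forest"`, `"logistic_regression"`,
#'   `"gaussian_naive_bayes"`, `"k_nearest_neighbor"`,
#'   `"support_vector_machine"`.
#' @param grid Optional list of hyperparameter combinations (each a named
#'   list); defaults to a small documented grid per method.
#' @param standardize Z-score features with training statistics before
#'   fitting (default TRUE for margin/distance-based methods, FALSE for
#'   trees).
#' @param seed Integer seed.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(scheme = c("MTH", "PM", "MT", "TH"),
                            method = c("support_vector_machine",
                                       "random_forest",
                                       "logistic_regression",
                                       "gaussian_naive_bayes",
                                       "k_nearest_neighbor"),
                            grid = NULL, standardize = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  if (is.null(grid)) grid <- default_grid(method)
  stopifnot(length(grid) >= 1)
  if (is.null(standardize)) standardize <- method != "random_forest"
  structure(list(scheme = scheme, method = method, grid = grid,
                 standardize = standardize, seed = seed),
            class = "classifier_spec")
}

default_grid <- function(method) {
  switch(method,
    support_vector_machine = {
      g <- expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.001))
      lapply(seq_len(nrow(g)), function(i) {
        list(cost = g$cost[i],
             gamma = if (is.na(g$gamma[i])) "scale" else g$gamma[i])
      })
    },
    random_forest = list(list(num_trees = 500, mtry = NULL)),
    logistic_regression = list(list()),
    gaussian_naive_bayes = list(list(laplace = 0)),
    k_nearest_neighbor = lapply(c(5, 1, 15), function(k) list(k = k))
  )
}

#' Classes of a binary scheme
#'
#' @param scheme Scheme code.
#' @return List with `negative` and `positive` thermal-class vectors.
#' @export
scheme_classes <- function(scheme) {
  switch(scheme,
         PM = list(negative = "psychrophilic", positive = "mesophilic"),
         MT = list(negative = "mesophilic", positive = "thermophilic"),
         TH = list(negative = "thermophilic",
                   positive = "hyperthermophilic"),
         MTH = list(negative = "mesophilic",
                    positive = c("thermophilic", "hyperthermophilic")),
         stop("unknown scheme: ", scheme, call. = FALSE))
}

# labels (thermal classes) -> factor negative/positive for a scheme;
# records outside the scheme get NA.
scheme_binary <- function(thermal_class, scheme) {
  sc <- scheme_classes(scheme)
  out <- rep(NA_character_, length(thermal_class))
  out[thermal_class %in% sc$negative] <- "negative"
  out[thermal_class %in% sc$positive] <- "positive"
  factor(out, levels = c("negative", "positive"))
}

fit_one <- function(method, x, y, params, seed) {
  switch(method,
    support_vector_machine = {
      gamma <- if (identical(params$gamma, "scale")) {
        1 / (ncol(x) * max(mean(apply(x, 2, stats::var)), 1e-12))
      } else params$gamma
      e1071::svm(x = x, y = y, kernel = "radial", cost = params$cost,
                 gamma = gamma, scale = FALSE)
    },
    random_forest = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      ranger::ranger(x = df, y = y, num.trees = params$num_trees,
                     mtry = params$mtry, probability = TRUE, seed = seed,
                     num.threads = 1)
    },
    logistic_regression = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family =
                                    stats::binomial()))
    },
    gaussian_naive_bayes = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      e1071::naiveBayes(x = df, y = y, laplace = params$laplace %||% 0)
    },
    k_nearest_neighbor = list(train = x, y = y, k = params$k)
  )
}

predict_one <- function(method, fit, x) {
  score <- switch(method,
    support_vector_machine = {
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")
      # e1071 orients the decision value toward the first factor level;
      # normalize so that the positive class means a positive score
      if (startsWith(colnames(dv)[1], "negative")) -drop(dv) else drop(dv)
    },
    random_forest = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      stats::predict(fit, df, num.threads = 1)$predictions[, "positive"] - 0.5
    },
    logistic_regression = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      stats::predict(fit, df, type = "link")
    },
    gaussian_naive_bayes = {
      df <- as.data.frame(x); names(df) <- make.names(colnames(x))
      stats::predict(fit, df, type = "raw")[, "positive"] - 0.5
    },
    k_nearest_neighbor = {
      pr <- class::knn(fit$train, x, fit$y, k = fit$k, prob = TRUE,
                       use.all = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "positive", p, 1 - p) - 0.5
    }
  )
  unname(score)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  drop <- sdv == 0 | !is.finite(sdv)
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  }
  list(center = mu[!drop], scale = sdv[!drop],
       keep = colnames(x)[!drop])
}

standardize_apply <- function(x, std) {
  scale(x[, std$keep, drop = FALSE], center = std$center,
        scale = std$scale)
}

#' Train a binary thermophilicity classifier
#'
#' Features are standardized with training-set statistics (when the spec
#' says so); hyperparameters are chosen by grid search maximizing accuracy
#' on the separate tuning set, with ties resolved in favor of the first
#' grid point in declared order.
#'
#' @param spec A [classifier_spec()].
#' @param x_train,y_train Training feature matrix and binary factor
#'   (levels `negative`, `positive`).
#' @param x_tune,y_tune Tuning set (disjoint from training at cluster
#'   level).
#' @param selected_ggap Descriptor names baked into the model for later
#'   featurization of raw sequences.
#' @return A `trained_model`.
#' @export
train_classifier <- function(spec, x_train, y_train, x_tune, y_tune,
                             selected_ggap = NULL) {
  y_train <- factor(y_train, levels = c("negative", "positive"))
  y_tune <- factor(y_tune, levels = c("negative", "positive"))
  if (nlevels(droplevels(y_train)) < 2 || nlevels(droplevels(y_tune)) < 2) {
    stop("both classes must be present in train and tune sets",
         call. = FALSE)
  }
  std <- standardize_fit(x_train)
  xt <- if (spec$standardize) standardize_apply(x_train, std) else
    x_train[, std$keep, drop = FALSE]
  xu <- if (spec$standardize) standardize_apply(x_tune, std) else
    x_tune[, std$keep, drop = FALSE]
  best <- NULL
  best_acc <- -Inf
  for (params in spec$grid) {
    fit <- fit_one(spec$method, xt, y_train, params, spec$seed)
    acc <- mean((predict_one(spec$method, fit, xu) > 0) ==
                  (y_tune == "positive"))
    if (acc > best_acc) {
      best <- list(fit = fit, params = params)
      best_acc <- acc
    }
  }
  structure(list(spec = spec, fit = best$fit, params = best$params,
                 tune_accuracy = best_acc, std = std,
                 feature_names = std$keep, selected_ggap = selected_ggap,
                 n_train = table(y_train)),
            class = "trained_model")
}

#' Predict with a trained model
#'
#' @param object A `trained_model`.
#' @param x Feature matrix with (at least) the model's feature columns.
#' @param ... Unused.
#' @return Tibble with columns `score` (real-valued, positive means the
#'   positive class) and `class` (`negative`/`positive`).
#' @export
predict.trained_model <- function(object, x, ...) {
  xs <- if (object$spec$standardize) standardize_apply(x, object$std) else
    x[, object$std$keep, drop = FALSE]
  s <- predict_one(object$spec$method, object$fit, xs)
  tibble::tibble(score = s,
                 class = ifelse(s > 0, "positive", "negative"))
}

#' Evaluation metrics from a confusion matrix
#'
#' @param tp,fp,fn,tn Confusion-matrix counts (positive = the scheme's
#'   positive class).
#' @return Named numeric vector: accuracy, recall, specificity, mcc. MCC is
#'   0 when its denominator vanishes.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(accuracy = (tp + tn) / n,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (denom > 0) (tp * tn - fp * fn) / denom else 0)
}

#' Cross-validate a classifier
#'
#' Stratified k-fold cross-validation. When a cluster assignment is given,
#' fold boundaries respect clusters (all members of a cluster share a
#' fold); otherwise every record is its own cluster. Each fold is fitted
#' with the first grid point of the spec (tuning is a separate concern, see
#' [train_classifier()]).
#'
#' @param spec A [classifier_spec()].
#' @param x Feature matrix.
#' @param y Binary factor (levels `negative`/`positive`).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @param clusters Optional integer cluster assignment (one per row).
#' @return List with `per_fold` (tibble of per-fold metrics) and `mean`
#'   (named numeric vector).
#' @export
cross_validate <- function(spec, x, y, folds = 5, seed = 1,
                           clusters = NULL) {
  stopifnot(folds >= 2)
  y <- factor(y, levels = c("negative", "positive"))
  n <- nrow(x)
  if (is.null(clusters)) clusters <- seq_len(n)
  # assign clusters to folds, stratified by the cluster's majority class
  cl_ids <- unique(clusters)
  cl_class <- vapply(cl_ids, function(cl) {
    names(which.max(table(y[clusters == cl])))
  }, character(1))
  fold_of_cluster <- stats::setNames(integer(length(cl_ids)),
                                     as.character(cl_ids))
  withr::with_seed(seed, {
    for (lv in unique(cl_class)) {
      idx <- sample(which(cl_class == lv))
      fold_of_cluster[as.character(cl_ids[idx])] <-
        rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of <- fold_of_cluster[as.character(clusters)]
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_of == f
    ytr <- droplevels(y[!test])
    if (nlevels(ytr) < 2 || length(unique(y[test])) < 2) {
      stop(sprintf("stratification error: fold %d lacks a class", f),
           call. = FALSE)
    }
    std <- suppressWarnings(standardize_fit(x[!test, , drop = FALSE]))
    xt <- if (spec$standardize) {
      standardize_apply(x[!test, , drop = FALSE], std)
    } else x[!test, std$keep, drop = FALSE]
    xe <- if (spec$standardize) {
      standardize_apply(x[test, , drop = FALSE], std)
    } else x[test, std$keep, drop = FALSE]
    fit <- fit_one(spec$method, xt, y[!test], spec$grid[[1]], spec$seed)
    pred <- predict_one(spec$method, fit, xe) > 0
    truth <- y[test] == "positive"
    per_fold[[f]] <- c(fold = f, confusion_metrics(
      tp = sum(pred & truth), fp = sum(pred & !truth),
      fn = sum(!pred & truth), tn = sum(!pred & !truth)))
  }
  per_fold <- tibble::as_tibble(do.call(rbind, per_fold))
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("accuracy", "recall", "specificity",
                                    "mcc")]))
}

#' Predict thermophilicity for raw sequences
#'
#' Featurizes the sequences with the model's selected g-gap descriptors and
#' applies the model. Sequences too short to hold any dipeptide window get
#' a zero g-gap block and are flagged in the output.
#'
#' @param model A `trained_model` with `selected_ggap` set.
#' @param records A `seq_records` tibble.
#' @return Tibble with columns `id`, `score`, `class`, `short_sequence`.
#' @export
predict_thermophilicity <- function(model, records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(id = character(), score = numeric(),
                          class = character(), short_sequence = logical()))
  }
  if (is.null(model$selected_ggap)) {
    stop("model carries no g-gap descriptor list", call. = FALSE)
  }
  x <- featurize_set(records, model$selected_ggap)
  maxg <- max(parse_ggap(model$selected_ggap)$g)
  short <- nchar(records$residues) <= maxg + 1
  p <- stats::predict(model, x)
  tibble::tibble(id = records$id, score = p$score, class = p$class,
                 short_sequence = short)
}

#' Save a trained model
#'
#' JSON envelope holding the versioned metadata (scheme, method, selected
#' dipeptides, feature names, standardization statistics, tuned
#' hyperparameters) plus the fitted R object serialized in base64, so that
#' reloaded models reproduce predictions bit-identically.
#'
#' @param model A `trained_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(
    format = "petminer_model", version = 1L,
    scheme = model$spec$scheme, method = model$spec$method,
    standardize = model$spec$standardize, seed = model$spec$seed,
    params = model$params, tune_accuracy = model$tune_accuracy,
    selected_ggap = model$selected_ggap,
    feature_names = model$feature_names,
    center = as.list(model$std$center), scale = as.list(model$std$scale),
    n_train = as.list(model$n_train),
    fit_rds_base64 = jsonlite::base64_enc(serialize(model, NULL))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a trained model
#'
#' @param path Path written by [save_model()].
#' @return A `trained_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "petminer_model")) {
    stop("not a petminer model file: ", path, call. = FALSE)
  }
  unserialize(jsonlite::base64_dec(obj$fit_rds_base64))
}
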