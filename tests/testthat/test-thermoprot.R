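test_that("OGT banding follows the four thermal classes with gaps", {
  expect_equal(band_ogt_to_class(c(10, 55, 30, 90, 40, 75, 14.9, 15)),
               c("psychrophilic", "thermophilic", "mesophilic",
                 "hyperthermophilic", NA, NA, "psychrophilic", NA))
  expect_equal(band_ogt_to_class(c(25, 37, 45, 70, 80, 80.01)),
               c("mesophilic", "mesophilic", "thermophilic",
                 "thermophilic", NA, "hyperthermophilic"))
})

test_that("pairwise identity equals the LCS oracle", {
  withr::with_seed(8, {
    for (i in 1:15) {
      a <- paste(sample(amino_acids(), sample(5:40, 1), TRUE),
                 collapse = "")
      b <- paste(sample(amino_acids(), sample(5:40, 1), TRUE),
                 collapse = "")
      expect_equal(pair_identity(a, b),
                   lcs_oracle(a, b) / min(nchar(a), nchar(b)))
    }
  })
})

test_that("greedy clustering groups identical and splits unrelated sequences", {
  recs <- seq_records(c("a", "b"), c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(unname(cluster_identity(recs, 0.4)), c(1, 1))
  recs2 <- seq_records(c("a", "b"),
                       c(strrep("A", 10), strrep("C", 10)))
  expect_equal(length(unique(cluster_identity(recs2, 0.4))), 2)
  # identity exactly at the threshold joins (inclusive rule)
  a <- "AAAAACCCCC"; b <- "AAGGG"
  expect_equal(lcs_oracle(a, b) / 5, 0.4)
  recs3 <- seq_records(c("a", "b"), c(a, b))
  expect_equal(length(unique(cluster_identity(recs3, 0.4))), 1)
})

test_that("cluster-aware splits never straddle partitions and balance classes", {
  recs <- seq_records(sprintf("s%02d", 1:30),
                      random_seqs(30, c(30, 60), seed = 14))
  cl <- rep(1:10, each = 3)
  names(cl) <- recs$id
  labs <- rep(c("pos", "neg"), 15)
  part <- split_by_cluster(cl, c(train = .6, tune = .2, validation = .2),
                           labels = labs, seed = 2)
  for (g in unique(cl)) {
    expect_length(unique(part[cl == g]), 1)
  }
  part2 <- split_by_cluster(cl, c(train = .6, tune = .2, validation = .2),
                            labels = labs, seed = 2)
  expect_identical(part, part2)
  expect_warning(split_by_cluster(stats::setNames(rep(1, 5),
                                                  letters[1:5])),
                 "single cluster")
})

test_that("Gini selection keeps k descriptors and ignores dead features", {
  withr::with_seed(9, {
    n <- 120
    x <- matrix(stats::runif(n * 20), n, 20)
    colnames(x) <- enumerate_ggap_candidates(0)[1:20]
    y <- rep(c("positive", "negative"), each = n / 2)
    x[y == "positive", 1:10] <- x[y == "positive", 1:10] + 1  # informative
    x[, 11:15] <- 0.5                                        # constant
  })
  sel <- select_ggap_features(x, y, k = 10, seed = 4)
  expect_length(sel, 10)
  expect_false(any(colnames(x)[11:15] %in% sel))
  expect_error(select_ggap_features(x, rep("positive", nrow(x)), k = 3),
               "two classes")
})

test_that("training tunes on the separate set and is deterministic", {
  withr::with_seed(10, {
    n <- 80
    x <- matrix(stats::rnorm(2 * n * 2), 2 * n, 2,
                dimnames = list(NULL, c("f1", "f2")))
    y <- rep(c("negative", "positive"), n)  # alternating
    x[y == "positive", 1] <- x[y == "positive", 1] + 6  # separable
  })
  tr <- seq_len(100); tu <- 101:160
  spec <- classifier_spec("MTH", "support_vector_machine", seed = 3)
  m1 <- train_classifier(spec, x[tr, ], y[tr], x[tu, ], y[tu])
  expect_equal(m1$tune_accuracy, 1)
  m2 <- train_classifier(spec, x[tr, ], y[tr], x[tu, ], y[tu])
  expect_identical(predict(m1, x)$score, predict(m2, x)$score)
})

test_that("zero-variance features are dropped with a warning", {
  withr::with_seed(10, {
    x <- cbind(f1 = stats::rnorm(40), dead = rep(1, 40),
               f2 = stats::rnorm(40))
    y <- rep(c("negative", "positive"), 20)
  })
  spec <- classifier_spec("MTH", "logistic_regression")
  expect_warning(
    m <- train_classifier(spec, x, y, x, y),
    "zero-variance")
  expect_false("dead" %in% m$feature_names)
})

test_that("model serialization round-trips predictions bit-identically", {
  withr::with_seed(12, {
    x <- matrix(stats::rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- factor(ifelse(x[, 1] + stats::rnorm(200) > 0, "positive",
                       "negative"), levels = c("negative", "positive"))
    xnew <- matrix(stats::rnorm(100 * 5), 100, 5,
                   dimnames = list(NULL, paste0("f", 1:5)))
  })
  spec <- classifier_spec("MTH", "support_vector_machine", seed = 8)
  m <- train_classifier(spec, x[1:150, ], y[1:150], x[151:200, ],
                        y[151:200])
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m, xnew)$score, predict(m2, xnew)$score)
})

test_that("confusion metrics match their closed forms", {
  m <- confusion_metrics(tp = 8, fp = 2, fn = 1, tn = 9)
  expect_equal(unname(m["mcc"]), (8 * 9 - 2 * 1) / sqrt(10 * 9 * 11 * 10))
  expect_equal(round(unname(m["mcc"]), 4), 0.7035)
  # all-positive predictions on a balanced set
  ap <- confusion_metrics(tp = 10, fp = 10, fn = 0, tn = 0)
  expect_equal(unname(ap["recall"]), 1)
  expect_equal(unname(ap["specificity"]), 0)
  expect_equal(unname(ap["mcc"]), 0)
})

test_that("cross-validation reports per-fold metrics and flags bad folds", {
  withr::with_seed(15, {
    x <- matrix(stats::rnorm(100 * 3), 100, 3,
                dimnames = list(NULL, paste0("f", 1:3)))
    y <- rep(c("negative", "positive"), 50)
    x[y == "positive", 1] <- x[y == "positive", 1] + 5
  })
  spec <- classifier_spec("MTH", "logistic_regression")
  cv <- suppressWarnings(cross_validate(spec, x, y, folds = 5, seed = 2))
  expect_equal(nrow(cv$per_fold), 5)
  expect_gte(cv$mean[["accuracy"]], 0.9)
  # three positives cannot stratify into five folds
  y2 <- c(rep("positive", 3), rep("negative", 97))
  expect_error(suppressWarnings(
    cross_validate(spec, x, y2, folds = 5, seed = 2)),
    "stratification")
})

test_that("thermophilicity prediction featurizes raw sequences and flags short ones", {
  g <- gen_ogt_proteomes(n_per_class = 60, delta = 0.15, seed = 44,
                         length_range = c(80, 120))
  sel <- fixed_ggap_set()
  x <- featurize_set(g$records, sel)
  y <- ifelse(g$truth$class == "thermophilic", "positive", "negative")
  spec <- classifier_spec("MTH", "support_vector_machine", seed = 1,
                          grid = list(list(cost = 1, gamma = "scale")))
  ord <- as.vector(rbind(1:60, 61:120))  # interleave the two classes
  tr <- ord[1:80]; tu <- ord[81:120]
  m <- suppressWarnings(  # rare dipeptides may be constant at this n
    train_classifier(spec, x[tr, ], y[tr], x[tu, ], y[tu],
                     selected_ggap = sel))
  out <- predict_thermophilicity(m, g$records[1:10, ])
  expect_equal(out$id, g$records$id[1:10])
  expect_false(any(out$short_sequence))
  # determinism: same input, same labels
  out2 <- predict_thermophilicity(m, g$records[1:10, ])
  expect_identical(out$score, out2$score)
  empty <- predict_thermophilicity(m, g$records[0, ])
  expect_equal(nrow(empty), 0)
})
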