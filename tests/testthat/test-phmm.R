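test_that("model building follows the gap rule and normalization invariants", {
  aln <- protein_msa(paste0("s", 1:3), rep("ACDEFGHIKL", 3))
  m <- build_phmm(aln)
  expect_equal(m$M, 10)
  consensus <- strsplit("ACDEFGHIKL", "")[[1]]
  expect_equal(amino_acids()[apply(m$match_emissions, 1, which.max)],
               consensus)
  # a 60%-gap column is not a match state under the 0.5 rule
  aln2 <- protein_msa(paste0("s", 1:5),
                      c("A-CDE", "A-CDE", "AWCDE", "A-CDE", "A-CDE"))
  m2 <- build_phmm(aln2)
  expect_equal(m2$M, 4)
  expect_equal(m2$column_map, c(1L, 3L, 4L, 5L))
  expect_error(build_phmm(protein_msa(c("a", "b"), c("-", "-"))),
               "no match states")
})

test_that("emission and transition rows stay normalized over random alignments", {
  withr::with_seed(19, {
    for (i in 1:40) {
      n <- sample(2:8, 1); L <- sample(3:20, 1)
      rows <- vapply(seq_len(n), function(j) {
        s <- sample(c(amino_acids(), "-"), L, TRUE,
                    prob = c(rep(0.9 / 20, 20), 0.1))
        paste(s, collapse = "")
      }, character(1))
      ok <- colMeans(do.call(rbind,
                             strsplit(rows, "")) == "-") <= 0.5
      if (!any(ok)) next
      m <- build_phmm(protein_msa(paste0("s", 1:n), rows),
                      weights = sample(c("uniform", "henikoff"), 1))
      expect_true(all(abs(rowSums(m$match_emissions) - 1) < 1e-12))
      expect_true(all(m$match_emissions > 0))
      if (m$M > 1) {
        expect_true(all(abs(m$trans$mm + m$trans$mi + m$trans$md - 1)
                        < 1e-12))
        expect_true(all(abs(m$trans$im + m$trans$ii - 1) < 1e-12))
        expect_true(all(abs(m$trans$dm + m$trans$dd - 1) < 1e-12))
      }
    }
  })
})

test_that("forward scores match exhaustive path enumeration on toy models", {
  for (M in 1:3) {
    mod <- mk_toy_model(M, seed = 100 + M)
    for (L in 1:3) {
      for (s in all_strings(L)) {
        expect_equal(forward_score(mod, s), brute_force_bits(mod, s),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("a consensus sequence outscores its reversal for an asymmetric model", {
  mod <- mk_toy_model(4, seed = 41)
  cons <- paste(amino_acids()[apply(mod$match_emissions, 1, which.max)],
                collapse = "")
  rev <- paste(rev(strsplit(cons, "")[[1]]), collapse = "")
  if (cons != rev) {
    expect_gt(brute_force_bits(mod, cons), brute_force_bits(mod, rev))
    expect_gt(forward_score(mod, cons), forward_score(mod, rev))
  }
})

test_that("forward dominates viterbi, and they agree on single-path cases", {
  withr::with_seed(23, {
    for (i in 1:25) {
      mod <- mk_toy_model(sample(1:4, 1), seed = 200 + i)
      s <- paste(sample(amino_acids(), sample(1:6, 1), TRUE),
                 collapse = "")
      f <- forward_score(mod, s)
      v <- viterbi_score(mod, s)
      expect_gte(f, v$bits - 1e-9)
    }
  })
  # M = 1 with a single residue admits exactly one path
  mod1 <- mk_toy_model(1, seed = 77)
  expect_equal(forward_score(mod1, "A"), viterbi_score(mod1, "A")$bits,
               tolerance = 1e-12)
})

test_that("viterbi paths are valid state sequences of the architecture", {
  withr::with_seed(29, {
    for (i in 1:30) {
      mod <- mk_toy_model(sample(2:4, 1), seed = 300 + i)
      s <- paste(sample(amino_acids(), sample(2:7, 1), TRUE),
                 collapse = "")
      path <- viterbi_score(mod, s)$path
      core <- path[path$state %in% c("M", "I", "D"), ]
      expect_gte(nrow(core[core$state == "M", ]), 1)
      # match/delete indices strictly increase; inserts repeat their index
      mi <- core$index[core$state != "I"]
      expect_true(all(diff(mi) >= 1))
      # emitted steps equal the sequence length
      expect_equal(sum(path$state %in% c("N", "M", "I", "C")), nchar(s))
    }
  })
})

test_that("search ranks hits by score with strict thresholds and id ties", {
  fam <- gen_homolog_family(n_active = 6, n_inactive = 0, length = 40,
                            mutation_rate = 0.05, seed = 31)
  mod <- build_phmm(fam$alignment)
  db <- c(fam$records$residues[1:3],
          random_seqs(3, c(40, 40), seed = 32))
  names(db) <- c("fam1", "fam2", "fam3", "rnd1", "rnd2", "rnd3")
  hits <- hmm_search(mod, db)
  expect_equal(nrow(hits), 6)
  expect_equal(hits$rank, 1:6)
  expect_true(!is.unsorted(rev(hits$bits)))
  expect_true(all(hits$id[1:3] %in% c("fam1", "fam2", "fam3")))
  top <- hits$bits[1]
  expect_equal(nrow(hmm_search(mod, db, score_threshold = top)), 0)
  expect_equal(nrow(hmm_search(mod, db, score_threshold = -Inf)), 6)
})

test_that("family members outrank unrelated sequences perfectly", {
  fam <- gen_homolog_family(n_active = 20, n_inactive = 0, length = 60,
                            mutation_rate = 0.05, seed = 2)
  mod <- build_phmm(fam$alignment)
  rnd <- random_seqs(20, c(50, 70), seed = 3)
  fam_bits <- vapply(fam$records$residues, forward_score, numeric(1),
                     model = mod)
  rnd_bits <- vapply(rnd, forward_score, numeric(1), model = mod)
  expect_equal(roc_auc(fam_bits, rnd_bits), 1)
})

test_that("model scores rise as synthetic families mutate less", {
  prev <- -Inf
  for (rate in c(0.3, 0.1, 0.02)) {
    sc <- vapply(1:3, function(seed) {
      fam <- gen_homolog_family(n_active = 8, n_inactive = 0, length = 50,
                                mutation_rate = rate, seed = seed)
      mod <- build_phmm(fam$alignment)
      cons <- paste(amino_acids()[apply(mod$match_emissions, 1,
                                        which.max)], collapse = "")
      forward_score(mod, cons)
    }, numeric(1))
    expect_gt(mean(sc), prev)
    prev <- mean(sc)
  }
})

test_that("AUC follows the Mann-Whitney convention including ties", {
  expect_equal(roc_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(1, 3), c(2, 4)), 0.25)
  expect_equal(roc_auc(c(5, 5, 5), c(5, 5)), 0.5)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
  # invariance under strictly monotone transforms
  withr::with_seed(37, {
    p <- stats::rnorm(20); n <- stats::rnorm(15)
    a <- roc_auc(p, n)
    expect_equal(roc_auc(exp(p), exp(n)), a)
    expect_equal(roc_auc(p^3 + 5 * p, n^3 + 5 * n), a)
  })
  # cross-check against an established implementation
  withr::with_seed(38, {
    p <- stats::rnorm(30, 1); n <- stats::rnorm(30)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(1, 0), each = 30), predictor = c(p, n),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(p, n), ref, tolerance = 1e-12)
  })
})

test_that("Spearman rho matches the rank-difference formula", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(out <- spearman_rho(c(1, 1, 1), c(1, 2, 3)),
                 "zero rank variance")
  expect_true(is.na(out))
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("discrimination on identical sequence sets is uninformative", {
  n <- 10
  aln <- protein_msa(sprintf("s%02d", 1:n), rep("ACDEFGHIKLWY", n))
  recs <- seq_records(sprintf("s%02d", 1:n), rep("ACDEFGHIKLWY", n),
                      activity_label = rep(c("active", "inactive"),
                                           each = n / 2))
  r <- discriminate_score_method(recs, aln, folds = 5, seed = 1)
  expect_equal(r$pooled_auc, 0.5)
  d <- discriminate_difference_method(recs, aln, folds = 5, seed = 1)
  expect_equal(d$pooled_auc, 0.5)
  expect_true(all(abs(d$scores$score) < 1e-9))
})

test_that("difference method keeps pace with the score method on subfamilies", {
  for (seed in 1:3) {
    fam <- gen_homolog_family(n_active = 15, n_inactive = 15, length = 80,
                              mutation_rate = 0.05, seed = seed)
    s <- discriminate_score_method(fam$records, fam$alignment, folds = 5,
                                   seed = seed)
    d <- discriminate_difference_method(fam$records, fam$alignment,
                                        folds = 5, seed = seed)
    expect_gte(d$pooled_auc, s$pooled_auc - 0.05)
    # determinism under a fixed seed
    s2 <- discriminate_score_method(fam$records, fam$alignment, folds = 5,
                                    seed = seed)
    expect_identical(s$scores$score, s2$scores$score)
  }
})

test_that("profile HMM serialization round-trips scores exactly", {
  fam <- gen_homolog_family(n_active = 5, n_inactive = 0, length = 30,
                            mutation_rate = 0.1, seed = 9)
  mod <- build_phmm(fam$alignment)
  f <- withr::local_tempfile(fileext = ".json")
  write_phmm(mod, f)
  mod2 <- read_phmm(f)
  expect_equal(mod2$M, mod$M)
  expect_equal(mod2$match_emissions, mod$match_emissions,
               tolerance = 1e-15)
  s <- random_seqs(5, c(20, 40), seed = 10)
  expect_equal(vapply(s, forward_score, numeric(1), model = mod),
               vapply(s, forward_score, numeric(1), model = mod2),
               tolerance = 1e-12)
})
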