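#' Profile HMM construction and scoring
#'
#' A Plan7-style profile hidden Markov model over protein sequences, built
#' from a multiple sequence alignment and scored in local alignment mode.
#' Architecture: flanking states N and C emit background residues with a
#' geometric self-loop; entry from B is uniform over the M match states;
#' exit to E is allowed from every match state with probability
#' 1/(M - k + 1) at state k (uniform over exit points), and from the last
#' delete state. Insert states sit between consecutive match states; delete
#' states are silent. Scores are reported in bits:
#' log2 P(sequence | model) - log2 P(sequence | null), where the null emits
#' i.i.d. background residues with geometric length matched to the model
#' length (r = M/(M+1)).
#'
#' @name phmm
NULL

new_profile_hmm <- function(M, column_map, match_emissions, insert_emissions,
                            trans, background, config = list()) {
  stopifnot(M >= 1, length(column_map) == M, !is.unsorted(column_map,
                                                          strictly = TRUE))
  checkrows <- function(m) {
    stopifnot(all(abs(rowSums(m) - 1) < 1e-12), all(m >= 0))
  }
  checkrows(match_emissions)
  if (M > 1) {
    checkrows(insert_emissions)
    for (nm in c("mm", "mi", "md", "im", "ii", "dm", "dd")) {
      stopifnot(length(trans[[nm]]) == M - 1)
    }
    tm <- cbind(trans$mm, trans$mi, trans$md)
    ti <- cbind(trans$im, trans$ii)
    td <- cbind(trans$dm, trans$dd)
    stopifnot(all(abs(rowSums(tm) - 1) < 1e-12),
              all(abs(rowSums(ti) - 1) < 1e-12),
              all(abs(rowSums(td) - 1) < 1e-12))
  }
  stopifnot(abs(sum(background) - 1) < 1e-12)
  structure(list(M = M, column_map = as.integer(column_map),
                 match_emissions = match_emissions,
                 insert_emissions = insert_emissions,
                 trans = trans, background = background, config = config),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm: %d match states (from %d alignment columns)\n",
              x$M, max(x$column_map)))
  invisible(x)
}

# Henikoff position-based sequence weights, normalized to mean 1.
henikoff_weights <- function(mat) {
  w <- numeric(nrow(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    keep <- col != "-"
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    w[keep] <- w[keep] + 1 / (r * as.numeric(tab[col[keep]]))
  }
  if (sum(w) == 0) return(rep(1, nrow(mat)))
  w * nrow(mat) / sum(w)
}

#' Build a profile HMM from an alignment
#'
#' Match states are the alignment columns whose gap fraction does not
#' exceed `match_gap_threshold` (default 0.5). Match emissions are
#' pseudocounted, background-mixed weighted residue counts; insert
#' emissions default to the background; transitions are estimated from the
#' observed per-row state paths with Laplace pseudocounts.
#'
#' @param aln A `protein_msa` with at least 2 rows.
#' @param match_gap_threshold Columns with gap fraction above this value
#'   become insert columns.
#' @param pseudocount Pseudocount weight mixed into emissions (relative to
#'   total observed weight) and added to each transition type.
#' @param background `"uniform"`, `"swissprot"`, or a named frequency
#'   vector over the 20 canonical residues.
#' @param weights `"uniform"` or `"henikoff"` position-based sequence
#'   weighting.
#' @return A `profile_hmm`.
#' @export
build_phmm <- function(aln, match_gap_threshold = 0.5, pseudocount = 1,
                       background = "uniform", weights = "uniform") {
  mat <- as.matrix(aln)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 alignment rows", call. = FALSE)
  bg <- if (is.character(background)) {
    switch(background,
           uniform = stats::setNames(rep(1 / 20, 20), amino_acids()),
           swissprot = background_frequencies(),
           stop("unknown background: ", background, call. = FALSE))
  } else {
    stopifnot(setequal(names(background), amino_acids()))
    background[amino_acids()] / sum(background)
  }
  gapfrac <- colMeans(mat == "-")
  match_cols <- which(gapfrac <= match_gap_threshold)
  M <- length(match_cols)
  if (M == 0) {
    stop("no match states: every column exceeds the gap threshold",
         call. = FALSE)
  }
  w <- switch(weights,
              uniform = rep(1, n),
              henikoff = henikoff_weights(mat),
              stop("unknown weighting scheme: ", weights, call. = FALSE))

  aa <- amino_acids()
  em <- matrix(0, M, 20, dimnames = list(NULL, aa))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    keep <- col %in% aa
    if (any(keep)) {
      cw <- tapply(w[keep], factor(col[keep], levels = aa), sum)
      cw[is.na(cw)] <- 0
      em[k, ] <- cw
    }
    em[k, ] <- (em[k, ] + pseudocount * bg) / (sum(em[k, ]) + pseudocount)
  }
  ie <- matrix(rep(bg, each = max(M - 1, 1)), max(M - 1, 1), 20,
               dimnames = list(NULL, aa))

  # transition counts from per-row state paths
  cn <- list(mm = 0, mi = 0, md = 0, im = 0, ii = 0, dm = 0, dd = 0)
  cnt <- lapply(cn, function(z) rep(0, max(M - 1, 1)))
  if (M > 1) {
    is_res <- mat != "-"
    for (r in seq_len(n)) {
      st <- ifelse(is_res[r, match_cols], "M", "D")
      for (k in seq_len(M - 1)) {
        between <- if (match_cols[k + 1] - match_cols[k] > 1) {
          sum(is_res[r, (match_cols[k] + 1):(match_cols[k + 1] - 1)])
        } else 0
        if (st[k] == "M") {
          if (between > 0) {
            cnt$mi[k] <- cnt$mi[k] + w[r]
            cnt$ii[k] <- cnt$ii[k] + w[r] * (between - 1)
            cnt$im[k] <- cnt$im[k] + w[r]
          } else if (st[k + 1] == "M") {
            cnt$mm[k] <- cnt$mm[k] + w[r]
          } else {
            cnt$md[k] <- cnt$md[k] + w[r]
          }
        } else {
          if (st[k + 1] == "M") cnt$dm[k] <- cnt$dm[k] + w[r]
          else cnt$dd[k] <- cnt$dd[k] + w[r]
        }
      }
    }
  }
  pc <- pseudocount
  tm <- cbind(cnt$mm + pc, cnt$mi + pc, cnt$md + pc)
  tm <- tm / rowSums(tm)
  ti <- cbind(cnt$im + pc, cnt$ii + pc)
  ti <- ti / rowSums(ti)
  td <- cbind(cnt$dm + pc, cnt$dd + pc)
  td <- td / rowSums(td)
  trans <- list(mm = tm[, 1], mi = tm[, 2], md = tm[, 3],
                im = ti[, 1], ii = ti[, 2], dm = td[, 1], dd = td[, 2])
  new_profile_hmm(M, match_cols, em, ie, trans, bg,
                  config = list(match_gap_threshold = match_gap_threshold,
                                pseudocount = pseudocount,
                                weights = weights))
}

# Shared scoring scaffold: precomputed log2 parameter set.
phmm_log_params <- function(model) {
  M <- model$M
  r <- M / (M + 1)
  exit_k <- 1 / (M - seq_len(M) + 1)
  list(
    M = M,
    lq = log2(r), l1q = log2(1 - r),
    lr = log2(r), l1r = log2(1 - r),
    lentry = -log2(M),
    lexit = log2(exit_k),
    lcont = log2(1 - exit_k[seq_len(max(M - 1, 0))]),
    lem = log2(model$match_emissions),
    lei = log2(model$insert_emissions),
    lmm = log2(model$trans$mm), lmi = log2(model$trans$mi),
    lmd = log2(model$trans$md),
    lim = log2(model$trans$im), lii = log2(model$trans$ii),
    ldm = log2(model$trans$dm), ldd = log2(model$trans$dd),
    lbg = log2(model$background)
  )
}

# log2 background emission per sequence position; ambiguity codes emit with
# probability 1/20 under both model and null, so they cancel in the odds.
seq_log_bg <- function(code, lbg) {
  out <- lbg[code]
  out[is.na(code)] <- log2(1 / 20)
  out
}

phmm_dp <- function(model, residues, algorithm = c("forward", "viterbi")) {
  algorithm <- match.arg(algorithm)
  p <- phmm_log_params(model)
  M <- p$M
  code <- aa_codes(residues)
  ccode <- code
  ccode[is.na(ccode)] <- 0L
  lbg_seq <- seq_log_bg(code, p$lbg)
  lei <- if (M > 1) p$lei else matrix(numeric(0), 0, 20)
  res <- .phmm_dp_cpp(ccode, p$lem, lei,
                      p$lmm, p$lmi, p$lmd, p$lim, p$lii, p$ldm, p$ldd,
                      lbg_seq, p$lexit, p$lcont, p$lq, p$l1q, p$lentry,
                      algorithm == "viterbi")
  bt <- if (algorithm == "viterbi") {
    list(M = res$btM, D = res$btD, I = res$btI, E = res$btE, C = res$btC)
  } else NULL
  list(logp = res$logp, bt = bt, code = code)
}

phmm_null_logp <- function(model, residues) {
  p <- phmm_log_params(model)
  code <- aa_codes(residues)
  sum(seq_log_bg(code, p$lbg)) + length(code) * p$lr + p$l1r
}

#' Forward bit score of a sequence under a profile HMM
#'
#' log2 of the ratio between the full (summed over all paths) local-mode
#' model likelihood and the null-model likelihood. Ambiguity codes are
#' emitted with background probability by every state and therefore cancel
#' in the odds ratio.
#'
#' @param model A `profile_hmm`.
#' @param residues Residue string.
#' @return Bit score (numeric scalar).
#' @export
forward_score <- function(model, residues) {
  dp <- phmm_dp(model, residues, "forward")
  dp$logp - phmm_null_logp(model, residues)
}

#' Viterbi bit score and best state path
#'
#' @param model A `profile_hmm`.
#' @param residues Residue string.
#' @return List with `bits` (numeric) and `path`, a data frame with columns
#'   `state` (N/M/I/D/C) and `index` (match/insert/delete state index, NA
#'   for flanks), one row per path step in sequence order (delete states
#'   emit nothing and appear between emitting steps).
#' @export
viterbi_score <- function(model, residues) {
  dp <- phmm_dp(model, residues, "viterbi")
  L <- length(dp$code)
  bits <- dp$logp - phmm_null_logp(model, residues)
  if (L == 0) return(list(bits = bits, path = NULL))
  bt <- dp$bt
  M <- model$M
  # trace C backwards to the exit position
  i <- L
  steps <- list()
  while (i >= 1 && bt$C[i] == 2L) {
    steps[[length(steps) + 1]] <- data.frame(state = "C", index = NA_integer_)
    i <- i - 1
  }
  stopifnot(i >= 1)  # exit position
  exit_choice <- bt$E[i]
  if (exit_choice == M + 1L) {
    # exited through D_M: walk the delete chain at position i
    k <- M
    while (k >= 2 && bt$D[i, k] == 2L) {
      steps[[length(steps) + 1]] <- data.frame(state = "D", index = k)
      k <- k - 1
    }
    steps[[length(steps) + 1]] <- data.frame(state = "D", index = k)
    cur <- list(state = "M", index = k - 1L)
  } else {
    cur <- list(state = "M", index = as.integer(exit_choice))
  }
  while (i >= 1) {
    if (cur$state == "M") {
      steps[[length(steps) + 1]] <- data.frame(state = "M", index = cur$index)
      prev <- bt$M[i, cur$index]
      i <- i - 1
      if (prev == 1L) { cur <- list(state = "N", index = NA); break }
      if (prev == 2L) cur <- list(state = "M", index = cur$index - 1L)
      if (prev == 3L) cur <- list(state = "I", index = cur$index - 1L)
      if (prev == 4L) {
        # walk delete chain at previous position
        k <- cur$index - 1L
        while (k >= 2 && bt$D[i, k] == 2L) {
          steps[[length(steps) + 1]] <- data.frame(state = "D", index = k)
          k <- k - 1L
        }
        steps[[length(steps) + 1]] <- data.frame(state = "D", index = k)
        cur <- list(state = "M", index = k - 1L)
      }
    } else if (cur$state == "I") {
      steps[[length(steps) + 1]] <- data.frame(state = "I", index = cur$index)
      prev <- bt$I[i, cur$index]
      i <- i - 1
      cur <- if (prev == 1L) list(state = "M", index = cur$index)
      else list(state = "I", index = cur$index)
    }
  }
  while (i >= 1) {
    steps[[length(steps) + 1]] <- data.frame(state = "N", index = NA_integer_)
    i <- i - 1
  }
  path <- do.call(rbind, rev(steps))
  rownames(path) <- NULL
  list(bits = bits, path = path)
}

#' Search a sequence collection with a profile HMM
#'
#' Scores every sequence with [forward_score()] and returns hits with
#' bit score strictly greater than `score_threshold`, ranked by decreasing
#' score with ties broken by id.
#'
#' @param model A `profile_hmm`.
#' @param records A `seq_records` tibble (or named character vector of
#'   residue strings).
#' @param score_threshold Bit-score cutoff (strict); `-Inf` returns all.
#' @return Tibble with columns `id`, `bits`, `rank`.
#' @export
hmm_search <- function(model, records, score_threshold = -Inf) {
  if (is.character(records)) {
    ids <- names(records); res <- unname(records)
  } else {
    ids <- records$id; res <- records$residues
  }
  bits <- vapply(res, function(s) forward_score(model, s), numeric(1),
                 USE.NAMES = FALSE)
  keep <- bits > score_threshold
  ord <- order(-bits[keep], ids[keep])
  tibble::tibble(id = ids[keep][ord], bits = bits[keep][ord],
                 rank = seq_along(ord))
}

#' ROC AUC by the Mann-Whitney rank statistic
#'
#' Probability that a positive score exceeds a negative score, counting
#' ties as half.
#'
#' @param scores_pos,scores_neg Numeric score vectors, both nonempty.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both score sets must be nonempty",
                               call. = FALSE)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Returns
#' `NA` with a warning when either variable has zero rank variance.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    warning("zero rank variance: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# Extract rows of a master alignment, drop all-gap columns, return msa.
sub_alignment <- function(aln, ids) {
  idx <- match(ids, aln$id)
  stopifnot(!anyNA(idx))
  m <- as.matrix(aln)[idx, , drop = FALSE]
  keep <- colSums(m != "-") > 0
  protein_msa(ids, apply(m[, keep, drop = FALSE], 1, paste, collapse = ""))
}

stratified_folds <- function(labels, folds, seed) {
  withr::with_seed(seed, {
    assign <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

discriminate_impl <- function(records, master_alignment, folds, seed,
                              difference) {
  lab <- records$activity_label
  if (anyNA(lab)) stop("all records need an activity_label", call. = FALSE)
  fold_of <- stratified_folds(lab, folds, seed)
  scores <- numeric(nrow(records))
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train_act <- records$id[fold_of != f & lab == "active"]
    if (length(train_act) < 2) {
      stop(sprintf("fold %d retains fewer than 2 actives in training", f),
           call. = FALSE)
    }
    hmm_a <- build_phmm(sub_alignment(master_alignment, train_act))
    test_seqs <- ungap(master_alignment)[records$id[test]]
    s <- vapply(test_seqs, function(x) forward_score(hmm_a, x), numeric(1))
    if (difference) {
      train_inact <- records$id[fold_of != f & lab == "inactive"]
      if (length(train_inact) < 2) {
        stop(sprintf("fold %d retains fewer than 2 inactives in training",
                     f), call. = FALSE)
      }
      hmm_i <- build_phmm(sub_alignment(master_alignment, train_inact))
      s <- s - vapply(test_seqs, function(x) forward_score(hmm_i, x),
                      numeric(1))
    }
    scores[test] <- s
  }
  fold_auc <- vapply(seq_len(folds), function(f) {
    idx <- which(fold_of == f)
    pos <- scores[idx][lab[idx] == "active"]
    neg <- scores[idx][lab[idx] == "inactive"]
    if (length(neg) == 0) {
      stop(sprintf("fold %d has no inactives to evaluate", f), call. = FALSE)
    }
    roc_auc(pos, neg)
  }, numeric(1))
  pooled_auc <- roc_auc(scores[lab == "active"], scores[lab == "inactive"])
  rho <- if (all(is.finite(records$activity_value))) {
    spearman_rho(scores, records$activity_value)
  } else NA_real_
  structure(list(
    method = if (difference) "difference" else "score",
    fold_auc = fold_auc, pooled_auc = pooled_auc, spearman = rho,
    scores = tibble::tibble(id = records$id, fold = fold_of,
                            activity_label = lab, score = scores)
  ), class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("%s-method discrimination: pooled AUC %.3f, Spearman rho %s\n",
              x$method, x$pooled_auc,
              ifelse(is.na(x$spearman), "NA", sprintf("%.3f", x$spearman))))
  invisible(x)
}

#' Score-method activity discrimination
#'
#' Cross-validated test of whether profile-HMM bit scores separate active
#' from inactive family members. Sequences are split into stratified folds;
#' in each round an HMM is built from the sub-alignment of the training
#' actives (rows extracted from one fixed master alignment with all-gap
#' columns dropped) and held-out actives and inactives are scored with it.
#' Held-out scores are pooled across folds; AUC uses the Mann-Whitney rank
#' statistic and rho is the Spearman correlation between pooled scores and
#' continuous activity values when those are available.
#'
#' @param records `seq_records` with `activity_label` (and optionally
#'   `activity_value`) set; all ids must be rows of `master_alignment`.
#' @param master_alignment A `protein_msa` containing every record.
#' @param folds Number of CV folds.
#' @param seed Integer seed controlling fold assignment.
#' @return A `discrimination_result`.
#' @export
discriminate_score_method <- function(records, master_alignment, folds = 5,
                                      seed = 1) {
  discriminate_impl(records, master_alignment, folds, seed,
                    difference = FALSE)
}

#' Difference-method activity discrimination
#'
#' As [discriminate_score_method()], but a second HMM is built from the
#' training inactives in each fold and the predictive score is
#' bits(active HMM) - bits(inactive HMM).
#'
#' @inheritParams discriminate_score_method
#' @return A `discrimination_result`.
#' @export
discriminate_difference_method <- function(records, master_alignment,
                                           folds = 5, seed = 1) {
  discriminate_impl(records, master_alignment, folds, seed,
                    difference = TRUE)
}

#' Serialize a profile HMM to a text file
#'
#' JSON with full numeric precision; `read_phmm()` restores an identical
#' model.
#'
#' @param model A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phmm <- function(model, path) {
  obj <- list(
    format = "petminer_phmm", version = 1L,
    M = model$M, column_map = model$column_map,
    match_emissions = model$match_emissions,
    insert_emissions = model$insert_emissions,
    trans = model$trans,
    background = as.list(model$background),
    config = model$config
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized profile HMM
#'
#' @param path Path written by [write_phmm()].
#' @return A `profile_hmm`.
#' @export
read_phmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "petminer_phmm")) {
    stop("not a petminer profile-HMM file: ", path, call. = FALSE)
  }
  em <- matrix(unlist(obj$match_emissions), nrow = obj$M,
               dimnames = list(NULL, amino_acids()))
  ie <- obj$insert_emissions
  if (is.list(ie)) ie <- matrix(unlist(ie), ncol = 20)
  if (is.null(dim(ie))) ie <- matrix(ie, ncol = 20)
  colnames(ie) <- amino_acids()
  if (is.null(dim(em))) em <- matrix(em, ncol = 20,
                                     dimnames = list(NULL, amino_acids()))
  bg <- unlist(obj$background)[amino_acids()]
  trans <- lapply(obj$trans, as.numeric)
  new_profile_hmm(obj$M, obj$column_map, em, ie, trans, bg,
                  config = obj$config)
}
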