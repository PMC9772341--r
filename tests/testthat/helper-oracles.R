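# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (explicit enumeration / grid search / plain loops) and
# share no code with the implementation paths they check.

# ---- profile-HMM brute force: enumerate every state path explicitly ----

brute_force_bits <- function(model, residues) {
  M <- model$M
  code <- match(strsplit(residues, "")[[1]], amino_acids())
  L <- length(code)
  r <- M / (M + 1); q <- r
  exitp <- 1 / (M - seq_len(M) + 1)
  contp <- 1 - exitp
  bg <- model$background
  em <- model$match_emissions; ie <- model$insert_emissions
  tr <- model$trans
  core_sum <- function(k, i, seg) {  # entering M_k, about to emit seg[i]
    if (i > length(seg)) return(0)
    p_emit <- em[k, seg[i]]
    i2 <- i + 1
    out <- 0
    if (i2 == length(seg) + 1) out <- out + p_emit * exitp[k]
    if (k < M) {
      cont <- contp[k]
      out <- out + p_emit * cont * tr$mm[k] * core_sum(k + 1, i2, seg)
      ins_sum <- function(kk, ii) {
        if (ii > length(seg)) return(0)
        pe <- ie[kk, seg[ii]]
        pe * tr$im[kk] * core_sum(kk + 1, ii + 1, seg) +
          pe * tr$ii[kk] * ins_sum(kk, ii + 1)
      }
      out <- out + p_emit * cont * tr$mi[k] * ins_sum(k, i2)
      del_sum <- function(kk, ii) {
        if (kk == M) return(if (ii == length(seg) + 1) 1 else 0)
        tr$dm[kk] * core_sum(kk + 1, ii, seg) +
          tr$dd[kk] * del_sum(kk + 1, ii)
      }
      out <- out + p_emit * cont * tr$md[k] * del_sum(k + 1, i2)
    }
    out
  }
  total <- 0
  for (n in 0:(L - 1)) for (cc in 0:(L - 1 - n)) {
    m <- L - n - cc
    seg <- code[(n + 1):(n + m)]
    pre <- if (n > 0) prod(q * bg[code[1:n]]) else 1
    suf <- if (cc > 0) prod(q * bg[code[(L - cc + 1):L]]) else 1
    core <- 0
    for (j in 1:M) core <- core + (1 / M) * core_sum(j, 1, seg)
    total <- total + pre * (1 - q) * core * suf * (1 - q)
  }
  null <- prod(bg[code]) * r^L * (1 - r)
  unname(log2(total) - log2(null))
}

# Random valid toy model with M match states (reproducible per seed).
mk_toy_model <- function(M, seed) {
  withr::with_seed(seed, {
    rdir <- function(n, k) {
      m <- matrix(stats::rexp(n * k), n, k)
      m / rowSums(m)
    }
    em <- rdir(M, 20); colnames(em) <- amino_acids()
    ie <- rdir(max(M - 1, 1), 20); colnames(ie) <- amino_acids()
    tm <- rdir(max(M - 1, 1), 3)
    ti <- rdir(max(M - 1, 1), 2)
    td <- rdir(max(M - 1, 1), 2)
    petminer:::new_profile_hmm(
      M, seq_len(M), em, ie,
      list(mm = tm[, 1], mi = tm[, 2], md = tm[, 3],
           im = ti[, 1], ii = ti[, 2], dm = td[, 1], dd = td[, 2]),
      stats::setNames(rep(1 / 20, 20), amino_acids()))
  })
}

# all strings of a given length over an alphabet
all_strings <- function(len, alphabet = c("A", "C")) {
  if (len == 0) return("")
  apply(do.call(expand.grid, rep(list(alphabet), len)), 1, paste,
        collapse = "")
}

# ---- longest common subsequence by plain dynamic programming ----

lcs_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (x[i] == y[j]) prev[j] + 1 else
        max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

# ---- isoelectric point by dense-grid sign change ----

pi_grid_oracle <- function(residues, step = 0.001) {
  pka <- feature_constants()$pka
  cnt <- table(factor(strsplit(residues, "")[[1]], levels = amino_acids()))
  charge <- function(pH) {
    pos <- c(1, cnt["H"], cnt["K"], cnt["R"])
    pkp <- pka[c("Nterm", "H", "K", "R")]
    neg <- c(1, cnt["D"], cnt["E"], cnt["C"], cnt["Y"])
    pkn <- pka[c("Cterm", "D", "E", "C", "Y")]
    sum(pos / (1 + 10^(pH - pkp))) - sum(neg / (1 + 10^(pkn - pH)))
  }
  grid <- seq(0, 14, by = step)
  ch <- vapply(grid, charge, numeric(1))
  i <- which(ch <= 0)[1]
  if (is.na(i)) return(14)
  if (i == 1) return(0)
  grid[i - 1] + step * ch[i - 1] / (ch[i - 1] - ch[i])
}

# ---- naive single-sequence featurization (plain loops) ----

naive_featurize <- function(residues, selected_ggap) {
  rc <- residue_classes(); cst <- feature_constants()
  s <- strsplit(residues, "")[[1]]
  canon <- s[s %in% amino_acids()]
  n <- length(canon)
  aac <- vapply(amino_acids(), function(a) sum(canon == a) / n, numeric(1))
  ggap <- vapply(selected_ggap, function(d) {
    p <- strsplit(d, "|", fixed = TRUE)[[1]]
    g <- as.integer(p[2])
    L <- length(s)
    if (L <= g + 1) return(0)
    hits <- 0
    for (i in seq_len(L - g - 1)) {
      if (s[i] == p[1] && s[i + g + 1] == p[3]) hits <- hits + 1
    }
    hits / (L - g - 1)
  }, numeric(1))
  cnt <- function(set) sum(canon %in% set)
  phys <- c(
    cnt(rc$acidic) / n, cnt(rc$basic) / n, cnt(rc$non_polar) / n,
    cnt(rc$acyclic) / n, cnt(rc$aliphatic) / n, cnt(rc$aromatic) / n,
    cnt(rc$charged) / n, cnt(rc$EFMR) / n,
    (cnt(rc$basic) + 1) / (cnt(rc$acidic) + 1),
    (cnt(rc$non_polar) + 1) / (cnt(rc$polar) + 1),
    (cnt(rc$acyclic) + 1) / (cnt(rc$cyclic) + 1),
    (cnt(rc$charged) + 1) / (n - cnt(rc$charged) + 1),
    cnt(rc$tiny) / n, cnt(rc$small) / n,
    sum(vapply(canon, function(a) cst$max_asa[a], numeric(1))) / n,
    (cnt(c("E", "K")) + 1) / (cnt(c("Q", "H")) + 1),
    (cnt(rc$charged) + 1) / (cnt(rc$polar) + 1),
    cnt(rc$IVYWREL) / n,
    sum(vapply(canon, function(a) cst$mass[a], numeric(1))) +
      cst$water_mass,
    sum(vapply(canon, function(a) cst$heat_capacity[a], numeric(1))) / n
  )
  unname(c(aac, ggap, phys))
}

# fixed descriptor set used where the particular choice is irrelevant
fixed_ggap_set <- function() {
  enumerate_ggap_candidates(0)[c(1, 25, 50, 120, 200, 260, 300, 350,
                                 380, 400)]
}

random_seqs <- function(n, len_range, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(amino_acids(),
                   sample(len_range[1]:len_range[2], 1), replace = TRUE),
            collapse = "")
    }, character(1))
  })
}
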