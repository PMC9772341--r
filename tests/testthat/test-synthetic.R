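test_that("generators are byte-identical under a fixed seed", {
  a <- gen_ogt_proteomes(n_per_class = 20, delta = 0.05, seed = 5)
  b <- gen_ogt_proteomes(n_per_class = 20, delta = 0.05, seed = 5)
  expect_identical(a, b)
  c <- gen_ogt_proteomes(n_per_class = 20, delta = 0.05, seed = 6)
  expect_false(identical(a$records$residues, c$records$residues))
  f1 <- gen_homolog_family(n_active = 5, n_inactive = 5, seed = 3)
  f2 <- gen_homolog_family(n_active = 5, n_inactive = 5, seed = 3)
  expect_identical(f1, f2)
})

test_that("frequency shifting reallocates mass and rejects impossible deltas", {
  bg <- background_frequencies()
  set <- residue_classes()$IVYWREL
  sh <- petminer:::shift_frequencies(bg, set, 0.1)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  expect_equal(sum(sh[set]) - sum(bg[set]), 0.1, tolerance = 1e-12)
  expect_error(petminer:::shift_frequencies(bg, set, 0.9),
               "negative frequencies")
})

test_that("composition effects appear in the generated proteomes", {
  ivywrel <- residue_classes()$IVYWREL
  comp <- function(recs) {
    vapply(recs$residues, function(s) {
      x <- strsplit(s, "")[[1]]
      mean(x %in% ivywrel)
    }, numeric(1))
  }
  g0 <- gen_ogt_proteomes(n_per_class = 500, delta = 0,
                          length_range = c(100, 160), seed = 41)
  pos <- startsWith(g0$records$id, "pos")
  d0 <- mean(comp(g0$records[pos, ])) - mean(comp(g0$records[!pos, ]))
  se <- sqrt(2 * 0.25 / (500 * 100))  # conservative SE bound
  expect_lt(abs(d0), 3 * se * 2)
  g1 <- gen_ogt_proteomes(n_per_class = 500, delta = 0.1,
                          length_range = c(100, 160), seed = 41)
  d1 <- mean(comp(g1$records[pos, ])) - mean(comp(g1$records[!pos, ]))
  expect_gte(d1, 0.05)
  # OGT values sit inside the class bands
  expect_true(all(g1$records$ogt[pos] >= 55 & g1$records$ogt[pos] <= 70))
  expect_true(all(g1$records$ogt[!pos] >= 25 & g1$records$ogt[!pos] <= 37))
})

test_that("family truth alignments are exact and motifs behave by construction", {
  fam <- gen_homolog_family(n_active = 12, n_inactive = 12, length = 100,
                            mutation_rate = 0.08, seed = 13)
  expect_identical(unname(ungap(fam$alignment)), fam$records$residues)
  # every active carries the intact nucleophile elbow, checkable directly
  # on the raw sequence because motif sites are protected from indels
  acts <- fam$records$activity_label == "active"
  motif_ok <- vapply(seq_len(nrow(fam$records)), function(i) {
    s <- fam$records$residues[i]
    grepl("G.S.G", s)
  }, logical(1))
  expect_true(all(motif_ok[acts]))
  # actives carry positive activity, inactives zero
  expect_true(all(fam$records$activity_value[acts] > 0))
  expect_true(all(fam$records$activity_value[!acts] == 0))
})

test_that("motif columns are immune to mutation in actives", {
  fam <- gen_homolog_family(n_active = 10, n_inactive = 10, length = 80,
                            mutation_rate = 0, inactive_divergence = 0,
                            indel_rate = 0, seed = 21)
  # with zero mutation/indel rates all actives equal the ancestor
  acts <- fam$records$activity_label == "active"
  expect_equal(length(unique(fam$records$residues[acts])), 1)
  anc <- strsplit(fam$records$residues[acts][1], "")[[1]]
  mpos <- as.integer(names(fam$motif_sites))
  expect_equal(anc[mpos], unname(fam$motif_sites))
  # inactives have every motif site ablated
  for (s in fam$records$residues[!acts]) {
    x <- strsplit(s, "")[[1]]
    expect_true(all(x[mpos] != unname(fam$motif_sites)))
  }
})

test_that("planted dipeptides appear in positives and leave negatives alone", {
  g <- gen_ogt_proteomes(n_per_class = 50, delta = 0,
                         length_range = c(100, 140), seed = 31)
  pos_ids <- g$records$id[startsWith(g$records$id, "pos")]
  before <- g$records
  pl <- plant_dipeptide_signal(g$records, c("W|1|W"), count = 3,
                               positive_ids = pos_ids, seed = 31)
  neg <- !startsWith(pl$records$id, "pos")
  expect_identical(pl$records$residues[neg], before$residues[neg])
  for (s in pl$records$residues[!neg]) {
    hits <- gregexpr("(?=W.W)", s, perl = TRUE)[[1]]
    expect_gte(sum(hits > 0), 3)
  }
  cpos <- vapply(pl$records$residues[!neg], ggap_composition, numeric(1),
                 descriptor = "W|1|W")
  cneg <- vapply(pl$records$residues[neg], ggap_composition, numeric(1),
                 descriptor = "W|1|W")
  expect_gt(mean(cpos), mean(cneg))
  expect_equal(nrow(pl$truth), 3 * length(pos_ids))
})

test_that("partial OGT tables cover the exact requested fraction", {
  truth <- tibble::tibble(id = sprintf("s%03d", 1:200),
                          ogt = stats::runif(200, 20, 80))
  expect_length(gen_ogt_table(truth, 0, seed = 1), 200)
  expect_length(gen_ogt_table(truth, 1, seed = 1), 0)
  t35 <- gen_ogt_table(truth, 0.35, seed = 1)
  expect_length(t35, 130)
  expect_true(all(names(t35) %in% truth$id))
  expect_identical(gen_ogt_table(truth, 0.35, seed = 1), t35)
})

test_that("generated compositions track their target frequencies", {
  g <- gen_ogt_proteomes(n_per_class = 300, delta = 0.08,
                         length_range = c(150, 150), seed = 61)
  pos <- startsWith(g$records$id, "pos")
  target <- petminer:::shift_frequencies(
    background_frequencies(),
    union(residue_classes()$IVYWREL, c("D", "K")), 0.08)
  obs <- table(factor(unlist(strsplit(g$records$residues[pos], "")),
                      levels = amino_acids()))
  obs <- as.numeric(obs) / sum(obs)
  n_res <- 300 * 150
  se <- sqrt(target * (1 - target) / n_res)
  expect_true(all(abs(obs - target) < 3.5 * se + 1e-9))
})
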