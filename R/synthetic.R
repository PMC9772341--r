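#' Synthetic sequence data with known ground truth
#'
#' Generators that emulate the inputs of the mining workflow at desk
#' scale: two-class proteomes whose residue compositions differ by a
#' tunable effect correlated with an OGT label; homolog families with an
#' intact catalytic motif in the active subfamily and an ablated motif in
#' the inactives, with the true alignment tracked through every indel; a
#' planted g-gap dipeptide signal; and partial OGT tables. All generators
#' are deterministic functions of (config, seed); each operation draws
#' from its own RNG stream derived from the master seed.
#'
#' @name synthetic
NULL

# Reallocate `delta` probability mass onto a residue set, proportionally
# within and outside the set.
shift_frequencies <- function(freqs, set, delta) {
  p_set <- sum(freqs[set])
  if (delta > 1 - p_set || delta < -p_set) {
    stop("composition effect delta leaves negative frequencies",
         call. = FALSE)
  }
  out <- freqs
  out[set] <- freqs[set] * (p_set + delta) / p_set
  rest <- setdiff(names(freqs), set)
  out[rest] <- freqs[rest] * (1 - p_set - delta) / (1 - p_set)
  out / sum(out)
}

random_protein <- function(len, freqs) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

#' Generate two-class OGT-labeled proteomes
#'
#' Negative-class (mesophile-like) sequences are drawn i.i.d. from the
#' background frequencies; positive-class (thermophile-like) sequences are
#' drawn from the background with `delta` total probability mass shifted
#' proportionally onto a thermophily-associated residue set (default
#' IVYWREL plus D and K, mimicking the charged/hydrophobic enrichment of
#' thermophilic proteomes). OGT values are drawn uniformly inside each
#' class's thermal band.
#'
#' @param n_per_class Sequences per class.
#' @param delta Probability mass shifted onto `target_set` for the
#'   positive class (0 = identical compositions).
#' @param length_range Min/max sequence length (uniform integer).
#' @param background Named residue frequency vector.
#' @param target_set Residue set receiving the shifted mass.
#' @param ogt_pos,ogt_neg OGT ranges (degrees C) for positive and negative
#'   class.
#' @param class_pos,class_neg Thermal-class names attached to each group.
#' @param seed Integer master seed.
#' @return List with `records` (a `seq_records` tibble with `ogt` set) and
#'   `truth` (tibble: id, class, ogt).
#' @export
gen_ogt_proteomes <- function(n_per_class = 200, delta = 0.05,
                              length_range = c(120, 220),
                              background = background_frequencies(),
                              target_set = union(residue_classes()$IVYWREL,
                                                 c("D", "K")),
                              ogt_pos = c(55, 70), ogt_neg = c(25, 37),
                              class_pos = "thermophilic",
                              class_neg = "mesophilic", seed = 1) {
  freq_pos <- shift_frequencies(background, target_set, delta)
  withr::with_seed(split_seed(seed, 1), {
    lens <- sample(length_range[1]:length_range[2], 2 * n_per_class,
                   replace = TRUE)
    res <- c(
      vapply(lens[seq_len(n_per_class)], random_protein, character(1),
             freqs = freq_pos),
      vapply(lens[n_per_class + seq_len(n_per_class)], random_protein,
             character(1), freqs = background)
    )
    ogt <- c(stats::runif(n_per_class, ogt_pos[1], ogt_pos[2]),
             stats::runif(n_per_class, ogt_neg[1], ogt_neg[2]))
  })
  ids <- c(sprintf("pos_%04d", seq_len(n_per_class)),
           sprintf("neg_%04d", seq_len(n_per_class)))
  cls <- rep(c(class_pos, class_neg), each = n_per_class)
  recs <- seq_records(id = ids, residues = res, ogt = ogt)
  list(records = recs,
       truth = tibble::tibble(id = ids, class = cls, ogt = ogt))
}

default_motif_sites <- function(len) {
  if (len < 20) {
    stop("default motif layout needs an ancestor of at least 20 residues",
         call. = FALSE)
  }
  p0 <- floor(len * 0.45)
  span <- max(3, round(len * 0.2))
  d_pos <- max(2, p0 - span)
  h_pos <- min(len - 2, p0 + 4 + span)
  sites <- c(stats::setNames("D", d_pos),
             stats::setNames("G", p0), stats::setNames("S", p0 + 2),
             stats::setNames("G", p0 + 4),
             stats::setNames("H", h_pos))
  stopifnot(!anyDuplicated(names(sites)))
  sites
}

#' Generate a homolog family with active and inactive members
#'
#' An ancestor sequence is drawn from the background; descendants evolve
#' by per-site substitution and geometric-length indels (star phylogeny).
#' Active members keep the catalytic motif — a Gly-x-Ser-x-Gly nucleophile
#' elbow plus distal His and Asp sites, echoing the serine-hydrolase triad
#' — immune to substitution; inactive members have each motif site
#' replaced by a random non-motif residue. Motif columns are protected
#' from indels so the true alignment stays simple; insertions at the same
#' inter-column slot are left-aligned against each other.
#'
#' @param n_active,n_inactive Family sizes.
#' @param length Ancestor length.
#' @param mutation_rate Per-site substitution probability (a substitution
#'   draws from the background and may silently restore the original
#'   residue).
#' @param inactive_divergence Extra per-site substitution rate applied to
#'   a shared inactive-subfamily ancestor before per-sequence mutation:
#'   inactive homologs form their own diverged subfamily, as inactive
#'   relatives of an enzyme family typically do.
#' @param indel_rate Per-slot insertion and per-column deletion
#'   probability; insertion lengths are geometric with mean 1.5.
#' @param motif_sites Named character vector: ancestor position ->
#'   required residue. Default: the triad layout described above.
#' @param background Residue frequencies.
#' @param seed Integer master seed.
#' @return List with `records` (`seq_records` with activity labels and
#'   values), `alignment` (the true `protein_msa` over all members),
#'   `truth` (tibble: id, active, activity_value, aligned row) and
#'   `motif_sites`.
#' @export
gen_homolog_family <- function(n_active = 20, n_inactive = 20,
                               length = 120, mutation_rate = 0.05,
                               inactive_divergence = 0.15,
                               indel_rate = 0.01, motif_sites = NULL,
                               background = background_frequencies(),
                               seed = 1) {
  if (is.null(motif_sites)) motif_sites <- default_motif_sites(length)
  mpos <- as.integer(names(motif_sites))
  if (max(mpos) > length) {
    stop("motif does not fit within the sequence length", call. = FALSE)
  }
  n <- n_active + n_inactive
  ids <- c(sprintf("act_%03d", seq_len(n_active)),
           sprintf("inact_%03d", seq_len(n_inactive)))
  active <- rep(c(TRUE, FALSE), c(n_active, n_inactive))
  aa <- names(background)
  withr::with_seed(split_seed(seed, 2), {
    ancestor <- chars(random_protein(length, background))
    ancestor[mpos] <- motif_sites
    inactive_ancestor <- ancestor
    div <- stats::runif(length) < inactive_divergence
    div[mpos] <- FALSE
    inactive_ancestor[div] <- sample(aa, sum(div), replace = TRUE,
                                     prob = background)
    # per-seq events
    col_chars <- matrix("", n, length)      # residue or "" when deleted
    ins_after <- matrix("", n, length + 1)  # insertion after column j-1
    for (i in seq_len(n)) {
      s <- if (active[i]) ancestor else inactive_ancestor
      mut <- stats::runif(length) < mutation_rate
      mut[mpos] <- FALSE
      s[mut] <- sample(aa, sum(mut), replace = TRUE, prob = background)
      if (!active[i]) {
        for (j in seq_along(mpos)) {
          s[mpos[j]] <- sample(setdiff(aa, motif_sites[j]), 1)
        }
      }
      del <- stats::runif(length) < indel_rate
      del[mpos] <- FALSE
      s[del] <- ""
      col_chars[i, ] <- s
      ins_slots <- stats::runif(length + 1) < indel_rate
      # no insertions inside the protected motif span
      protected <- seq(min(mpos), max(mpos)) + 1L
      ins_slots[protected[protected <= length]] <- FALSE
      for (slot in which(ins_slots)) {
        ilen <- 1 + stats::rgeom(1, 1 / 1.5)
        ins_after[i, slot] <- random_protein(ilen, background)
      }
    }
    activity_value <- ifelse(active, stats::rlnorm(n, 0, 0.5), 0)
  })
  # assemble the true alignment: slot widths = max insertion length
  slot_w <- apply(ins_after, 2, function(x) max(nchar(x)))
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  rows <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (j in seq_len(length + 1)) {
      if (slot_w[j] > 0) parts <- c(parts, pad(ins_after[i, j], slot_w[j]))
      if (j <= length) {
        parts <- c(parts,
                   if (nzchar(col_chars[i, j])) col_chars[i, j] else "-")
      }
    }
    paste(parts, collapse = "")
  }, character(1))
  aln <- protein_msa(ids, rows)
  res <- ungap(aln)
  recs <- seq_records(
    id = ids, residues = unname(res),
    activity_label = ifelse(active, "active", "inactive"),
    activity_value = activity_value
  )
  list(records = recs, alignment = aln,
       truth = tibble::tibble(id = ids, active = active,
                              activity_value = activity_value,
                              aligned_row = unname(rows)),
       motif_sites = motif_sites)
}

#' Plant a g-gap dipeptide signal into positive sequences
#'
#' Writes `count` non-overlapping occurrences of every planted descriptor
#' into each positive sequence at seeded random positions (the `a` and `b`
#' slots are overwritten; gap slots keep their residues). Negative
#' sequences are returned unmodified.
#'
#' @param records A `seq_records` tibble.
#' @param descriptors Descriptor names, e.g. `"W|1|W"`.
#' @param count Occurrences of each descriptor per positive sequence.
#' @param positive_ids Ids of the sequences to modify.
#' @param seed Integer master seed.
#' @return List with `records` (modified tibble) and `truth` (tibble: id,
#'   descriptor, start position).
#' @export
plant_dipeptide_signal <- function(records, descriptors, count = 3,
                                   positive_ids, seed = 1) {
  stopifnot(count >= 1)
  d <- parse_ggap(descriptors)
  truth <- list()
  withr::with_seed(split_seed(seed, 3), {
    for (id in positive_ids) {
      i <- match(id, records$id)
      stopifnot(!is.na(i))
      s <- chars(records$residues[i])
      L <- base::length(s)
      occupied <- rep(FALSE, L)
      for (di in seq_along(descriptors)) {
        w <- d$g[di] + 2L
        for (rep_i in seq_len(count)) {
          starts <- sample(seq_len(max(L - w + 1, 0)))
          placed <- FALSE
          for (st in starts) {
            span <- st:(st + w - 1)
            if (!any(occupied[span])) {
              s[st] <- d$a[di]
              s[st + w - 1] <- d$b[di]
              occupied[span] <- TRUE
              truth[[base::length(truth) + 1]] <-
                tibble::tibble(id = id, descriptor = descriptors[di],
                               start = st)
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop("insufficient room to plant descriptor ",
                 descriptors[di], " in sequence ", id, call. = FALSE)
          }
        }
      }
      records$residues[i] <- paste(s, collapse = "")
    }
  })
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate a partial OGT table
#'
#' Covers a seeded uniform sample of `round((1 - unmapped_fraction) * n)`
#' ids, exercising the classifier-fallback path of the triage pipeline.
#'
#' @param truth Tibble with columns `id` and `ogt`.
#' @param unmapped_fraction Fraction of ids to leave out, in \[0, 1\].
#' @param seed Integer master seed.
#' @return Named numeric vector (id -> OGT).
#' @export
gen_ogt_table <- function(truth, unmapped_fraction = 0, seed = 1) {
  stopifnot(unmapped_fraction >= 0, unmapped_fraction <= 1)
  n_mapped <- round((1 - unmapped_fraction) * nrow(truth))
  withr::with_seed(split_seed(seed, 4), {
    keep <- sample(seq_len(nrow(truth)), n_mapped)
  })
  stats::setNames(truth$ogt[keep], truth$id[keep])
}
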