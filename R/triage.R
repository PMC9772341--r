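#' Triage configuration
#'
#' Per-source bit-score windows, the thermotolerance OGT cutoff, and the
#' redundancy-removal mode. Score windows are open intervals: a hit passes
#' when its bit score is strictly inside `(min, max)`. The shipped defaults
#' mirror the mining workflow's intent — high scorers from a broad
#' reference database (`dbA`, > 100 bits) but deliberately low scorers from
#' thermal metagenomes (`dbB`, < 55 bits) — though because the package's
#' bit scores are not calibrated against any external tool, the windows are
#' configuration, not constants.
#'
#' @param score_windows Named list of `c(min, max)` bit windows, one per
#'   source tag; use `-Inf`/`Inf` for open ends.
#' @param ogt_threshold Thermotolerance cutoff in degrees C (inclusive:
#'   OGT at or above the threshold counts as thermotolerant).
#' @param dedup_mode Currently `"exact_excluding_signal_peptide"`.
#' @param seed Integer seed recorded in reports.
#' @return A `triage_config` list.
#' @export
triage_config <- function(score_windows = list(dbA = c(100, Inf),
                                               dbB = c(-Inf, 55)),
                          ogt_threshold = 50,
                          dedup_mode = "exact_excluding_signal_peptide",
                          seed = 1) {
  for (w in score_windows) {
    stopifnot(length(w) == 2, w[1] < w[2])
  }
  stopifnot(is.finite(ogt_threshold))
  structure(list(score_windows = score_windows,
                 ogt_threshold = ogt_threshold,
                 dedup_mode = dedup_mode, seed = seed),
            class = "triage_config")
}

#' Annotate hits with measured or predicted thermotolerance
#'
#' Hits present in the OGT table carry their measured OGT and are
#' thermotolerant when OGT is at or above the threshold. Hits absent from
#' the table are routed through the thermophilicity classifier: they are
#' thermotolerant when predicted positive (thermophilic-side class of the
#' model's scheme). Provenance (`measured` vs `predicted`) is recorded.
#'
#' @param hits Tibble from [hmm_search()] (columns `id`, `bits`).
#' @param records The `seq_records` the hits refer to.
#' @param ogt_table Named numeric vector (id -> OGT), e.g. from
#'   [read_ogt_table()].
#' @param model A `trained_model`, required when any hit is unmapped.
#' @param ogt_threshold Cutoff in degrees C.
#' @return `hits` with added columns `ogt`, `provenance`, `pred_score`,
#'   `thermotolerant`.
#' @export
map_ogt <- function(hits, records, ogt_table, model = NULL,
                    ogt_threshold = 50) {
  ogt <- unname(ogt_table[hits$id])
  unmapped <- is.na(ogt)
  pred_score <- rep(NA_real_, nrow(hits))
  thermo <- ogt >= ogt_threshold
  if (any(unmapped)) {
    if (is.null(model)) {
      stop("configuration error: unmapped hits present but no ",
           "thermophilicity model supplied", call. = FALSE)
    }
    idx <- match(hits$id[unmapped], records$id)
    pred <- predict_thermophilicity(model, records[idx, , drop = FALSE])
    pred_score[unmapped] <- pred$score
    thermo[unmapped] <- pred$class == "positive"
  }
  hits$ogt <- ogt
  hits$provenance <- ifelse(unmapped, "predicted", "measured")
  hits$pred_score <- pred_score
  hits$thermotolerant <- thermo
  hits
}

#' Apply thermotolerance and per-source score-window filters
#'
#' A hit is kept when it is thermotolerant and its bit score lies strictly
#' inside its source's window (both endpoints exclusive, so a score exactly
#' at a `> 100` cutoff is excluded).
#'
#' @param hits Annotated hits from [map_ogt()], with a `source` column.
#' @param config A [triage_config()].
#' @return `hits` with added logical columns `pass_score`, `pass_thermo`,
#'   `pass_all`.
#' @export
apply_filters <- function(hits, config) {
  unknown <- setdiff(unique(hits$source), names(config$score_windows))
  if (length(unknown) > 0) {
    stop("no score window configured for source tag(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  win <- do.call(rbind, config$score_windows[hits$source])
  hits$pass_score <- unname(hits$bits > win[, 1] & hits$bits < win[, 2])
  hits$pass_thermo <- hits$thermotolerant
  hits$pass_all <- hits$pass_score & hits$pass_thermo
  hits
}

#' Collapse redundant candidates
#'
#' Two candidates are redundant when their mature sequences — residues
#' after the annotated signal peptide, or the whole chain when none is
#' annotated — are identical. One representative is kept per group: the
#' highest bit score, ties broken by lexicographic id.
#'
#' @param hits Filtered hits tibble (columns `id`, `bits`).
#' @param records The underlying `seq_records` (for residues and
#'   signal-peptide annotations).
#' @return `hits` with added columns `dedup_group` (integer group id) and
#'   `representative` (logical).
#' @export
dedup_candidates <- function(hits, records) {
  if (nrow(hits) == 0) {
    hits$dedup_group <- integer(0)
    hits$representative <- logical(0)
    return(hits)
  }
  idx <- match(hits$id, records$id)
  sp <- records$signal_peptide_end[idx]
  mature <- ifelse(is.na(sp), records$residues[idx],
                   substring(records$residues[idx], sp + 1))
  grp <- match(mature, unique(mature))
  rep_flag <- logical(nrow(hits))
  for (g in unique(grp)) {
    members <- which(grp == g)
    best <- members[order(-hits$bits[members], hits$id[members])][1]
    rep_flag[best] <- TRUE
  }
  hits$dedup_group <- grp
  hits$representative <- rep_flag
  hits
}

#' Run the full candidate triage pipeline
#'
#' hmm search over the database, OGT mapping with classifier fallback,
#' thermotolerance and score-window filtering, then redundancy removal.
#' Every input sequence appears exactly once in the report; `selected` is
#' true exactly for hits that pass every filter and are their redundancy
#' group's representative. Stage counts are recorded in the `"stage_log"`
#' attribute.
#'
#' @param seq_db A `seq_records` tibble (must carry a `source` tag per
#'   sequence).
#' @param seed_alignment A `protein_msa` of the family used to build the
#'   search HMM.
#' @param ogt_table Named numeric vector (id -> OGT).
#' @param model A `trained_model` for unmapped hits (may be NULL when the
#'   table covers everything).
#' @param config A [triage_config()].
#' @return The candidate report: a tibble with one row per input sequence
#'   and columns `id`, `source`, `bits`, `ogt`, `provenance`, `pred_score`,
#'   `thermotolerant`, `pass_score`, `pass_thermo`, `pass_all`,
#'   `dedup_group`, `representative`, `selected`.
#' @export
run_pipeline <- function(seq_db, seed_alignment, ogt_table, model = NULL,
                         config = triage_config()) {
  if (nrow(seq_db) == 0) {
    out <- tibble::tibble(id = character(), source = character(),
                          bits = numeric(), ogt = numeric(),
                          provenance = character(), pred_score = numeric(),
                          thermotolerant = logical(),
                          pass_score = logical(), pass_thermo = logical(),
                          pass_all = logical(), dedup_group = integer(),
                          representative = logical(), selected = logical())
    attr(out, "stage_log") <- list(n_input = 0L)
    return(out)
  }
  hmm <- build_phmm(seed_alignment)
  hits <- hmm_search(hmm, seq_db, score_threshold = -Inf)
  hits$source <- seq_db$source[match(hits$id, seq_db$id)]
  hits <- map_ogt(hits, seq_db, ogt_table, model,
                  ogt_threshold = config$ogt_threshold)
  hits <- apply_filters(hits, config)
  passed <- hits[hits$pass_all, , drop = FALSE]
  passed <- dedup_candidates(passed, seq_db)
  hits$dedup_group <- passed$dedup_group[match(hits$id, passed$id)]
  hits$representative <- passed$representative[match(hits$id, passed$id)]
  hits$representative[is.na(hits$representative)] <- FALSE
  hits$selected <- hits$pass_all & hits$representative
  out <- hits[, c("id", "source", "bits", "ogt", "provenance",
                  "pred_score", "thermotolerant", "pass_score",
                  "pass_thermo", "pass_all", "dedup_group",
                  "representative", "selected")]
  attr(out, "stage_log") <- list(
    n_input = nrow(seq_db),
    n_scored = nrow(hits),
    n_thermotolerant = sum(hits$pass_thermo),
    n_in_score_window = sum(hits$pass_score),
    n_pass_all = sum(hits$pass_all),
    n_dedup_groups = length(unique(stats::na.omit(hits$dedup_group))),
    n_selected = sum(hits$selected),
    ogt_threshold = config$ogt_threshold,
    seed = config$seed
  )
  out
}
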