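#' Remove gap-dominated alignment columns
#'
#' Columns whose gap fraction is strictly greater than `max_gap_fraction`
#' are removed ("more than 90% gaps" under the default); a column with a
#' gap fraction exactly at the threshold is retained. The mapping from
#' filtered to original column indices is kept for reporting.
#'
#' @param aln A `protein_msa`.
#' @param max_gap_fraction Threshold in \[0, 1\] (default 0.9).
#' @return List with `alignment` (filtered `protein_msa`, or NULL when
#'   nothing survives), `retained_index` (original indices of the retained
#'   columns), `n_removed`, `n_retained`.
#' @export
filter_gap_columns <- function(aln, max_gap_fraction = 0.9) {
  m <- as.matrix(aln)
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= max_gap_fraction)
  if (length(keep) == 0) {
    warning("no columns survive the gap filter")
    return(list(alignment = NULL, retained_index = integer(0),
                n_removed = ncol(m), n_retained = 0L))
  }
  filtered <- protein_msa(
    aln$id, apply(m[, keep, drop = FALSE], 1, paste, collapse = ""))
  list(alignment = filtered, retained_index = keep,
       n_removed = ncol(m) - length(keep), n_retained = length(keep))
}

# Map one alignment column to test categories.
column_categories <- function(col, grouping, drop_gaps) {
  cat <- character(length(col))
  is_gap <- col == "-"
  canon <- col %in% amino_acids()
  if (grouping == "amino_acid") {
    cat[canon] <- col[canon]
  } else {
    cls <- msa_residue_classes()
    cat[canon] <- cls[col[canon]]
  }
  cat[!canon & !is_gap] <- "ambiguous"
  cat[is_gap] <- "gap"
  if (drop_gaps) cat[is_gap] <- NA_character_
  cat
}

#' Chi-squared association test at one alignment position
#'
#' Builds the categories-by-label contingency table at one column of a
#' (filtered) alignment and applies Pearson's chi-squared test of
#' independence, two-sided, without continuity correction. Categories are
#' either the observed residues (`grouping = "amino_acid"`) or the
#' five-class residue-type partition of [msa_residue_classes()]. Gaps form
#' their own category by default since the presence of an insertion is
#' itself positional information; `drop_gaps = TRUE` excludes gapped rows
#' instead. Rows with zero total are dropped before computing the degrees
#' of freedom. A column with a single observed category yields a degenerate
#' test: statistic 0, p = 1.
#'
#' @param aln A `protein_msa` (typically after [filter_gap_columns()]).
#' @param labels Character/factor vector of `active`/`inactive` labels,
#'   one per alignment row.
#' @param column Column index within `aln`.
#' @param grouping `"amino_acid"` or `"residue_class"`.
#' @param drop_gaps Exclude gapped rows instead of keeping a gap category.
#' @param guard Warn when any expected count falls below 5 (the chi-squared
#'   approximation degrades there).
#' @return List with `column`, `table`, `chi2`, `dof`, `p`, `grouping`.
#' @export
position_chi2 <- function(aln, labels, column,
                          grouping = c("amino_acid", "residue_class"),
                          drop_gaps = FALSE, guard = FALSE) {
  grouping <- match.arg(grouping)
  stopifnot(length(labels) == length(aln$id),
            column >= 1, column <= aln$n_columns)
  col <- substring(aln$aligned, column, column)
  cat <- column_categories(col, grouping, drop_gaps)
  keep <- !is.na(cat)
  tab <- table(category = cat[keep], label = factor(labels[keep]))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(column = column, table = tab, chi2 = 0,
                dof = 0L, p = 1, grouping = grouping))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (guard && any(ct$expected < 5)) {
    warning(sprintf("column %d: expected count below 5; ", column),
            "chi-squared approximation may be poor")
  }
  list(column = column, table = tab, chi2 = unname(ct$statistic),
       dof = unname(ct$parameter), p = unname(ct$p.value),
       grouping = grouping)
}

#' Scan every alignment column for label association
#'
#' Applies [position_chi2()] to every column and reports raw p-values in
#' the style of a positional screen; a Bonferroni-adjusted column is
#' included for reference but is never used for the `flag` column, which
#' uses the raw `p < alpha` rule.
#'
#' @param aln A `protein_msa` (typically gap-filtered).
#' @param labels `active`/`inactive` labels, one per row.
#' @param grouping `"amino_acid"` or `"residue_class"`.
#' @param alpha Raw significance threshold (default 0.01).
#' @param original_index Optional integer vector mapping columns of `aln`
#'   to columns of the unfiltered alignment (see [filter_gap_columns()]).
#' @param drop_gaps Passed to [position_chi2()].
#' @return Tibble with columns `column`, `original_column`, `chi2`, `dof`,
#'   `p`, `p_bonferroni`, `flag`; the attribute `"significant"` holds the
#'   flagged column indices.
#' @export
scan_alignment <- function(aln, labels,
                           grouping = c("amino_acid", "residue_class"),
                           alpha = 0.01, original_index = NULL,
                           drop_gaps = FALSE) {
  grouping <- match.arg(grouping)
  res <- lapply(seq_len(aln$n_columns), function(j) {
    r <- position_chi2(aln, labels, j, grouping, drop_gaps)
    c(column = j, chi2 = r$chi2, dof = r$dof, p = r$p)
  })
  df <- tibble::as_tibble(do.call(rbind, res))
  df$original_column <- if (is.null(original_index)) df$column else
    original_index[df$column]
  df$p_bonferroni <- pmin(1, df$p * nrow(df))
  df$flag <- df$p < alpha
  df <- df[, c("column", "original_column", "chi2", "dof", "p",
               "p_bonferroni", "flag")]
  attr(df, "significant") <- df$column[df$flag]
  df
}
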