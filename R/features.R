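#' Amino-acid composition
#'
#' Fraction of each of the 20 canonical residues among the unambiguous
#' residues of a sequence. Ambiguity codes (B, Z, X, U, O) are excluded from
#' both numerator and denominator, so the 20 fractions always sum to 1.
#'
#' @param residues Residue string (or a single `seq_records` row's
#'   `residues` value).
#' @return Named numeric vector of length 20 (names `aac_A` .. `aac_Y`).
#' @export
aa_composition <- function(residues) {
  code <- aa_codes(residues)
  n <- sum(!is.na(code))
  if (n == 0) {
    stop("degenerate input: sequence has no unambiguous residues",
         call. = FALSE)
  }
  counts <- tabulate(code, nbins = 20)
  stats::setNames(counts / n, paste0("aac_", amino_acids()))
}

#' Enumerate g-gap dipeptide descriptors
#'
#' A g-gap dipeptide `a(x)_g b` is residue `a`, then `g` arbitrary residues,
#' then residue `b`. For each value of g the 400 ordered residue pairs are
#' enumerated in lexicographic order; g values are visited in increasing
#' order. With g in \{0, 1, 2\} this yields the full 1200-descriptor
#' candidate set.
#'
#' @param g_values Integer vector of gap lengths, each >= 0.
#' @return Character vector of descriptor names of the form `"A|1|C"`.
#' @export
enumerate_ggap_candidates <- function(g_values = 0:2) {
  if (length(g_values) == 0) stop("g_values must be nonempty", call. = FALSE)
  if (any(g_values < 0)) stop("g values must be >= 0", call. = FALSE)
  g_values <- sort(unique(as.integer(g_values)))
  aa <- amino_acids()
  unlist(lapply(g_values, function(g) {
    grid <- expand.grid(b = aa, a = aa, stringsAsFactors = FALSE)
    sprintf("%s|%d|%s", grid$a, g, grid$b)
  }))
}

parse_ggap <- function(descriptor) {
  parts <- strsplit(descriptor, "|", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  g <- as.integer(vapply(parts, `[`, character(1), 2))
  b <- vapply(parts, `[`, character(1), 3)
  if (any(!a %in% amino_acids()) || any(!b %in% amino_acids()) ||
      any(is.na(g)) || any(g < 0)) {
    stop("invalid g-gap descriptor(s)", call. = FALSE)
  }
  list(a = a, g = g, b = b)
}

# All 400 compositions at a fixed g for one sequence, as a numeric vector
# ordered like enumerate_ggap_candidates(g). Ambiguous residues at the a or
# b slot exclude the window from the numerator only.
ggap_all_at_g <- function(code, g) {
  L <- length(code)
  nwin <- L - g - 1
  out <- numeric(400)
  if (nwin < 1) {
    attr(out, "short_sequence") <- TRUE
    return(out)
  }
  a <- code[seq_len(nwin)]
  b <- code[seq_len(nwin) + g + 1]
  keep <- !is.na(a) & !is.na(b)
  idx <- (a[keep] - 1L) * 20L + b[keep]
  out <- tabulate(idx, nbins = 400) / nwin
  out
}

#' g-gap dipeptide composition
#'
#' Number of windows matching the descriptor divided by the total number of
#' windows, `L - g - 1`. A sequence too short to hold any window yields 0
#' with a `short_sequence` attribute rather than an error, so fixed-length
#' feature vectors remain computable.
#'
#' @param residues Residue string.
#' @param descriptor Descriptor name, e.g. `"A|1|C"`.
#' @return Fraction in \[0, 1\].
#' @export
ggap_composition <- function(residues, descriptor) {
  d <- parse_ggap(descriptor)
  stopifnot(length(d$a) == 1)
  code <- aa_codes(residues)
  v <- ggap_all_at_g(code, d$g)
  i <- (match(d$a, amino_acids()) - 1L) * 20L + match(d$b, amino_acids())
  out <- v[i]
  if (isTRUE(attr(v, "short_sequence"))) attr(out, "short_sequence") <- TRUE
  out
}

# g-gap feature block for a selected descriptor list (vectorized per seq).
ggap_block <- function(residues, descriptors) {
  d <- parse_ggap(descriptors)
  code <- aa_codes(residues)
  gs <- sort(unique(d$g))
  per_g <- lapply(gs, function(g) ggap_all_at_g(code, g))
  names(per_g) <- as.character(gs)
  idx <- (match(d$a, amino_acids()) - 1L) * 20L + match(d$b, amino_acids())
  vals <- vapply(seq_along(descriptors), function(i) {
    per_g[[as.character(d$g[i])]][idx[i]]
  }, numeric(1))
  stats::setNames(vals, paste0("ggap_", descriptors))
}

#' Molecular weight of a protein chain
#'
#' Sum of average residue masses plus one water. Ambiguity codes contribute
#' the mean canonical residue mass; when any are present the result carries
#' an `ambiguous_residues` attribute.
#'
#' @param residues Residue string.
#' @param constants Constant tables, see [feature_constants()].
#' @return Mass in Da.
#' @export
molecular_weight <- function(residues, constants = feature_constants()) {
  code <- aa_codes(residues)
  masses <- constants$mass[amino_acids()]
  m <- masses[code]
  n_amb <- sum(is.na(code))
  m[is.na(code)] <- mean(masses)
  out <- sum(m) + constants$water_mass
  if (n_amb > 0) attr(out, "ambiguous_residues") <- n_amb
  out
}

# Net Henderson-Hasselbalch charge at a given pH.
net_charge <- function(counts, pka, pH) {
  pos_groups <- c(Nterm = 1, H = unname(counts["H"]), K = unname(counts["K"]),
                  R = unname(counts["R"]))
  neg_groups <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
                  C = unname(counts["C"]), Y = unname(counts["Y"]))
  pos_pka <- pka[c("Nterm", "H", "K", "R")]
  neg_pka <- pka[c("Cterm", "D", "E", "C", "Y")]
  sum(pos_groups / (1 + 10^(pH - pos_pka))) -
    sum(neg_groups / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point
#'
#' pH at which the net Henderson-Hasselbalch charge of the chain is zero,
#' found by bisection on \[0, 14\]. The net charge is strictly decreasing in
#' pH, so the root is unique.
#'
#' @param residues Residue string.
#' @param pka Named pKa set; see [feature_constants()].
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(residues, pka = feature_constants()$pka,
                              tol = 1e-4) {
  code <- aa_codes(residues)
  counts <- stats::setNames(tabulate(code, nbins = 20), amino_acids())
  lo <- 0; hi <- 14
  f_lo <- net_charge(counts, pka, lo)
  if (f_lo <= 0) return(lo)
  if (net_charge(counts, pka, hi) >= 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, pka, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Residue-type and physicochemical features
#'
#' The 20 order-free features: compositions of acidic, basic, non-polar,
#' acyclic, aliphatic, aromatic, charged and EFMR residues; smoothed ratios
#' basic/acidic, non-polar/polar, acyclic/cyclic, charged/non-charged; tiny
#' and small compositions; mean maximum solvent-accessible area; the
#' (E+K)/(Q+H) ratio; the charged/polar ratio; IVYWREL composition;
#' molecular weight (Da); and mean per-residue heat capacity.
#'
#' Compositions are class counts over the unambiguous length. Ratios are
#' smoothed as (numerator + 1)/(denominator + 1) so they stay finite on
#' short or compositionally extreme sequences.
#'
#' @param residues Residue string.
#' @param classes Residue class table, see [residue_classes()].
#' @param constants Constant tables, see [feature_constants()].
#' @return Named numeric vector of length 20.
#' @export
physicochemical_features <- function(residues,
                                     classes = residue_classes(),
                                     constants = feature_constants()) {
  code <- aa_codes(residues)
  n <- sum(!is.na(code))
  if (n == 0) {
    stop("degenerate input: sequence has no unambiguous residues",
         call. = FALSE)
  }
  counts <- stats::setNames(tabulate(code, nbins = 20), amino_acids())
  csum <- function(set) sum(counts[set])
  comp <- function(set) csum(set) / n
  ratio <- function(a, b) (a + 1) / (b + 1)
  c(
    comp_acidic = comp(classes$acidic),
    comp_basic = comp(classes$basic),
    comp_non_polar = comp(classes$non_polar),
    comp_acyclic = comp(classes$acyclic),
    comp_aliphatic = comp(classes$aliphatic),
    comp_aromatic = comp(classes$aromatic),
    comp_charged = comp(classes$charged),
    comp_EFMR = comp(classes$EFMR),
    ratio_basic_acidic = ratio(csum(classes$basic), csum(classes$acidic)),
    ratio_non_polar_polar = ratio(csum(classes$non_polar),
                                  csum(classes$polar)),
    ratio_acyclic_cyclic = ratio(csum(classes$acyclic),
                                 csum(classes$cyclic)),
    ratio_charged_non_charged = ratio(csum(classes$charged),
                                      n - csum(classes$charged)),
    comp_tiny = comp(classes$tiny),
    comp_small = comp(classes$small),
    mean_max_asa = sum(constants$max_asa[amino_acids()] * counts) / n,
    ratio_EK_QH = ratio(csum(c("E", "K")), csum(c("Q", "H"))),
    ratio_charged_polar = ratio(csum(classes$charged), csum(classes$polar)),
    comp_IVYWREL = comp(classes$IVYWREL),
    mol_weight = as.numeric(molecular_weight(residues, constants)),
    heat_capacity = sum(constants$heat_capacity[amino_acids()] * counts) / n
  )
}

#' Full feature vector for one sequence
#'
#' Concatenates the 20 amino-acid compositions, the g-gap dipeptide block
#' for the selected descriptors (10 under defaults), and the 20
#' physicochemical features: 50 named values under defaults.
#'
#' @param residues Residue string.
#' @param selected_ggap Ordered descriptor names, typically the output of
#'   [select_ggap_features()].
#' @param classes,constants Overridable tables.
#' @return Named numeric vector of length `20 + length(selected_ggap) + 20`.
#' @export
featurize <- function(residues, selected_ggap,
                      classes = residue_classes(),
                      constants = feature_constants()) {
  c(aa_composition(residues),
    ggap_block(residues, selected_ggap),
    physicochemical_features(residues, classes, constants))
}

#' Feature matrix for a sequence collection
#'
#' @param records A `seq_records` tibble (or character vector of residue
#'   strings).
#' @param selected_ggap Ordered descriptor names.
#' @param classes,constants Overridable tables.
#' @return Numeric matrix, one row per sequence, rownames = ids.
#' @export
featurize_set <- function(records, selected_ggap,
                          classes = residue_classes(),
                          constants = feature_constants()) {
  if (is.character(records)) {
    res <- records
    ids <- if (!is.null(names(records))) names(records) else
      paste0("seq", seq_along(records))
  } else {
    res <- records$residues
    ids <- records$id
  }
  m <- t(vapply(res, featurize, numeric(40 + length(selected_ggap)),
                selected_ggap = selected_ggap, classes = classes,
                constants = constants, USE.NAMES = FALSE))
  dimnames(m) <- list(ids, names(featurize(res[1], selected_ggap,
                                           classes, constants)))
  m
}

# g-gap candidate matrix: all candidate descriptors for a collection.
ggap_candidate_matrix <- function(records, candidates =
                                    enumerate_ggap_candidates(0:2)) {
  d <- parse_ggap(candidates)
  gs <- sort(unique(d$g))
  res <- if (is.character(records)) records else records$residues
  ids <- if (is.character(records)) {
    if (!is.null(names(records))) names(records) else
      paste0("seq", seq_along(records))
  } else records$id
  ord <- order(d$g, d$a, d$b)
  # per sequence: concatenate per-g 400-blocks, then pick candidate order
  cand_idx <- integer(length(candidates))
  for (i in seq_along(candidates)) {
    gpos <- match(d$g[i], gs) - 1L
    cand_idx[i] <- gpos * 400L + (match(d$a[i], amino_acids()) - 1L) * 20L +
      match(d$b[i], amino_acids())
  }
  m <- t(vapply(res, function(s) {
    code <- aa_codes(s)
    unlist(lapply(gs, function(g) ggap_all_at_g(code, g)))[cand_idx]
  }, numeric(length(candidates)), USE.NAMES = FALSE))
  dimnames(m) <- list(ids, candidates)
  m
}
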