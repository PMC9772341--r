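#' Construct a sequence record table
#'
#' The shared sequence data model: a tibble with one row per protein
#' sequence and the columns `id`, `description`, `residues`,
#' `signal_peptide_end` (1-based index of the last signal-peptide residue,
#' `NA` when absent), `ogt` (optimal growth temperature, degrees C),
#' `source` (free tag, e.g. the database a hit came from), `activity_label`
#' (`"active"`/`"inactive"`) and `activity_value` (nonnegative continuous
#' activity proxy).
#'
#' @param id Character vector of unique identifiers.
#' @param residues Character vector of residue strings (canonical 20 codes
#'   plus tolerated ambiguity codes B, Z, X, U, O).
#' @param description Optional free-text descriptions.
#' @param signal_peptide_end Optional integer vector; must be >= 1 and
#'   strictly less than the sequence length where present.
#' @param ogt,source,activity_label,activity_value Optional annotations.
#' @return A tibble of class `seq_records`.
#' @export
seq_records <- function(id, residues, description = "",
                        signal_peptide_end = NA_integer_,
                        ogt = NA_real_, source = NA_character_,
                        activity_label = NA_character_,
                        activity_value = NA_real_) {
  x <- tibble::tibble(
    id = as.character(id),
    description = as.character(description),
    residues = toupper(as.character(residues)),
    signal_peptide_end = as.integer(signal_peptide_end),
    ogt = as.numeric(ogt),
    source = as.character(source),
    activity_label = as.character(activity_label),
    activity_value = as.numeric(activity_value)
  )
  validate_seq_records(x)
}

validate_seq_records <- function(x) {
  if (nrow(x) == 0) return(structure(x, class = c("seq_records", class(x))))
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(x$residues))) {
    stop("empty residue string for id(s): ",
         paste(x$id[!nzchar(x$residues)], collapse = ", "), call. = FALSE)
  }
  Map(check_alphabet, x$residues, x$id)
  sp <- x$signal_peptide_end
  bad <- !is.na(sp) & (sp < 1L | sp >= nchar(x$residues))
  if (any(bad)) {
    stop("signal_peptide_end out of range for id(s): ",
         paste(x$id[bad], collapse = ", "), call. = FALSE)
  }
  lab <- x$activity_label
  if (any(!is.na(lab) & !lab %in% c("active", "inactive"))) {
    stop("activity_label must be 'active' or 'inactive'", call. = FALSE)
  }
  if (!inherits(x, "seq_records")) class(x) <- c("seq_records", class(x))
  x
}

# Parse a structured "SP=a..b" token out of a description; returns the end
# coordinate (1-based inclusive) or NA.
parse_sp_token <- function(description) {
  m <- regmatches(description,
                  regexpr("SP=([0-9]+)\\.\\.([0-9]+)", description))
  if (length(m) == 0 || !nzchar(m)) return(NA_integer_)
  as.integer(sub("SP=[0-9]+\\.\\.", "", m))
}

#' Read protein sequences from a FASTA file
#'
#' Residues are uppercased, a single terminal `*` stop is stripped, and a
#' structured `SP=1..k` token in the description (signal peptide spanning
#' residues 1..k) is parsed into `signal_peptide_end`.
#'
#' @param path Path to a FASTA file.
#' @return A `seq_records` tibble, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    warning("empty FASTA file: ", path)
    return(seq_records(character(), character()))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record header",
                 nonblank[1]), call. = FALSE)
  }
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("invalid residue code(s) in FASTA file ", path, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- toupper(as.character(aa))
  res <- sub("\\*$", "", res)
  seq_records(
    id = id, residues = res, description = desc,
    signal_peptide_end = vapply(desc, parse_sp_token, integer(1),
                                USE.NAMES = FALSE)
  )
}

#' Write sequence records to FASTA
#'
#' The signal-peptide annotation, when present, is serialized as a
#' structured `SP=1..k` token in the description so that
#' `read_fasta(write_fasta(x))` recovers it.
#'
#' @param records A `seq_records` tibble.
#' @param path Output path.
#' @param width Line width for wrapped residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- records$description[i]
    sp <- records$signal_peptide_end[i]
    if (!is.na(sp) && !grepl("SP=", desc)) {
      desc <- trimws(paste(desc, sprintf("SP=1..%d", sp)))
    }
    header <- if (nzchar(desc)) paste(records$id[i], desc) else records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a protein multiple sequence alignment
#'
#' @param id Character vector of row identifiers.
#' @param aligned Character vector of equal-length aligned strings; `-` is
#'   the gap character.
#' @return An object of class `protein_msa` with fields `id`, `aligned`,
#'   `n_columns`.
#' @export
protein_msa <- function(id, aligned) {
  id <- as.character(id)
  aligned <- toupper(as.character(aligned))
  aligned <- gsub(".", "-", aligned, fixed = TRUE)
  if (length(aligned) == 0) stop("alignment has no rows", call. = FALSE)
  len <- nchar(aligned)
  if (length(unique(len)) != 1) {
    bad <- id[len != stats::median(len)]
    stop("alignment rows differ in length; offending id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate alignment row id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (len[1] < 1) stop("alignment has zero columns", call. = FALSE)
  Map(function(s, i) check_alphabet(gsub("-", "", s, fixed = TRUE), i),
      aligned, id)
  structure(list(id = id, aligned = aligned, n_columns = len[1]),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d rows x %d columns\n",
              length(x$id), x$n_columns))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param x A `protein_msa`.
#' @param ... Unused.
#' @return Character matrix, one row per sequence, one column per alignment
#'   column, rownames = ids.
#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$aligned, "", fixed = TRUE))
  rownames(m) <- x$id
  m
}

#' Remove gaps from alignment rows
#'
#' @param aln A `protein_msa`.
#' @return Named character vector of ungapped residue strings.
#' @export
ungap <- function(aln) {
  stats::setNames(gsub("-", "", aln$aligned, fixed = TRUE), aln$id)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Stockholm. `.` gaps are normalized to `-`.
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"stockholm"`.
#' @return A `protein_msa`.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "aligned-fasta") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0) stop("no FASTA records in ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    ends <- c(hdr[-1] - 1, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[seq(hdr[i] + 1, ends[i])], collapse = "")
    }, character(1))
    seqs <- gsub("\\s", "", seqs)
    protein_msa(ids, seqs)
  } else {
    lines <- readLines(path, warn = FALSE)
    seqlines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                        nzchar(trimws(lines))]
    if (length(seqlines) == 0) {
      stop("no sequence rows in Stockholm file ", path, call. = FALSE)
    }
    parts <- regmatches(seqlines, regexec("^(\\S+)\\s+(\\S+)\\s*$", seqlines))
    bad <- vapply(parts, length, integer(1)) != 3
    if (any(bad)) {
      stop("malformed Stockholm sequence line: ", seqlines[bad][1],
           call. = FALSE)
    }
    ids <- vapply(parts, `[`, character(1), 2)
    seqs <- vapply(parts, `[`, character(1), 3)
    # concatenate interleaved blocks in first-appearance order
    uid <- unique(ids)
    full <- vapply(uid, function(u) paste(seqs[ids == u], collapse = ""),
                   character(1))
    protein_msa(uid, full)
  }
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A `protein_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste0(">", aln$id, "\n", aln$aligned), path)
  invisible(path)
}

#' Read an optimal-growth-temperature table
#'
#' Expects a TSV with header columns `id` and `ogt_celsius`.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector: id -> OGT in degrees C.
#' @export
read_ogt_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "ogt_celsius")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("OGT table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate id(s) in OGT table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(df$ogt_celsius))
  bad <- which(!is.finite(val))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric OGT value in row %d ('%s')",
                 bad[1] + 1L, df$ogt_celsius[bad[1]]), call. = FALSE)
  }
  stats::setNames(val, df$id)
}

#' Read an activity label table
#'
#' TSV with header columns `id`, `activity_label` (active/inactive) and an
#' optional `activity_value` column.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `id`, `activity_label`, `activity_value`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "activity_label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("label table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("duplicate id(s) in label table",
                                 call. = FALSE)
  if (any(!df$activity_label %in% c("active", "inactive"))) {
    stop("activity_label must be 'active' or 'inactive'", call. = FALSE)
  }
  tibble::tibble(
    id = as.character(df$id),
    activity_label = df$activity_label,
    activity_value = if ("activity_value" %in% names(df)) {
      as.numeric(df$activity_value)
    } else NA_real_
  )
}

#' Write a data frame as a TSV report
#'
#' @param rows A data frame or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
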