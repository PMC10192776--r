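# Key-residue conservation scoring on gapped protein alignments.
#
# Functionally critical residues are specified in the ungapped 1-based
# coordinates of a reference sequence (UniProt numbering) and mapped through
# the alignment to 0-based columns. Each record contributes one of three
# states at a scored column: a residue (occupied), an internal gap, or
# "terminated" -- the record's sequence has already ended (a run of gaps
# extending to the alignment edge), the signature of truncated MAG
# assemblies. Two identity denominators are reported: over all records
# (pid_all) and over occupied records only (pid_occupied).

#' Key-residue specification
#'
#' @param gene Gene name (e.g. `"oxc"`).
#' @param reference_id Alignment record id of the reference sequence whose
#'   ungapped numbering defines residue positions.
#' @param positions Integer vector of 1-based reference positions, strictly
#'   increasing.
#' @param expected Character vector of expected residues (single letters),
#'   same length as `positions`.
#' @return A `key_residue_spec` object.
#' @export
key_residue_spec <- function(gene, reference_id, positions, expected) {
  positions <- as.integer(positions)
  expected <- toupper(expected)
  if (length(positions) != length(expected))
    stop_ox("positions and expected must have equal length")
  if (any(diff(positions) <= 0L)) stop_ox("positions must be strictly increasing")
  if (!all(expected %in% AA20))
    stop_ox("expected residues must be standard amino-acid letters")
  structure(list(gene = gene, reference_id = reference_id,
                 positions = positions, expected = expected),
            class = "key_residue_spec")
}

#' Read a key-residue specification from CSV
#'
#' Expected columns: `gene`, `reference_id`, `position`, `expected`.
#' @param path CSV path.
#' @return A named list of `key_residue_spec`, one per gene in the file.
#' @export
read_key_residues <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "reference_id", "position", "expected")
  if (!all(need %in% names(df)))
    stop_ox("key residue CSV must have columns: %s", paste(need, collapse = ", "))
  out <- lapply(split(df, df$gene), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    key_residue_spec(d$gene[1L], d$reference_id[1L], d$position, d$expected)
  })
  out
}

#' Bundled key-residue specifications
#'
#' Returns the specifications shipped with the package for the oxc
#' (oxalyl-CoA decarboxylase: E-56, Y-120, E-121, Y-483, S-553, R-555),
#' oxdC (oxalate decarboxylase: R-270, E-333, Y-340) and frc (formyl-CoA
#' transferase: Q-17, W-48, D-169, G-259, G-260) genes, identified by
#' mutagenesis studies referenced in UniProtKB. The reference ids are
#' placeholders to be replaced with the reference record id of the user's
#' alignment. oxlT key residues are not enumerated here and must be
#' supplied by the user.
#' @return Named list of `key_residue_spec`.
#' @export
bundled_key_residues <- function() {
  read_key_residues(system.file("extdata", "key_residues.csv",
                                package = "oxalotrace", mustWork = TRUE))
}

#' Map reference residue positions to alignment columns
#'
#' @param aln An `oxa_alignment`.
#' @param reference_id Record id of the reference sequence.
#' @return Integer vector mapping 1-based ungapped reference positions to
#'   0-based alignment columns; `map[i]` is the column of reference
#'   residue `i`.
#' @export
map_reference_positions <- function(aln, reference_id) {
  stopifnot(inherits(aln, "oxa_alignment"))
  if (!reference_id %in% aln_ids(aln))
    stop_ox("reference id '%s' not present in alignment", reference_id)
  refrow <- aln$seq[reference_id, ]
  cols0 <- which(refrow != "-") - 1L
  setNames(cols0, seq_along(cols0))
}

#' Classify per-record states at an alignment column
#'
#' A record is `terminated` at column `c` when every character from `c` to
#' either alignment edge is a gap (a trailing-gap run, or a leading-gap run
#' for records that have not yet started); other gaps are `internal_gap`;
#' anything else (including `X`) is `residue`.
#'
#' @param aln An `oxa_alignment`.
#' @param column 0-based column index.
#' @return Character vector of states, one per record, named by record id.
#' @export
classify_column_states <- function(aln, column) {
  stopifnot(inherits(aln, "oxa_alignment"))
  L <- ncol(aln$seq)
  if (column < 0L || column >= L)
    stop_ox("column %d out of range [0, %d)", column, L)
  j <- column + 1L
  apply(aln$seq, 1L, function(s) {
    if (s[j] != "-") return("residue")
    if (all(s[j:L] == "-") || all(s[1:j] == "-")) return("terminated")
    "internal_gap"
  })
}

#' Score key-residue conservation
#'
#' For each key residue, reports the 0-based alignment column, occupancy
#' (fraction of records with a residue present), `pid_all` (fraction of all
#' records carrying the expected residue), `pid_occupied` (fraction of
#' occupied records carrying it; `NA` when occupancy is zero), the count of
#' records terminated before the column, and the substitution spectrum.
#' `X` residues count toward occupancy but never match. The identity
#' `pid_all == pid_occupied * occupancy` holds by construction.
#'
#' @param aln An `oxa_alignment`.
#' @param spec A [key_residue_spec()].
#' @param record_class Optional subset of record classes to score (requires
#'   `record_class` metadata). Position mapping always uses the full
#'   alignment, so the reference need not belong to the scored classes.
#' @return A `conservation_report`: data.frame with one row per key residue
#'   and a `substitutions` attribute (named list of residue-count tables).
#' @export
score_key_residues <- function(aln, spec, record_class = NULL) {
  stopifnot(inherits(aln, "oxa_alignment"), inherits(spec, "key_residue_spec"))
  posmap <- map_reference_positions(aln, spec$reference_id)
  beyond <- spec$positions[spec$positions > length(posmap)]
  if (length(beyond) > 0L)
    stop_ox("position %d beyond reference length %d",
            beyond[1L], length(posmap))

  scored <- aln
  if (!is.null(record_class)) {
    if (is.null(aln$meta) || !"record_class" %in% names(aln$meta))
      stop_ox("record_class filtering requires record_class metadata")
    ids <- aln$meta$id[aln$meta$record_class %in% record_class]
    if (length(ids) == 0L) stop_ox("no records of class %s",
                                   paste(record_class, collapse = "/"))
    scored <- subset_alignment(aln, ids)
  }
  n <- nrow(scored$seq)

  rows <- vector("list", length(spec$positions))
  subs <- vector("list", length(spec$positions))
  for (k in seq_along(spec$positions)) {
    col0 <- posmap[[as.character(spec$positions[k])]]
    states <- classify_column_states(scored, col0)
    chars <- scored$seq[, col0 + 1L]
    occupied <- states == "residue"
    match_exp <- occupied & chars == spec$expected[k]
    occupancy <- sum(occupied) / n
    pid_all <- sum(match_exp) / n
    pid_occ <- if (sum(occupied) > 0L) sum(match_exp) / sum(occupied) else NA_real_
    sub_tab <- table(chars[occupied & !match_exp])
    rows[[k]] <- data.frame(
      gene = spec$gene,
      position = spec$positions[k],
      expected = spec$expected[k],
      column_index = col0,
      n_records = n,
      occupancy = occupancy,
      pid_all = pid_all,
      pid_occupied = pid_occ,
      n_terminated = sum(states == "terminated"),
      n_internal_gap = sum(states == "internal_gap"),
      stringsAsFactors = FALSE
    )
    subs[[k]] <- sub_tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(subs) <- paste0(spec$expected, spec$positions)
  attr(out, "substitutions") <- subs
  class(out) <- c("conservation_report", "data.frame")
  out
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("Key-residue conservation (%s), %d residue(s), %d records\n",
              x$gene[1L], nrow(x), x$n_records[1L]))
  df <- as.data.frame(x)
  df$occupancy <- sprintf("%.1f%%", 100 * df$occupancy)
  df$pid_all <- sprintf("%.1f%%", 100 * df$pid_all)
  df$pid_occupied <- ifelse(is.na(x$pid_occupied), "NA",
                            sprintf("%.1f%%", 100 * x$pid_occupied))
  print(df[, c("position", "expected", "column_index", "occupancy",
               "pid_all", "pid_occupied", "n_terminated")], row.names = FALSE)
  invisible(x)
}

#' Position frequency matrix and information content (sequence logo)
#'
#' Gap-excluded per-column residue frequencies with Shannon information
#' content in bits, `IC = log2(20) - H`. `X` characters are excluded from
#' the frequency denominator (they carry no residue identity). Columns with
#' zero occupancy get `NA` frequencies and IC.
#'
#' @param aln An `oxa_alignment`.
#' @param columns Optional integer vector of 0-based columns (default: all).
#' @param small_sample_correction Subtract the Miller-Madow bias term
#'   `(20 - 1) / (2 ln(2) n)` from the IC (off by default).
#' @return A `logo_matrix`: list with `freq` (columns x 20 matrix),
#'   `information_content` (bits), `n_occupied`, `columns` (0-based).
#' @export
logo_matrix <- function(aln, columns = NULL,
                        small_sample_correction = FALSE) {
  stopifnot(inherits(aln, "oxa_alignment"))
  L <- ncol(aln$seq)
  if (nrow(aln$seq) == 0L) stop_ox("alignment is empty")
  cols0 <- if (is.null(columns)) 0:(L - 1L) else as.integer(columns)
  if (any(cols0 < 0L | cols0 >= L)) stop_ox("column index out of range")
  freq <- matrix(NA_real_, nrow = length(cols0), ncol = length(AA20),
                 dimnames = list(cols0, AA20))
  ic <- rep(NA_real_, length(cols0))
  nocc <- integer(length(cols0))
  for (i in seq_along(cols0)) {
    chars <- aln$seq[, cols0[i] + 1L]
    res <- chars[chars %in% AA20]
    nocc[i] <- length(res)
    if (length(res) == 0L) next
    p <- table(factor(res, levels = AA20)) / length(res)
    freq[i, ] <- as.numeric(p)
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    ic_i <- log2(20) - h
    if (small_sample_correction)
      ic_i <- ic_i - (length(AA20) - 1) / (2 * log(2) * length(res))
    ic[i] <- ic_i
  }
  structure(list(freq = freq, information_content = ic,
                 n_occupied = nocc, columns = cols0),
            class = "logo_matrix")
}

#' Write a logo matrix as a WebLogo-style position frequency TSV
#'
#' @param lm A `logo_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_logo_matrix <- function(lm, path) {
  stopifnot(inherits(lm, "logo_matrix"))
  df <- data.frame(column = lm$columns, lm$freq,
                   information_content = lm$information_content,
                   n_occupied = lm$n_occupied, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a conservation report as CSV
#'
#' The substitution spectrum is serialized as `res:count` pairs separated
#' by `;` in a `substitutions` column.
#' @param report A `conservation_report`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_conservation_report <- function(report, path) {
  stopifnot(inherits(report, "conservation_report"))
  subs <- attr(report, "substitutions")
  df <- as.data.frame(report)
  df$substitutions <- vapply(subs, function(s) {
    if (length(s) == 0L) return("")
    paste(sprintf("%s:%d", names(s), as.integer(s)), collapse = ";")
  }, character(1L))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
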