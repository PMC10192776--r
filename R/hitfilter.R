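# BLAST tabular hit parsing and retention filtering.
#
# Candidate sequences for the gene surveys are drawn from BLAST searches
# whose tabular output is curated down to a tractable set: hits must have
# E-value strictly below a cutoff and fractional percent identity strictly
# below a cutoff (so that near-duplicates of the query are excluded), one
# best hit is kept per subject, and the retained set is capped at a target
# size by E-value rank.

#' Retention policy for BLAST hits
#'
#' @param e_max Maximum E-value (exclusive). Hits are retained only when
#'   `e_value < e_max`. Default `1e-50`.
#' @param pid_max Maximum percent identity as a fraction in (0, 1]
#'   (exclusive bound). Default `0.87`.
#' @param target_max_records Cap on the number of retained records; when the
#'   filtered set is larger it is ranked by ascending E-value (ties broken by
#'   subject id) and truncated. Default `200`.
#' @param dedupe_on Either `"subject_id"` (keep the lowest-E-value hit per
#'   subject) or `"none"`.
#' @return A `filter_policy` object (a validated list).
#' @export
filter_policy <- function(e_max = 1e-50, pid_max = 0.87,
                          target_max_records = 200L,
                          dedupe_on = c("subject_id", "none")) {
  dedupe_on <- match.arg(dedupe_on)
  if (!is.numeric(e_max) || length(e_max) != 1L || e_max <= 0)
    stop_ox("e_max must be a single positive number")
  if (!is.numeric(pid_max) || length(pid_max) != 1L ||
      pid_max <= 0 || pid_max > 1)
    stop_ox("pid_max must be a fraction in (0, 1]")
  target_max_records <- as.integer(target_max_records)
  if (is.na(target_max_records) || target_max_records < 1L)
    stop_ox("target_max_records must be >= 1")
  structure(list(e_max = e_max, pid_max = pid_max,
                 target_max_records = target_max_records,
                 dedupe_on = dedupe_on),
            class = "filter_policy")
}

#' Parse tabular BLAST output (outfmt 6/7)
#'
#' Reads the standard 12-column tab-separated BLAST dialect
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore). Lines beginning with `#` (outfmt 7
#' comments) are skipped. Extra trailing columns are ignored.
#'
#' @param path Path to the tabular file.
#' @param pid_scale How percent identity is encoded in the file:
#'   `"percent"` (0--100, the BLAST+ default, normalized to a fraction on
#'   read) or `"fraction"` (already 0--1). Never guessed from the data.
#' @return A data.frame of hit records with columns `query_id`, `subject_id`,
#'   `percent_identity` (fraction in \[0, 1\]), `alignment_length`,
#'   `e_value`, `bit_score`.
#' @export
parse_blast_tab <- function(path, pid_scale = c("percent", "fraction")) {
  pid_scale <- match.arg(pid_scale)
  if (!file.exists(path)) stop_ox("BLAST tabular file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  if (length(data_lines) == 0L) {
    warn_ox("no data lines in %s; returning empty hit table", path)
    return(empty_hits())
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 12L)
  if (length(bad) > 0L)
    stop_ox("malformed BLAST line %d in %s: fewer than 12 tab-separated fields",
            which(keep)[bad[1L]], path)
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  hits <- data.frame(
    query_id = m[, 1L],
    subject_id = m[, 2L],
    percent_identity = as.numeric(m[, 3L]),
    alignment_length = as.integer(m[, 4L]),
    e_value = as.numeric(m[, 11L]),
    bit_score = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  if (anyNA(hits$percent_identity) || anyNA(hits$e_value))
    stop_ox("malformed BLAST line %d in %s: non-numeric pident or evalue",
            which(keep)[which(is.na(hits$percent_identity) |
                              is.na(hits$e_value))[1L]], path)
  if (pid_scale == "percent") hits$percent_identity <- hits$percent_identity / 100
  if (any(hits$percent_identity < 0 | hits$percent_identity > 1))
    stop_ox("percent identity outside [0, 1] after normalization; check pid_scale")
  if (any(hits$e_value < 0)) stop_ox("negative E-value encountered")
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = integer(),
             e_value = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Filter BLAST hits under a retention policy
#'
#' Applies, in fixed order: (1) the E-value rule `e_value < e_max`, (2) the
#' identity rule `percent_identity < pid_max`, (3) optional deduplication
#' keeping the lowest-E-value hit per subject, (4) the record cap by
#' ascending E-value rank (ties broken lexicographically by subject id).
#' Every removed record is attributed to exactly the first rule it fails.
#'
#' @param hits Data.frame from [parse_blast_tab()].
#' @param policy A [filter_policy()].
#' @return A list with elements `hits` (the retained data.frame) and
#'   `report` (data.frame of per-rule removal counts plus the retained
#'   count), of class `filter_result`.
#' @export
filter_hits <- function(hits, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  required <- c("query_id", "subject_id", "percent_identity", "e_value")
  if (!all(required %in% names(hits)))
    stop_ox("hits must contain columns: %s", paste(required, collapse = ", "))

  n0 <- nrow(hits)
  fail_e <- hits$e_value >= policy$e_max
  fail_pid <- !fail_e & hits$percent_identity >= policy$pid_max
  keep <- !fail_e & !fail_pid
  kept <- hits[keep, , drop = FALSE]

  n_dedupe <- 0L
  if (policy$dedupe_on == "subject_id" && nrow(kept) > 0L) {
    ord <- order(kept$e_value, kept$subject_id)
    kept <- kept[ord, , drop = FALSE]
    dup <- duplicated(kept$subject_id)
    n_dedupe <- sum(dup)
    kept <- kept[!dup, , drop = FALSE]
  }

  n_cap <- 0L
  kept <- kept[order(kept$e_value, kept$subject_id), , drop = FALSE]
  if (nrow(kept) > policy$target_max_records) {
    n_cap <- nrow(kept) - policy$target_max_records
    message(sprintf(
      "hit cap applied: %d records beyond the %d lowest-E-value hits dropped",
      n_cap, policy$target_max_records))
    kept <- kept[seq_len(policy$target_max_records), , drop = FALSE]
  }
  rownames(kept) <- NULL

  report <- data.frame(
    rule = c("e_value", "percent_identity", "dedupe", "cap", "retained"),
    count = c(sum(fail_e), sum(fail_pid), n_dedupe, n_cap, nrow(kept)),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(report$count) == n0)
  structure(list(hits = kept, report = report), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("BLAST hit filter result\n")
  cat(sprintf("  retained: %d\n", nrow(x$hits)))
  removed <- x$report[x$report$rule != "retained", , drop = FALSE]
  for (i in seq_len(nrow(removed)))
    cat(sprintf("  removed by %-16s %d\n", removed$rule[i], removed$count[i]))
  invisible(x)
}

#' Write filtered hits and the removal report
#'
#' @param result A `filter_result` from [filter_hits()].
#' @param hits_path Output TSV path (12-column dialect, pident back on the
#'   0--100 scale).
#' @param report_path Optional CSV path for the removal report.
#' @return Invisibly, `hits_path`.
#' @export
write_filtered_hits <- function(result, hits_path, report_path = NULL) {
  stopifnot(inherits(result, "filter_result"))
  h <- result$hits
  out <- data.frame(h$query_id, h$subject_id,
                    sprintf("%.3f", h$percent_identity * 100),
                    h$alignment_length, 0L, 0L, 0L, 0L, 0L, 0L,
                    format(h$e_value, digits = 3), h$bit_score)
  write.table(out, hits_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(report_path)) write.csv(result$report, report_path, row.names = FALSE)
  invisible(hits_path)
}
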