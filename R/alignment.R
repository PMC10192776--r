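# Gapped protein alignment container with per-record metadata.
#
# An alignment is stored as a character matrix (records x columns) of
# single residues, with record ids as rownames and an optional metadata
# data.frame (taxonomy, source environment, record class) keyed by id.
# Residues are upper-cased on construction; '.' is read as the gap '-'.

RECORD_CLASSES <- c("isolate", "MAG", "transcript", "fungal_outgroup")

#' Construct a protein alignment
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (letters from the 20-residue alphabet plus `-`, `.` and `X`), or a
#'   character matrix with one row per record.
#' @param meta Optional data.frame with an `id` column matching sequence
#'   names; typical columns are `phylum`, `class`, `genus`,
#'   `source_environment` and `record_class` (one of isolate, MAG,
#'   transcript, fungal_outgroup).
#' @return An object of class `oxa_alignment`.
#' @export
alignment <- function(seqs, meta = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop_ox("sequences must have unique names")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop_ox("all sequences must have equal (aligned) length; got lengths %s",
              paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop_ox("alignment records must have unique ids")
  mat <- toupper(mat)
  mat[mat == "."] <- "-"
  ok <- mat %in% c(AA20, "-", "X")
  if (!all(ok)) {
    offending <- unique(mat[!ok])
    stop_ox("invalid residue character(s): %s", paste(offending, collapse = " "))
  }
  if (!is.null(meta)) {
    if (!"id" %in% names(meta)) stop_ox("meta must have an 'id' column")
    missing_ids <- setdiff(rownames(mat), meta$id)
    if (length(missing_ids) > 0L)
      stop_ox("meta lacks rows for: %s", paste(missing_ids, collapse = ", "))
    meta <- meta[match(rownames(mat), meta$id), , drop = FALSE]
    rownames(meta) <- NULL
    if ("record_class" %in% names(meta)) {
      bad <- setdiff(unique(meta$record_class), c(RECORD_CLASSES, NA))
      if (length(bad) > 0L)
        stop_ox("unknown record_class value(s): %s", paste(bad, collapse = ", "))
    }
  }
  structure(list(seq = mat, meta = meta), class = "oxa_alignment")
}

#' @export
print.oxa_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d records x %d columns\n",
              nrow(x$seq), ncol(x$seq)))
  if (!is.null(x$meta))
    cat(sprintf("  metadata fields: %s\n",
                paste(setdiff(names(x$meta), "id"), collapse = ", ")))
  invisible(x)
}

#' @export
dim.oxa_alignment <- function(x) dim(x$seq)

aln_ids <- function(aln) rownames(aln$seq)

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA (protein). All records must have equal length.
#' @param meta Optional metadata data.frame or path to a metadata CSV with
#'   an `id` column.
#' @return An `oxa_alignment`.
#' @export
read_alignment <- function(path, meta = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (is.character(meta)) meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  alignment(seqs, meta = meta)
}

#' Write an alignment to FASTA
#'
#' @param aln An `oxa_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "oxa_alignment"))
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Subset an alignment by record ids or metadata
#'
#' @param aln An `oxa_alignment`.
#' @param ids Character vector of record ids to keep.
#' @return An `oxa_alignment` with the selected records.
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(inherits(aln, "oxa_alignment"))
  missing_ids <- setdiff(ids, aln_ids(aln))
  if (length(missing_ids) > 0L)
    stop_ox("ids not in alignment: %s", paste(missing_ids, collapse = ", "))
  meta <- if (!is.null(aln$meta)) aln$meta[match(ids, aln$meta$id), , drop = FALSE]
  alignment(aln$seq[ids, , drop = FALSE], meta = meta)
}
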