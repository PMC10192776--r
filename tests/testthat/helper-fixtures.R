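# In-code fixtures shared across test files.

# alignment from a named character vector, no metadata
aln_of <- function(...) alignment(c(...))

# write a 12-column BLAST outfmt-6 line
blast_line <- function(q = "q1", s, pid, len = 300, e, bits = 500) {
  paste(q, s, pid, len, 0, 0, 1, len, 1, len, e, bits, sep = "\t")
}

write_blast <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# random gapped alignment for property tests: n records x L columns with
# given gap and truncation behavior
random_alignment <- function(n, L, p_gap = 0.1, p_trunc = 0.2) {
  mat <- matrix(sample(AA20, n * L, replace = TRUE), n, L)
  gaps <- matrix(runif(n * L) < p_gap, n, L)
  mat[gaps] <- "-"
  for (i in seq_len(n)) {
    if (runif(1) < p_trunc) {
      cut <- sample(seq(ceiling(L / 2), L - 1L), 1L)
      if (runif(1) < 0.5) mat[i, (cut + 1L):L] <- "-" else mat[i, 1L:(L - cut)] <- "-"
    }
  }
  rownames(mat) <- sprintf("r%03d", seq_len(n))
  alignment(mat)
}

# independent recount of occupancy / identity at a column, written with
# rle-based terminal-run detection rather than the package's index scan
recount_column <- function(aln, col0, expected) {
  m <- aln$seq
  n <- nrow(m)
  j <- col0 + 1L
  occ <- 0L; match <- 0L; term <- 0L
  for (i in seq_len(n)) {
    ch <- m[i, j]
    if (ch != "-") {
      occ <- occ + 1L
      if (ch == expected) match <- match + 1L
    } else {
      r <- rle(m[i, ] == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      k <- which(starts <= j & j <= ends)
      is_terminal_run <- r$values[k] &&
        (starts[k] == 1L || ends[k] == ncol(m))
      if (is_terminal_run) term <- term + 1L
    }
  }
  list(occupancy = occ / n, pid_all = match / n,
       pid_occupied = if (occ > 0) match / occ else NA_real_,
       n_terminated = term)
}
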