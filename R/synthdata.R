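# Seeded synthetic inputs with known truth for every analysis stage:
# multi-clade protein families with group-correlated metadata, conserved
# key sites and MAG-like truncation; BLAST-style hit tables with controlled
# pass/fail composition; additive distance matrices from known trees.
#
# All generators consume an explicit seed and are fully deterministic;
# truth records carry every generated parameter so downstream expectations
# can be computed without re-deriving the generator.

#' Configuration for a synthetic protein family
#'
#' @param n_groups Number of clades (default 2).
#' @param records_per_group Records per clade (default 10).
#' @param seq_length Ungapped sequence length (default 120).
#' @param group_divergence Per-site substitution probability between the
#'   common ancestor and each group consensus (default 0.3).
#' @param within_noise Per-site substitution probability around the group
#'   consensus (default 0.02).
#' @param key_sites Data.frame with columns `position`, `residue`,
#'   `conservation` (probability the site carries the residue, per record).
#' @param truncation_fraction Fraction of records rendered MAG-like by
#'   replacing a random suffix or prefix with gaps (default 0).
#' @param min_kept_fraction Minimum fraction of the sequence a truncated
#'   record retains (default 1/3). Values above 0.5 guarantee that any two
#'   truncated records still overlap, which distance-based tree building
#'   requires.
#' @param label_map Data.frame with one row per group: columns `taxonomy`
#'   and `environment` (defaults generated as group1..k / env1..k).
#' @param seed Integer seed (mandatory).
#' @return A `family_config` list.
#' @export
family_config <- function(n_groups = 2L, records_per_group = 10L,
                          seq_length = 120L, group_divergence = 0.3,
                          within_noise = 0.02, key_sites = NULL,
                          truncation_fraction = 0, min_kept_fraction = 1 / 3,
                          label_map = NULL, seed) {
  if (missing(seed)) stop_ox("seed is mandatory")
  probs <- c(group_divergence, within_noise, truncation_fraction)
  if (any(probs < 0 | probs > 1)) stop_ox("probabilities must lie in [0, 1]")
  if (min_kept_fraction <= 0 || min_kept_fraction >= 1)
    stop_ox("min_kept_fraction must lie in (0, 1)")
  if (!is.null(key_sites)) {
    stopifnot(all(c("position", "residue", "conservation") %in% names(key_sites)),
              all(key_sites$position >= 1),
              all(key_sites$position <= seq_length),
              all(key_sites$conservation >= 0 & key_sites$conservation <= 1),
              all(toupper(key_sites$residue) %in% AA20))
  }
  if (is.null(label_map))
    label_map <- data.frame(taxonomy = paste0("taxon_", seq_len(n_groups)),
                            environment = paste0("env_", seq_len(n_groups)),
                            stringsAsFactors = FALSE)
  stopifnot(nrow(label_map) == n_groups)
  structure(list(n_groups = as.integer(n_groups),
                 records_per_group = as.integer(records_per_group),
                 seq_length = as.integer(seq_length),
                 group_divergence = group_divergence,
                 within_noise = within_noise,
                 key_sites = key_sites,
                 truncation_fraction = truncation_fraction,
                 min_kept_fraction = min_kept_fraction,
                 label_map = label_map,
                 seed = as.integer(seed)),
            class = "family_config")
}

substitute_sites <- function(seq_vec, prob) {
  hit <- stats::runif(length(seq_vec)) < prob
  if (any(hit))
    seq_vec[hit] <- vapply(seq_vec[hit], function(r)
      sample(setdiff(AA20, r), 1L), "")
  seq_vec
}

#' Generate a synthetic protein family
#'
#' Group consensus sequences are derived from a common ancestor by per-site
#' substitution with probability `group_divergence` (uniform over the 19
#' alternative residues); records are sampled around their group consensus
#' with `within_noise`; key sites are then forced to the specified residue
#' with probability `conservation`, independently per record, or otherwise
#' substituted; finally a `truncation_fraction` of records get a random
#' suffix (or prefix, equal odds) replaced by gaps. Metadata labels follow
#' the group.
#'
#' @param cfg A [family_config()].
#' @return A list: `aln` (an `oxa_alignment` with metadata), `truth` (the
#'   config plus per-record group assignments and truncation spans).
#' @export
generate_family <- function(cfg) {
  stopifnot(inherits(cfg, "family_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  ancestor <- sample(AA20, L, replace = TRUE)
  consensus <- lapply(seq_len(cfg$n_groups), function(g)
    substitute_sites(ancestor, cfg$group_divergence))

  n <- cfg$n_groups * cfg$records_per_group
  ids <- sprintf("g%d_rec%02d", rep(seq_len(cfg$n_groups),
                                    each = cfg$records_per_group),
                 rep(seq_len(cfg$records_per_group), cfg$n_groups))
  group <- rep(seq_len(cfg$n_groups), each = cfg$records_per_group)
  mat <- matrix("", n, L, dimnames = list(ids, NULL))
  for (i in seq_len(n))
    mat[i, ] <- substitute_sites(consensus[[group[i]]], cfg$within_noise)

  if (!is.null(cfg$key_sites)) {
    for (k in seq_len(nrow(cfg$key_sites))) {
      pos <- cfg$key_sites$position[k]
      res <- toupper(cfg$key_sites$residue[k])
      conserved <- stats::runif(n) < cfg$key_sites$conservation[k]
      mat[conserved, pos] <- res
      if (any(!conserved))
        mat[!conserved, pos] <- vapply(which(!conserved), function(i)
          sample(setdiff(AA20, res), 1L), "")
    }
  }

  n_trunc <- round(cfg$truncation_fraction * n)
  truncated <- data.frame(id = character(0), side = character(0),
                          from = integer(0), stringsAsFactors = FALSE)
  if (n_trunc > 0L) {
    which_trunc <- sample.int(n, n_trunc)
    for (i in which_trunc) {
      side <- sample(c("suffix", "prefix"), 1L)
      cut <- sample(seq(ceiling(L * cfg$min_kept_fraction), L - 1L), 1L)
      if (side == "suffix") mat[i, (cut + 1L):L] <- "-"
      else mat[i, 1L:(L - cut)] <- "-"
      truncated <- rbind(truncated,
                         data.frame(id = ids[i], side = side, from = cut,
                                    stringsAsFactors = FALSE))
    }
  }

  meta <- data.frame(
    id = ids,
    taxonomy = cfg$label_map$taxonomy[group],
    source_environment = cfg$label_map$environment[group],
    record_class = ifelse(ids %in% truncated$id, "MAG", "isolate"),
    group = group,
    stringsAsFactors = FALSE
  )
  aln <- alignment(mat, meta = meta)
  list(aln = aln,
       truth = list(config = cfg, group = setNames(group, ids),
                    ancestor = paste(ancestor, collapse = ""),
                    consensus = vapply(consensus, paste, "", collapse = ""),
                    truncated = truncated))
}

#' Write a generated family to disk
#'
#' Emits aligned FASTA, metadata CSV and a truth JSON (with the seed in
#' every header).
#' @param fam Result of [generate_family()].
#' @param prefix Output path prefix; files `<prefix>.fasta`,
#'   `<prefix>_meta.csv`, `<prefix>_truth.json` are written.
#' @return Invisibly, the three paths.
#' @export
write_family <- function(fam, prefix) {
  fasta <- paste0(prefix, ".fasta")
  metacsv <- paste0(prefix, "_meta.csv")
  truthjson <- paste0(prefix, "_truth.json")
  write_alignment(fam$aln, fasta)
  write.csv(fam$aln$meta, metacsv, row.names = FALSE)
  truth <- fam$truth
  truth$config$key_sites <- truth$config$key_sites %||% list()
  jsonlite::write_json(truth, truthjson, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(fasta = fasta, meta = metacsv, truth = truthjson))
}

#' Generate a BLAST-style hit table with known pass/fail composition
#'
#' Passing hits satisfy both retention rules (E-value below 1e-50 and
#' fractional identity below 0.87); each failing hit violates exactly its
#' designated rule. Rows are shuffled deterministically by the seed.
#'
#' @param n_pass Hits passing both rules.
#' @param n_fail_e Hits failing only the E-value rule.
#' @param n_fail_pid Hits failing only the identity rule.
#' @param seed Integer seed.
#' @param path Optional output TSV path (outfmt-6); when `NULL` no file is
#'   written.
#' @return List with `hits` (data.frame in parsed form), `truth` (the
#'   composition counts) and `path`.
#' @export
generate_hit_table <- function(n_pass, n_fail_e, n_fail_pid, seed,
                               path = NULL) {
  stopifnot(n_pass >= 0, n_fail_e >= 0, n_fail_pid >= 0)
  set.seed(as.integer(seed))
  mk <- function(n, tag, e_rng, pid_rng) {
    if (n == 0L) return(NULL)
    data.frame(
      query_id = "query1",
      subject_id = sprintf("%s_%03d", tag, seq_len(n)),
      percent_identity = round(stats::runif(n, pid_rng[1], pid_rng[2]), 4),
      alignment_length = sample(200:500, n, replace = TRUE),
      e_value = 10^stats::runif(n, log10(e_rng[1]), log10(e_rng[2])),
      bit_score = round(stats::runif(n, 200, 900), 1),
      stringsAsFactors = FALSE
    )
  }
  hits <- rbind(
    mk(n_pass, "pass", c(1e-180, 1e-51), c(0.30, 0.86)),
    mk(n_fail_e, "faile", c(1e-49, 1e-10), c(0.30, 0.86)),
    mk(n_fail_pid, "failp", c(1e-180, 1e-51), c(0.875, 0.999))
  )
  if (is.null(hits)) hits <- empty_hits()
  if (nrow(hits) > 1L) hits <- hits[sample.int(nrow(hits)), , drop = FALSE]
  rownames(hits) <- NULL
  if (!is.null(path)) {
    out <- data.frame(hits$query_id, hits$subject_id,
                      sprintf("%.2f", hits$percent_identity * 100),
                      hits$alignment_length, 0L, 0L, 1L, hits$alignment_length,
                      1L, hits$alignment_length,
                      formatC(hits$e_value, format = "e", digits = 2),
                      hits$bit_score)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  list(hits = hits,
       truth = list(n_pass = n_pass, n_fail_e = n_fail_e,
                    n_fail_pid = n_fail_pid, seed = as.integer(seed)),
       path = path)
}

#' Generate an additive distance matrix from a random tree
#'
#' Simulates a random topology with branch lengths, returns the exact
#' path-length (patristic) distance matrix together with the generating
#' tree -- the canonical oracle input for neighbor joining, which must
#' recover the tree exactly from additive data.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param seed Integer seed.
#' @param min_branch,max_branch Branch length range (uniform).
#' @return List with `d` (distance matrix) and `tree` (the true `phylo`).
#' @export
generate_additive_matrix <- function(n_taxa, seed, min_branch = 0.05,
                                     max_branch = 1) {
  stopifnot(n_taxa >= 4L)
  set.seed(as.integer(seed))
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) stats::runif(n, min_branch, max_branch))
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(d = d, tree = tree)
}
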