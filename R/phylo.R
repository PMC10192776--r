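# Desk-scale phylogenetics: p-distances, neighbor-joining with bootstrap
# supports, Newick round trips, and clade-metadata concordance.
#
# Trees are represented as ape "phylo" objects throughout; bootstrap
# supports live in node.label as integer percentages (root label empty).
# The neighbor-joining agglomeration is implemented here with a fixed
# deterministic tie-break (lowest index pair) so that runs are exactly
# reproducible; ape's independent NJ implementation is used only as a
# cross-check in the test suite.

#' Pairwise p-distance matrix with pairwise deletion
#'
#' Proportion of mismatching residues over columns where both records carry
#' a residue (gaps and only-gap overlaps excluded). `X` never matches
#' anything, including another `X`, but does count as a compared column.
#'
#' @param aln An `oxa_alignment` with at least 3 records.
#' @return A symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "oxa_alignment"))
  m <- aln$seq
  n <- nrow(m)
  if (n < 3L) stop_ox("p_distance needs at least 3 records")
  present <- m != "-"
  isres <- present & m != "X"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- present[i, ] & present[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop_ox("records '%s' and '%s' share no comparable columns",
                rownames(m)[i], rownames(m)[j])
      match_ij <- comp & isres[i, ] & isres[j, ] & m[i, ] == m[j, ]
      d[i, j] <- d[j, i] <- 1 - sum(match_ij) / nc
    }
  }
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_ox("distance matrix must be square")
  if (is.null(rownames(d))) stop_ox("distance matrix must have ids as dimnames")
  if (max(abs(d - t(d))) > 1e-8) stop_ox("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop_ox("distance matrix diagonal must be zero")
  if (any(d < 0)) stop_ox("distances must be non-negative")
  invisible(TRUE)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration under the standard Q-criterion. Ties in Q are
#' broken deterministically by the lowest (i, j) index pair in the current
#' matrix ordering. Negative branch lengths are clamped to zero with a
#' message. The result is an unrooted `phylo` object; on an additive
#' distance matrix the tree's path-length matrix reproduces the input
#' exactly.
#'
#' @param d Symmetric distance matrix with ids as dimnames (n >= 3).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop_ox("nj_tree needs at least 3 taxa")
  labels <- rownames(d)

  # node bookkeeping: tips 1..n, internal nodes numbered from n+1
  # (ape convention: root/internal nodes n+1 .. 2n-2 for unrooted binary)
  n_internal <- n - 2L
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  active_nodes <- seq_len(n)      # ape node ids of active clusters
  next_internal <- 2L * n - 2L    # assign internal ids downward, root = n+1
  D <- d
  clamped <- 0L

  add_edge <- function(parent, child, len) {
    edge <<- rbind(edge, c(parent, child))
    if (len < 0) { clamped <<- clamped + 1L; len <- 0 }
    edge_len <<- c(edge_len, len)
  }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # lowest-index tie-break: scan column-major over upper triangle via
    # which() on the row-major minimum
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    bi <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    newnode <- next_internal
    next_internal <- next_internal - 1L
    add_edge(newnode, active_nodes[i], bi)
    add_edge(newnode, active_nodes[j], bj)

    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    ids <- c(active_nodes[keep], newnode)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
    active_nodes <- ids
  }

  # final 3-cluster star joined at the root node (n+1), three-point formulas
  root <- n + 1L
  stopifnot(next_internal == root)
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(root, active_nodes[1], b1)
  add_edge(root, active_nodes[2], b2)
  add_edge(root, active_nodes[3], b3)

  if (clamped > 0L)
    message(sprintf("nj_tree: %d negative branch length(s) clamped to 0", clamped))

  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = labels, Nnode = n_internal),
                  class = "phylo", order = "unknown")
  tr <- stats::reorder(tr, "cladewise")
  tr
}

#' Column-bootstrap supports for the NJ tree
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds an NJ tree
#' per replicate, and scores each internal edge of the reference tree by
#' the percentage of replicates containing the same bipartition
#' (ape::prop.clades with unrooted bipartition matching).
#'
#' @param aln An `oxa_alignment`.
#' @param n_reps Number of bootstrap replicates (default 500, the usual
#'   choice for published trees).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return The reference `phylo` tree with integer percentage supports in
#'   `node.label` (root label `""`).
#' @export
bootstrap_support <- function(aln, n_reps = 500L, seed) {
  stopifnot(inherits(aln, "oxa_alignment"))
  if (missing(seed)) stop_ox("seed is required")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop_ox("n_reps must be >= 1")
  ref <- nj_tree(p_distance(aln))
  L <- ncol(aln$seq)
  set.seed(as.integer(seed))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- alignment(aln$seq[, cols, drop = FALSE])
    reps[[r]] <- suppressMessages(nj_tree(p_distance(baln)))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_reps))
  # first internal node is the (arbitrary) root trifurcation: no bipartition
  labs <- as.character(support)
  labs[1L] <- ""
  ref$node.label <- labs
  ref
}

#' Read a Newick tree
#'
#' Internal node labels are parsed as bootstrap supports when numeric.
#' @param path Newick file path.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_ox("tree file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # single-quoted labels (which may contain spaces or punctuation) are
  # substituted with safe placeholders before parsing, then restored
  quoted <- regmatches(txt, gregexpr("'[^']*'", txt))[[1L]]
  restore <- character(0)
  if (length(quoted) > 0L) {
    keys <- sprintf("QUOTEDLBL%03d", seq_along(quoted))
    restore <- setNames(gsub("^'|'$", "", quoted), keys)
    for (i in seq_along(quoted))
      txt <- sub(quoted[i], keys[i], txt, fixed = TRUE)
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop_ox("Newick parse error in %s: %s",
                                             path, conditionMessage(e)))
  if (is.null(tr)) stop_ox("Newick parse error in %s", path)
  unquote <- function(x) {
    hit <- x %in% names(restore)
    x[hit] <- restore[x[hit]]
    x
  }
  if (length(restore) > 0L) {
    tr$tip.label <- unquote(tr$tip.label)
    if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  }
  tr
}

#' Write a Newick tree
#'
#' @param tree A `phylo` tree (node labels preserved).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  needs_quote <- function(x) grepl("[][ (),:;']", x)
  labs <- c(tree$tip.label, tree$node.label %||% character(0))
  special <- unique(labs[needs_quote(labs)])
  if (length(special) > 0L) {
    keys <- sprintf("QUOTEDLBL%03d", seq_along(special))
    map <- setNames(keys, special)
    requote <- function(x) ifelse(x %in% special, map[x], x)
    tree$tip.label <- requote(tree$tip.label)
    if (!is.null(tree$node.label)) tree$node.label <- requote(tree$node.label)
    txt <- ape::write.tree(tree)
    for (i in seq_along(special))
      txt <- sub(keys[i], paste0("'", special[i], "'"), txt, fixed = TRUE)
    writeLines(txt, path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

# tip ids (indices) descending from each internal node
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  tips <- vector("list", total)
  for (i in seq_len(n)) tips[[i]] <- i
  for (e in ape::postorder(tree)) {    # child edges precede parent edges
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tips[[par]] <- c(tips[[par]], tips[[ch]])
  }
  tips[(n + 1L):total]
}

#' Clade-metadata concordance report
#'
#' Evaluates every internal node whose bootstrap support meets a threshold
#' and reports, per metadata field value, how pure the clade is: the
#' maximum fraction of its tips sharing one label (`purity`) and that
#' majority label. The summary counts maximal pure clades per label (pure
#' clades not nested inside a larger pure clade of the same label).
#' Missing metadata values are labelled `"unknown"`; label comparison is
#' case-insensitive after trimming.
#'
#' @param tree A `phylo` tree with supports in `node.label` (as from
#'   [bootstrap_support()] or a support-annotated Newick file).
#' @param meta Data.frame with an `id` column covering all tips.
#' @param metadata_field Column of `meta` to evaluate.
#' @param support_min Minimum support percentage (default 50, mirroring the
#'   display threshold used for published trees). Nodes with missing
#'   support (e.g. the root) are skipped.
#' @return A `clade_concordance` list: `clades` data.frame (node, size,
#'   support, purity, majority_label, is_pure, is_maximal_pure) and
#'   `summary` data.frame (label, n_pure_clades, largest_pure_clade).
#' @export
clade_concordance <- function(tree, meta, metadata_field, support_min = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!metadata_field %in% names(meta))
    stop_ox("metadata field '%s' not present", metadata_field)
  lab <- meta[[metadata_field]][match(tree$tip.label, meta$id)]
  lab <- tolower(trimws(as.character(lab)))
  lab[is.na(lab) | lab == ""] <- "unknown"

  n <- length(tree$tip.label)
  sup <- node_supports(tree)
  dt <- descendant_tips(tree)
  keep <- which(!is.na(sup) & sup >= support_min &
                vapply(dt, length, 1L) >= 2L)
  rows <- lapply(keep, function(k) {
    tips <- dt[[k]]
    tab <- sort(table(lab[tips]), decreasing = TRUE)
    data.frame(node = n + k, size = length(tips), support = sup[k],
               purity = as.numeric(tab[1L]) / length(tips),
               majority_label = names(tab)[1L],
               stringsAsFactors = FALSE)
  })
  clades <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(), size = integer(), support = numeric(),
               purity = numeric(), majority_label = character())
  clades$is_pure <- clades$purity == 1

  # maximal pure clades: pure and not a subset of a larger pure clade with
  # the same label
  clades$is_maximal_pure <- FALSE
  pure_idx <- which(clades$is_pure)
  for (i in pure_idx) {
    tips_i <- dt[[clades$node[i] - n]]
    nested <- any(vapply(pure_idx, function(j) {
      j != i && clades$majority_label[j] == clades$majority_label[i] &&
        all(tips_i %in% dt[[clades$node[j] - n]]) &&
        clades$size[j] > clades$size[i]
    }, logical(1L)))
    clades$is_maximal_pure[i] <- !nested
  }

  maximal <- clades[clades$is_maximal_pure, , drop = FALSE]
  summary_df <- if (nrow(maximal)) {
    agg <- split(maximal, maximal$majority_label)
    do.call(rbind, lapply(names(agg), function(l)
      data.frame(label = l, n_pure_clades = nrow(agg[[l]]),
                 largest_pure_clade = max(agg[[l]]$size),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(label = character(), n_pure_clades = integer(),
               largest_pure_clade = integer())
  }
  structure(list(clades = clades, summary = summary_df,
                 field = metadata_field, support_min = support_min),
            class = "clade_concordance")
}

#' @export
print.clade_concordance <- function(x, ...) {
  cat(sprintf("Clade concordance on '%s' (support >= %s): %d supported clades\n",
              x$field, x$support_min, nrow(x$clades)))
  if (nrow(x$summary)) {
    cat("Maximal pure clades per label:\n")
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}

# deterministic qualitative palette (Okabe-Ito plus extensions)
ITOL_PALETTE <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
                  "#D55E00", "#CC79A7", "#999999", "#8DD3C7", "#BEBADA",
                  "#FB8072", "#80B1D3", "#FDB462", "#B3DE69", "#FCCDE5")

#' Export iTOL colorstrip annotation datasets
#'
#' Writes one iTOL colorstrip dataset text file per metadata field with a
#' deterministic label-to-color assignment (labels sorted, then mapped onto
#' a fixed qualitative palette; labels beyond the palette get a
#' deterministic grey fallback and a message).
#'
#' @param tree A `phylo` tree.
#' @param meta Data.frame with `id` column covering all tips.
#' @param metadata_fields Character vector of columns of `meta` to export.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named by field).
#' @export
export_itol_annotations <- function(tree, meta, metadata_fields, dir = ".") {
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(tree$tip.label, meta$id)
  if (length(missing_tips) > 0L)
    stop_ox("tips missing from metadata: %s", paste(missing_tips, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (field in metadata_fields) {
    if (!field %in% names(meta)) stop_ox("metadata field '%s' not present", field)
    lab <- as.character(meta[[field]][match(tree$tip.label, meta$id)])
    lab[is.na(lab) | lab == ""] <- "unknown"
    levels_sorted <- sort(unique(lab))
    if (length(levels_sorted) > length(ITOL_PALETTE))
      message(sprintf("field '%s': %d labels exceed palette; grey fallback used",
                      field, length(levels_sorted) - length(ITOL_PALETTE)))
    cols <- ifelse(seq_along(levels_sorted) <= length(ITOL_PALETTE),
                   ITOL_PALETTE[pmin(seq_along(levels_sorted), length(ITOL_PALETTE))],
                   "#666666")
    colmap <- setNames(cols, levels_sorted)
    path <- file.path(dir, sprintf("itol_%s.txt", field))
    con <- file(path, "w")
    writeLines(c("DATASET_COLORSTRIP",
                 "SEPARATOR TAB",
                 paste0("DATASET_LABEL\t", field),
                 "COLOR\t#000000",
                 paste0("LEGEND_TITLE\t", field),
                 paste("LEGEND_SHAPES", paste(rep("1", length(levels_sorted)),
                                              collapse = "\t"), sep = "\t"),
                 paste("LEGEND_COLORS", paste(colmap, collapse = "\t"), sep = "\t"),
                 paste("LEGEND_LABELS", paste(levels_sorted, collapse = "\t"),
                       sep = "\t"),
                 "DATA"), con)
    writeLines(paste(tree$tip.label, colmap[lab], lab, sep = "\t"), con)
    close(con)
    paths[field] <- path
  }
  invisible(paths)
}
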