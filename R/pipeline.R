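# End-to-end orchestration: filter -> conservation -> tree -> concordance
# -> energetics from one structured configuration, with a JSON run
# manifest recording inputs, parameters and output checksums.

#' Validate a pipeline run configuration
#'
#' The configuration is a named list (typically read from YAML with
#' [read_run_config()]) with optional stage blocks `hitfilter`,
#' `conservation`, `phylo`, `energetics`, a mandatory `seed` and `out_dir`.
#' Referenced input files must exist at validation time.
#'
#' @param cfg Named list.
#' @return The validated config (with defaults filled), invisibly classed
#'   `run_config`.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop_ox("config must set a seed")
  if (is.null(cfg$out_dir)) stop_ox("config must set out_dir")
  inputs <- c(cfg$hitfilter$hits, cfg$conservation$alignment,
              cfg$conservation$metadata, cfg$conservation$key_residues,
              cfg$phylo$alignment, cfg$phylo$metadata)
  missing_files <- inputs[!file.exists(inputs)]
  if (length(missing_files) > 0L)
    stop_ox("config references missing file(s): %s",
            paste(missing_files, collapse = ", "))
  defaults <- list(
    hitfilter = list(e_max = 1e-50, pid_max = 0.87, cap = 200L,
                     pid_scale = "percent"),
    phylo = list(bootstrap = 100L, support_min = 50,
                 fields = "source_environment"),
    energetics = list(reactions = c("oxalotrophy", "aom_sr"))
  )
  for (stage in names(defaults))
    if (!is.null(cfg[[stage]]))
      cfg[[stage]] <- modifyList(defaults[[stage]], cfg[[stage]])
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_ox("config file not found: %s", path)
  validate_run_config(yaml::read_yaml(path))
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(names(h)))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order, writing each
#' stage's artifacts under `out_dir` and a `manifest.json` recording the
#' seed, per-stage parameters, input checksums and output checksums. A
#' stage failure halts the run with the stage named; downstream artifacts
#' are not written.
#'
#' @param cfg A `run_config` (or a named list, validated on entry).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop_ox("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- res
  }

  if (!is.null(cfg$hitfilter)) run_stage("hitfilter", function() {
    hc <- cfg$hitfilter
    hits <- parse_blast_tab(hc$hits, pid_scale = hc$pid_scale)
    res <- filter_hits(hits, filter_policy(hc$e_max, hc$pid_max, hc$cap))
    hits_path <- file.path(out, "filtered_hits.tsv")
    report_path <- file.path(out, "filter_report.csv")
    write_filtered_hits(res, hits_path, report_path)
    list(params = hc[c("e_max", "pid_max", "cap")],
         inputs = md5_of(hc$hits),
         outputs = md5_of(c(hits_path, report_path)))
  })

  aln <- NULL
  if (!is.null(cfg$conservation)) run_stage("conservation", function() {
    cc <- cfg$conservation
    aln <<- read_alignment(cc$alignment, meta = cc$metadata)
    specs <- read_key_residues(cc$key_residues)
    paths <- character(0)
    for (spec in specs) {
      rep_path <- file.path(out, sprintf("conservation_%s.csv", spec$gene))
      write_conservation_report(score_key_residues(aln, spec), rep_path)
      lm_path <- file.path(out, sprintf("logo_%s.tsv", spec$gene))
      cols <- map_reference_positions(aln, spec$reference_id)
      write_logo_matrix(
        logo_matrix(aln, columns = cols[as.character(spec$positions)]),
        lm_path)
      paths <- c(paths, rep_path, lm_path)
    }
    list(inputs = md5_of(c(cc$alignment, cc$key_residues)),
         outputs = md5_of(paths))
  })

  if (!is.null(cfg$phylo)) run_stage("phylo", function() {
    pc <- cfg$phylo
    paln <- if (!is.null(pc$alignment))
      read_alignment(pc$alignment, meta = pc$metadata) else aln
    if (is.null(paln)) stop_ox("no alignment available")
    tree <- bootstrap_support(paln, n_reps = pc$bootstrap, seed = cfg$seed)
    tree_path <- file.path(out, "nj_tree.nwk")
    write_newick(tree, tree_path)
    paths <- tree_path
    for (field in pc$fields) {
      cc_rep <- clade_concordance(tree, paln$meta, field,
                                  support_min = pc$support_min)
      cc_path <- file.path(out, sprintf("concordance_%s.csv", field))
      write.csv(cc_rep$clades, cc_path, row.names = FALSE)
      paths <- c(paths, cc_path)
    }
    itol <- export_itol_annotations(tree, paln$meta, pc$fields, dir = out)
    list(params = pc[c("bootstrap", "support_min")],
         outputs = md5_of(c(paths, itol)))
  })

  if (!is.null(cfg$energetics)) run_stage("energetics", function() {
    ec <- cfg$energetics
    known <- list(oxalotrophy = reaction_oxalotrophy(),
                  aom_sr = reaction_aom_sr())
    rxns <- known[unlist(ec$reactions)]
    grid <- tp_grid(rxns)
    grid_path <- file.path(out, "energetics_grid.csv")
    write.csv(grid, grid_path, row.names = FALSE)
    list(outputs = md5_of(grid_path))
  })

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
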