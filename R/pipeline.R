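# End-to-end pipeline: simulate -> partition -> classify-gene ->
# detect-inversions -> pcr-screen -> map-character, with a single seed
# fanned out to per-stage child seeds, structured logging and a JSON-able
# run report.

#' The 4-genome whole-genome-alignment panel configuration
#'
#' One genome per rearrangement state on the path to the triple-inverted
#' plastome: none, 50-kb only, 50+36, 50+36+24. Decomposing this panel's
#' gene orders yields seven collinear blocks (six distinct interior
#' breakpoints).
#'
#' @return Data frame with columns `taxon`, `inv50`, `inv36`, `inv24`.
#' @export
alignment_panel_config <- function() {
  data.frame(
    taxon = c("Tamarindus_indica", "Arachis_hypogaea", "Lupinus_luteus",
              "Maackia_fauriei"),
    inv50 = c(FALSE, TRUE, TRUE, TRUE),
    inv36 = c(FALSE, FALSE, TRUE, TRUE),
    inv24 = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Path to a packaged example tree
#'
#' `"main"` is the screening-panel topology under which the 24-kb-positive
#' taxa are monophyletic; `"its_alt"` is an alternative placing the two
#' 24-kb-negative Sophoreae genera inside that clade (the nuclear-ITS-style
#' arrangement), under which the single-origin test fails.
#'
#' @param which `"main"` or `"its_alt"`.
#' @return File path to a Newick tree.
#' @export
packaged_tree_path <- function(which = c("main", "its_alt")) {
  which <- match.arg(which)
  fn <- c(main = "screen_tree_main.nwk", its_alt = "screen_tree_its_alt.nwk")
  system.file("extdata", fn[[which]], package = "plastomeR", mustWork = TRUE)
}

#' Assemble a pipeline run configuration
#'
#' @param seed Master seed; per-stage child seeds are derived stably.
#' @param profile `"mini"` (fast) or `"full"` (paper-scale sizes).
#' @param stages Stage names to run, a subset of the defaults.
#' @param truncation_threshold,min_ir_len,max_mismatch Stage thresholds.
#' @param tree Path to the screening tree (defaults to the packaged main
#'   topology).
#' @return A `RunConfig` list.
#' @export
run_config <- function(seed = 1L, profile = c("mini", "full"),
                       stages = c("simulate", "partition", "classify_gene",
                                  "detect_inversions", "pcr_screen",
                                  "map_character"),
                       truncation_threshold = 0.5, min_ir_len = 1000L,
                       max_mismatch = 2L, tree = NULL) {
  profile <- match.arg(profile)
  structure(list(seed = as.integer(seed), profile = profile, stages = stages,
                 truncation_threshold = truncation_threshold,
                 min_ir_len = as.integer(min_ir_len),
                 max_mismatch = as.integer(max_mismatch),
                 tree = if (is.null(tree)) packaged_tree_path("main") else
                   tree),
            class = "RunConfig")
}

stage_log <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full synthetic-plastome analysis pipeline
#'
#' Executes the toggled stages in order and collects one report; identical
#' configuration and seed give an identical report. A stage failure marks
#' the stage failed and skips stages that depend on it.
#'
#' @param config A [run_config()].
#' @param out Optional path; when given, the report is serialized there as
#'   JSON.
#' @param verbose Log one line per stage.
#' @return The run report (list), with the configuration echoed under
#'   `$config` and per-stage results under `$stages`.
#' @export
run_pipeline <- function(config = run_config(), out = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  seed <- config$seed
  profile <- config$profile
  report <- list(config = list(seed = seed, profile = profile,
                               stages = config$stages,
                               truncation_threshold =
                                 config$truncation_threshold,
                               min_ir_len = config$min_ir_len,
                               max_mismatch = config$max_mismatch),
                 stages = list())
  run_stage <- function(name, deps, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    failed_dep <- deps[vapply(deps, function(d) {
      !is.null(report$stages[[d]]) && identical(report$stages[[d]]$status,
                                                "failed") ||
        (d %in% config$stages && is.null(report$stages[[d]]))
    }, logical(1))]
    if (length(failed_dep) > 0L) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = paste("dependency failed:",
                                                    failed_dep[1L]))
      stage_log(verbose, name, "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(list(status = "ok", result = fun()),
                    error = function(e) list(status = "failed",
                                             error = conditionMessage(e)))
    report$stages[[name]] <<- res
    stage_log(verbose, name, res$status)
    invisible(NULL)
  }

  env <- new.env()

  run_stage("simulate", character(0), function() {
    env$reference <- generate_plastome(default_gene_catalog(profile),
                                       seed = derive_seed(seed, 0L),
                                       id = "reference")
    env$screen_panel <- build_panel(screen_panel_config(),
                                    seed = derive_seed(seed, 1L),
                                    profile = profile)
    env$align_panel <- build_panel(alignment_panel_config(),
                                   seed = derive_seed(seed, 2L),
                                   profile = profile)
    list(n_screen_genomes = length(env$screen_panel),
         n_alignment_genomes = length(env$align_panel),
         reference_length = nchar(env$reference$sequence))
  })

  run_stage("partition", "simulate", function() {
    focal <- env$screen_panel[["Maackia_fauriei"]]
    part <- partition_genome(focal, min_len = config$min_ir_len)
    summ <- genome_summary(focal, part)
    env$partition <- part
    list(region_lengths = as.list(part$lengths),
         total_bp = summ$total_bp,
         gc_percent = summ$gc_percent,
         coding_fraction_cds = summ$coding_fraction_cds,
         n_features_with_ir_duplicates = summ$n_features_with_ir_duplicates)
  })

  run_stage("classify_gene", "simulate", function() {
    panel <- build_rps16_panel(seed = derive_seed(seed, 3L))
    sv <- survey_gene(panel, "rps16", env$reference,
                      truncation_threshold = config$truncation_threshold)
    env$rps16_survey <- sv
    list(tally = as.list(sv$tally), n_taxa = nrow(sv$table))
  })

  run_stage("detect_inversions", "simulate", function() {
    ref <- env$align_panel[["Tamarindus_indica"]]
    others <- env$align_panel[names(env$align_panel) != ref$id]
    perms <- lapply(env$align_panel, shared_gene_order, reference = ref,
                    min_len = config$min_ir_len)
    blocks <- lcb_decomposition(perms)
    focal <- env$align_panel[["Maackia_fauriei"]]
    hist <- infer_inversion_events(perms[["Maackia_fauriei"]], focal,
                                   min_len = config$min_ir_len)
    list(n_lcb = length(blocks),
         n_events_focal = length(hist$events),
         event_sizes = vapply(hist$events, function(e) e$size, numeric(1)),
         event_left_labels = vapply(hist$events, function(e) e$left_label,
                                    character(1)),
         event_right_labels = vapply(hist$events, function(e) e$right_label,
                                     character(1)),
         history_status = hist$status)
  })

  run_stage("pcr_screen", "simulate", function() {
    res <- run_panel_screen(env$screen_panel, default_assays(),
                            metadata = screen_panel_config(),
                            max_mismatch = config$max_mismatch)
    env$screen_result <- res
    list(calls = res$calls, tallies = res$tallies)
  })

  run_stage("map_character", c("simulate", "pcr_screen"), function() {
    tree <- load_tree(config$tree)
    calls <- env$screen_result$calls
    m <- data.frame(taxon = calls$taxon, stringsAsFactors = FALSE)
    for (inv in setdiff(names(calls), "taxon")) {
      m[[inv]] <- ifelse(calls[[inv]] == "PRESENT", "1",
                         ifelse(calls[[inv]] == "ABSENT", "0", "?"))
    }
    reports <- lapply(setdiff(names(calls), "taxon"), function(inv) {
      r <- assess_synapomorphy(tree, m, inv)
      list(character = r$character, min_changes = r$min_changes,
           n_gains = r$n_gains, single_origin = r$single_origin,
           clade = r$clade, conflicting_taxa = r$conflicting_taxa)
    })
    names(reports) <- setdiff(names(calls), "taxon")
    reports
  })

  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}

#' Command-line entry point
#'
#' A thin dispatcher over the pipeline stages. Subcommands: `simulate`,
#' `partition`, `classify-gene`, `detect-inversions`, `pcr-screen`,
#' `map-character`, `run-all`. Common flags: `--seed`, `--profile`,
#' `--out`; `partition` additionally accepts an input GenBank path and
#' `--min-ir-len`.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, invisibly: 0 ok, 1 validation error, 2 runtime
#'   error.
#' @export
plastome_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  if (length(args) == 0L) {
    message("usage: plastome_cli <simulate|partition|classify-gene|",
            "detect-inversions|pcr-screen|map-character|run-all> [options]")
    return(invisible(1L))
  }
  sub <- args[1L]
  seed <- as.integer(get_opt("--seed", "1"))
  profile <- get_opt("--profile", "mini")
  out <- get_opt("--out")
  status <- tryCatch({
    if (sub == "partition" && length(args) >= 2L && !startsWith(args[2L], "--")) {
      rec <- load_plastome(args[2L], format = "genbank")
      part <- partition_genome(rec,
                               min_len = as.integer(get_opt("--min-ir-len",
                                                            "1000")))
      print(part)
      print(genome_summary(rec, part))
      if (!is.null(out)) {
        jsonlite::write_json(list(lengths = as.list(part$lengths)), out,
                             auto_unbox = TRUE, digits = NA)
      }
      0L
    } else {
      stage_map <- c(simulate = "simulate", partition = "partition",
                     `classify-gene` = "classify_gene",
                     `detect-inversions` = "detect_inversions",
                     `pcr-screen` = "pcr_screen",
                     `map-character` = "map_character")
      stages <- if (sub == "run-all") {
        c("simulate", "partition", "classify_gene", "detect_inversions",
          "pcr_screen", "map_character")
      } else if (sub %in% names(stage_map)) {
        unique(c("simulate", stage_map[[sub]],
                 if (stage_map[[sub]] == "map_character") "pcr_screen"))
      } else {
        message("unknown subcommand: ", sub)
        return(invisible(1L))
      }
      cfg <- run_config(seed = seed, profile = profile, stages = stages)
      rep <- run_pipeline(cfg, out = out, verbose = TRUE)
      failed <- any(vapply(rep$stages, function(s)
        identical(s$status, "failed"), logical(1)))
      if (failed) 2L else 0L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
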