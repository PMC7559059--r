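# End-to-end orchestration: load or simulate PC matrices, curate, build one
# phenogram per category, optionally ingest a reference sequence tree, run
# all pairwise Icong tests, and write the report artifacts.

.runconfig_keys <- c("mode", "matrices", "sim", "reference_tree",
                     "min_presence", "distance", "calibration", "out_dir",
                     "log_level", "seed")

#' Read and validate a pipeline run configuration
#'
#' JSON schema (unknown keys are errors):
#' \describe{
#'   \item{mode}{`"matrices"` or `"simulate"` (exactly one input mode).}
#'   \item{matrices}{for mode `"matrices"`: named object category -> TSV path.}
#'   \item{sim}{for mode `"simulate"`: either `{"preset": name}` or a subset
#'     of [sim_config] fields.}
#'   \item{reference_tree}{optional Newick path of a reference (e.g.
#'     sequence-based) tree sharing the species set.}
#'   \item{min_presence}{rare-family curation threshold (default 3).}
#'   \item{distance}{object with optional `transform` (`"one_minus_r"` or
#'     `"half"`) and `log1p` (logical).}
#'   \item{calibration}{object with optional `mode`, `null_model`, `R`,
#'     `rooted`.}
#'   \item{out_dir}{output directory (created if needed).}
#'   \item{log_level}{`"info"` (default) or `"quiet"`.}
#'   \item{seed}{master seed (default 1).}
#' }
#'
#' @param path path to a JSON configuration file, or a list with the same
#'   structure.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    check_that(file.exists(path), paste0("config file not found: ", path))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  unknown <- setdiff(names(cfg), .runconfig_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  check_that(!is.null(cfg$mode) && cfg$mode %in% c("matrices", "simulate"),
             "config 'mode' must be 'matrices' or 'simulate'")
  check_that(!is.null(cfg$out_dir) && nzchar(cfg$out_dir),
             "config 'out_dir' is required")
  if (cfg$mode == "matrices") {
    check_that(is.list(cfg$matrices) && length(cfg$matrices) >= 1L &&
                 !is.null(names(cfg$matrices)),
               "mode 'matrices' needs a named 'matrices' object")
    for (cat in names(cfg$matrices))
      check_that(file.exists(cfg$matrices[[cat]]),
                 paste0("matrix file for category '", cat, "' not found: ",
                        cfg$matrices[[cat]]))
    if (!is.null(cfg$sim)) stop("'sim' is only valid in simulate mode", call. = FALSE)
  } else {
    if (!is.null(cfg$matrices))
      stop("'matrices' is only valid in matrices mode", call. = FALSE)
  }
  if (!is.null(cfg$reference_tree))
    check_that(file.exists(cfg$reference_tree),
               paste0("reference tree not found: ", cfg$reference_tree))
  cfg$min_presence <- if (is.null(cfg$min_presence)) 3L else as.integer(cfg$min_presence)
  cfg$log_level <- if (is.null(cfg$log_level)) "info" else cfg$log_level
  check_that(cfg$log_level %in% c("info", "quiet"),
             "log_level must be 'info' or 'quiet'")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  dist_keys <- setdiff(names(cfg$distance), c("transform", "log1p"))
  if (length(dist_keys))
    stop("unknown 'distance' keys: ", paste(dist_keys, collapse = ", "), call. = FALSE)
  cal_keys <- setdiff(names(cfg$calibration), c("mode", "null_model", "R", "rooted"))
  if (length(cal_keys))
    stop("unknown 'calibration' keys: ", paste(cal_keys, collapse = ", "), call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full protein-content congruence pipeline
#'
#' Stages: load or simulate the category PC matrices; curate each with the
#' rare-family filter; compute correlation distances and UPGMA phenograms
#' (one Newick file per category); assemble the tree set (reference tree
#' and/or simulated true tree first, then phenograms); calibrate; run the
#' all-vs-all Icong tests; write `report.tsv`, `report.md`,
#' `provenance.json` and `run.log` into the output directory.
#'
#' @param config a path to a JSON run configuration, or a list (see
#'   [read_run_config]).
#' @return invisibly, a list with `trees` (named list of `phylo`), `table`
#'   (the [congruence_table]) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t_start <- Sys.time()
  logmsg <- function(...) {
    line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
    writeLines(line, log_con)
    if (cfg$log_level != "quiet") message(line)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " started")
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logmsg("stage ", name, " done in ",
           format(round(as.numeric(Sys.time() - t0, units = "secs"), 2)), " s")
    out
  }

  # --- input ---------------------------------------------------------------
  inp <- stage("input", {
    if (cfg$mode == "simulate") {
      sc <- cfg$sim
      simcfg <- if (!is.null(sc$preset)) {
        sim_preset(sc$preset, seed = cfg$seed)
      } else {
        sc <- if (is.null(sc)) list() else sc
        sc$seed <- cfg$seed
        do.call(sim_config, sc)
      }
      sim <- simulate_pc_dataset(simcfg)
      logmsg("simulated ", length(sim$matrices), " matrices on ",
             simcfg$n_species, " species (master seed ", cfg$seed, ")")
      list(matrices = sim$matrices, sim = sim)
    } else {
      mats <- lapply(names(cfg$matrices), function(cat)
        read_pc_matrix(cfg$matrices[[cat]], category = cat))
      names(mats) <- names(cfg$matrices)
      list(matrices = mats, sim = NULL)
    }
  })
  sim <- inp$sim
  matrices <- inp$matrices

  # --- curation ------------------------------------------------------------
  matrices <- stage("curation", {
    lapply(matrices, function(m) {
      out <- filter_rare_families(m, cfg$min_presence, quiet = TRUE)
      logmsg("category '", attr(m, "category"), "': ", nrow(m) - nrow(out),
             " rare families removed, ", nrow(out), " kept")
      check_that(nrow(out) >= 2L,
                 paste0("category '", attr(m, "category"),
                        "' has < 2 families after curation"))
      out
    })
  })

  # --- phenograms ----------------------------------------------------------
  transform <- if (is.null(cfg$distance$transform)) "one_minus_r" else cfg$distance$transform
  use_log1p <- isTRUE(cfg$distance$log1p)
  tree_dir <- file.path(cfg$out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  phenograms <- stage("phenograms", {
    lapply(matrices, function(m) {
      cat <- attr(m, "category")
      d <- tryCatch(correlation_distance(m, transform = transform,
                                         log1p = use_log1p),
                    error = function(e)
                      stop("category '", cat, "': ", conditionMessage(e),
                           call. = FALSE))
      phen <- upgma(d)
      write_newick(phen, file.path(tree_dir, paste0(cat, ".nwk")))
      phen
    })
  })

  # --- tree set ------------------------------------------------------------
  trees <- stage("tree_set", {
    ts <- list()
    if (!is.null(cfg$reference_tree)) {
      ref <- read_newick(cfg$reference_tree)[[1L]]
      ts$reference <- ref
    } else if (!is.null(sim)) {
      ts$true_tree <- sim$tree
      write_newick(sim$tree, file.path(tree_dir, "true_tree.nwk"))
    }
    c(ts, phenograms)
  })
  leafset <- trees[[1L]]$tip.label
  for (nmi in names(trees))
    check_that(setequal(trees[[nmi]]$tip.label, leafset),
               paste0("tree '", nmi, "' does not share the common species set"))

  # --- calibration ---------------------------------------------------------
  cal <- stage("calibration", {
    cc <- cfg$calibration
    mode <- if (is.null(cc$mode)) "regression" else cc$mode
    icong_calibration(length(leafset), mode = mode,
                      null_model = if (is.null(cc$null_model)) "yule" else cc$null_model,
                      R = if (is.null(cc$R)) 2000L else cc$R,
                      rooted = if (is.null(cc$rooted)) TRUE else isTRUE(cc$rooted),
                      seed = cfg$seed + 1L)
  })

  # --- congruence ----------------------------------------------------------
  tab <- stage("congruence", congruence_table(trees, cal))

  # --- report --------------------------------------------------------------
  paths <- stage("report", {
    tsv <- file.path(cfg$out_dir, "report.tsv")
    md <- file.path(cfg$out_dir, "report.md")
    write_congruence_report(tab, tsv, md)
    prov <- list(
      package = "icongr",
      version = as.character(utils::packageVersion("icongr")),
      seed = cfg$seed,
      config = unclass(cfg),
      sim_config = if (!is.null(sim)) unclass(sim$config) else NULL,
      calibration = list(mode = cal$mode, n = cal$n, rooted = cal$rooted,
                         expected_mast = cal$expected_mast,
                         null_model = cal$null_model, R = cal$R,
                         seed = cal$seed, a = cal$a, b = cal$b,
                         p_slope = cal$p_slope, p_shift = cal$p_shift))
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    list(report_tsv = tsv, report_md = md,
         provenance = file.path(cfg$out_dir, "provenance.json"),
         log = log_path, tree_dir = tree_dir)
  })
  logmsg("pipeline finished in ",
         format(round(as.numeric(Sys.time() - t_start, units = "secs"), 2)), " s")
  invisible(list(trees = trees, table = tab, paths = paths,
                 simulation = sim))
}
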