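#' Validate an analysis configuration
#'
#' @param config Named list (or path to a JSON file) with elements:
#'   `edge_file`, `region_file` (input tables; see [read_connectome()]),
#'   `stages` (subset of `"metrics"`, `"core"`, `"gn"`, `"control"`,
#'   `"edr"`, `"coarsen"`), `seed`, `out_dir`, and optional stage settings
#'   `sbm_restarts`, `edr_grid`, `edr_reps`, `edr_bin_width`,
#'   `null_replicates`, `removal_step`.
#' @return The normalized config list (invisibly usable by
#'   [run_analysis()]); errors on missing files or unsatisfied stage
#'   dependencies (the EDR and control stages need region coordinates).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(stages = c("metrics", "core", "gn", "control"),
                   seed = 1, out_dir = "connectoscope-out",
                   sbm_restarts = 20, edr_grid = seq(0, 2, 0.05),
                   edr_reps = 100, edr_bin_width = NULL,
                   null_replicates = 0, removal_step = 0)
  config <- utils::modifyList(defaults, config)
  known <- c("metrics", "core", "gn", "control", "edr", "coarsen")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (f in c("edge_file", "region_file")) {
    if (is.null(config[[f]])) stop("config lacks `", f, "`")
    if (!file.exists(config[[f]])) stop("missing input file: ", config[[f]])
  }
  needs_coords <- intersect(config$stages, "edr")
  if (length(needs_coords)) {
    hdr <- names(readr::read_tsv(config$region_file, n_max = 0,
                                 show_col_types = FALSE))
    if (!all(c("x", "y", "z") %in% hdr)) {
      stop("stage(s) ", paste(needs_coords, collapse = ", "),
           " require region coordinates (x, y, z columns)")
    }
  }
  config
}

#' Run the full connectome analysis battery
#'
#' Executes the requested stages in dependency order on an input
#' connectome and writes a report bundle: degree and betweenness ranking
#' CSVs, a reciprocity/density summary, a core-periphery JSON plus
#' per-node core probabilities CSV, the Girvan-Newman dendrogram as
#' Newick with a depth CSV, a controllability JSON (drivers, optional
#' degree-preserving null model) with an optional removal-curve CSV, an
#' EDR fit JSON with deviation-curve CSV, and a run log recording seeds,
#' package version and a config digest. Reruns with the same config and
#' seed reproduce the numeric tables exactly.
#'
#' @param config See [validate_config()].
#' @return Tibble manifest of written artifacts (columns `stage`,
#'   `file`). If a stage fails, the error is recorded in
#'   `error_manifest.json` and remaining stages still run.
#' @export
run_analysis <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  C <- read_connectome(config$edge_file, config$region_file)
  set.seed(config$seed)
  stage_seeds <- stats::setNames(
    as.list(sample.int(.Machine$integer.max, 6)),
    c("metrics", "core", "gn", "control", "edr", "coarsen"))
  manifest <- list()
  errors <- list()
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(stage = stage,
                                                        file = file)
  }
  out <- function(...) file.path(config$out_dir, paste0(...))
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible())
    tryCatch(fn(), error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
    })
  }

  run_stage("metrics", function() {
    readr::write_csv(graph_summary(C), out("summary.csv"))
    readr::write_csv(dplyr::arrange(degree_table(C), .data$rank_in),
                     out("degrees.csv"))
    bt <- betweenness_table(C)
    readr::write_csv(dplyr::arrange(bt$nodes, .data$rank),
                     out("node_betweenness.csv"))
    readr::write_csv(dplyr::arrange(bt$edges, dplyr::desc(.data$bc)),
                     out("edge_betweenness.csv"))
    emit("metrics", out("summary.csv")); emit("metrics", out("degrees.csv"))
    emit("metrics", out("node_betweenness.csv"))
    emit("metrics", out("edge_betweenness.csv"))
  })

  fit <- NULL
  run_stage("core", function() {
    fit <<- fit_core_periphery(C, n_restarts = config$sbm_restarts,
                               seed = stage_seeds$core)
    readr::write_csv(tidy(fit), out("core_membership.csv"))
    jsonlite::write_json(
      list(glance = glance(fit), affinity = fit$affinity,
           block_densities = fit$block_densities),
      out("core_periphery.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
    emit("core", out("core_membership.csv"))
    emit("core", out("core_periphery.json"))
  })

  run_stage("gn", function() {
    d <- girvan_newman(C)
    gn_newick(d, out("dendrogram.nwk"))
    readr::write_csv(d$depth, out("onion_depth.csv"))
    emit("gn", out("dendrogram.nwk")); emit("gn", out("onion_depth.csv"))
    if (!is.null(fit)) {
      prof <- onion_profile(d, fit)
      jsonlite::write_json(list(association = prof$association,
                                degenerate = prof$degenerate),
                           out("onion_profile.json"), auto_unbox = TRUE,
                           digits = NA)
      emit("gn", out("onion_profile.json"))
    }
  })

  run_stage("control", function() {
    mr <- find_driver_nodes(C)
    ctl <- list(n_drivers = mr$n_drivers, driver_ids = mr$driver_nodes,
                perfect_matching = mr$perfect_matching)
    if (config$null_replicates > 0) {
      null <- driver_null_distribution(C, n_rep = config$null_replicates,
                                       seed = stage_seeds$control)
      ctl$null_mean <- mean(null$n_drivers)
      ctl$null_sd <- stats::sd(null$n_drivers)
    }
    jsonlite::write_json(ctl, out("controllability.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("control", out("controllability.json"))
    if (config$removal_step > 0) {
      D <- euclidean_distances(C)
      curve <- edge_removal_curve(C, D, step = config$removal_step)
      readr::write_csv(curve, out("removal_curve.csv"))
      emit("control", out("removal_curve.csv"))
    }
  })

  run_stage("edr", function() {
    D <- euclidean_distances(C)
    fit_edr <- match_lambda(C, D, grid = config$edr_grid,
                            n_rep = config$edr_reps,
                            seed = stage_seeds$edr,
                            bin_width = config$edr_bin_width)
    readr::write_csv(tidy(fit_edr), out("edr_deviations.csv"))
    jsonlite::write_json(glance(fit_edr), out("edr_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("edr", out("edr_deviations.csv")); emit("edr", out("edr_fit.json"))
  })

  run_stage("coarsen", function() {
    q <- coarsen(C)
    export_graph(q, out("quotient.graphml"), "graphml")
    readr::write_csv(attr(q, "plan")$intra_counts,
                     out("quotient_internal_links.csv"))
    emit("coarsen", out("quotient.graphml"))
    emit("coarsen", out("quotient_internal_links.csv"))
  })

  cfg_for_log <- config
  cfg_for_log$out_dir <- NULL
  log <- list(
    package = "connectoscope",
    version = as.character(utils::packageVersion("connectoscope")),
    seed = config$seed, stage_seeds = stage_seeds,
    config_digest = config_digest(cfg_for_log),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE)
  if (length(errors)) {
    jsonlite::write_json(errors, out("error_manifest.json"),
                         auto_unbox = TRUE)
  }
  dplyr::bind_rows(manifest)
}

# small stable polynomial digest of the serialized config (no extra deps)
config_digest <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
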