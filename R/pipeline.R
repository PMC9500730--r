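# Pipeline orchestration: a YAML/JSON config drives simulate -> library ->
# screen/annotate -> validate, writing CSV/JSON results plus a run report
# sufficient to re-run identically.

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  config
}

.params_from_config <- function(cfg) {
  p <- cfg$params
  if (is.null(p)) return(filtration_params())
  known <- names(formals(filtration_params))
  bad <- setdiff(names(p), known)
  if (length(bad))
    stop("unknown filtration parameter(s) in config: ",
         paste(bad, collapse = ", "))
  do.call(filtration_params, p)
}

.file_digest <- function(path) as.character(tools::md5sum(path))

#' Run the full annotation pipeline from a config
#'
#' The config (YAML or JSON file, or an equivalent list) has blocks:
#' \describe{
#'   \item{seed}{integer seed for the synthetic stages.}
#'   \item{library}{either \code{path} (a DIA library CSV/JSON written by
#'     \code{\link{write_dia_library}}) or \code{synthetic} with
#'     \code{n_compounds} / \code{fragments_per_compound}.}
#'   \item{simulate}{either \code{sample} + \code{blank} mzML paths, or
#'     \code{n_spike} (plus optional \code{\link{make_ground_truth}}
#'     arguments) to generate runs from the library.}
#'   \item{params}{\code{\link{filtration_params}} fields, verbatim.}
#'   \item{validate}{optional \code{inclusion} / \code{exclusion} CSV paths
#'     (column compound_id) for confusion statistics.}
#' }
#' Writes identifications.csv, fragments.csv, candidates.csv,
#' run-report.json (and confusion.json when validating) into \code{out}.
#'
#' @param config path to a YAML/JSON config, or a list.
#' @param out output directory (created if missing).
#' @return invisibly, a list with the identifications, tables, metrics and
#'   the report.
#' @export
run_pipeline <- function(config, out = ".") {
  cfg <- .read_config(config)
  for (field in c("library"))
    if (is.null(cfg[[field]]))
      stop("config error: missing required field '", field, "'")
  params <- .params_from_config(cfg)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  if (params$width_shift_literal)
    note("width-shift gate running in literal (unscaled) mode")

  inputs <- list()
  if (!is.null(cfg$library$path)) {
    entries <- read_dia_library(cfg$library$path)
    inputs$library <- .file_digest(cfg$library$path)
  } else if (!is.null(cfg$library$synthetic)) {
    syn <- cfg$library$synthetic
    lib <- make_synthetic_library(
      n_compounds = syn$n_compounds,
      fragments_per_compound = if (is.null(syn$fragments_per_compound))
        c(4, 9) else syn$fragments_per_compound,
      seed = seed)
    entries <- lib$entries
  } else stop("config error: library needs 'path' or 'synthetic'")

  truth <- NULL
  if (!is.null(cfg$simulate$sample)) {
    sample <- read_ms_run(cfg$simulate$sample)
    blank <- if (!is.null(cfg$simulate$blank))
      read_ms_run(cfg$simulate$blank) else NULL
    inputs$sample <- .file_digest(cfg$simulate$sample)
    if (!is.null(cfg$simulate$blank))
      inputs$blank <- .file_digest(cfg$simulate$blank)
  } else if (!is.null(cfg$simulate$n_spike)) {
    gt_args <- cfg$simulate
    gt_args$entries <- entries
    gt_args$seed <- seed
    gt_args <- gt_args[names(gt_args) %in%
                         names(formals(make_ground_truth))]
    truth <- do.call(make_ground_truth, gt_args)
    runs <- simulate_run(truth)
    sample <- runs$sample; blank <- runs$blank
    write_ground_truth(truth, file.path(out, "truth.json"))
  } else stop("config error: simulate needs 'sample' or 'n_spike'")

  ids <- annotate_run(sample, blank, entries, params)
  id_tab <- identifications_table(ids)
  frag_tab <- fragments_table(ids)
  cand_tab <- as.data.frame(attr(ids, "candidates"))
  utils::write.csv(id_tab, file.path(out, "identifications.csv"),
                   row.names = FALSE)
  utils::write.csv(frag_tab, file.path(out, "fragments.csv"),
                   row.names = FALSE)
  utils::write.csv(cand_tab, file.path(out, "candidates.csv"),
                   row.names = FALSE)

  metrics <- NULL
  if (!is.null(cfg$validate)) {
    inc <- utils::read.csv(cfg$validate$inclusion)$compound_id
    exc <- utils::read.csv(cfg$validate$exclusion)$compound_id
    metrics <- evaluate_inclusion_exclusion(id_tab$compound_id, inc, exc)
    jsonlite::write_json(unclass(metrics), file.path(out, "confusion.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  report <- list(
    tool = paste0("swathAnnotator ",
                  as.character(utils::packageVersion("swathAnnotator"))),
    seed = seed, params = params[setdiff(names(params), "score_weights")],
    score_weights = as.list(params$score_weights),
    input_digests = inputs,
    counts = list(library_entries = length(entries),
                  candidates = nrow(cand_tab),
                  identifications = nrow(id_tab)),
    results = c("identifications.csv", "fragments.csv", "candidates.csv",
                if (!is.null(truth)) "truth.json",
                if (!is.null(metrics)) "confusion.json"),
    warnings = warnings_log)
  jsonlite::write_json(report, file.path(out, "run-report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(identifications = ids, identifications_table = id_tab,
                 fragments_table = frag_tab, candidates = cand_tab,
                 metrics = metrics, truth = truth, report = report))
}
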