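## Workflow orchestration: three named workflows (differential, assay,
## simulate) behind plain functions plus a CLI front end. Logs go to stderr,
## result tables to the output directory; every threshold that shaped a run is
## recorded in run_metadata.json.

log_msg <- function(level, ..., verbosity = getOption("axonedit.verbosity", "info")) {
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (ranks[[level]] >= ranks[[verbosity]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

write_run_metadata <- function(out_dir, workflow, params) {
  meta <- c(list(workflow = workflow,
                 package_version = as.character(utils::packageVersion("axonedit")),
                 r_version = R.version.string,
                 timestamp = format(Sys.time(), tz = "UTC")), params)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the differential editing workflow
#'
#' Reads (or accepts in memory) a count table and a compartment design, applies
#' the coverage filter, the two one-tailed t-tests with per-tail BH correction,
#' and writes the per-site result table, per-sample summaries and the global
#' summary to `out_dir`.
#'
#' @param counts a `site_base_counts` data.frame or a path to a count TSV.
#' @param design a [compartment_design()].
#' @param out_dir output directory (created if needed).
#' @param thresholds a [threshold_config()].
#' @param paired use the paired t-test variant.
#' @param histogram_breaks delta histogram bin edges.
#' @return Invisibly, a list with `results` (differential_result),
#'   `summary` (differential_summary) and `sample_summaries`.
#' @export
run_differential <- function(counts, design, out_dir,
                             thresholds = threshold_config(), paired = FALSE,
                             histogram_breaks = seq(-1, 1, by = 0.05)) {
  if (is.character(counts)) counts <- read_count_table(counts)
  counts <- validate_counts(counts)
  missing <- setdiff(c(design$a_samples, design$b_samples),
                     unique(counts$sample_id))
  if (length(missing))
    abort_validation("design samples absent from count table: ",
                     paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("info", "differential workflow: ", length(unique(
    site_key(counts$transcript_id, counts$position))), " sites, ",
    length(design$a_samples), "+", length(design$b_samples), " samples")
  res <- differential_editing(counts, design, thresholds, paired = paired)
  summ <- summarize_differential(res, histogram_breaks)
  retained <- res[c("transcript_id", "position")]
  samp <- sample_summaries(counts, retained)
  write_results_table(res, file.path(out_dir, "differential_results.tsv"))
  write_results_table(samp, file.path(out_dir, "sample_summaries.tsv"))
  write_results_table(summ$delta_histogram, file.path(out_dir, "delta_histogram.tsv"))
  jsonlite::write_json(summ[setdiff(names(summ), "delta_histogram")],
                       file.path(out_dir, "differential_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_metadata(out_dir, "differential",
                     list(thresholds = unclass(thresholds), paired = paired,
                          test = if (paired) "paired t" else "Welch t",
                          a_samples = design$a_samples,
                          b_samples = design$b_samples))
  log_msg("info", sprintf("calls: %d A_higher / %d B_higher / %d no_change",
                          summ$n_a_higher_significant, summ$n_b_higher_significant,
                          summ$n_no_change))
  invisible(list(results = res, summary = summ, sample_summaries = samp))
}

#' Run the in vitro assay detection workflow
#'
#' Takes per-replicate experimental and control count tables over the same
#' amplicon adenosines, calls editing events per replicate against the
#' binomial error null, averages replicates, and writes the detection table
#' plus the merged known-site report.
#'
#' @param experimental,control lists of data.frames (or paths to TSVs) with
#'   columns `position`, `a_count`, `g_count` (`ag_coverage` is derived when
#'   absent).
#' @param sites an `editing_sites` table (or path) carrying in vivo levels.
#' @param out_dir output directory.
#' @param thresholds a [threshold_config()].
#' @param min_replicates_detected see [summarize_replicates()].
#' @param fold_cutoff see [table1_report()].
#' @return Invisibly, a list with `detection` and `report` data.frames.
#' @export
run_assay <- function(experimental, control, sites, out_dir,
                      thresholds = threshold_config(),
                      min_replicates_detected = 3, fold_cutoff = 2) {
  load_rep <- function(x) {
    if (is.character(x)) x <- read_results_table(x)
    if (!all(c("position", "a_count", "g_count") %in% names(x)))
      abort_parse("replicate tables need columns position, a_count, g_count")
    if (is.null(x$ag_coverage)) x$ag_coverage <- x$a_count + x$g_count
    x
  }
  experimental <- lapply(experimental, load_rep)
  control <- lapply(control, load_rep)
  if (is.character(sites)) sites <- read_site_table(sites)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("info", "assay workflow: ", length(experimental), " experimental + ",
          length(control), " control replicates, ",
          nrow(experimental[[1]]), " adenosines")
  det <- summarize_replicates(experimental, control, thresholds,
                              min_replicates_detected)
  rep <- table1_report(det, sites, fold_cutoff)
  write_results_table(det, file.path(out_dir, "detection_results.tsv"))
  write_results_table(rep, file.path(out_dir, "site_report.tsv"))
  write_run_metadata(out_dir, "assay",
                     list(thresholds = unclass(thresholds),
                          min_replicates_detected = min_replicates_detected,
                          fold_cutoff = fold_cutoff,
                          n_experimental = length(experimental),
                          n_control = length(control)))
  invisible(list(detection = det, report = rep))
}

#' Run the simulation workflow
#'
#' Generates a synthetic two-compartment dataset and/or an amplicon assay
#' dataset and writes them in the TSV formats the other two workflows read.
#'
#' @param compartment_spec a [compartment_sim_spec()], or `NULL` to skip.
#' @param assay_spec an [assay_sim_spec()], or `NULL` to skip.
#' @param out_dir output directory.
#' @return Invisibly, a list with the generated objects.
#' @export
run_simulate <- function(compartment_spec = NULL, assay_spec = NULL, out_dir) {
  if (is.null(compartment_spec) && is.null(assay_spec))
    abort_validation("provide at least one simulation spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (!is.null(compartment_spec)) {
    sim <- simulate_compartment_counts(compartment_spec)
    write_results_table(sim$sites, file.path(out_dir, "sites.tsv"))
    write_results_table(sim$counts, file.path(out_dir, "counts.tsv"))
    write_results_table(sim$truth, file.path(out_dir, "truth_compartment.tsv"))
    write_results_table(
      data.frame(sample_id = c(sim$design$a_samples, sim$design$b_samples),
                 compartment = rep(c("A", "B"), c(length(sim$design$a_samples),
                                                  length(sim$design$b_samples))),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "design.tsv"))
    out$compartment <- sim
    log_msg("info", "wrote compartment simulation: ", compartment_spec$n_sites,
            " sites x ", 2 * compartment_spec$n_pairs, " samples")
  }
  if (!is.null(assay_spec)) {
    sim <- simulate_assay_counts(assay_spec)
    for (i in seq_along(sim$experimental))
      write_results_table(sim$experimental[[i]],
                          file.path(out_dir, sprintf("assay_exp_%d.tsv", i)))
    for (i in seq_along(sim$control))
      write_results_table(sim$control[[i]],
                          file.path(out_dir, sprintf("assay_ctl_%d.tsv", i)))
    write_results_table(sim$truth, file.path(out_dir, "truth_assay.tsv"))
    out$assay <- sim
    log_msg("info", "wrote assay simulation: ", assay_spec$n_adenosines,
            " adenosines x ", assay_spec$n_experimental, "+",
            assay_spec$n_control, " replicates")
  }
  specs <- list()
  if (!is.null(compartment_spec)) specs$compartment_spec <- unclass(compartment_spec)
  if (!is.null(assay_spec)) specs$assay_spec <- unclass(assay_spec)
  write_run_metadata(out_dir, "simulate", specs)
  invisible(out)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) abort_parse(path, ": malformed config line: ", lines[which(bad)[1]])
  setNames(lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
           vapply(kv, function(x) trimws(x[1]), character(1)))
}

#' Command-line entry point
#'
#' Dispatches `axonedit differential|assay|simulate` with the documented
#' flags; used by the `exec/axonedit` script and callable directly with an
#' argument vector. A flat `key=value` config file (`--config`) supplies
#' defaults that explicit flags override. Exit status: 0 on success, 2 on
#' validation/parse errors, 1 on any other error.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return The exit status, invisibly.
#' @export
axonedit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    axonedit_cli_inner(args)
    0L
  },
  axonedit_parse_error = function(e) { message("[ERROR] ", conditionMessage(e)); 2L },
  axonedit_validation_error = function(e) { message("[ERROR] ", conditionMessage(e)); 2L },
  error = function(e) { message("[ERROR] ", conditionMessage(e)); 1L })
  invisible(status)
}

axonedit_cli_inner <- function(args) {
  usage <- "usage: axonedit <differential|assay|simulate> [options]"
  if (!length(args)) abort_parse(usage)
  workflow <- args[1]
  rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--counts", type = "character", help = "count table TSV"),
    optparse::make_option("--sites", type = "character", help = "known-site TSV"),
    optparse::make_option("--a-samples", type = "character",
                          help = "comma-separated compartment A sample ids"),
    optparse::make_option("--b-samples", type = "character",
                          help = "comma-separated compartment B sample ids"),
    optparse::make_option("--experimental", type = "character",
                          help = "comma-separated experimental replicate TSVs"),
    optparse::make_option("--control", type = "character",
                          help = "comma-separated control replicate TSVs"),
    optparse::make_option("--out", type = "character", help = "output directory"),
    optparse::make_option("--config", type = "character",
                          help = "flat key=value config file"),
    optparse::make_option("--min-coverage", type = "integer", default = NA),
    optparse::make_option("--fdr-level", type = "double", default = NA),
    optparse::make_option("--p0", type = "double", default = NA),
    optparse::make_option("--adjusted-p", type = "double", default = NA),
    optparse::make_option("--min-replicates-detected", type = "integer", default = NA),
    optparse::make_option("--fold-cutoff", type = "double", default = NA),
    optparse::make_option("--paired", action = "store_true", default = FALSE),
    optparse::make_option("--n-sites", type = "integer", default = NA),
    optparse::make_option("--n-pairs", type = "integer", default = NA),
    optparse::make_option("--n-adenosines", type = "integer", default = NA),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--log-level", type = "character", default = "info"))
  parser <- optparse::OptionParser(usage = usage, option_list = opt_list)
  opt <- optparse::parse_args(parser, args = rest)
  cfg <- if (!is.null(opt$config)) read_flat_config(opt$config) else list()
  pick <- function(flag, key, cast = identity, default = NULL) {
    v <- opt[[flag]]
    if (!is.null(v) && !(length(v) == 1 && is.na(v))) return(v)
    if (!is.null(cfg[[key]])) return(cast(cfg[[key]]))
    default
  }
  old <- options(axonedit.verbosity = pick("log-level", "log_level",
                                           default = "info"))
  on.exit(options(old), add = TRUE)
  thresholds <- threshold_config(
    min_coverage = pick("min-coverage", "min_coverage", as.integer, 20L),
    fdr_level = pick("fdr-level", "fdr_level", as.numeric, 0.1),
    error_rate_p0 = pick("p0", "error_rate_p0", as.numeric, 0.001),
    detection_adjusted_p = pick("adjusted-p", "detection_adjusted_p",
                                as.numeric, 0.001))
  out_dir <- pick("out", "out")
  if (is.null(out_dir)) abort_parse("--out is required")
  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  if (workflow == "differential") {
    a <- pick("a-samples", "a_samples"); b <- pick("b-samples", "b_samples")
    cpath <- pick("counts", "counts")
    if (is.null(cpath) || is.null(a) || is.null(b))
      abort_parse("differential needs --counts, --a-samples, --b-samples")
    design <- compartment_design(split_csv(a), split_csv(b))
    run_differential(cpath, design, out_dir, thresholds, paired = opt$paired)
  } else if (workflow == "assay") {
    ex <- pick("experimental", "experimental"); ct <- pick("control", "control")
    spath <- pick("sites", "sites")
    if (is.null(ex) || is.null(ct) || is.null(spath))
      abort_parse("assay needs --experimental, --control, --sites")
    run_assay(as.list(split_csv(ex)), as.list(split_csv(ct)), spath, out_dir,
              thresholds,
              min_replicates_detected =
                pick("min-replicates-detected", "min_replicates_detected",
                     as.integer, 3L),
              fold_cutoff = pick("fold-cutoff", "fold_cutoff", as.numeric, 2))
  } else if (workflow == "simulate") {
    spec <- compartment_sim_spec(
      n_sites = pick("n-sites", "n_sites", as.integer, 1000L),
      n_pairs = pick("n-pairs", "n_pairs", as.integer, 4L),
      seed = opt$seed)
    n_aden <- pick("n-adenosines", "n_adenosines", as.integer, 126L)
    ## plant two Table-1-scale editing levels (0.78% and 10.33%) at the first
    ## and last quartile adenosines of the amplicon
    aspec <- assay_sim_spec(
      n_adenosines = n_aden,
      edited_positions = setNames(c(0.0078, 0.1033),
                                  c(max(1, n_aden %/% 4), max(2, 3 * n_aden %/% 4))),
      seed = opt$seed)
    run_simulate(spec, aspec, out_dir)
  } else {
    abort_parse("unknown workflow '", workflow, "'; ", usage)
  }
  invisible(NULL)
}
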