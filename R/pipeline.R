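#' Validate a pipeline configuration
#'
#' A configuration is a named list (usually read from YAML) with a mandatory
#' integer `seed`, either a `simulate` block or an `inputs` block naming the
#' input files, and optional `linkage`, `count`, `stats`, `splice`,
#' `metagene` blocks overriding stage parameters. Unknown top-level fields
#' are rejected with a field-level message.
#'
#' @param config list or YAML path.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("seed", "simulate", "inputs", "linkage", "count", "stats",
             "splice", "metagene")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  if (is.null(config$seed)) stop("config field 'seed' is required")
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop("config field 'seed' must be a single integer")
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config needs either a 'simulate' block or an 'inputs' block")
  }
  if (!is.null(config$inputs)) {
    need <- c("library", "linkage_reads", "screen_reads")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) {
      stop("config field 'inputs' is missing: ", paste(miss, collapse = ", "))
    }
    for (f in need) {
      if (!file.exists(config$inputs[[f]])) {
        stop("inputs$", f, ": file not found: ", config$inputs[[f]])
      }
    }
  }
  config
}

# md5 of the canonical JSON serialization of an R object
object_digest <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the screen pipeline from a configuration
#'
#' Stages run in dependency order: simulate (or load inputs) -> linkage ->
#' count -> stats. Each stage's record accounting goes into a run manifest
#' (`manifest.json`) whose discard and pass counts sum exactly to the
#' stage's input count; reruns with the same config and seed produce
#' identical outputs and manifest digests. Failures abort with a
#' stage-tagged error.
#'
#' @param config list or YAML path, see [validate_config()]. Stage blocks:
#' \describe{
#'   \item{simulate}{`n_genes`, `frac_essential`, ... (any [sim_config()]
#'     field except `seed`), plus `modality` (`"fitness"`, `"polysome"`,
#'     `"isoform"`, `"dual_barcode"`) and modality arguments such as `days`
#'     or `n_affected`.}
#'   \item{linkage}{`min_reads` (5), `edit_threshold` (2).}
#'   \item{count}{`min_umis` (20).}
#'   \item{stats}{`numerator_sample`, `denominator_sample` (required unless
#'     modality is `dual_barcode`), `numerator_reporter`,
#'     `denominator_reporter`, `floor` (20), `n_perm` (1000), `alpha_frac`
#'     (0.25), `fdr_threshold` (0.05), `min_good` (3).}
#' }
#' @param out_dir output directory; created if missing.
#' @return invisibly, a list with the `manifest`, output file `paths`, and
#'   in-memory `results` (linkage, counts, ratios, gene results).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(
    tool = "relic",
    version = as.character(utils::packageVersion("relic")),
    seed = seed,
    config_hash = object_digest(config),
    input_digests = list(),
    stages = list()
  )
  paths <- list()

  # --- stage: simulate or load -------------------------------------------
  reporters <- c(globin = "ACGTAC")
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    modality <- sim_args$modality %||% "fitness"
    mod_args <- sim_args[names(sim_args) %in% c("days", "n_affected",
                                                "stabilization")]
    sim_args <- sim_args[!names(sim_args) %in% c("modality", "days",
                                                 "n_affected", "stabilization")]
    cfg <- tryCatch(
      do.call(sim_config, c(list(seed = seed), sim_args)),
      error = function(e) stop("[simulate] ", conditionMessage(e), call. = FALSE)
    )
    sim_lib <- simulate_library(cfg)
    screen <- switch(modality,
      fitness = do.call(simulate_fitness_screen, c(list(sim_lib), mod_args)),
      polysome = do.call(simulate_polysome_screen, c(list(sim_lib), mod_args)),
      isoform = do.call(simulate_isoform_screen, c(list(sim_lib), mod_args)),
      dual_barcode = do.call(simulate_dual_barcode_screen, c(list(sim_lib), mod_args)),
      stop("[simulate] unknown modality: ", modality)
    )
    reporters <- screen$reporters
    linkage_reads <- simulate_linkage_reads(sim_lib)
    screen_reads <- screen$reads
    library_tbl <- sim_lib$library
    paths$library <- file.path(out_dir, "library.csv")
    data.table::fwrite(library_tbl, paths$library)
    manifest$stages$simulate <- list(
      modality = modality,
      n_sgrnas = nrow(library_tbl),
      n_true_barcodes = nrow(sim_lib$linkage_truth),
      linkage_reads = nrow(linkage_reads),
      screen_reads = nrow(screen_reads)
    )
  } else {
    library_tbl <- read_sgrna_library(config$inputs$library)
    linkage_reads <- as.data.frame(
      data.table::fread(config$inputs$linkage_reads, colClasses = "character"))
    screen_reads <- as.data.frame(
      data.table::fread(config$inputs$screen_reads, colClasses = "character"))
    if (!is.null(config$inputs$reporters)) {
      reporters <- unlist(config$inputs$reporters)
    }
    manifest$input_digests <- as.list(tools::md5sum(unlist(
      config$inputs[c("library", "linkage_reads", "screen_reads")])))
    screen <- NULL
  }

  # --- stage: linkage -----------------------------------------------------
  lk <- config$linkage %||% list()
  linkage <- tryCatch(
    build_linkage_table(linkage_reads, library_tbl,
                        min_reads = lk$min_reads %||% 5,
                        edit_threshold = lk$edit_threshold %||% 2),
    error = function(e) stop("[linkage] ", conditionMessage(e), call. = FALSE)
  )
  paths$linkage <- file.path(out_dir, "linkage.csv")
  write_linkage(linkage, paths$linkage)
  manifest$stages$linkage <- attr(linkage, "log")

  # --- stage: count -------------------------------------------------------
  ct <- config$count %||% list()
  parsed <- tryCatch({
    if (!"seq" %in% names(screen_reads)) {
      stop("screen reads need a 'seq' column (barcode+UMI+reporter layout)")
    }
    parse_screen_reads(screen_reads, reporter_whitelist = reporters)
  }, error = function(e) stop("[count] ", conditionMessage(e), call. = FALSE))
  counts <- tryCatch(
    apply_umi_floor(count_umis(parsed, linkage), min_umis = ct$min_umis %||% 20),
    error = function(e) stop("[count] ", conditionMessage(e), call. = FALSE)
  )
  paths$counts <- file.path(out_dir, "counts.csv")
  write_counts(counts, paths$counts)
  manifest$stages$parse <- attr(parsed, "log")
  manifest$stages$count <- c(attr(counts, "log"),
                             list(records_below_floor = sum(!counts$pass_floor)))

  # --- stage: stats -------------------------------------------------------
  results <- NULL
  ratios <- NULL
  if (!is.null(config$stats)) {
    st <- config$stats
    ratios <- tryCatch({
      if (identical(st$modality, "dual_barcode")) {
        dual_barcode_stats(counts, st$sample %||% "pool",
                           st$reporter %||% names(reporters)[1L],
                           st$control %||% names(reporters)[2L],
                           floor = st$floor %||% 20)
      } else {
        if (is.null(st$numerator_sample) || is.null(st$denominator_sample)) {
          stop("stats block needs numerator_sample and denominator_sample")
        }
        cn <- contrast(st$name %||% "contrast",
                       st$numerator_sample, st$denominator_sample,
                       st$numerator_reporter, st$denominator_reporter,
                       st$modality %||% "fitness_rna")
        log2_ratio_centered(counts, cn, floor = st$floor %||% 20)
      }
    }, error = function(e) stop("[stats] ", conditionMessage(e), call. = FALSE))
    results <- tryCatch(
      rra_gene_test(ratios,
                    n_perm = st$n_perm %||% 1000,
                    alpha_frac = st$alpha_frac %||% 0.25,
                    seed = seed + 1000L,
                    fdr_threshold = st$fdr_threshold %||% 0.05,
                    min_good = st$min_good %||% 3),
      error = function(e) stop("[stats] ", conditionMessage(e), call. = FALSE)
    )
    paths$ratios <- file.path(out_dir, "ratios.csv")
    data.table::fwrite(as.data.frame(ratios), paths$ratios)
    paths$gene_results <- file.path(out_dir, "gene_results.csv")
    write_gene_results(results, paths$gene_results)
    manifest$stages$stats <- list(
      units = nrow(ratios), genes = nrow(results), hits = sum(results$is_hit)
    )
  }

  out_files <- unlist(paths)
  manifest$output_digests <- as.list(
    setNames(unname(tools::md5sum(out_files)), basename(out_files)))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    manifest = manifest, paths = paths,
    results = list(linkage = linkage, counts = counts, ratios = ratios,
                   gene_results = results,
                   truth = if (!is.null(config$simulate)) screen$truth)
  ))
}
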