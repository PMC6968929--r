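#' Read a lineage table from CSV/TSV
#'
#' Reads a delimited text file into a validated [lineage_table()]. The file
#' must have a header row with the required columns `lineage_id, method,
#' area, age, l23, l4, l5, l6` (optional MADM subclone and subtype columns
#' are picked up when present). Counts must be non-negative integers; blank
#' cells are errors, never silently interpreted as zero, because zero counts
#' are meaningful to the censoring rules downstream.
#'
#' @param path file path.
#' @param dialect `"csv"` (comma, default) or `"tsv"` (tab). Guessed from
#'   the file extension when omitted.
#' @param col_map optional named character vector mapping canonical column
#'   names to the names actually used in the file, e.g.
#'   `c(l23 = "layer2_3", lineage_id = "clone")`.
#' @return a [lineage_table()].
#' @export
read_lineage_table <- function(path, dialect = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) "tsv" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "tsv"))
  sep <- if (dialect == "csv") "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = NA,
                         na.strings = c("NA", ""), check.names = FALSE,
                         quote = "\"", comment.char = "", encoding = "UTF-8")
  if (!is.null(col_map)) {
    stopifnot(!is.null(names(col_map)))
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(x)) {
        stop("column-mapping source '", src, "' not found in ", path,
             call. = FALSE)
      }
      names(x)[names(x) == src] <- canon
    }
  }
  lineage_table(x)
}

#' @rdname read_lineage_table
#' @param x lineage table to write.
#' @export
write_lineage_table <- function(x, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) "tsv" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "tsv"))
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration
#'
#' Run configurations are YAML (or JSON) key/value files driving
#' [run_pipeline()]. A `seed` is mandatory; unknown top-level keys are
#' rejected so that typos never silently change an analysis.
#'
#' Recognised keys: `seed`, `input` (lineage-table path), `output`
#' (directory), `stages` (character vector over classify, summarize,
#' permute, infer, simulate, fit, compare, synth), `filters`
#' (`min_size`, `max_size`; the neurogenic 3-12 window is applied by
#' default), `area` (restrict to one cortical area),
#' `permute` (`repeats`), `infer` (`draws`, `burn_in`, `thinning`, `alpha`,
#' `beta_a`, `beta_b`, `n_max`, `n_aux`), `simulate` (simulator spec as
#' nested lists mirroring [sim_model_spec()]), `fit` (fitting controls).
#'
#' @param path YAML/JSON file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of configuration values.
#' @export
as_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  allowed <- c("seed", "input", "output", "stages", "filters", "area",
               "permute", "infer", "simulate", "fit")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    stop("configuration must provide an integer 'seed'", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

#' Write and read structured result reports
#'
#' Reports are self-describing JSON documents: a `meta` block (package
#' version, seed and config echo when supplied) plus arbitrary
#' named results (scalars, vectors, tables). Plain text keeps reports
#' diffable and round-trippable.
#'
#' @param report named list of results.
#' @param path output file path.
#' @param seed,config optional provenance recorded in the `meta` block.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the report list with the `meta` block attached as attribute
#'   `meta`.
#' @export
write_report <- function(report, path, seed = NULL, config = NULL) {
  stopifnot(is.list(report))
  ## named atomic vectors become JSON objects (not bare arrays) so that
  ## their names survive the round trip
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  report <- namedify(report)
  doc <- list(
    meta = list(
      package = "pclineage",
      version = as.character(utils::packageVersion("pclineage")),
      seed = seed,
      config = config),
    results = report)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- doc$results
  if (is.null(out)) out <- list()
  ## inverse of the writer's named-vector encoding: collapse named lists
  ## of same-typed scalars back into named vectors
  simplify <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, simplify)
    scalar <- vapply(x, function(e)
      is.atomic(e) && length(e) == 1L && !is.list(e), logical(1L))
    if (length(x) > 0L && all(scalar) && !is.null(names(x)) &&
        length(unique(vapply(x, function(e) class(e)[1L],
                             character(1L)))) == 1L) {
      unlist(x)
    } else x
  }
  out <- simplify(out)
  attr(out, "meta") <- doc$meta
  out
}
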