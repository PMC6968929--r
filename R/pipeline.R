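#' Run a reproducible analysis pipeline
#'
#' Executes the requested stages in a fixed order — `synth`, `classify`,
#' `summarize`, `permute`, `infer`, `simulate`, `fit`, `compare` — wiring
#' all randomness off a single master seed (per-stage seeds are derived
#' deterministically from the stage name via [stage_seed()]'s scheme).
#' Every run writes its result files under `config$output` and emits
#' exactly one manifest recording the config echo, master seed, package
#' version, per-stage output digests (MD5) and wall-clock timestamps. A
#' stage failure aborts the run with a manifest recording the failing
#' stage.
#'
#' Stage behaviour: `synth` generates the two-population preset dataset
#' ([synthetic_preset()]) and writes it as the input table for later
#' stages when no `input` is configured; `classify` writes the input
#' table augmented with laminar class and configuration code; `summarize`
#' writes a [summarize_lineages()] report; `permute` runs
#' [run_permutation_analysis()]; `infer` runs [run_inference()] and
#' writes the progenitor-count distribution; `simulate` runs
#' [simulate_model()] from `config$simulate`; `fit` runs [fit_model()]
#' against the summarised input; `compare` z-scores the observed
#' summaries against the simulated repeats.
#'
#' @param config a `run_config` (see [read_run_config()] /
#'   [as_run_config()]).
#' @return the manifest (list of class `run_manifest`), invisibly written
#'   to `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  config <- as_run_config(unclass(config))
  stages <- config$stages
  if (is.null(stages)) stages <- "summarize"
  order_ref <- c("synth", "classify", "summarize", "permute", "infer",
                 "simulate", "fit", "compare")
  unknown <- setdiff(stages, order_ref)
  if (length(unknown) > 0L) {
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- order_ref[order_ref %in% stages]
  out_dir <- config$output
  if (is.null(out_dir)) stop("config$output directory required",
                             call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(package = "pclineage",
                   version = as.character(utils::packageVersion("pclineage")),
                   seed = seed, config = unclass(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())

  dat <- NULL
  load_input <- function() {
    if (!is.null(dat)) return(dat)
    if (is.null(config$input)) stop("no input table configured",
                                    call. = FALSE)
    x <- read_lineage_table(config$input)
    if (!is.null(config$area)) x <- x[x$area == config$area, , drop = FALSE]
    ## neurogenic 3-12 window by default; override via config$filters
    x <- neurogenic_filter(x,
                           config$filters$min_size %||% 3L,
                           config$filters$max_size %||% 12L)
    x
  }

  sim_reps <- NULL
  failed <- NULL
  for (st in stages) {
    t0 <- Sys.time()
    outputs <- character(0)
    res <- tryCatch({
      switch(st,
        synth = {
          spec <- synthetic_preset(seed = stage_seed(seed, "synth"))
          g <- generate_lineage_dataset(spec)
          path <- file.path(out_dir, "synthetic_lineages.csv")
          write_lineage_table(g$table, path)
          tpath <- file.path(out_dir, "synthetic_truth.csv")
          utils::write.csv(g$truth, tpath, row.names = FALSE, quote = FALSE)
          if (is.null(config$input)) {
            config$input <- path
          }
          outputs <- c(path, tpath)
        },
        classify = {
          x <- load_input(); dat <- x
          x$laminar_class <- as.character(classify_laminar(x))
          x$config_code <- as.character(configuration_code(x))
          path <- file.path(out_dir, "classified.csv")
          utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                           quote = FALSE)
          outputs <- path
        },
        summarize = {
          x <- load_input(); dat <- x
          sm <- summarize_lineages(x)
          path <- file.path(out_dir, "summary.json")
          write_report(unclass(sm), path, seed = seed)
          outputs <- path
        },
        permute = {
          x <- load_input(); dat <- x
          nrep <- config$permute$repeats %||% 1000L
          pr <- run_permutation_analysis(x, n_repeats = nrep,
                                         seed = stage_seed(seed, "permute"))
          path <- file.path(out_dir, "permutation.json")
          write_report(list(n_repeats = pr$n_repeats,
                            observed = as.list(pr$observed),
                            perm_mean = as.list(pr$perm_mean),
                            perm_sd = as.list(pr$perm_sd),
                            flagged = as.list(pr$flagged)),
                       path, seed = seed)
          outputs <- path
        },
        infer = {
          x <- load_input(); dat <- x
          ic <- config$infer
          cfg <- gibbs_config(
            n_draws = ic$draws %||% 4000L,
            burn_in = ic$burn_in %||% 1000L,
            thinning = ic$thinning %||% 1L,
            n_max = ic$n_max %||% 20L,
            beta_a = ic$beta_a %||% 1, beta_b = ic$beta_b %||% 1,
            alpha = ic$alpha %||% 1, n_aux = ic$n_aux %||% 3L,
            seed = stage_seed(seed, "infer"))
          fit <- run_inference(x, cfg)
          pk <- progenitor_count_distribution(fit)
          path <- file.path(out_dir, "inference.json")
          write_report(list(k_distribution = as.list(pk),
                            modal_k = as.integer(names(which.max(pk))),
                            mean_loglik = mean(fit$loglik)),
                       path, seed = seed)
          pred <- posterior_predictive(fit, n_lineages = nrow(x) * 10L,
                                       seed = stage_seed(seed, "predictive"))
          ppath <- file.path(out_dir, "posterior_predictive.csv")
          write_lineage_table(pred, ppath)
          outputs <- c(path, ppath)
        },
        simulate = {
          spec <- .spec_from_config(config$simulate,
                                    stage_seed(seed, "simulate"))
          sim_reps <- simulate_model(spec)
          paths <- vapply(seq_along(sim_reps), function(i) {
            pth <- file.path(out_dir, sprintf("sim_repeat_%03d.csv", i))
            write_lineage_table(sim_reps[[i]], pth)
            pth
          }, character(1L))
          outputs <- paths
        },
        fit = {
          x <- load_input(); dat <- x
          template <- .spec_from_config(config$simulate,
                                        stage_seed(seed, "fit-template"))
          fc <- config$fit
          fit <- fit_model(summarize_lineages(x), template,
                           n_eval_repeats = fc$n_eval_repeats %||% 40L,
                           max_cycles = fc$max_cycles %||% 40L,
                           seed = stage_seed(seed, "fit"))
          path <- file.path(out_dir, "fit.json")
          write_report(list(z = as.list(fit$z),
                            objective = fit$objective,
                            spec = .spec_to_list(fit$spec)),
                       path, seed = seed)
          outputs <- path
        },
        compare = {
          x <- load_input(); dat <- x
          if (is.null(sim_reps)) stop("'compare' requires the 'simulate' ",
                                      "stage in the same run", call. = FALSE)
          obs <- laminar_fractions(x)
          zs <- vapply(seq_along(obs), function(j) {
            sims <- vapply(sim_reps, function(r) laminar_fractions(r)[j],
                           numeric(1L))
            zscore(obs[j], sims)
          }, numeric(1L))
          names(zs) <- paste0("z_frac_", names(obs))
          path <- file.path(out_dir, "compare.json")
          write_report(as.list(zs), path, seed = seed)
          outputs <- path
        })
      "ok"
    }, error = function(e) e)
    entry <- list(stage = st,
                  started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                  finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    if (inherits(res, "error")) {
      entry$status <- "failed"
      entry$error <- conditionMessage(res)
      manifest$stages[[st]] <- entry
      failed <- st
      break
    }
    entry$status <- "ok"
    entry$outputs <- as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs)))
    manifest$stages[[st]] <- entry
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$status <- if (is.null(failed)) "ok" else
    paste0("failed at stage '", failed, "'")
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- structure(manifest, class = c("run_manifest", "list"))
  if (!is.null(failed)) {
    stop("pipeline failed at stage '", failed, "': ",
         manifest$stages[[failed]]$error, call. = FALSE)
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Build a sim_model_spec from the nested-list form used in config files.
.spec_from_config <- function(sim_cfg, seed) {
  if (is.null(sim_cfg)) {
    spec <- synthetic_preset(seed = seed)
    return(spec)
  }
  types <- lapply(sim_cfg$types, function(ty) {
    progenitor_spec(M = unlist(ty$M), P = unlist(ty$P),
                    q = ty$q %||% 0, fraction = ty$fraction %||% 1)
  })
  sim_model_spec(types,
                 n_progenitors = sim_cfg$n_progenitors %||% 100L,
                 n_repeats = sim_cfg$n_repeats %||% 100L,
                 size_filter = unlist(sim_cfg$size_filter) %||% c(3L, 12L),
                 seed = seed)
}

.spec_to_list <- function(spec) {
  list(types = lapply(spec$types, function(ty)
    list(M = as.list(ty$M), P = as.list(ty$P), q = ty$q,
         fraction = ty$fraction)),
    n_progenitors = spec$n_progenitors, n_repeats = spec$n_repeats,
    size_filter = spec$size_filter)
}
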