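# End-to-end orchestration: read-or-simulate inputs, evaluate by
# cross-validation, rank candidates, write every intermediate plus a
# manifest recording config and output fingerprints.

with_stage <- function(stage, quiet, expr) {
  if (!quiet) message("[circnea] stage: ", stage)
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[circnea] stage %s done (%.1fs)", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

read_pipeline_inputs <- function(input, quiet) {
  if (inherits(input, "synthetic_config")) {
    with_stage("simulate", quiet, {
      am <- simulate_associations(input)
      list(am = am, dag = simulate_dag(input),
           expr = simulate_expression(input))
    })
  } else {
    assert_that(is.list(input) &&
                  all(c("associations", "dag", "expression") %in% names(input)),
                "input must be a synthetic_config or a list with paths ",
                "'associations', 'dag', 'expression'")
    for (nm in c("associations", "dag", "expression")) {
      if (!file.exists(input[[nm]])) {
        stop("missing input path: ", nm, " = '", input[[nm]], "'",
             call. = FALSE)
      }
    }
    with_stage("read", quiet, {
      list(am = read_associations(input$associations),
           dag = read_dag(input$dag),
           expr = read_expression(input$expression))
    })
  }
}

#' Run the full association-prediction pipeline
#'
#' Simulates (or reads) the inputs, samples balanced negatives, evaluates
#' the configured pipeline by stratified cross-validation, trains on all
#' labelled pairs to rank unconfirmed candidates, and (optionally) writes
#' every intermediate plus a manifest to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param input either a [synthetic_config()] (data are simulated) or a
#'   named list of paths `associations`, `dag`, `expression`.
#' @param out_dir output directory; `NULL` skips writing artifacts.
#' @param quiet suppress per-stage log lines on standard error.
#' @return list with `cv` (a `cv_report`), `ranking`, `pairs`, `manifest`
#'   and, when written, `paths`.
#' @export
run_all <- function(config = pipeline_config(), input = synthetic_config(),
                    out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dat <- read_pipeline_inputs(input, quiet)

  pairs <- with_stage("sample_negatives", quiet, {
    sample_negatives(dat$am, seed = stage_seed(config, 1000))
  })
  cv <- with_stage("cross_validate", quiet, {
    cross_validate(dat$am, dat$dag, dat$expr, pairs, config)
  })
  ranking <- with_stage("rank", quiet, {
    rank_candidates(dat$am, dat$dag, dat$expr, pairs, config)
  })

  result <- list(cv = cv, ranking = ranking, pairs = pairs, am = dat$am)

  manifest <- list(
    package = "circnea",
    version = as.character(utils::packageVersion("circnea")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass_deep(config),
    input = if (inherits(input, "synthetic_config")) {
      c(list(type = "synthetic"), unclass(input))
    } else c(list(type = "files"), input),
    shapes = list(m = nrow(dat$am), n = ncol(dat$am),
                  pairs = nrow(pairs), positives = sum(pairs$label)),
    mean_metrics = as.list(cv$mean)
  )

  if (!is.null(out_dir)) {
    paths <- with_stage("write", quiet, {
      write_artifacts(out_dir, dat, pairs, cv, ranking)
    })
    manifest$outputs <- as.list(stats::setNames(unname(tools::md5sum(paths)),
                                                names(paths)))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    result$paths <- c(paths, manifest = manifest_path)
  }
  result$manifest <- manifest
  result
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

write_artifacts <- function(out_dir, dat, pairs, cv, ranking) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    associations = file.path(out_dir, "associations.tsv"),
    dag = file.path(out_dir, "dag.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    pairs = file.path(out_dir, "pairs.tsv"),
    cv = file.path(out_dir, "cv_report.json"),
    ranking = file.path(out_dir, "ranking.tsv"))
  write_associations(dat$am, paths[["associations"]])
  write_dag(dat$dag, paths[["dag"]])
  write_expression(dat$expr, paths[["expression"]])
  utils::write.table(pairs, paths[["pairs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(k = cv$k, leakage = cv$leakage, ablation = cv$ablation,
         per_fold = cv$per_fold, mean = as.list(cv$mean)),
    paths[["cv"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(ranking, paths[["ranking"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
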