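#' Read a probes x samples expression table
#'
#' Expects a tab-separated file whose first column holds probe ids and whose
#' header row holds sample ids.  Duplicate probe or sample ids and
#' non-numeric cells are rejected with the offending location.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs at least one sample",
                          call. = FALSE)
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  probe_ids <- df[[1]]
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
              dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !(df[[j + 1]] %in% c("NA", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   df[[j + 1]][bad[[1]]], bad[[1]], sample_ids[[j]]),
           call. = FALSE)
    }
    m[, j] <- v
  }
  m
}

#' Write a probes x samples expression table
#'
#' Inverse of [read_expression_table()]; values are written with 17
#' significant digits so a round trip preserves them exactly.
#'
#' @param mat Numeric matrix with probe rownames and sample colnames.
#' @param path Output TSV path.
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  chr <- formatC(mat, digits = 17, format = "g")
  df <- data.frame(probe_id = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a diagnostic model to JSON
#'
#' @param model A `diag_model`.
#' @param path Output JSON path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "diag_model"))
  obj <- list(
    schema = "seromiR/diag_model/1",
    probes = model$probes,
    weights = as.numeric(model$weights),
    raw_min = model$raw_min, raw_max = model$raw_max,
    cutpoint = model$cutpoint, k = model$k,
    n_discovery = model$n_discovery,
    seed = if (is.null(model$seed)) NA else model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a diagnostic model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `diag_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(probes = obj$probes,
         weights = setNames(obj$weights, obj$probes),
         raw_min = obj$raw_min, raw_max = obj$raw_max,
         cutpoint = obj$cutpoint, k = as.integer(obj$k),
         n_discovery = obj$n_discovery, seed = obj$seed),
    class = "diag_model"
  )
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline in one nested
#' list that round-trips losslessly through YAML.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Global integer seed.
#' @param simulate List: `enabled`, plus arguments of
#'   [simulate_mced_study()] (`n_signature`, `effect`, `discovery`,
#'   `validation`, `n_target_probes`).
#' @param input List of paths used when `simulate$enabled` is `FALSE`:
#'   `discovery_expr`, `discovery_meta`, `validation_expr`,
#'   `validation_meta` (TSV expression, CSV metadata).
#' @param qc List: `cv_threshold`, `flag_threshold`, `floor`,
#'   `presence_filter`.
#' @param dedup List: `enabled`, `threshold`, `priority`.
#' @param train List: `k_max`, `folds`, `grid_step`.
#' @param evaluate List: `subgroups` (metadata columns).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "pipeline_out",
                            seed = 1L,
                            simulate = list(),
                            input = list(),
                            qc = list(),
                            dedup = list(),
                            train = list(),
                            evaluate = list()) {
  merge_defaults <- function(user, defaults) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = merge_defaults(simulate, list(
      enabled = TRUE, n_signature = 4L, effect = 2,
      discovery = c(208L, 208L), validation = c(1358L, 1970L),
      n_target_probes = 2588L
    )),
    input = merge_defaults(input, list(
      discovery_expr = NULL, discovery_meta = NULL,
      validation_expr = NULL, validation_meta = NULL
    )),
    qc = merge_defaults(qc, list(
      cv_threshold = 0.15, flag_threshold = 10L, floor = 1,
      presence_filter = 0
    )),
    dedup = merge_defaults(dedup, list(
      enabled = FALSE, threshold = 0.99, priority = NULL
    )),
    train = merge_defaults(train, list(
      k_max = 50L, folds = 10L, grid_step = 1
    )),
    evaluate = merge_defaults(evaluate, list(
      subgroups = c("stage", "histology")
    ))
  )
  stopifnot(cfg$qc$cv_threshold > 0, cfg$qc$flag_threshold >= 0,
            cfg$train$folds >= 2, cfg$train$k_max >= 1,
            cfg$train$grid_step > 0,
            cfg$dedup$threshold > 0, cfg$dedup$threshold < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(out_dir = raw$out_dir, seed = raw$seed,
                  simulate = raw$simulate, input = raw$input, qc = raw$qc,
                  dedup = raw$dedup, train = raw$train,
                  evaluate = raw$evaluate)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

read_metadata_csv <- function(path) {
  if (is.null(path) || !file.exists(path)) {
    stop("metadata file not found: ",
         if (is.null(path)) "(not configured)" else path, call. = FALSE)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

#' Run the end-to-end diagnostic pipeline
#'
#' Executes simulate (optional) -> QC/preprocess -> dedup (optional) ->
#' differential expression -> model training -> evaluation, writing
#' self-describing artifacts (`model.json`, `report.json`,
#' `de_results.csv`, `qc_report.csv`) stamped with the configuration hash
#' and seed into `config$out_dir`.  Any stage error aborts with the stage
#' name and cause.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the trained `model`, the discovery and
#'   validation `eval_report`s, the `de_result`, and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  disc_raw <- valid_raw <- NULL
  if (isTRUE(config$simulate$enabled)) {
    study <- run_stage("simulate", simulate_mced_study(
      seed = config$seed,
      n_signature = config$simulate$n_signature,
      effect = config$simulate$effect,
      discovery = config$simulate$discovery,
      validation = config$simulate$validation,
      n_target_probes = config$simulate$n_target_probes
    ))
    disc_raw <- study$discovery
    valid_raw <- study$validation
    disc_norm <- run_stage("qc", preprocess_pipeline(
      disc_raw, cv_threshold = config$qc$cv_threshold,
      flag_threshold = config$qc$flag_threshold, floor = config$qc$floor,
      presence_filter = config$qc$presence_filter
    ))
    valid_norm <- run_stage("qc", preprocess_pipeline(
      valid_raw, cv_threshold = config$qc$cv_threshold,
      flag_threshold = config$qc$flag_threshold, floor = config$qc$floor,
      presence_filter = config$qc$presence_filter
    ))
    disc_meta <- disc_norm$samples
    valid_meta <- valid_norm$samples
    disc_expr <- disc_norm$expr
    valid_expr <- valid_norm$expr
    qc_report <- rbind(disc_norm$qc, valid_norm$qc)
  } else {
    disc_expr <- run_stage("qc", read_expression_table(
      config$input$discovery_expr))
    valid_expr <- if (!is.null(config$input$validation_expr)) {
      run_stage("qc", read_expression_table(config$input$validation_expr))
    }
    disc_meta <- run_stage("de", read_metadata_csv(
      config$input$discovery_meta))
    valid_meta <- if (!is.null(valid_expr)) {
      run_stage("de", read_metadata_csv(config$input$validation_meta))
    }
    qc_report <- NULL
  }

  if (isTRUE(config$dedup$enabled) && !is.null(valid_expr)) {
    dd <- run_stage("dedup", remove_redundant(
      list(discovery = disc_expr, validation = valid_expr),
      priority_dataset = "discovery", threshold = config$dedup$threshold
    ))
    keep <- dd$retained$sample_id[dd$retained$dataset == "validation"]
    valid_expr <- valid_expr[, keep, drop = FALSE]
    valid_meta <- valid_meta[match(keep, valid_meta$sample_id), ,
                             drop = FALSE]
  }

  disc_case <- run_stage("de", {
    if (is.null(disc_meta$class)) stop("metadata lacks a 'class' column")
    disc_meta$class[match(colnames(disc_expr), disc_meta$sample_id)] !=
      "non-cancer"
  })
  de <- run_stage("de", de_analysis(disc_expr, disc_case))

  model <- run_stage("train", train_diagnostic_model(
    disc_expr, disc_case, k_grid = seq_len(config$train$k_max),
    folds = config$train$folds, seed = config$seed,
    grid_step = config$train$grid_step
  ))

  disc_eval <- run_stage("evaluate", evaluate_model(
    model, disc_expr, disc_case, metadata = disc_meta,
    subgroups = config$evaluate$subgroups
  ))
  valid_eval <- if (!is.null(valid_expr)) {
    valid_case <- valid_meta$class[match(colnames(valid_expr),
                                         valid_meta$sample_id)] !=
      "non-cancer"
    run_stage("evaluate", evaluate_model(
      model, valid_expr, valid_case, metadata = valid_meta,
      subgroups = config$evaluate$subgroups
    ))
  }

  paths <- list(
    model = file.path(config$out_dir, "model.json"),
    report = file.path(config$out_dir, "report.json"),
    de = file.path(config$out_dir, "de_results.csv"),
    qc = file.path(config$out_dir, "qc_report.csv")
  )
  write_model(model, paths$model)
  de_out <- de[order(de$rank),
               c("probe", "logFC", "t", "p_value", "adj_p_value", "rank")]
  write.csv(de_out, paths$de, row.names = FALSE)
  if (!is.null(qc_report)) write.csv(qc_report, paths$qc, row.names = FALSE)

  report <- list(
    schema = "seromiR/report/1", config_hash = hash, seed = config$seed,
    panel = model$probes, k = model$k, cutpoint = model$cutpoint,
    discovery = list(auc = disc_eval$auc,
                     sensitivity = disc_eval$sensitivity,
                     specificity = disc_eval$specificity,
                     n_case = disc_eval$n_case,
                     n_control = disc_eval$n_control)
  )
  if (!is.null(valid_eval)) {
    report$validation <- list(auc = valid_eval$auc,
                              sensitivity = valid_eval$sensitivity,
                              specificity = valid_eval$specificity,
                              n_case = valid_eval$n_case,
                              n_control = valid_eval$n_control)
  }
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)

  invisible(list(model = model, de = de, discovery_eval = disc_eval,
                 validation_eval = valid_eval, paths = paths,
                 config_hash = hash))
}
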