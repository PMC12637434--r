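# Plain-text serialization of the package's tables and containers.
# Trial tables and value tables are CSV (UTF-8, comma, header, '.' decimal,
# seconds as floats); the spike container is a JSON metadata file plus a
# sparse long CSV of nonzero counts; configurations are YAML.

.required_trial_cols <- c("session_id", "trial", "block_side", "choice",
                          "outcome", "stim_collected", "r", "t_go", "t_move",
                          "t_outcome", "t_stim")

#' Read and write trial tables
#'
#' @param session a `session_data`.
#' @param path CSV file path.
#' @return `write_trials` returns the path invisibly; `read_trials` returns
#'   a `session_data` (block boundaries recomputed from side changes).
#' @export
write_trials <- function(session, path) {
  tr <- session$trials
  out <- cbind(session_id = session$session_id, tr)
  out$hemisphere <- session$hemisphere
  out$cs_present <- session$cs_present
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(.required_trial_cols, names(df))
  stopf(length(missing) == 0, "trial table is missing columns: %s",
        paste(missing, collapse = ", "))
  stopf(!anyNA(df$r) && !anyNA(df$trial), "NaN in required fields r/trial")
  tr <- df[, .required_trial_cols[-1]]
  tr$stim_collected <- as.logical(tr$stim_collected)
  boundaries <- c(1L, which(diff(match(tr$block_side, c("L", "R"))) != 0) + 1L)
  structure(list(
    session_id = df$session_id[1], trials = tr,
    block_boundaries = boundaries,
    hemisphere = if ("hemisphere" %in% names(df)) df$hemisphere[1] else "left",
    cs_present = if ("cs_present" %in% names(df)) isTRUE(df$cs_present[1])
                 else TRUE,
    config = NULL, seed = NA_integer_
  ), class = "session_data")
}

#' Read and write decision-variable tables
#'
#' @param values data frame from [extract_decision_variables()].
#' @param path CSV file path.
#' @export
write_values <- function(values, path) {
  write.csv(values, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_values
#' @export
read_values <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  stopf("trial" %in% names(df), "values table must have a trial column")
  df
}

#' Read and write the spike container
#'
#' The container is a pair of plain-text files: `<path>.json` holds the
#' dimensions, bin width, and neuron metadata; `<path>.csv` holds the
#' nonzero entries of the neurons x grid-rows count matrix in long form.
#' The round trip is exact.
#'
#' @param counts neurons x grid rows matrix.
#' @param meta neuron metadata data frame.
#' @param path file path prefix (without extension).
#' @param bin bin width in seconds.
#' @export
write_spike_container <- function(counts, meta, path, bin = 0.01) {
  stopf(nrow(meta) == nrow(counts),
        "metadata rows (%d) must match neurons (%d)", nrow(meta),
        nrow(counts))
  nz <- which(counts != 0, arr.ind = TRUE)
  jsonlite::write_json(
    list(n_neurons = nrow(counts), n_rows = ncol(counts), bin = bin,
         meta = meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(neuron = nz[, 1], row = nz[, 2],
                       count = counts[nz]),
            paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_container
#' @export
read_spike_container <- function(path) {
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- read.csv(paste0(path, ".csv"))
  counts <- matrix(0, js$n_neurons, js$n_rows)
  counts[cbind(long$neuron, long$row)] <- long$count
  list(counts = counts, meta = as.data.frame(js$meta), bin = js$bin)
}

#' Check that behavioral and neural inputs describe the same trials
#'
#' @param values decision-variable data frame.
#' @param timeline an [build_event_timeline()] result.
#' @param counts neurons x grid rows matrix.
#' @return invisibly `TRUE`; otherwise a named validation error.
#' @export
validate_inputs <- function(values, timeline, counts) {
  stopf(!anyNA(values$trial), "values table has missing trial ids")
  miss <- setdiff(timeline$trial_info$trial, values$trial)
  stopf(length(miss) == 0,
        "values table lacks %d trials present in the timeline (e.g. trial %s)",
        length(miss), if (length(miss)) miss[1] else "")
  stopf(ncol(counts) == timeline$n_rows,
        "spike container has %d grid rows but the timeline has %d",
        ncol(counts), timeline$n_rows)
  invisible(TRUE)
}

#' Read and write task configurations as YAML
#'
#' @param config a [task_config()].
#' @param path YAML file path.
#' @export
write_task_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  do.call(task_config, yaml::read_yaml(path))
}

# polynomial rolling hash of a character string (configuration fingerprints)
.config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a reproducibility manifest
#'
#' Records the configuration (with a fingerprint), seeds, and package
#' version alongside an analysis output so deterministic runs can be
#' reproduced bit-for-bit.
#'
#' @param path JSON file path.
#' @param config any serializable configuration list.
#' @param seeds named list or vector of seeds used.
#' @export
write_manifest <- function(path, config, seeds) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "valuecode",
         version = as.character(utils::packageVersion("valuecode")),
         config = config, config_hash = .config_hash(as.character(cfg_json)),
         seeds = seeds, timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
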