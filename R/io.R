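# Configuration and trace I/O, provenance records.

#' Write / read a parameter set
#'
#' Parameter sets are serialised as a flat key-to-value mapping so every
#' field of [cell_params()] is a stable config key. YAML or JSON is chosen
#' from the file extension.
#'
#' @param params A `cell_params` object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a validated `cell_params`.
#' @export
write_params <- function(params, path) {
  flat <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(flat, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension (use .yaml or .json)", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension (use .yaml or .json)", call. = FALSE)
  }
  do.call(cell_params, raw)
}

#' Write / read a simulated trace as CSV
#'
#' Column headers carry explicit units (`time_ms`, `cai_uM`,
#' `tension_kPa`) to prevent silent unit drift; extra state columns are
#' preserved.
#'
#' @param trace An `hcm_trace` tibble.
#' @param path CSV file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` an
#'   `hcm_trace` tibble.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_ms", "cai_uM", "tension_kPa")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trace file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tb <- tibble::as_tibble(df)
  structure(tb, class = c("hcm_trace", class(tb)))
}

#' Write / read calibration ranges as YAML
#'
#' @param ranges A `calibration_ranges` tibble (`biomarker`, `lo`, `hi`).
#' @param path YAML file path.
#' @return `write_ranges()` returns `path` invisibly; `read_ranges()` a
#'   `calibration_ranges` tibble.
#' @export
write_ranges <- function(ranges, path) {
  lst <- setNames(
    lapply(seq_len(nrow(ranges)), function(i) {
      list(lo = ranges$lo[i], hi = ranges$hi[i])
    }),
    ranges$biomarker)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_ranges
#' @export
read_ranges <- function(path) {
  lst <- yaml::read_yaml(path)
  rows <- purrr::map_dfr(names(lst), function(nm) {
    if (lst[[nm]]$lo > lst[[nm]]$hi) {
      stop("range for ", nm, " has lo > hi", call. = FALSE)
    }
    tibble::tibble(biomarker = nm, lo = lst[[nm]]$lo, hi = lst[[nm]]$hi)
  })
  structure(rows, class = c("calibration_ranges", class(tibble::tibble())))
}

#' Provenance record for an output
#'
#' Machine-readable record of how a table or trace was produced: package
#' version, seed, and a hash of the parameter configuration.
#'
#' @param params A `cell_params` object (or any serialisable config).
#' @param seed The seed used, if any.
#' @param extra Optional named list merged into the record.
#' @param path Optional JSON path to write the record to.
#' @return The record as a named list (invisibly if written).
#' @export
provenance_record <- function(params, seed = NULL, extra = list(),
                              path = NULL) {
  cfg_json <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE,
                               digits = NA)
  rec <- c(list(
    package = "hcmtwitch",
    version = as.character(utils::packageVersion("hcmtwitch")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                        seq_along(utf8ToInt(cfg_json))) %%
                            .Machine$integer.max)
  ), extra)
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null")
    return(invisible(rec))
  }
  rec
}
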