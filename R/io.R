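# Tidy long-format CSV is the interchange format for all assay data:
# columns series_id, x, y, with per-series metadata (design, parameters,
# seeds) in a JSON sidecar keyed by series_id. All writes are atomic
# (write to a temporary file in the target directory, then rename), so an
# interrupted run never leaves a truncated output.

# atomic write: run writer(tmp), then rename into place
.write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path,
                                    call. = FALSE)
  invisible(path)
}

#' Write assay series to tidy CSV with a JSON sidecar
#'
#' @param series_list Named list of `assay_series` (names become
#'   `series_id`; unnamed lists get `series_1`, ...).
#' @param path Output CSV path (columns `series_id`, `x`, `y`).
#' @param sidecar_path Optional JSON sidecar path; receives each series'
#'   metadata plus any `extra` fields (design, parameters, seed).
#' @param extra Named list merged into the sidecar top level.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series_list, path, sidecar_path = NULL,
                             extra = list()) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  ids <- names(series_list)
  if (is.null(ids) || any(ids == "")) {
    ids <- paste0("series_", seq_along(series_list))
  }
  df <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(series_id = ids[i], x = s$x, y = s$y)
  }))
  .write_atomic(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
  if (!is.null(sidecar_path)) {
    meta <- lapply(series_list, series_meta)
    names(meta) <- ids
    payload <- c(extra, list(series = meta))
    .write_atomic(sidecar_path, function(tmp) {
      jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  }
  invisible(path)
}

#' Read assay series from tidy CSV (with optional JSON sidecar)
#'
#' @param path CSV with columns `series_id`, `x`, `y`.
#' @param sidecar_path Optional sidecar JSON written by
#'   [write_series_csv()]; its per-series metadata is reattached.
#' @param kind Series kind passed to [assay_series()].
#' @return Named list of `assay_series`.
#' @export
read_series_csv <- function(path, sidecar_path = NULL, kind = "time") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta_all <- if (!is.null(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)$series
  } else NULL
  ids <- unique(df$series_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$series_id == id, , drop = FALSE]
    m <- if (!is.null(meta_all) && id %in% names(meta_all))
      as.list(meta_all[[id]]) else list()
    assay_series(sub$x, sub$y, kind = kind, meta = m)
  })
  names(out) <- ids
  out
}

#' Write a fit object as JSON (atomically)
#'
#' Serializes any of the package's fit objects (classes are recorded in the
#' payload) with full numeric precision.
#'
#' @param fit A fit object (`vsc_fit`, `langmuir_fit`, `competition_fit`,
#'   `one_site_fit`) or any list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- unclass(fit)
  payload$.class <- class(fit)[1L]
  payload <- lapply(payload, function(v) if (is.object(v)) unclass(v) else v)
  .write_atomic(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  })
}

#' Write a run manifest
#'
#' Records configuration, package version and seeds so a run can be
#' reproduced exactly: identical manifests imply identical outputs for the
#' deterministic stages.
#'
#' @param path Output JSON path.
#' @param config Named list describing the run.
#' @param seed Integer seed(s) used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL) {
  payload <- list(
    package = "bindkin",
    version = as.character(utils::packageVersion("bindkin")),
    seed = seed,
    config = config
  )
  .write_atomic(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  })
}
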