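#' Labelled assay series
#'
#' The common data currency of all generators, readers and fitters: an ordered
#' grid (`x` = time in s, concentration in M, or injection index) with a signal
#' (`y` = AU, RU, or ucal) and free-form metadata (substrate and enzyme
#' concentrations, analyte concentration, phase boundaries, ...).
#'
#' @param x Numeric grid (time, concentration, or injection index).
#' @param y Numeric signal, same length as `x`.
#' @param kind One of `"time"`, `"dose"`, `"injection"`.
#' @param meta Named list of metadata.
#' @return A `data.frame` of class `assay_series` with columns `x`, `y` and
#'   attributes `kind` and `meta`.
#' @export
assay_series <- function(x, y, kind = c("time", "dose", "injection"),
                         meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (!is.list(meta)) stop("'meta' must be a list", call. = FALSE)
  out <- data.frame(x = x, y = y)
  attr(out, "kind") <- kind
  attr(out, "meta") <- meta
  class(out) <- c("assay_series", "data.frame")
  out
}

#' Metadata of an assay series
#' @param series An `assay_series`.
#' @return Named list of metadata.
#' @export
series_meta <- function(series) {
  attr(series, "meta") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assay_series <- function(x, ...) {
  m <- series_meta(x)
  cat(sprintf("<assay_series: %s, %d points%s>\n", attr(x, "kind"), nrow(x),
              if (length(m)) paste0("; meta: ", paste(names(m), collapse = ", ")) else ""))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

# interpolate series b onto the x grid of series a; error when grids do not
# overlap at all
.interp_onto <- function(a, b, what = "series") {
  if (max(b$x) < min(a$x) || min(b$x) > max(a$x)) {
    stop(what, " does not overlap the target grid", call. = FALSE)
  }
  if (length(b$x) == length(a$x) && all(b$x == a$x)) return(b$y)
  stats::approx(b$x, b$y, xout = a$x, rule = 2)$y
}
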