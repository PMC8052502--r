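#' Physical constants for energy calculations
#'
#' Gas constant and reference temperature used throughout the thermodynamic
#' report layer. `R_cal` is in cal mol^-1 K^-1 and `T_ref` in K; binding free
#' energies are reported in kcal/mol at `T_ref`.
#'
#' @return Named list with `R_cal` (1.986 cal mol^-1 K^-1) and `T_ref` (298 K).
#' @export
#' @examples
#' bk_constants()$R_cal
bk_constants <- function() {
  list(R_cal = 1.986, T_ref = 298)
}

# internal base units: M, s, L, cal, kcal/mol, RU, AU
.unit_factors <- c(
  "M"       = 1,
  "mM"      = 1e-3,
  "uM"      = 1e-6,
  "µM" = 1e-6,
  "nM"      = 1e-9,
  "pM"      = 1e-12,
  "s"       = 1,
  "L"       = 1,
  "uL"      = 1e-6,
  "µL" = 1e-6,
  "kcal/mol" = 1,
  "RU"      = 1,
  "AU"      = 1,
  "cal"     = 1,
  "ucal"    = 1e-6,
  "µcal" = 1e-6,
  "1/Ms"    = 1,
  "M-1s-1"  = 1,
  "1/s"     = 1
)

#' Convert a value with a unit tag to internal base units
#'
#' Internal base units are molar for concentrations, seconds for time, litres
#' for volume, calories for heat, kcal/mol for molar energies, and instrument
#' units (RU, AU) as-is. Rate constants in M^-1 s^-1 or s^-1 are already
#' internal.
#'
#' @param value Numeric value(s).
#' @param unit Unit tag, one of `"nM"`, `"uM"`, `"mM"`, `"M"`, `"pM"`, `"s"`,
#'   `"L"`, `"uL"`, `"kcal/mol"`, `"RU"`, `"AU"`, `"cal"`, `"ucal"`, `"1/Ms"`,
#'   `"1/s"`.
#' @return `value` scaled to internal units.
#' @export
#' @examples
#' to_internal(34, "nM")    # 3.4e-8 M
#' to_internal(2.5, "uL")   # 2.5e-6 L
to_internal <- function(value, unit) {
  stopifnot(is.numeric(value))
  if (!is.character(unit) || length(unit) != 1L || !unit %in% names(.unit_factors)) {
    stop("unknown unit tag: '", unit, "'", call. = FALSE)
  }
  value * unname(.unit_factors[[unit]])
}

#' Summarize replicate measurements
#'
#' Mean and sample standard deviation (n-1 denominator) across replicate
#' experiments, the convention used for all tabulated binding constants.
#' A single replicate has sd 0 by definition.
#'
#' @param values Non-empty numeric vector of replicate values.
#' @return Object of class `replicate_summary`: list with `mean`, `sd`, `n`.
#' @export
#' @examples
#' summarize_replicates(c(33.6, 34.0, 34.4))  # mean 34, sd 0.4, n 3
summarize_replicates <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    stop("'values' must be a non-empty numeric vector without NAs", call. = FALSE)
  }
  n <- length(values)
  structure(
    list(
      mean = mean(values),
      sd = if (n == 1L) 0 else stats::sd(values),
      n = n
    ),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%g ± %g (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}
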