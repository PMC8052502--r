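#' Standard binding free energy from a dissociation constant
#'
#' dG_bind = -R T ln(1/KD) = R T ln(KD), in kcal/mol with R in cal/mol/K.
#' Negative for any sub-molar KD.
#'
#' @param KD Dissociation constant in M (> 0).
#' @param temperature Temperature in K.
#' @return Binding free energy in kcal/mol.
#' @export
#' @examples
#' delta_g_bind(34e-9)  # ~ -10.2
delta_g_bind <- function(KD, temperature = bk_constants()$T_ref) {
  if (any(KD <= 0)) stop("KD must be > 0", call. = FALSE)
  bk_constants()$R_cal * temperature * log(KD) / 1000
}

#' Binding free-energy difference between a variant and a reference
#'
#' ddG = R T ln(KD / KD_ref) in kcal/mol: positive for weaker binders
#' (larger KD), antisymmetric under swapping the arguments, and equal to
#' delta_g_bind(KD) - delta_g_bind(KD_ref) exactly.
#'
#' @param KD,KD_ref Dissociation constants in M (> 0).
#' @param temperature Temperature in K.
#' @return ddG in kcal/mol.
#' @export
#' @examples
#' delta_delta_g(240e-9, 34e-9)  # ~ +1.2
delta_delta_g <- function(KD, KD_ref, temperature = bk_constants()$T_ref) {
  if (any(KD <= 0) || any(KD_ref <= 0)) stop("KD must be > 0", call. = FALSE)
  bk_constants()$R_cal * temperature * log(KD / KD_ref) / 1000
}

#' Fraction of total binding energy attributed to a component
#'
#' Two explicit modes (no inference): `"remainder"` returns
#' 100 (|dG_total| - ddG)/|dG_total| - the share of binding energy left after
#' removing a component whose loss costs `ddG_component`; `"component"`
#' returns 100 ddG_component/|dG_total| - the share a component contributes
#' to a stated total.
#'
#' @param ddG_component Energy attributed to the component, kcal/mol.
#' @param dG_total_magnitude Positive magnitude of the total energy, kcal/mol.
#' @param mode `"remainder"` or `"component"`.
#' @return Percentage.
#' @export
#' @examples
#' energy_fraction(1.2, 10.2, "remainder")  # ~88
#' energy_fraction(1.0, 1.2, "component")   # ~83
energy_fraction <- function(ddG_component, dG_total_magnitude,
                            mode = c("remainder", "component")) {
  mode <- match.arg(mode)
  if (any(dG_total_magnitude <= 0)) {
    stop("dG_total_magnitude must be > 0", call. = FALSE)
  }
  if (mode == "remainder") {
    100 * (dG_total_magnitude - ddG_component) / dG_total_magnitude
  } else {
    100 * ddG_component / dG_total_magnitude
  }
}

#' Ratio of two quantities (fold change)
#'
#' @param a,b Numerators and denominators (`b != 0`).
#' @return a/b.
#' @export
#' @examples
#' fold_change(13.1e4, 1.953e4)  # ~6.7
fold_change <- function(a, b) {
  if (any(b == 0)) stop("denominator must be nonzero", call. = FALSE)
  a / b
}

#' Reference binding constants for the C5a ligand panel
#'
#' The published mean kinetic constants (n = 3 experiments each) for the
#' catalytically dead peptidase binding full-length C5a at five NaCl
#' concentrations, the core and des-Arg truncations, and six surface point
#' mutants. Values are in SI units (ka M^-1 s^-1, kd s^-1, KD M);
#' `ddG_printed` is the tabulated free-energy difference vs the
#' rhC5a / 150 mM NaCl reference, in kcal/mol.
#'
#' @return `data.frame` with columns `label`, `ka`, `ka_sd`, `kd`, `kd_sd`,
#'   `KD`, `KD_sd`, `ddG_printed`, `n`.
#' @export
c5a_binding_constants <- function() {
  rows <- list(
    # label,                 ka(e4), sd,    kd(e-3), sd,   KD(nM), sd,  ddG
    list("rhC5a (150 mM NaCl)",   13.1,  0.3,   4.4,  0.3,   34,   3,   0.0),
    list("rhC5a (350 mM NaCl)",   6.85,  0.95,  4.31, 0.28,  63.5, 7.5, 0.4),
    list("rhC5a (550 mM NaCl)",   3.92,  0.38,  5.4,  0.5,  140,  20,   0.8),
    list("rhC5a (750 mM NaCl)",   2.56,  0.28,  6.51, 0.43, 256,  30,   1.2),
    list("rhC5a (950 mM NaCl)",   1.953, 0.137, 9.10, 0.78, 466,  30,   1.5),
    list("rhC5a_core",            3.52,  0.05,  8.5,  0.3,  240,  10,   1.2),
    list("rhC5a_dR",              6.17,  0.52, 11.8,  1.0,  191,   9,   1.0),
    list("rhC5a_K4A,K5A",        18.0,   1.2,   5.83, 0.37,  32.5, 3.0, 0.0),
    list("rhC5a_K12A,K14A",      15.8,   1.2,   4.05, 0.30,  25.6, 0.3, -0.2),
    list("rhC5a_R37A",            8.12,  0.49, 17.6,  0.12, 217,  11,   1.1),
    list("rhC5a_R40A",            8.80,  0.74, 20.5,  1.4,  234,  20,   1.1),
    list("rhC5a_R46A",           11.1,   1.3,  17.8,  0.7,  162,  21,   0.9),
    list("rhC5a_K49A",           19.5,   1.0,   5.0,  0.7,   26,   2,  -0.2)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r[[1]],
               ka = r[[2]] * 1e4, ka_sd = r[[3]] * 1e4,
               kd = r[[4]] * 1e-3, kd_sd = r[[5]] * 1e-3,
               KD = r[[6]] * 1e-9, KD_sd = r[[7]] * 1e-9,
               ddG_printed = r[[8]], n = 3L)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a kinetic/thermodynamic report for a panel of binding records
#'
#' One row per record with the tabulation conventions of the field: ka on the
#' x1e4 scale, kd on the x1e-3 scale, KD in nM, and energies in kcal/mol at
#' 1 d.p. ddG is computed from the KD means against the declared reference
#' record (positive = weaker binding); dG_bind is reported for every row.
#' A derived-quantities block carries the per-row fold changes vs the
#' reference and the remainder energy fraction.
#'
#' @param records `data.frame` with columns `label`, `ka`, `kd`, `KD` in SI
#'   units (optionally `ka_sd`, `kd_sd`, `KD_sd`).
#' @param reference_label Label of the reference record (must be present).
#' @param temperature Temperature in K for the energy columns.
#' @return List of class `thermo_report`: `table` (display-scaled
#'   `data.frame`), `derived` (`data.frame` of fold changes and energy
#'   fractions), `reference_label`, `temperature`.
#' @export
build_report <- function(records, reference_label,
                         temperature = bk_constants()$T_ref) {
  stopifnot(is.data.frame(records),
            all(c("label", "ka", "kd", "KD") %in% names(records)))
  i_ref <- match(reference_label, records$label)
  if (is.na(i_ref)) {
    stop("reference label '", reference_label, "' not found", call. = FALSE)
  }
  KD_ref <- records$KD[i_ref]
  dG <- delta_g_bind(records$KD, temperature)
  ddG <- delta_delta_g(records$KD, KD_ref, temperature)
  tab <- data.frame(
    label = records$label,
    ka_e4 = signif(records$ka / 1e4, 3),
    kd_e3 = signif(records$kd * 1e3, 3),
    stringsAsFactors = FALSE
  )
  tab$KD_nM <- signif(records$KD * 1e9, 3)
  tab$dG_bind <- round(dG, 1)
  tab$ddG <- round(ddG, 1)
  if (all(c("ka_sd", "kd_sd", "KD_sd") %in% names(records))) {
    tab$ka_e4_sd <- signif(records$ka_sd / 1e4, 2)
    tab$kd_e3_sd <- signif(records$kd_sd * 1e3, 2)
    tab$KD_nM_sd <- signif(records$KD_sd * 1e9, 2)
  }
  dG_ref_mag <- abs(dG[i_ref])
  derived <- data.frame(
    label = records$label,
    KD_fold_vs_ref = round(records$KD / KD_ref, 1),
    ka_fold_ref_over_row = round(records$ka[i_ref] / records$ka, 1),
    kd_fold_row_over_ref = round(records$kd / records$kd[i_ref], 1),
    energy_fraction_remainder = round(
      energy_fraction(ddG, dG_ref_mag, "remainder"), 0),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, derived = derived,
         reference_label = reference_label, temperature = temperature),
    class = "thermo_report"
  )
}

#' @export
print.thermo_report <- function(x, ...) {
  cat(sprintf("Binding report (reference: %s, T = %g K)\n",
              x$reference_label, x$temperature))
  print(x$table, row.names = FALSE)
  invisible(x)
}
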