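#' Average daily intake from drinking water
#'
#' `ADI = C * IR * EF * ED / (BW * AT)` in mg/kg/day. With the default
#' scenario, where the averaging time equals exposure duration times
#' exposure frequency, the duration and frequency cancel and the dose
#' reduces to `C * IR / BW`.
#'
#' @param conc Concentration(s) in mg/L, non-negative.
#' @param profile An [exposure_profile()].
#' @return Dose(s) in mg/kg/day.
#' @export
average_daily_intake <- function(conc, profile = exposure_profile()) {
  stopifnot(inherits(profile, "exposure_profile"))
  if (any(conc < 0, na.rm = TRUE)) abort("concentrations must be >= 0.")
  conc * profile$intake_rate * profile$exposure_frequency *
    profile$exposure_duration /
    (profile$body_weight * profile$averaging_time)
}

#' Hazard quotient
#'
#' The non-carcinogenic risk ratio `HQ = ADI / RfD`; values below 1 mean
#' the dose is under the no-adverse-effect reference dose.
#'
#' @param adi Average daily intake(s), mg/kg/day.
#' @param rfd Oral reference dose(s), mg/kg/day, strictly positive.
#' @param metal Optional metal name used in error messages.
#' @return Dimensionless quotient(s).
#' @export
hazard_quotient <- function(adi, rfd, metal = NULL) {
  if (any(is.na(rfd)) || any(rfd <= 0)) {
    abort(paste0("missing or non-positive reference dose",
                 if (!is.null(metal)) paste0(" for ", metal), "."))
  }
  adi / rfd
}

#' Carcinogenic risk
#'
#' Lifetime excess cancer probability `CR = ADI * CSF`. A missing slope
#' factor yields `NA` (the metal is excluded from the carcinogenic index),
#' which is a valid state rather than an error.
#'
#' @param adi Average daily intake(s), mg/kg/day.
#' @param csf Cancer slope factor(s), (mg/kg/day)^-1, `NA` if unavailable.
#' @return Risk probability(ies); `NA` where no slope factor exists.
#' @export
carcinogenic_risk <- function(adi, csf) {
  if (any(csf < 0, na.rm = TRUE)) abort("cancer slope factors must be >= 0.")
  adi * csf
}

#' Classify a carcinogenic index against the acceptable band
#'
#' The conventional acceptable lifetime excess cancer risk spans 1e-6 to
#' 1e-4 (one case per million to one per ten thousand exposed).
#'
#' @param ci Carcinogenic index value(s).
#' @return Factor: `below_acceptable`, `acceptable`, `above_acceptable`.
#' @export
classify_cancer_risk <- function(ci) {
  cut(ci, breaks = c(-Inf, 1e-6, 1e-4, Inf),
      labels = c("below_acceptable", "acceptable", "above_acceptable"))
}

#' Deterministic drinking-water health risk per sample
#'
#' Runs the full exposure chain for each sample: per-metal average daily
#' intake, hazard quotient (ADI/RfD) and their sum the hazard index (HI),
#' plus — when slope factors are available and requested — per-metal
#' carcinogenic risk (ADI x CSF) and their sum the carcinogenic index
#' (CI), classified against the 1e-6 to 1e-4 acceptable band. Replicates
#' are averaged per station x season unless `by_replicate = TRUE`.
#'
#' @param data Sample tibble in [sample_schema()] layout.
#' @param standards Standards tibble; needs `rfd` for every metal, and
#'   `csf` for at least one metal if `with_csf = TRUE`. When `with_csf =
#'   TRUE` and `standards` is left at its default, the documented
#'   [example_csf_table()] values are used; a supplied table without any
#'   slope factor errors.
#' @param profile An [exposure_profile()].
#' @param with_csf Compute the carcinogenic chain (off by default: slope
#'   factors are an explicit modelling choice).
#' @param by_replicate Keep replicates as separate rows.
#' @return A tibble with one row per sample: `adi_*`, `hq_*`, `hi`,
#'   `exceeds_unity`, and with `with_csf` also `cr_*`, `ci`, `ci_class`
#'   and a `no_csf` note listing metals lacking a slope factor.
#' @examples
#' health_risk(station_fixture(variants = "as_printed"))
#' @export
health_risk <- function(data, standards = default_standards(),
                        profile = exposure_profile(), with_csf = FALSE,
                        by_replicate = FALSE) {
  assert_sample_frame(data)
  rfd <- standards_lookup(standards, METALS, "rfd")
  if (any(is.na(rfd))) {
    abort(paste0("missing reference dose for: ",
                 paste(METALS[is.na(rfd)], collapse = ", ")))
  }
  recs <- collapse_replicates(data, by_replicate)
  out <- recs[intersect(names(recs),
                        c("sample_id", "river", "season", "replicate",
                          "variant"))]
  adi <- vapply(METALS, function(m) {
    average_daily_intake(recs[[paste0(m, "_mg_l")]], profile)
  }, numeric(nrow(recs)))
  adi <- matrix(adi, nrow = nrow(recs))
  hq <- sweep(adi, 2, rfd, "/")
  colnames(adi) <- paste0("adi_", METALS)
  colnames(hq) <- paste0("hq_", METALS)
  out <- dplyr::bind_cols(out, as_tibble(adi), as_tibble(hq))
  out$hi <- rowSums(hq)
  out$exceeds_unity <- out$hi > 1
  if (with_csf) {
    # the explicit flag is the opt-in: with the default standards it loads
    # the documented example slope factors; a user-supplied table must
    # carry its own
    if (missing(standards)) standards <- example_csf_table()
    csf <- standards_lookup(standards, METALS, "csf")
    if (all(is.na(csf))) abort("no metal has a cancer slope factor.")
    cr <- vapply(seq_along(METALS), function(j) {
      carcinogenic_risk(adi[, j], csf[[j]])
    }, numeric(nrow(recs)))
    cr <- matrix(cr, nrow = nrow(recs),
                 dimnames = list(NULL, paste0("cr_", METALS)))
    out <- dplyr::bind_cols(out, as_tibble(cr))
    out$ci <- rowSums(cr[, !is.na(csf), drop = FALSE])
    out$ci_class <- classify_cancer_risk(out$ci)
    out$no_csf <- paste(METALS[is.na(csf)], collapse = ",")
  }
  out$censored <- recs$.censored
  out
}

#' Export a risk table as tidy CSV
#' @param result Output of [health_risk()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(result, path) {
  readr::write_csv(result, path)
  invisible(path)
}

#' Hazard-quotient decomposition per sample
#'
#' @param result Output of [health_risk()].
#' @param ... Unused.
#' @return A ggplot object: stacked per-metal hazard quotients with the
#'   HI = 1 threshold line.
#' @export
plot_hazard_index <- function(result, ...) {
  long <- result %>%
    select(all_of(c("sample_id", "season")), dplyr::starts_with("hq_")) %>%
    tidyr::pivot_longer(dplyr::starts_with("hq_"),
                        names_to = "metal", values_to = "hq",
                        names_prefix = "hq_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$hq,
                                     fill = .data$metal)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~season) +
    ggplot2::labs(x = "station", y = "hazard quotient",
                  title = "Hazard index decomposition (dashed: HI = 1)")
}
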