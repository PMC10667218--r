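#' Water-quality standards table
#'
#' Builds the per-metal constants that parameterize the pollution index and
#' the health-risk chain: the drinking-water permissible limit (mg/L), the
#' oral reference dose RfD (mg/kg/day) and, optionally, a cancer slope
#' factor CSF ((mg/kg/day)^-1). Any metal may omit the CSF; carcinogenic
#' risk is then not computed for it.
#'
#' @param permissible_limit Named numeric vector of limits in mg/L; names are
#'   metal codes (`cd`, `cu`, `fe`, `pb`, `zn`).
#' @param rfd Named numeric vector of oral reference doses in mg/kg/day.
#' @param csf Named numeric vector of cancer slope factors; metals without a
#'   slope factor are simply absent (or `NA`).
#' @return A tibble with columns `metal`, `permissible_limit`, `rfd`, `csf`.
#' @seealso [default_standards()], [read_standards_yaml()]
#' @export
standards_table <- function(permissible_limit, rfd = NULL, csf = NULL) {
  metals <- names(permissible_limit)
  if (is.null(metals) || any(!nzchar(metals))) {
    abort("`permissible_limit` must be a named vector of metal limits.")
  }
  if (any(!is.finite(permissible_limit)) || any(permissible_limit <= 0)) {
    abort("permissible limits must be strictly positive and finite.")
  }
  out <- tibble(
    metal = tolower(metals),
    permissible_limit = unname(permissible_limit),
    rfd = NA_real_,
    csf = NA_real_
  )
  if (!is.null(rfd)) {
    if (any(stats::na.omit(rfd) <= 0)) abort("reference doses must be > 0.")
    out$rfd <- unname(rfd[out$metal])
  }
  if (!is.null(csf)) {
    if (any(stats::na.omit(csf) < 0)) abort("cancer slope factors must be >= 0.")
    out$csf <- unname(csf[out$metal])
  }
  out
}

#' Default standards: WHO drinking-water limits and standard oral RfDs
#'
#' Limits (mg/L): Cd 0.003, Cu 2, Fe 0.3, Pb 0.01, Zn 3 — the WHO
#' guideline values, with cadmium at the 0.003 mg/L acceptable limit used
#' for river screening. Oral reference doses (mg/kg/day): Cd 5e-4, Cu 0.04,
#' Fe 0.7, Pb 3.5e-3, Zn 0.3. No cancer slope factors are set by default;
#' see [example_csf_table()].
#'
#' @return A standards tibble (see [standards_table()]).
#' @export
default_standards <- function() {
  standards_table(
    permissible_limit = c(cd = 0.003, cu = 2, fe = 0.3, pb = 0.01, zn = 3),
    rfd = c(cd = 0.0005, cu = 0.04, fe = 0.7, pb = 0.0035, zn = 0.3)
  )
}

#' Example cancer slope factors (explicit opt-in)
#'
#' Oral slope factors are not defaulted silently because published values
#' vary by agency and route; this example table (Cd 6.1, Pb 0.0085
#' (mg/kg/day)^-1, others absent) is provided for demonstration and must be
#' requested explicitly (e.g. `health_risk(..., with_csf = TRUE)`).
#'
#' @return A standards tibble with the `csf` column populated for Cd and Pb.
#' @export
example_csf_table <- function() {
  std <- default_standards()
  std$csf[std$metal == "cd"] <- 6.1
  std$csf[std$metal == "pb"] <- 0.0085
  std
}

#' Read / write a standards table as YAML
#'
#' The YAML layout is one mapping per metal with keys `permissible_limit`,
#' `rfd` and (optionally) `csf`, e.g. `cd: {permissible_limit: 0.003,
#' rfd: 0.0005}`.
#'
#' @param path File path.
#' @return `read_standards_yaml()` returns a standards tibble;
#'   `write_standards_yaml()` returns `path` invisibly.
#' @export
read_standards_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lim <- vapply(raw, function(x) as.numeric(x$permissible_limit), numeric(1))
  rfd <- vapply(raw, function(x) {
    if (is.null(x$rfd)) NA_real_ else as.numeric(x$rfd)
  }, numeric(1))
  csf <- vapply(raw, function(x) {
    if (is.null(x$csf)) NA_real_ else as.numeric(x$csf)
  }, numeric(1))
  standards_table(lim, rfd = rfd, csf = csf)
}

#' @rdname read_standards_yaml
#' @param standards A standards tibble.
#' @export
write_standards_yaml <- function(standards, path) {
  lst <- lapply(seq_len(nrow(standards)), function(i) {
    row <- standards[i, ]
    out <- list(permissible_limit = row$permissible_limit)
    if (!is.na(row$rfd)) out$rfd <- row$rfd
    if (!is.na(row$csf)) out$csf <- row$csf
    out
  })
  names(lst) <- standards$metal
  yaml::write_yaml(lst, path)
  invisible(path)
}

standards_lookup <- function(standards, metals, column) {
  idx <- match(metals, standards$metal)
  if (anyNA(idx)) {
    abort(paste0("no standards entry for metal(s): ",
                 paste(metals[is.na(idx)], collapse = ", ")))
  }
  setNames(standards[[column]][idx], metals)
}

#' Ingestion exposure profile
#'
#' The deterministic drinking-water exposure scenario: body weight (kg),
#' water intake rate (L/day), exposure frequency (days/year), exposure
#' duration (years) and averaging time (days). By default the averaging
#' time equals exposure duration x exposure frequency, under which the
#' average daily intake reduces to C x IR / BW.
#'
#' Presets: `"default"` (70 kg, 2 L/day, 365 d/yr, 70 yr), `"ed_30yr"`,
#' `"ed_65yr"` (shorter residence durations) and `"ir_1.5L"` (lower intake
#' rate), all otherwise identical to the default scenario.
#'
#' @param body_weight kg.
#' @param intake_rate L/day.
#' @param exposure_frequency days/year.
#' @param exposure_duration years.
#' @param averaging_time days; defaults to `exposure_duration *
#'   exposure_frequency`.
#' @param preset Optional preset name overriding the individual arguments.
#' @return A list of class `exposure_profile`.
#' @export
exposure_profile <- function(body_weight = 70, intake_rate = 2,
                             exposure_frequency = 365,
                             exposure_duration = 70,
                             averaging_time = NULL,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "ed_30yr", "ed_65yr", "ir_1.5L"))
    if (preset == "ed_30yr") exposure_duration <- 30
    if (preset == "ed_65yr") exposure_duration <- 65
    if (preset == "ir_1.5L") intake_rate <- 1.5
  }
  if (is.null(averaging_time)) {
    averaging_time <- exposure_duration * exposure_frequency
  }
  vals <- c(body_weight, intake_rate, exposure_frequency,
            exposure_duration, averaging_time)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all exposure-profile fields must be strictly positive.")
  }
  structure(
    list(body_weight = body_weight, intake_rate = intake_rate,
         exposure_frequency = exposure_frequency,
         exposure_duration = exposure_duration,
         averaging_time = averaging_time),
    class = "exposure_profile"
  )
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("Exposure profile: BW", x$body_weight, "kg, IR", x$intake_rate,
      "L/day, EF", x$exposure_frequency, "d/yr, ED", x$exposure_duration,
      "yr, AT", x$averaging_time, "days\n")
  invisible(x)
}

#' Read / write an exposure profile as YAML
#' @param path File path.
#' @return The profile, or `path` invisibly for the writer.
#' @export
read_exposure_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  exposure_profile(
    body_weight = raw$body_weight, intake_rate = raw$intake_rate,
    exposure_frequency = raw$exposure_frequency,
    exposure_duration = raw$exposure_duration,
    averaging_time = raw$averaging_time
  )
}

#' @rdname read_exposure_yaml
#' @param profile An `exposure_profile`.
#' @export
write_exposure_yaml <- function(profile, path) {
  yaml::write_yaml(unclass(profile), path)
  invisible(path)
}
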