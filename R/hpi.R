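#' Relative weight of a metal
#'
#' The reciprocal of the permissible limit, `Rw = 1 / limit` (L/mg): metals
#' with stricter limits weigh more in the pollution index.
#'
#' @param limit Permissible limit(s), mg/L, strictly positive.
#' @return Numeric vector of relative weights.
#' @export
relative_weight <- function(limit) {
  if (any(!is.finite(limit)) || any(limit <= 0)) {
    abort("permissible limits must be strictly positive.")
  }
  1 / limit
}

#' Normalized parameter weights
#'
#' `Wp_m = Rw_m / sum(Rw)`, so the weights sum to one over the metal set of
#' the standards table.
#'
#' @param standards A standards tibble, or a named numeric vector of
#'   permissible limits.
#' @return Named numeric vector of weights summing to 1.
#' @export
parameter_weights <- function(standards) {
  limits <- if (is.data.frame(standards)) {
    setNames(standards$permissible_limit, standards$metal)
  } else {
    standards
  }
  if (!length(limits)) abort("the standards table is empty.")
  rw <- relative_weight(limits)
  rw / sum(rw)
}

#' Contamination status
#'
#' The measured concentration expressed as a fraction of the permissible
#' limit, `Sc = conc / limit`.
#'
#' @param conc Measured concentration(s), mg/L, non-negative.
#' @param limit Permissible limit(s), mg/L, strictly positive.
#' @return Numeric vector of dimensionless ratios.
#' @export
contamination_status <- function(conc, limit) {
  if (any(!is.finite(limit)) || any(limit <= 0)) {
    abort("permissible limits must be strictly positive.")
  }
  if (any(conc < 0, na.rm = TRUE)) abort("concentrations must be >= 0.")
  conc / limit
}

#' Five-band pollution classification
#'
#' Maps an index value to the drinking-water pollution band: 0-0.25
#' negligible (excellent water), 0.25-0.5 very low (good), 0.5-0.75 low
#' (poor), 0.75-1 moderate (very poor), above 1 high pollution (not fit
#' for drinking). A value sitting exactly on a band edge is assigned to
#' the lower band, so 0.25 itself classifies as negligible.
#'
#' @param value Non-negative index value(s).
#' @return Ordered factor with levels [hpi_band_levels()].
#' @export
classify_hpi <- function(value) {
  if (any(value < 0, na.rm = TRUE)) abort("index values must be >= 0.")
  cut(value, breaks = c(-Inf, 0.25, 0.5, 0.75, 1, Inf),
      labels = hpi_band_levels(), ordered_result = TRUE)
}

#' @rdname classify_hpi
#' @export
hpi_band_levels <- function() {
  c("negligible/excellent", "very_low/good", "low/poor",
    "moderate/very_poor", "high/unfit")
}

#' Band edges of the pollution classification
#'
#' @return A tibble with `lower`, `upper`, `label`; lower edge closed,
#'   upper edge open (last band unbounded).
#' @export
hpi_bands <- function() {
  tibble(lower = c(0, 0.25, 0.5, 0.75, 1),
         upper = c(0.25, 0.5, 0.75, 1, Inf),
         label = hpi_band_levels())
}

#' Heavy-metal pollution index
#'
#' Computes, per sample, the weighted pollution index: each metal
#' contributes a sub-index `Wp_m * Sc_m` (normalized limit-reciprocal
#' weight times concentration-to-limit ratio) and the total is the sum of
#' sub-indices over the five metals. A sample whose concentrations all
#' equal their limits scores exactly 1.
#'
#' Replicates are averaged per station x season before indexing unless
#' `by_replicate = TRUE`. Metals named in `exclude` have their sub-index
#' dropped from the total without renormalizing the weights — this is the
#' "what if this metal were absent" reading, under which removing the
#' dominant metal can move a sample from the unfit band into the excellent
#' band; renormalizing would instead redistribute its weight.
#'
#' Censored concentrations enter at their stored substitution value; rows
#' using any flagged value are marked in the `censored` column and a
#' warning is raised. Rows with missing concentrations yield `NA`.
#'
#' @param data Sample tibble in [sample_schema()] layout.
#' @param standards Standards tibble; defaults to [default_standards()].
#' @param exclude Character vector of metal codes whose sub-index is
#'   dropped (no reweighting).
#' @param by_replicate Keep replicates as separate rows instead of
#'   averaging per station x season.
#' @return A tibble with one row per sample: identifying columns,
#'   per-metal sub-indices `hpi_cd` ... `hpi_zn`, `hpi_total`, `band`, and
#'   `censored`.
#' @examples
#' hpi(station_fixture(variants = "as_printed"))
#' @export
hpi <- function(data, standards = default_standards(), exclude = NULL,
                by_replicate = FALSE) {
  assert_sample_frame(data)
  exclude <- tolower(exclude)
  bad <- setdiff(exclude, METALS)
  if (length(bad)) {
    abort(paste0("unknown metal(s) in `exclude`: ", paste(bad, collapse = ", ")))
  }
  limits <- standards_lookup(standards, METALS, "permissible_limit")
  wp <- parameter_weights(setNames(limits, METALS))
  recs <- collapse_replicates(data, by_replicate)
  sub <- vapply(METALS, function(m) {
    sc <- contamination_status(recs[[paste0(m, "_mg_l")]], limits[[m]])
    unname(wp[[m]]) * sc
  }, numeric(nrow(recs)))
  sub <- matrix(sub, nrow = nrow(recs),
                dimnames = list(NULL, paste0("hpi_", METALS)))
  keep <- setdiff(METALS, exclude)
  total <- rowSums(sub[, paste0("hpi_", keep), drop = FALSE])
  out <- dplyr::bind_cols(recs[intersect(names(recs),
                                         c("sample_id", "river", "season",
                                           "lon", "lat", "replicate",
                                           "variant"))],
                          as_tibble(sub))
  out$hpi_total <- total
  out$band <- classify_hpi(total)
  out$censored <- recs$.censored
  if (any(out$censored, na.rm = TRUE)) {
    warn("some samples use detection-limit substitution values; their index is approximate.")
  }
  out
}

# mean concentrations per station x season (the default analysis unit);
# a cell counts as censored if any replicate used a substituted value
collapse_replicates <- function(data, by_replicate) {
  flags <- intersect(bdl_cols(), names(data))
  cens <- if (length(flags)) {
    rowSums(as.matrix(data[flags]), na.rm = TRUE) > 0
  } else {
    rep(FALSE, nrow(data))
  }
  data$.censored <- cens
  if (by_replicate || !all(c("sample_id", "season") %in% names(data))) {
    return(data)
  }
  keys <- intersect(c("sample_id", "river", "season", "variant"), names(data))
  data %>%
    group_by(across(all_of(keys))) %>%
    summarise(across(all_of(c("lon", "lat")[c("lon", "lat") %in% names(data)]),
                     mean),
              across(all_of(conc_cols()), ~ mean(.x)),
              .censored = any(.data$.censored),
              .groups = "drop")
}

#' Export a pollution-index table as tidy CSV
#' @param result Output of [hpi()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hpi_csv <- function(result, path) {
  readr::write_csv(result, path)
  invisible(path)
}

#' Pollution-index band shares as a bar chart
#'
#' @param result Output of [hpi()].
#' @param ... Unused.
#' @return A ggplot object: samples per band, filled by season if present.
#' @export
plot_hpi_bands <- function(result, ...) {
  p <- ggplot2::ggplot(result, ggplot2::aes(x = .data$band)) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "pollution band", y = "samples",
                  title = "Heavy-metal pollution index classification")
  if ("season" %in% names(result)) {
    p + ggplot2::geom_bar(ggplot2::aes(fill = .data$season),
                          position = "dodge")
  } else {
    p + ggplot2::geom_bar()
  }
}
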