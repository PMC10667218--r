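#' Station-level concentration fixture from a Moroccan two-season survey
#'
#' A small built-in table of station-level heavy-metal concentrations
#' (mg/L) from a winter/spring monitoring campaign on three rivers
#' (Nfifikh, Hassar, El Maleh) and the coastal lagoon Douar El Marja near
#' Mohammedia, Morocco. It is the worked-example input for the pollution
#' index and health-risk chains and the reference set for their checks.
#'
#' The survey report states some values ambiguously; the fixture keeps
#' every stated reading rather than guessing intent:
#' * Where a range is given across a station pair (e.g. Cd 0.006-0.009
#'   mg/L across the two downstream El Maleh stations), one station
#'   carries the low end and the other the high end.
#' * One winter sentence for the border river pairs metals and values in
#'   an order that contradicts the campaign-wide ranges (it would put Cu
#'   at 0.34 mg/L while Fe, not Cu, reaches 0.34 elsewhere). Both readings
#'   are kept: `variant = "as_printed"` (Cu 0.34, Fe 0.009) and
#'   `variant = "range_consistent"` (Fe 0.34, Cu 0.009). Downstream
#'   summaries should pick one variant or treat them as alternatives.
#' * The station labels "S4"/"S5" are used by the source for stations on
#'   both El Maleh and Hassar; labels are kept as stated and rows are
#'   disambiguated by the `river` column.
#' * Spring samples at the border-river stations and at the confluence
#'   station were below detection for all metals; they are kept as `NA`
#'   concentrations with all `bdl_*` flags set, for use with
#'   [apply_censoring()].
#'
#' Station coordinates were not published; the `lon`/`lat` columns are
#' synthetic placeholders in the study region, adequate for interpolation
#' demos only.
#'
#' @param variants Which readings of the ambiguous winter sentence to
#'   include; default both.
#' @return A tibble in [sample_schema()] layout (replicate = 1 throughout)
#'   plus `variant` and `note` columns.
#' @export
station_fixture <- function(variants = c("as_printed", "range_consistent")) {
  variants <- match.arg(variants, several.ok = TRUE)
  row <- function(id, river, season, lon, lat, cd, cu, fe, pb, zn,
                  variant = "as_printed", note = "") {
    tibble(sample_id = id, river = river, season = season,
           lon = lon, lat = lat, replicate = 1L,
           cd_mg_l = cd, cu_mg_l = cu, fe_mg_l = fe,
           pb_mg_l = pb, zn_mg_l = zn,
           bdl_cd = is.na(cd), bdl_cu = is.na(cu), bdl_fe = is.na(fe),
           bdl_pb = is.na(pb), bdl_zn = is.na(zn),
           variant = variant, note = note)
  }
  fx <- bind_rows(
    # El Maleh downstream pair: ranges split low/high across the stations
    row("S8", "El Maleh", "winter", -7.310, 33.640,
        0.006, 0.006, 0.006, 0.008, 0.009,
        note = "downstream station, low end of the stated winter ranges"),
    row("S9", "El Maleh", "winter", -7.300, 33.650,
        0.009, 0.007, 0.009, 0.009, 0.009,
        note = "downstream station, high end of the stated winter ranges"),
    # El Maleh urban pair after the city crossing (Zn range split)
    row("S4", "El Maleh", "winter", -7.285, 33.685,
        0.010, 0.010, 0.009, 0.010, 0.009,
        note = "urban reach after the city crossing, Zn low end"),
    row("S5", "El Maleh", "winter", -7.280, 33.695,
        0.010, 0.010, 0.009, 0.010, 0.300,
        note = "urban reach after the city crossing, Zn high end"),
    # Hassar winter pair (labelled S4/S5 in the source as well)
    row("S4", "Hassar", "winter", -7.365, 33.600,
        0.007, 0.010, 0.007, 0.009, 0.009,
        note = "tributary station, low end of the stated Cd range"),
    row("S5", "Hassar", "winter", -7.360, 33.610,
        0.009, 0.009, 0.007, 0.009, 0.009,
        note = "tributary station, high end of the stated Cd range"),
    # Hassar spring: all metals at 0.009 mg/L
    row("S4", "Hassar", "spring", -7.365, 33.600,
        0.009, 0.009, 0.009, 0.009, 0.009,
        note = "spring reading, all five metals at 0.009 mg/L"),
    row("S5", "Hassar", "spring", -7.360, 33.610,
        0.009, 0.009, 0.009, 0.009, 0.009,
        note = "spring reading, all five metals at 0.009 mg/L"),
    # Confluence station: winter dilution, spring below detection
    row("S10", "Hassar", "winter", -7.330, 33.625,
        0.005, 0.005, 0.006, 0.006, 0.009,
        note = "confluence with the main river, winter dilution"),
    row("S10", "Hassar", "spring", -7.330, 33.625,
        NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
        note = "confluence, spring: all metals below detection"),
    # Border river (Nfifikh): upstream reference and in-prefecture station
    row("S1", "Nfifikh", "winter", -7.180, 33.700,
        0.009, 0.018, 0.007, 0.019, 0.018,
        note = "upstream reference outside the prefecture"),
    row("S2", "Nfifikh", "winter", -7.175, 33.720,
        0.008, 0.340, 0.009, 0.020, 0.060,
        variant = "as_printed",
        note = "in-prefecture winter reading, metal/value pairing as stated"),
    row("S2", "Nfifikh", "winter", -7.175, 33.720,
        0.008, 0.009, 0.340, 0.020, 0.060,
        variant = "range_consistent",
        note = "in-prefecture winter reading, Fe/Cu pairing consistent with campaign ranges"),
    row("S1", "Nfifikh", "spring", -7.180, 33.700,
        NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
        note = "spring: all metals below detection"),
    row("S2", "Nfifikh", "spring", -7.175, 33.720,
        NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
        note = "spring: all metals below detection"),
    # Coastal lagoon
    row("S3", "Douar El Marja lagoon", "winter", -7.255, 33.710,
        0.010, 0.010, 0.020, 0.220, 0.170,
        note = "coastal lagoon near the industrial zone, winter"),
    row("S3", "Douar El Marja lagoon", "spring", -7.255, 33.710,
        0.009, 0.010, 0.009, 0.009, 0.009,
        note = "coastal lagoon, spring")
  )
  # `variants` only selects among readings of the ambiguous winter sentence;
  # unambiguous rows are always returned
  ambiguous <- fx$sample_id == "S2" & fx$season == "winter"
  fx[!ambiguous | fx$variant %in% variants, ]
}
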