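#' Default seasonal inter-metal correlation targets
#'
#' Two 5x5 Pearson target matrices reflecting a common seasonal pattern in
#' riverine monitoring: moderate common-source correlation in winter
#' (Cd-Cu 0.727, Cd-Zn and Cu-Zn 0.607, others uncorrelated) and a
#' near-deterministic common source in spring (Cd/Fe/Zn pairwise 0.999,
#' Cd-Pb 0.998, Fe-Pb and Zn-Pb 0.997, Cu with every other metal 0.85).
#'
#' @return Named list of matrices, one per season.
#' @export
default_correlations <- function() {
  mk <- function() {
    m <- diag(5)
    dimnames(m) <- list(METALS, METALS)
    m
  }
  winter <- mk()
  winter["cd", "cu"] <- winter["cu", "cd"] <- 0.727
  winter["cd", "zn"] <- winter["zn", "cd"] <- 0.607
  winter["cu", "zn"] <- winter["zn", "cu"] <- 0.607
  spring <- mk()
  for (pair in list(c("cd", "fe"), c("cd", "zn"), c("fe", "zn"))) {
    spring[pair[1], pair[2]] <- spring[pair[2], pair[1]] <- 0.999
  }
  spring["cd", "pb"] <- spring["pb", "cd"] <- 0.998
  spring["fe", "pb"] <- spring["pb", "fe"] <- 0.997
  spring["zn", "pb"] <- spring["pb", "zn"] <- 0.997
  spring["cu", c("cd", "fe", "pb", "zn")] <- 0.85
  spring[c("cd", "fe", "pb", "zn"), "cu"] <- 0.85
  list(winter = winter, spring = spring)
}

#' Synthetic sampling-design configuration
#'
#' Describes a two-season river monitoring campaign: stations with
#' coordinates in a bounding box, river labels assigned by longitude band
#' (plus an optional lagoon station), replicate counts, per-metal marginal
#' concentration ranges (mg/L), per-season inter-metal Pearson correlation
#' targets, per-metal detection limits and stations forced below detection
#' in a given season.
#'
#' Defaults emulate a 10-station, 3-river + 1-lagoon, two-season design
#' with 3 replicates per station, marginal ranges Cd and Cu 0.005-0.01,
#' Fe 0.007-0.34, Pb 0.007-0.22, Zn 0.009-0.3 mg/L, the
#' [default_correlations()] targets, and spring censoring at the two most
#' upstream stations of the border river.
#'
#' @param n_stations Number of stations.
#' @param rivers Character vector of river labels; stations are assigned by
#'   longitude band in this order.
#' @param lagoon_station Station id (e.g. `"S3"`) relabelled as a coastal
#'   lagoon rather than a river, or `NULL`.
#' @param seasons Season labels.
#' @param replicates Replicates per station and season (>= 1).
#' @param ranges Named list `metal = c(low, high)` in mg/L, `0 < low < high`.
#' @param correlations Named list (by season) of 5x5 correlation matrices;
#'   symmetric, unit diagonal. Non-positive-semidefinite matrices are
#'   repaired by eigenvalue clipping (error if the repair moves the matrix
#'   by more than 0.1 in Frobenius norm).
#' @param detection_limits Named numeric vector, mg/L per metal.
#' @param censor_stations Named list `season = c(station ids)` forced below
#'   detection in that season.
#' @param censor_policy One of `"half_lod"`, `"zero"`, `"drop"`.
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param seed Integer seed for the root generator.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_stations = 10,
                             rivers = c("Nfifikh", "Hassar", "El Maleh"),
                             lagoon_station = "S3",
                             seasons = c("winter", "spring"),
                             replicates = 3,
                             ranges = list(cd = c(0.005, 0.01),
                                           cu = c(0.005, 0.01),
                                           fe = c(0.007, 0.34),
                                           pb = c(0.007, 0.22),
                                           zn = c(0.009, 0.3)),
                             correlations = default_correlations(),
                             detection_limits = c(cd = 0.004, cu = 0.004,
                                                  fe = 0.006, pb = 0.006,
                                                  zn = 0.008),
                             censor_stations = list(spring = c("S1", "S2")),
                             censor_policy = "half_lod",
                             bbox = c(-7.45, -7.15, 33.55, 33.75),
                             seed = 1L) {
  if (n_stations < 1) abort("`n_stations` must be >= 1.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (!length(seasons)) abort("at least one season is required.")
  if (!length(rivers)) abort("at least one river label is required.")
  for (m in METALS) {
    r <- ranges[[m]]
    if (is.null(r) || length(r) != 2 || r[1] <= 0 || r[1] >= r[2]) {
      abort(paste0("range for ", m, " must satisfy 0 < low < high."))
    }
  }
  correlations <- lapply(correlations, validate_correlation)
  missing_seasons <- setdiff(seasons, names(correlations))
  if (length(missing_seasons)) {
    # seasons without a stated target get independence
    for (s in missing_seasons) {
      correlations[[s]] <- diag(5)
      dimnames(correlations[[s]]) <- list(METALS, METALS)
    }
  }
  structure(
    list(n_stations = as.integer(n_stations), rivers = rivers,
         lagoon_station = lagoon_station, seasons = seasons,
         replicates = as.integer(replicates), ranges = ranges,
         correlations = correlations, detection_limits = detection_limits,
         censor_stations = censor_stations, censor_policy = censor_policy,
         bbox = bbox, seed = as.integer(seed)),
    class = "generator_config"
  )
}

validate_correlation <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != 5 || ncol(m) != 5) abort("correlation matrices must be 5x5.")
  if (is.null(dimnames(m))) dimnames(m) <- list(METALS, METALS)
  m <- m[METALS, METALS]
  if (max(abs(m - t(m))) > 1e-8) abort("correlation matrix must be symmetric.")
  if (max(abs(diag(m) - 1)) > 1e-8) {
    abort("correlation matrix must have a unit diagonal.")
  }
  if (any(abs(m) > 1 + 1e-8)) abort("correlations must lie in [-1, 1].")
  m
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Clips negative eigenvalues to 1e-10, reconstructs, and rescales to a
#' unit diagonal. Errors if the repaired matrix differs from the input by
#' more than `tol` in Frobenius norm — such an input is treated as a user
#' mistake rather than numerical noise.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param tol Maximum admissible Frobenius-norm change (default 0.1).
#' @return A positive-semidefinite correlation matrix.
#' @export
nearest_psd <- function(m, tol = 0.1) {
  eig <- eigen(m, symmetric = TRUE)
  if (min(eig$values) >= 0) return(m)
  vals <- pmax(eig$values, 1e-10)
  out <- eig$vectors %*% diag(vals) %*% t(eig$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  if (sqrt(sum((out - m)^2)) > tol) {
    abort("correlation matrix is too far from positive semidefinite to repair.")
  }
  dimnames(out) <- dimnames(m)
  out
}

# Latent Gaussian correlation that yields Pearson r between the
# uniform-transformed marginals: rho = 2 sin(pi r / 6).
latent_correlation <- function(r) {
  rho <- 2 * sin(pi * r / 6)
  diag(rho) <- 1
  rho
}

#' Generate synthetic water-sample records
#'
#' Draws station coordinates uniformly in the configured bounding box
#' (rivers assigned by longitude band), then per season draws correlated
#' metal concentrations through a Gaussian copula: a latent multivariate
#' normal with the season's (PSD-repaired, latent-adjusted) correlation
#' matrix is mapped through the normal CDF onto the configured uniform
#' concentration ranges, so empirical Pearson correlations between metals
#' match the targets while every marginal stays inside its range.
#' Censoring (configured stations plus anything naturally below a
#' detection limit) is then applied via [apply_censoring()].
#'
#' Each season consumes an independent sub-stream derived from the root
#' seed, so seasons are individually reproducible.
#'
#' @param config A [generator_config()].
#' @return A tibble in the canonical [sample_schema()] layout with
#'   `n_stations * length(seasons) * replicates` rows (fewer under the
#'   `"drop"` censoring policy).
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ns <- config$n_stations
  stations <- local({
    set.seed(config$seed)
    tibble(
      sample_id = paste0("S", seq_len(ns)),
      lon = runif(ns, config$bbox[1], config$bbox[2]),
      lat = runif(ns, config$bbox[3], config$bbox[4])
    )
  })
  breaks <- seq(config$bbox[1], config$bbox[2],
                length.out = length(config$rivers) + 1)
  band <- findInterval(stations$lon, breaks, rightmost.closed = TRUE)
  band <- pmin(pmax(band, 1L), length(config$rivers))
  stations$river <- config$rivers[band]
  if (!is.null(config$lagoon_station)) {
    hit <- stations$sample_id %in% config$lagoon_station
    stations$river[hit] <- "Douar El Marja lagoon"
  }

  per_season <- purrr::imap(
    setNames(config$seasons, config$seasons),
    function(season, idx) {
      i <- match(season, config$seasons)
      set.seed(config$seed + 1000L * i)
      n <- ns * config$replicates
      target <- nearest_psd(config$correlations[[season]])
      latent <- nearest_psd(latent_correlation(target))
      # exact second-moment matching: the latent sample correlation equals
      # the target exactly (up to the copula transform), so recovery does
      # not degrade with moderate sample sizes; plain Cholesky colouring
      # is used when n is too small to standardize empirically
      z <- if (n > 10) {
        MASS::mvrnorm(n, mu = rep(0, 5), Sigma = latent, empirical = TRUE)
      } else {
        matrix(rnorm(n * 5), n, 5) %*% chol(latent)
      }
      u <- pnorm(z)
      conc <- vapply(seq_along(METALS), function(j) {
        r <- config$ranges[[METALS[j]]]
        r[1] + u[, j] * (r[2] - r[1])
      }, numeric(n))
      colnames(conc) <- conc_cols()
      out <- tibble(
        sample_id = rep(stations$sample_id, each = config$replicates),
        river = rep(stations$river, each = config$replicates),
        season = season,
        lon = rep(stations$lon, each = config$replicates),
        lat = rep(stations$lat, each = config$replicates),
        replicate = rep(seq_len(config$replicates), times = ns)
      )
      dplyr::bind_cols(out, as_tibble(conc))
    }
  )
  records <- bind_rows(per_season)
  for (m in METALS) records[[paste0("bdl_", m)]] <- FALSE

  forced <- config$censor_stations
  if (length(forced)) {
    for (season in names(forced)) {
      hit <- records$season == season & records$sample_id %in% forced[[season]]
      # force the whole station/season cell below detection
      for (m in METALS) {
        col <- paste0(m, "_mg_l")
        lod <- config$detection_limits[[m]]
        records[[col]][hit] <- pmin(records[[col]][hit], lod * 0.99)
      }
    }
  }
  apply_censoring(records, config$detection_limits, config$censor_policy)
}

#' Apply detection-limit censoring to sample records
#'
#' Every concentration strictly below its metal's detection limit is
#' flagged and handled per the policy: `"half_lod"` stores LOD/2 (the
#' common environmental-statistics substitution), `"zero"` stores 0, and
#' `"drop"` removes any record with at least one censored metal.
#'
#' @param records Sample tibble in [sample_schema()] layout.
#' @param detection_limits Named numeric vector (mg/L per metal).
#' @param policy `"half_lod"` (default), `"zero"` or `"drop"`.
#' @return The records tibble with flags set and substitutions applied.
#' @export
apply_censoring <- function(records, detection_limits,
                            policy = c("half_lod", "zero", "drop")) {
  assert_sample_frame(records)
  policy <- match.arg(policy)
  hit_any <- rep(FALSE, nrow(records))
  for (m in METALS) {
    lod <- detection_limits[[m]]
    if (is.null(lod) || is.na(lod)) next
    col <- paste0(m, "_mg_l")
    flag <- paste0("bdl_", m)
    hit <- !is.na(records[[col]]) & records[[col]] < lod
    if (!flag %in% names(records)) records[[flag]] <- FALSE
    records[[flag]] <- records[[flag]] | hit
    if (policy == "half_lod") records[[col]][hit] <- lod / 2
    if (policy == "zero") records[[col]][hit] <- 0
    hit_any <- hit_any | hit
  }
  if (policy == "drop") records <- records[!hit_any, , drop = FALSE]
  records
}

#' Read / write the canonical sample CSV
#'
#' @param path File path.
#' @return A sample tibble; the writer returns `path` invisibly.
#' @export
read_samples <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           river = readr::col_character(),
                           season = readr::col_character()
                         ))
  assert_sample_frame(out)
  out
}

#' @rdname read_samples
#' @param records Sample tibble.
#' @export
write_samples <- function(records, path) {
  assert_sample_frame(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' Serialize a generator configuration as YAML
#' @param config A [generator_config()]; `path` a file path.
#' @return The config, or `path` invisibly for the writer.
#' @export
read_generator_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$correlations <- lapply(raw$correlations, function(m) {
    matrix(unlist(m), 5, 5, dimnames = list(METALS, METALS))
  })
  raw$detection_limits <- unlist(raw$detection_limits)
  do.call(generator_config, raw)
}

#' @rdname read_generator_yaml
#' @param config A `generator_config`.
#' @param path File path.
#' @export
write_generator_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$correlations <- lapply(lst$correlations, function(m) {
    apply(unname(m), 1, as.numeric, simplify = FALSE)
  })
  lst$detection_limits <- as.list(lst$detection_limits)
  yaml::write_yaml(lst, path)
  invisible(path)
}
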