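#' Seasonal inter-metal Pearson correlation report
#'
#' Computes, on station-level mean concentrations, the 5x5 Pearson
#' correlation matrix between metals and the two-sided p-value of each
#' pair (the t-transform of r, as given by [stats::cor.test()]). No
#' multiple-testing correction is applied; the p-values are per-pair.
#' A metal with zero variance has undefined correlations; its pairs are
#' reported as `NA` with a warning.
#'
#' @param data Sample tibble in [sample_schema()] layout.
#' @param season Optional season label to subset to; default uses all rows.
#' @return An object of class `correlation_report`: list with `season`,
#'   `n` (stations used), `r` and `p` matrices. Use [tidy()] for a long
#'   tibble and [autoplot()] for a heatmap.
#' @export
correlation_matrix <- function(data, season = NULL) {
  assert_sample_frame(data)
  if (!is.null(season)) data <- data[data$season == season, , drop = FALSE]
  means <- collapse_replicates(data, by_replicate = FALSE)
  means <- means[stats::complete.cases(means[conc_cols()]), , drop = FALSE]
  if (nrow(means) < 3) {
    abort("need at least 3 stations with complete values.")
  }
  x <- as.matrix(means[conc_cols()])
  colnames(x) <- METALS
  degenerate <- apply(x, 2, sd) == 0
  if (any(degenerate)) {
    warn(paste0("zero-variance metal(s): ",
                paste(METALS[degenerate], collapse = ", "),
                "; their correlations are undefined."))
  }
  r <- suppressWarnings(cor(x))
  p <- matrix(NA_real_, 5, 5, dimnames = dimnames(r))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      if (!degenerate[i] && !degenerate[j]) {
        pv <- cor.test(x[, i], x[, j])$p.value
        p[i, j] <- p[j, i] <- pv
      }
    }
  }
  diag(p) <- 0
  structure(
    list(season = if (is.null(season)) "all" else season,
         n = nrow(means), r = r, p = p),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Pearson correlations (", x$season, ", n = ", x$n, " stations)\n",
      sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' @export
tidy.correlation_report <- function(x, ...) {
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    season = x$season,
    metal_1 = METALS[pairs[, 1]],
    metal_2 = METALS[pairs[, 2]],
    r = x$r[pairs],
    p_value = x$p[pairs]
  )
}

#' @export
autoplot.correlation_report <- function(object, ...) {
  d <- tibble(
    metal_1 = factor(rep(METALS, times = 5), levels = METALS),
    metal_2 = factor(rep(METALS, each = 5), levels = rev(METALS)),
    r = as.numeric(object$r)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metal_1, y = .data$metal_2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Inter-metal Pearson correlation -",
                                object$season),
                  x = NULL, y = NULL)
}

#' Export correlation reports as tidy CSV
#' @param reports A `correlation_report` or list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(reports, path) {
  if (inherits(reports, "correlation_report")) reports <- list(reports)
  readr::write_csv(purrr::map_dfr(reports, tidy), path)
  invisible(path)
}
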