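# Independent brute-force oracles, kept deliberately free of package code.

METALS5 <- c("cd", "cu", "fe", "pb", "zn")
WHO_LIMITS <- c(cd = 0.003, cu = 2, fe = 0.3, pb = 0.01, zn = 3)
RFD5 <- c(cd = 0.0005, cu = 0.04, fe = 0.7, pb = 0.0035, zn = 0.3)

# weighted pollution index from first principles
oracle_hpi <- function(conc, limits, exclude = character()) {
  rw <- 1 / limits
  wp <- rw / sum(rw)
  keep <- setdiff(names(limits), exclude)
  sum((wp * conc / limits)[keep])
}

# exposure chain from first principles
oracle_adi <- function(conc, bw = 70, ir = 2, ef = 365, ed = 70,
                       at = ed * ef) {
  conc * ir * ef * ed / (bw * at)
}

oracle_hi <- function(conc, rfd = RFD5) {
  sum(oracle_adi(conc) / rfd)
}

# one-row sample tibble from a named concentration vector
sample_row <- function(conc, sample_id = "X1", river = "R", season = "s",
                       lon = 0, lat = 0) {
  out <- tibble::tibble(sample_id = sample_id, river = river,
                        season = season, lon = lon, lat = lat,
                        replicate = 1L)
  for (m in METALS5) {
    out[[paste0(m, "_mg_l")]] <- unname(conc[[m]])
    out[[paste0("bdl_", m)]] <- FALSE
  }
  out
}

conc_matrix <- function(data) {
  as.matrix(data[, paste0(METALS5, "_mg_l")])
}
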