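test_that("record counts follow the sampling design and the drop policy", {
  cfg <- generator_config(seed = 11)
  g <- generate_samples(cfg)
  expect_equal(nrow(g), 10 * 2 * 3)
  expect_setequal(names(g), sample_schema())

  # forced spring censoring flags the configured stations
  sprung <- g[g$season == "spring" & g$sample_id %in% c("S1", "S2"), ]
  expect_true(all(as.matrix(sprung[paste0("bdl_", METALS5)])))

  dropped <- generate_samples(generator_config(seed = 11,
                                               censor_policy = "drop"))
  expect_equal(nrow(dropped),
               60 - sum(rowSums(as.matrix(g[paste0("bdl_", METALS5)])) > 0))
})

test_that("generation is deterministic given the seed, per season", {
  cfg <- generator_config(seed = 42)
  expect_identical(generate_samples(cfg), generate_samples(cfg))
  g1 <- generate_samples(generator_config(seed = 42, seasons = "winter"))
  g2 <- generate_samples(generator_config(seed = 43, seasons = "winter"))
  expect_false(identical(g1$cd_mg_l, g2$cd_mg_l))
})

test_that("uncensored marginals respect the configured ranges", {
  cfg <- generator_config(seed = 3, censor_stations = list())
  g <- generate_samples(cfg)
  for (m in METALS5) {
    r <- cfg$ranges[[m]]
    ok <- !g[[paste0("bdl_", m)]]
    vals <- g[[paste0(m, "_mg_l")]][ok]
    expect_true(all(vals >= r[1] & vals <= r[2]), label = m)
  }
})

test_that("empirical correlations recover the seasonal targets at n = 1000", {
  cfg <- generator_config(n_stations = 1000, replicates = 1,
                          censor_stations = list(), seed = 7)
  g <- generate_samples(cfg)
  for (s in c("winter", "spring")) {
    emp <- cor(conc_matrix(g[g$season == s, ]))
    tgt <- default_correlations()[[s]]
    dev <- abs(emp - tgt)
    expect_lt(max(dev), 0.05)
    hi <- tgt >= 0.99 & upper.tri(tgt)
    if (any(hi)) expect_lt(max(dev[hi]), 0.01)
  }
  # the near-unity spring Cd-Pb pair specifically
  sp <- g[g$season == "spring", ]
  expect_equal(cor(sp$cd_mg_l, sp$pb_mg_l), 0.998, tolerance = 0.01)
})

test_that("censoring substitutes and flags per policy", {
  rec <- sample_row(c(cd = 0.001, cu = 0.010, fe = 0.1, pb = 0.1, zn = 0.1))
  lod <- c(cd = 0.004, cu = 0.004, fe = 0.001, pb = 0.001, zn = 0.001)
  half <- apply_censoring(rec, lod, "half_lod")
  expect_equal(half$cd_mg_l, 0.002)
  expect_true(half$bdl_cd)
  expect_equal(half$cu_mg_l, 0.010)   # at/above the limit: untouched
  expect_false(half$bdl_cu)
  zero <- apply_censoring(rec, lod, "zero")
  expect_equal(zero$cd_mg_l, 0)
  clean <- sample_row(c(cd = 0.005, cu = 0.01, fe = 0.1, pb = 0.1,
                        zn = 0.1), sample_id = "X2")
  many <- dplyr::bind_rows(rec, clean)
  expect_equal(nrow(apply_censoring(many, lod, "drop")), 1)
  expect_error(apply_censoring(rec, lod, "median"))
})

test_that("correlation matrices are validated and repaired", {
  bad <- diag(5)
  bad[1, 2] <- 0.9   # asymmetric
  expect_error(generator_config(correlations = list(winter = bad,
                                                    spring = diag(5))),
               "symmetric")
  # slightly non-PSD: repairable by eigenvalue clipping
  m <- matrix(0.999, 5, 5); diag(m) <- 1
  m[1, 2] <- m[2, 1] <- -0.5
  expect_error(nearest_psd(m), "too far")
  near <- diag(5)
  near[1, 2] <- near[2, 1] <- 0.999
  near[1, 3] <- near[3, 1] <- 0.999
  near[2, 3] <- near[3, 2] <- 0.996  # min eigenvalue barely below zero
  rep <- nearest_psd(near)
  expect_gte(min(eigen(rep)$values), 0)
  expect_equal(unname(diag(rep)), rep(1, 5))
})

test_that("generator configuration rejects degenerate designs", {
  expect_error(generator_config(seasons = character()), "season")
  expect_error(generator_config(replicates = 0), "replicates")
  expect_error(generator_config(ranges = list(cd = c(0.01, 0.005),
                                              cu = c(0.005, 0.01),
                                              fe = c(0.007, 0.34),
                                              pb = c(0.007, 0.22),
                                              zn = c(0.009, 0.3))),
               "cd")
})

test_that("sample CSV and generator YAML round-trip", {
  g <- generate_samples(generator_config(seed = 5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_samples(g, csv)
  expect_equal(as.data.frame(read_samples(csv)), as.data.frame(g))

  yml <- withr::local_tempfile(fileext = ".yaml")
  cfg <- generator_config(seed = 5)
  write_generator_yaml(cfg, yml)
  cfg2 <- read_generator_yaml(yml)
  expect_identical(generate_samples(cfg2), g)
})

test_that("the station fixture carries the recorded survey readings", {
  fx <- station_fixture()
  em <- fx[fx$river == "El Maleh" & fx$sample_id == "S4", ]
  expect_equal(unname(unlist(em[, paste0(METALS5, "_mg_l")])),
               c(0.01, 0.01, 0.009, 0.01, 0.009))
  hs <- fx[fx$river == "Hassar" & fx$season == "spring" &
             fx$sample_id == "S4", ]
  expect_equal(unname(unlist(hs[, paste0(METALS5, "_mg_l")])),
               rep(0.009, 5))
  lg <- fx[fx$river == "Douar El Marja lagoon" & fx$season == "winter", ]
  expect_equal(lg$pb_mg_l, 0.22)
  expect_equal(lg$zn_mg_l, 0.17)
  # both readings of the ambiguous border-river sentence are present
  s2 <- fx[fx$sample_id == "S2" & fx$season == "winter", ]
  expect_setequal(s2$variant, c("as_printed", "range_consistent"))
  expect_setequal(round(c(s2$cu_mg_l, s2$fe_mg_l), 3),
                  c(0.34, 0.009, 0.009, 0.34))
  # one-variant selection drops the other reading only
  one <- station_fixture(variants = "range_consistent")
  expect_equal(sum(one$sample_id == "S2" & one$season == "winter"), 1)
  expect_equal(nrow(one), nrow(fx) - 1)
})
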