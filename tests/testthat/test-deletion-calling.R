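test_that("cluster shifts are signed reference-minus-sample differences", {
  a <- obs_row("m1", 0.5, 3)
  b <- obs_row("m1", 0.5, 3)
  z <- compute_shift(a, b)
  expect_equal(z$d_theta, 0)
  expect_equal(z$d_r, 0)

  # the 3-site geometry: euploid theta 0.7048 / R 6, 6A-deleted mutant 1.0 / 4
  eu <- infinium_signal(ref_sites(), 2)
  mu <- infinium_signal(ref_sites(), c(0, 2, 2))
  z <- compute_shift(obs_row("m1", eu$norm_theta, eu$norm_r),
                     obs_row("m1", mu$norm_theta, mu$norm_r))
  expect_equal(round(z$d_theta, 4), -0.2952)
  expect_equal(z$d_r, 2)

  # antisymmetry
  z2 <- compute_shift(obs_row("m1", mu$norm_theta, mu$norm_r),
                      obs_row("m1", eu$norm_theta, eu$norm_r))
  expect_equal(z2$d_theta, -z$d_theta)
  expect_equal(z2$d_r, -z$d_r)

  # undefined theta on one side: d_theta NA, d_r still computed
  z3 <- compute_shift(obs_row("m1", 0.3, 2), obs_row("m1", NA, 0))
  expect_true(is.na(z3$d_theta))
  expect_equal(z3$d_r, 2)

  expect_error(compute_shift(obs_row("m1", .1, 1), obs_row("m2", .1, 1)),
               "aligned")
})

test_that("panel averaging handles single samples, means and all-null markers", {
  one <- obs_row("m1", 0.42, 3.3, "HIB_001")
  av <- panel_average(one)
  expect_equal(av$norm_theta, 0.42)
  expect_equal(av$norm_r, 3.3)
  expect_equal(av$sample_id, "AV_HIB")

  two <- rbind(obs_row("m1", 0.4, 2, "HIB_001"), obs_row("m1", 0.6, 4, "HIB_002"))
  av <- panel_average(two)
  expect_equal(av$norm_theta, 0.5)
  expect_equal(av$norm_r, 3)

  nulls <- rbind(obs_row("m1", NA, 0, "HIB_001"), obs_row("m1", NA, 0, "HIB_002"))
  av <- panel_average(nulls)
  expect_true(is.na(av$norm_theta))
  expect_equal(av$norm_r, 0)
  expect_error(panel_average(one[0, ]), "no panel")
})

test_that("a 96-sample noisy euploid panel averages onto the noise-free cluster", {
  cfg <- quick_config(seed = 4, n_markers = 60, noise_sd = 0.05,
                      deletions = list(), n_panel = 96)
  sim <- simulate_experiment(cfg)
  noisefree <- simulate_experiment(quick_config(seed = 4, n_markers = 60,
                                                noise_sd = 0, deletions = list(),
                                                n_panel = 1))
  truth <- noisefree$intensities[noisefree$intensities$sample_id == "Chara", ]
  truth <- truth[match(sim$markers$name, truth$marker_name), ]

  pan <- sim$intensities[grepl("^HIB_", sim$intensities$sample_id), ]
  av <- panel_average(pan)
  av <- av[match(sim$markers$name, av$marker_name), ]

  # delta-method SE of theta is (2/pi) * noise_sd / sqrt(X^2 + Y^2); restrict
  # to markers with both channels well away from the clamp at zero, where the
  # linearisation holds. Simultaneous bound over m markers at overall 1%:
  # z_{1 - 0.005/m} ~= 4 for m ~= 50.
  sites <- sim$markers$sites
  ch <- t(vapply(sites, function(s) {
    c(sum(s$gain * 2 * (s$allele == "A")), sum(s$gain * 2 * (s$allele == "B")))
  }, numeric(2)))
  ok <- ch[, 1] >= 2 & ch[, 2] >= 2
  se <- (2 / pi) * 0.05 / sqrt(rowSums(ch^2)) / sqrt(96)
  expect_true(any(ok))
  expect_true(all(abs(av$norm_theta[ok] - truth$norm_theta[ok]) <= 4 * se[ok]))
})

test_that("marker flagging is the two-axis disjunction with inclusive thresholds", {
  sh <- function(dt, dr) tibble::tibble(marker_name = "m", reference = "parent",
                                        d_theta = dt, d_r = dr)
  cfg <- caller_config()
  expect_true(flag_marker(sh(-0.2952, 0), config = cfg))
  expect_false(flag_marker(sh(0, 0), config = cfg))
  expect_true(flag_marker(sh(0.09, 0.6), config = cfg))     # R axis alone
  expect_true(flag_marker(sh(0.1, 0), config = cfg))        # tie flagged
  expect_true(flag_marker(sh(0, -0.5), config = cfg))
  expect_false(flag_marker(sh(NA, 0.2), config = cfg))      # NA contributes FALSE
  expect_true(flag_marker(sh(NA, 0.9), config = cfg))

  # panel concordance: both references must clear the disjunction
  expect_false(flag_marker(sh(0.3, 0), sh(0.02, 0.1), config = cfg))
  expect_true(flag_marker(sh(0.3, 0), sh(0.15, 0), config = cfg))
  relaxed <- caller_config(require_panel_concordance = FALSE)
  expect_true(flag_marker(sh(0.3, 0), sh(0.02, 0.1), config = relaxed))
})

test_that("null alleles are detected from the fluorescence floor", {
  expect_true(detect_null(obs_row("m", NA, 0), 0.2))
  expect_false(detect_null(obs_row("m", 1, 4), 0.2))
  # 3-site marker with one deleted site keeps R = 4: not a null
  mu <- infinium_signal(ref_sites(), c(0, 2, 2))
  expect_false(detect_null(obs_row("m", mu$norm_theta, mu$norm_r), 0.2))
})

test_that("HET confirmation needs strict betweenness near the midpoint", {
  eu <- infinium_signal(ref_sites(), 2)$norm_theta        # 0.704833
  mu <- infinium_signal(ref_sites(), c(0, 2, 2))$norm_theta  # 1
  f1 <- infinium_signal(ref_sites(), c(1, 2, 2))$norm_theta  # 0.844042
  expect_equal(round(f1, 4), 0.8440)
  expect_true(confirm_het(eu, mu, f1, 0.05))
  expect_lte(abs(f1 - (eu + mu) / 2), 0.0084)

  expect_false(confirm_het(eu, mu, eu, 0.05))              # F1 on the parent
  expect_false(confirm_het(eu, mu, 0.5, 0.05))             # outside [parent, mutant]
  expect_false(confirm_het(eu, mu, (eu + mu) / 2 + 0.06, 0.05))
  expect_true(is.na(confirm_het(NA, mu, f1, 0.05)))        # indeterminate
})

test_that("parent-stock biotype markers are excluded from deletion evidence", {
  cfg <- quick_config(seed = 6, n_markers = 200, biotype_rate = 0.05)
  sim <- simulate_experiment(cfg)
  calls <- call_mutant(sim, "f1_6B", parent_bc = "Chara_BC")
  bt <- sim$truth$biotype_markers
  expect_true(length(bt) > 0)
  expect_true(all(calls$biotype[calls$marker_name %in% bt]))
  expect_false(any(calls$flagged[calls$marker_name %in% bt]))
  rep <- attr(calls, "biotype_report")
  expect_setequal(rep$marker_name, bt)

  # identical stocks: nothing excluded
  none <- exclude_biotype_markers(calls,
                                  sim$intensities[sim$intensities$sample_id == "Chara", ],
                                  sim$intensities[sim$intensities$sample_id == "Chara", ])
  expect_equal(nrow(attr(none, "biotype_report")), 0)
})

test_that("subgenome attribution follows single-site null markers", {
  mk <- tibble::tibble(
    snp_index = 1:3, name = c("a", "b", "c"), chromosome = "6B",
    span_start = c(100, 200, 300), span_end = c(200, 300, 400),
    sites = list(
      data.frame(subgenome = "6B", position = 150, allele = "B", gain = 1),
      data.frame(subgenome = c("6A", "6B"), position = c(1, 2),
                 allele = c("A", "B"), gain = 1),
      data.frame(subgenome = "6A", position = 350, allele = "A", gain = 1)))
  calls <- tibble::tibble(marker_name = c("a", "b", "c"),
                          status = c("null", "poly", "none"))
  expect_equal(as.character(assign_subgenome(calls, mk)), "6B")

  calls$status <- c("null", "poly", "null")                # conflict 6B vs 6A
  expect_equal(as.character(assign_subgenome(calls, mk)), "unassigned")
  expect_equal(nrow(attr(assign_subgenome(calls, mk), "votes")), 2)

  calls$status <- c("poly", "poly", "none")                # no nulls at all
  expect_equal(as.character(assign_subgenome(calls, mk)), "unassigned")
})

test_that("noise-free calling equals the brute-force dosage-model prediction", {
  for (seed in 1:3) {
    cfg <- quick_config(seed = seed, n_markers = 120)
    sim <- simulate_experiment(cfg)
    calls <- call_mutant(sim, "mut_6B")
    expected <- oracle_flags(sim$markers, cfg$deletions[[1]])
    expect_identical(calls$flagged, expected)
  }
})

test_that("unknown sample ids are reported by name", {
  cfg <- quick_config(seed = 1, n_markers = 20, deletions = list())
  sim <- simulate_experiment(cfg)
  expect_error(call_deletions(sim$intensities, sim$markers, "nope", "Chara"),
               "'nope'")
})
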