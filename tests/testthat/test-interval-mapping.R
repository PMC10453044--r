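fake_calls <- function(pos, flagged, chrom = "6A") {
  tibble::tibble(marker_name = paste0("m", seq_along(pos)), chromosome = chrom,
                 span_start = pos, span_end = pos + 100,
                 status = ifelse(flagged, "poly", "none"), flagged = flagged)
}

test_that("runs require enough flagged markers and split on large gaps", {
  cfg <- mapper_config(gap_max = 1e6, min_markers = 2)
  expect_equal(nrow(find_runs(fake_calls(100, TRUE), cfg)), 0)

  r <- find_runs(fake_calls(c(100, 200, 1e9), c(TRUE, TRUE, TRUE)), cfg)
  expect_equal(nrow(r), 1)
  expect_equal(r$marker_names[[1]], c("m1", "m2"))

  # unflagged markers inside the span are discordant support, not splits
  r <- find_runs(fake_calls(c(100, 500, 900), c(TRUE, FALSE, TRUE)),
                 mapper_config(gap_max = 1e3, min_markers = 2))
  expect_equal(nrow(r), 1)
  expect_equal(r$discordant[[1]], "m2")

  expect_equal(nrow(find_runs(fake_calls(c(1, 2), c(FALSE, FALSE)), cfg)), 0)
})

test_that("interval coordinates and sizes follow the flanking-marker convention", {
  run <- fake_calls(c(1000, 5000, 9000), TRUE)
  iv <- make_interval(run)
  expect_equal(iv$start, 1000)
  expect_equal(iv$end, 9100)
  expect_equal(iv$size, iv$end - iv$start)          # difference, not +1
  expect_equal(iv$flank_start_marker, "m1")
  expect_equal(iv$flank_end_marker, "m3")
  expect_true(make_interval(run, target = c(4000, 4500))$contains_target)
  expect_false(make_interval(run, target = c(10000, 12000))$contains_target)
})

test_that("published flanking coordinates reproduce the published sizes", {
  mk <- read_marker_map(system.file("extdata", "feh_mutant_markers.csv",
                                    package = "hibdel"))
  pair <- function(names) mk[mk$name %in% names, ]
  iv6a <- make_interval(pair(c("wsnp_CAP8_c6680_3136899", "BobWhite_c44549_83")))
  iv6b <- make_interval(pair(c("BS00074183_51", "tplb0055h14_483")))
  iv6d <- make_interval(pair(c("D_GBQ4KXB01B5NHZ_336", "Kukri_c5531_358")))
  expect_equal(iv6a$size, 28246961)
  expect_equal(iv6b$size, 4876122)
  expect_equal(iv6d$size, 1600754)
  expect_equal(iv6a$start, 12836428)
  expect_equal(iv6a$end, 41083389)
})

test_that("a simulated deletion maps to one nested interval on its chromosome", {
  hits <- 0
  for (seed in 1:5) {
    cfg <- quick_config(seed = seed, n_markers = 300, noise_sd = 0.05,
                        biotype_rate = 0.02, n_panel = 8)
    sim <- simulate_experiment(cfg)
    calls <- call_mutant(sim, "mut_6B", parent_bc = "Chara_BC")
    iv <- map_intervals(calls, sim$markers)
    rec <- recover_truth(iv, sim$truth[["deletions"]][1, ], span_slack = 100)
    expect_true(rec$detected)
    expect_true(rec$nested)
    # boundary error bounded by the distance from the breakpoint to the
    # nearest informative hybridisation site (biotype markers are excluded
    # from evidence by design; probe span width is 100)
    del <- cfg$deletions[[1]]
    sites <- marker_sites(sim$markers)
    inb <- sites$subgenome == "6B" & sites$position >= del$start &
      sites$position <= del$end &
      !sites$name %in% sim$truth$biotype_markers
    expect_lte(rec$boundary_error_start, min(sites$position[inb]) - del$start)
    expect_lte(rec$boundary_error_end,
               del$end - max(sites$position[inb]) + 100)
    hits <- hits + rec$subgenome_correct
    # same-chromosome intervals never overlap
    for (ch in unique(iv$chromosome)) {
      v <- iv[iv$chromosome == ch, ]
      if (nrow(v) > 1) {
        v <- v[order(v$start), ]
        expect_true(all(v$start[-1] > v$end[-nrow(v)]))
      }
    }
  }
  expect_gte(hits, 4)  # single-site null support can be absent by chance
})

test_that("an F1 backcross recovers the same interval with HET support", {
  cfg <- quick_config(seed = 21, n_markers = 300)
  sim <- simulate_experiment(cfg)
  hom <- map_intervals(call_mutant(sim, "mut_6B", f1 = "f1_6B"), sim$markers)
  het <- map_intervals(call_mutant(sim, "f1_6B"), sim$markers)
  h1 <- hom[hom$chromosome == "6B", ]
  h2 <- het[het$chromosome == "6B", ]
  expect_equal(h2$start, h1$start)
  expect_equal(h2$end, h1$end)
  expect_gt(h1$n_het_confirmed, 0)
})

test_that("no deletions means no intervals", {
  for (seed in 1:3) {
    cfg <- quick_config(seed = seed, n_markers = 200, noise_sd = 0.05,
                        deletions = list(true_deletion("6B", 2e7, 2.6e7)),
                        n_panel = 8)
    sim <- simulate_experiment(cfg)
    # call an euploid panel member: no true signal anywhere
    calls <- call_deletions(sim$intensities, sim$markers, "Chara", "HIB_001",
                            panel_prefix = "HIB_")
    expect_equal(nrow(map_intervals(calls, sim$markers)), 0)
  }
})

test_that("lowering the theta threshold never shrinks the flagged set", {
  cfg <- quick_config(seed = 8, n_markers = 200, noise_sd = 0.05, n_panel = 6)
  sim <- simulate_experiment(cfg)
  strict <- call_mutant(sim, "mut_6B", config = caller_config(theta_threshold = 0.1))
  loose <- call_mutant(sim, "mut_6B", config = caller_config(theta_threshold = 0.05))
  expect_true(all(loose$flagged[strict$flagged]))
})
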