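test_that("genome layout is deterministic and matches the probe-grid spec", {
  cfg <- simulation_config(seed = 7)
  a <- make_genome(cfg)
  b <- make_genome(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_true(all(vapply(a$probes, function(p) all(diff(p) > 0), logical(1))))
  for (i in seq_len(nrow(a$chromosomes))) {
    p <- a$probes[[a$chromosomes$name[i]]]
    expect_gte(length(p), 4L)
    expect_true(all(p >= 1 & p <= a$chromosomes$length[i]))
  }
})

test_that("a 10 Mb / 2000-probe chromosome has ~4.59 kb median spacing", {
  cfg <- simulation_config(
    seed = 3,
    chromosomes = data.frame(name = "1", length = 1e7),
    n_probes = 2000L
  )
  layout <- make_genome(cfg)
  med_gap <- median(diff(layout$probes[["1"]]))
  expect_lt(abs(med_gap - 4590) / 4590, 0.20)
})

test_that("degenerate genome configurations are rejected", {
  expect_error(
    simulation_config(chromosomes = data.frame(name = "1", length = 0)),
    "configuration error"
  )
  expect_error(simulation_config(n_probes = 0), "configuration error")
  expect_error(simulation_config(missing_rate = 1), "configuration error")
})

test_that("planted truth respects carriers, coordinates and the event budget", {
  cfg <- simulation_config(seed = 5)
  layout <- make_genome(cfg)
  truth <- plant_truth(layout, cfg)

  budget <- sum(vapply(cfg$event_spec, function(e) {
    e$n_case_carriers + e$n_control_carriers
  }, numeric(1)))
  expect_identical(nrow(truth), as.integer(budget))

  ur <- truth[truth$label == "ultra_rare", ]
  expect_true(all(ur$cohort == "case"))
  expect_identical(anyDuplicated(ur$sample_id), 0L)

  poly <- truth[truth$label == "common_polymorphism", ]
  for (key in unique(paste(poly$chrom, poly$start, poly$end))) {
    carriers <- poly[paste(poly$chrom, poly$start, poly$end) == key, ]
    expect_gte(sum(carriers$cohort == "control"), 2L)
  }

  expect_true(all(truth$start <= truth$end))
  expect_true(all(truth$copy_number != 2L))
  for (i in seq_len(nrow(truth))) {
    pos <- layout$probes[[truth$chrom[i]]]
    expect_gte(sum(pos >= truth$start[i] & pos <= truth$end[i]), 4L)
  }
})

test_that("single-event specs are honoured literally", {
  cfg <- simulation_config(
    seed = 2, n_cases = 1L, n_controls = 5L,
    event_spec = list(
      list(label = "ultra_rare", copy_number = 3L,
           length_range = c(850000, 850000), n_case_carriers = 1L,
           n_control_carriers = 0L),
      list(label = "common_polymorphism", copy_number = 1L,
           length_range = c(6e4, 9e4), n_case_carriers = 0L,
           n_control_carriers = 5L)
    )
  )
  layout <- make_genome(cfg)
  truth <- plant_truth(layout, cfg)
  ur <- truth[truth$label == "ultra_rare", ]
  expect_identical(nrow(ur), 1L)
  expect_identical(ur$end - ur$start + 1L, 850000L)
  expect_identical(ur$cohort, "case")
  poly <- truth[truth$label == "common_polymorphism", ]
  expect_identical(nrow(poly), 5L)
  expect_identical(length(unique(paste(poly$chrom, poly$start, poly$end))), 1L)
})

test_that("per-sample planted events never overlap (brute-force pair scan)", {
  cfg <- simulation_config(
    seed = 9, n_cases = 20L, n_controls = 40L,
    event_spec = rep(list(list(label = "common_polymorphism",
                               copy_number = 3L, length_range = c(3e4, 2e5),
                               n_case_carriers = 2L,
                               n_control_carriers = 2L)), 50)
  )
  layout <- make_genome(cfg)
  truth <- plant_truth(layout, cfg)
  expect_identical(nrow(truth), 200L)
  for (sid in unique(truth$sample_id)) {
    ev <- truth[truth$sample_id == sid, ]
    if (nrow(ev) < 2) next
    for (i in seq_len(nrow(ev) - 1)) {
      for (j in seq.int(i + 1, nrow(ev))) {
        if (ev$chrom[i] != ev$chrom[j]) next
        expect_true(ev$end[i] < ev$start[j] || ev$end[j] < ev$start[i])
      }
    }
  }
})

test_that("intensity signal sits on the copy-number state means", {
  cfg <- simulation_config(
    seed = 4, n_cases = 1L, n_controls = 0L, noise_sd_lrr = 1e-6,
    baf_sd = 1e-6, missing_rate = 0, male_fraction = 0,
    event_spec = list(list(label = "ultra_rare", copy_number = 3L,
                           length_range = c(4e5, 5e5), n_case_carriers = 1L,
                           n_control_carriers = 0L))
  )
  layout <- make_genome(cfg)
  truth <- plant_truth(layout, cfg)
  cohort <- simulate_intensities(layout, truth, cfg)
  s <- cohort[["case_001"]]
  pos <- layout$probes[[truth$chrom]]
  inside <- pos >= truth$start & pos <= truth$end
  expect_lt(abs(mean(s$lrr[[truth$chrom]][inside]) - 0.40), 0.01)
  expect_lt(abs(mean(s$lrr[[truth$chrom]][!inside]) - 0.0), 0.01)
})

test_that("hemizygous regions lose the heterozygous BAF cluster", {
  cfg <- simulation_config(
    seed = 6, n_cases = 1L, n_controls = 0L, baf_sd = 1e-6,
    missing_rate = 0, male_fraction = 0,
    event_spec = list(list(label = "ultra_rare", copy_number = 1L,
                           length_range = c(4e5, 5e5), n_case_carriers = 1L,
                           n_control_carriers = 0L))
  )
  layout <- make_genome(cfg)
  truth <- plant_truth(layout, cfg)
  cohort <- simulate_intensities(layout, truth, cfg)
  s <- cohort[["case_001"]]
  pos <- layout$probes[[truth$chrom]]
  inside <- pos >= truth$start & pos <= truth$end
  baf_in <- s$baf[[truth$chrom]][inside]
  expect_false(any(abs(baf_in - 0.5) < 0.1))
  baf_out <- s$baf[[truth$chrom]][!inside]
  expect_true(any(abs(baf_out - 0.5) < 0.1))
})

test_that("empirical LRR noise tracks the configured SD", {
  cfg <- simulation_config(seed = 8, n_cases = 1L, n_controls = 0L,
                           noise_sd_lrr = 0.2, missing_rate = 0,
                           male_fraction = 0, event_spec = list())
  layout <- make_genome(cfg)
  cohort <- simulate_intensities(layout, plant_truth(layout, cfg), cfg)
  lrr <- unlist(cohort[[1]]$lrr, use.names = FALSE)
  expect_gte(length(lrr), 1000L)
  expect_lt(abs(sd(lrr) - 0.2) / 0.2, 0.05)
})

test_that("identical seed and config reproduce the cohort bit for bit", {
  cfg <- simulation_config(
    seed = 12, n_cases = 3L, n_controls = 3L,
    event_spec = list(
      list(label = "ultra_rare", copy_number = 3L,
           length_range = c(1e5, 2e5), n_case_carriers = 1L,
           n_control_carriers = 0L),
      list(label = "common_polymorphism", copy_number = 1L,
           length_range = c(6e4, 9e4), n_case_carriers = 1L,
           n_control_carriers = 3L)
    )
  )
  run <- function() {
    layout <- make_genome(cfg)
    truth <- plant_truth(layout, cfg)
    simulate_intensities(layout, truth, cfg)
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})

test_that("invalid noise configuration is rejected", {
  cfg <- simulation_config(seed = 1, n_cases = 1L, n_controls = 0L,
                           event_spec = list())
  layout <- make_genome(cfg)
  truth <- plant_truth(layout, cfg)
  cfg$noise_sd_lrr <- 0
  expect_error(simulate_intensities(layout, truth, cfg),
               "configuration error")
})
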