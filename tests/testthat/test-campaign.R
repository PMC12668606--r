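# batch execution, stop condition, strategies, determinism, conservation

test_that("a clean batch yields batch_size records and is seed-deterministic", {
  st <- mock_stages(0.5)
  cfg <- campaign_config(target_hits = 24, batch_size = 10, seed = 11)
  r1 <- run_batch(cfg, st, 0)
  expect_equal(length(r1), 10L)
  expect_true(all(vapply(r1, function(r) !nzchar(r$filter_reason),
                         logical(1))))
  r2 <- run_batch(cfg, st, 0)
  expect_identical(lapply(r1, function(r) r$metrics),
                   lapply(r2, function(r) r$metrics))
  expect_identical(vapply(r1, function(r) r$design_id, ""),
                   vapply(r2, function(r) r$design_id, ""))
})

test_that("clashing designs are recorded as filtered, not scored", {
  st <- mock_stages(1, clash_every = 10)   # every 10th design clashes
  cfg <- campaign_config(target_hits = 5, batch_size = 10, seed = 1)
  recs <- run_batch(cfg, st, 0)
  filtered <- Filter(function(r) nzchar(r$filter_reason), recs)
  expect_equal(length(filtered), 1L)
  expect_match(filtered[[1]]$filter_reason, "steric_clash")
  expect_equal(length(recs) - length(filtered), 9L)
})

test_that("a 50% mock campaign stops after exactly the arithmetic batch count", {
  st <- mock_stages(0.5)
  cfg <- campaign_config(target_hits = 24, batch_size = 10, seed = 1)
  state <- run_campaign(cfg, st)
  expect_equal(state$status, "completed")
  expect_equal(state$batches_done, 5L)
  expect_gte(state$hits, 24L)
  expect_lte(state$hits, 34L)
  expect_equal(state$designs_scored, 50L)
})

test_that("target 0 runs nothing; zero hit rate exhausts at max_batches", {
  st <- mock_stages(0)
  cfg0 <- campaign_config(target_hits = 0, batch_size = 10, seed = 1)
  s0 <- run_campaign(cfg0, st)
  expect_equal(s0$batches_done, 0L)
  expect_equal(s0$status, "completed")

  cfg <- campaign_config(target_hits = 5, batch_size = 4, max_batches = 3,
                         seed = 1)
  s <- run_campaign(cfg, st)
  expect_equal(s$batches_done, 3L)
  expect_equal(s$status, "exhausted")
  expect_equal(s$hits, 0L)
})

test_that("campaign CSV reproduces bit-identically under a fixed seed", {
  st <- mock_stages(0.5)
  d1 <- tempfile(); d2 <- tempfile()
  cfg1 <- campaign_config(target_hits = 12, batch_size = 10, seed = 99,
                          output_dir = d1)
  cfg2 <- campaign_config(target_hits = 12, batch_size = 10, seed = 99,
                          output_dir = d2)
  run_campaign(cfg1, st)
  run_campaign(cfg2, st)
  expect_identical(readLines(file.path(d1, "Scoring_Stats.csv")),
                   readLines(file.path(d2, "Scoring_Stats.csv")))
})

test_that("per-batch records are independent of the instance count", {
  st <- mock_stages(0.5)
  s1 <- run_campaign(campaign_config(target_hits = 24, batch_size = 10,
                                     seed = 5), st, parallel_instances = 1)
  s2 <- run_campaign(campaign_config(target_hits = 24, batch_size = 10,
                                     seed = 5), st, parallel_instances = 2)
  # both stop at/after the target; the 2-instance run may overshoot by a wave
  expect_gte(s2$hits, 24L)
  common <- intersect(unique(vapply(s1$records, function(r) r$batch_id, "")),
                      unique(vapply(s2$records, function(r) r$batch_id, "")))
  pick <- function(s) Filter(function(r) r$batch_id %in% common, s$records)
  key <- function(rs) vapply(rs, function(r) r$design_id, "")
  r1 <- pick(s1); r2 <- pick(s2)
  expect_identical(key(r1), key(r2))
  expect_identical(lapply(r1, function(r) r$metrics),
                   lapply(r2, function(r) r$metrics))
})

test_that("conservation holds: generated = filtered_out + scored", {
  set.seed(15)
  for (k in 1:5) {
    rate <- sample(c(0.25, 0.5, 1), 1)
    st <- mock_stages(rate, clash_every = sample(c(0, 3, 5), 1))
    cfg <- campaign_config(target_hits = sample(3:10, 1),
                           batch_size = sample(4:8, 1),
                           max_batches = 6, seed = k)
    s <- run_campaign(cfg, st)
    expect_equal(s$designs_generated,
                 s$designs_filtered_out + s$designs_scored)
    expect_lte(s$hits, s$designs_scored)
  }
})

test_that("sequence diversity scores many sequences on one fixed backbone", {
  st <- mock_stages(1)
  ref <- fixture_bundle_complex()
  cfg <- campaign_config(target_hits = 1, batch_size = 200,
                         strategy = "sequence_diversity", seed = 1)
  recs <- run_batch(cfg, strategy_dispatch(cfg, st, ref), 0)
  expect_equal(length(recs), 200L)
  expect_true(all(vapply(recs, function(r) r$strategy, "") ==
                    "sequence_diversity"))
  expect_error(strategy_dispatch(cfg, st), "reference")
})

test_that("partial diffusion perturbs only the binder; zero noise is identity", {
  st <- mock_stages(1)
  ref <- fixture_bundle_complex()
  cfg <- campaign_config(target_hits = 1, batch_size = 3,
                         strategy = "partial_diffusion", pd_noise = 0,
                         seed = 1)
  models <- strategy_dispatch(cfg, st, ref)$backbone_generator(3, c(65, 155), 1)
  for (m in models) {
    expect_identical(m$atoms, ref$atoms)
  }
  cfg$pd_noise <- 0.5
  models <- strategy_dispatch(cfg, st, ref)$backbone_generator(2, c(65, 155), 1)
  m <- models[[1]]
  expect_false(identical(chain_atoms(m, "A"), chain_atoms(ref, "A")))
  expect_identical(chain_atoms(m, "B"), chain_atoms(ref, "B"))

  # standard strategy ignores the reference entirely
  cfg_std <- campaign_config(target_hits = 1, batch_size = 2, seed = 1)
  expect_identical(strategy_dispatch(cfg_std, st, ref), st)
})

test_that("campaign summary reports rates, SE and a conserved rejection breakdown", {
  st <- mock_stages(0.5, clash_every = 5)
  cfg <- campaign_config(target_hits = 10, batch_size = 10, seed = 2)
  s <- run_campaign(cfg, st)
  sm <- campaign_summary(s)
  expect_equal(sm$hits / sm$designs_scored, sm$hit_rate)
  expect_equal(sm$hit_rate_se,
               sqrt(sm$hit_rate * (1 - sm$hit_rate) / sm$designs_scored))
  expect_equal(sum(unlist(sm$rejection_reasons)), sm$designs_filtered_out)
  expect_equal(sum(vapply(sm$per_batch, function(b) b$n, 0)),
               sm$designs_generated)

  empty <- campaign_summary(list(batches_done = 0L, designs_generated = 0L,
                                 designs_scored = 0L,
                                 designs_filtered_out = 0L, hits = 0L,
                                 per_instance_status = list(),
                                 status = "completed", records = list()))
  expect_equal(empty$hit_rate, 0)
})

test_that("campaign config validates and loads from JSON", {
  expect_error(campaign_config(target_hits = -1), "target_hits")
  expect_error(campaign_config(target_hits = 1, batch_size = 0), "batch_size")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(target_hits = 24, batch_size = 10, seed = 3,
                            strategy = "standard",
                            length_range = c(65, 155)), f, auto_unbox = TRUE)
  cfg <- read_campaign_config(f)
  expect_equal(cfg$target_hits, 24)
  expect_equal(cfg$length_range, c(65, 155))
  expect_s3_class(cfg$thresholds, "threshold_set")
})
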