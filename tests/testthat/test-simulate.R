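test_that("simulator enforces config validity", {
  regs <- data.frame(start = c(0, 50), end = c(100, 150), mu = 30,
                     log2fc = 0)
  expect_error(sim_config(200, c(3, 3), regs), "overlap")
  regs2 <- data.frame(start = 0, end = 300, mu = 30, log2fc = 0)
  expect_error(sim_config(200, c(3, 3), regs2), "within the genome")
  regs3 <- data.frame(start = 0, end = 100, mu = -1, log2fc = 0)
  expect_error(sim_config(200, c(3, 3), regs3), "positive")
})

test_that("truth reflects the config and draws are seed-deterministic", {
  regs <- data.frame(start = 100, end = 300, mu = 20, log2fc = 0)
  cfg <- sim_config(500, c(3, 3), regs, seed = 4)
  sim <- simulate_experiment(cfg)
  expect_false(sim$truth$regions$is_de[1])
  expect_equal(sim$truth$regions$direction[1], "none")
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim$coverage$counts, sim2$coverage$counts)
  # zero outside expressed regions
  expect_true(all(sim$coverage$counts[1:100, ] == 0))
})

test_that("fold changes scale group means as specified", {
  regs <- data.frame(start = 100, end = 700, mu = 30, log2fc = 2)
  cfg <- sim_config(1000, c(5, 5), regs, lib_factors = rep(1, 10),
                    seed = 9)
  sim <- simulate_experiment(cfg)
  core <- 150:650   # away from the 20-base edge ramps
  g1 <- mean(sim$coverage$counts[core, 1:5])
  g2 <- mean(sim$coverage$counts[core, 6:10])
  expect_equal(g1, 30, tolerance = 0.05)
  expect_equal(g2 / g1, 4, tolerance = 0.1)
  # -Inf fold change zeroes the non-reference group entirely
  regs$log2fc <- -Inf
  simz <- simulate_experiment(sim_config(1000, c(5, 5), regs, seed = 9))
  expect_true(all(simz$coverage$counts[, 6:10] == 0))
  expect_true(any(simz$coverage$counts[, 1:5] > 0))
})

test_that("simulator writes a runnable pipeline input directory", {
  dir <- tempfile()
  regs <- data.frame(start = c(100, 400), end = c(250, 550), mu = 25,
                     log2fc = c(0, 2))
  sim <- simulate_experiment(sim_config(800, c(2, 2), regs, seed = 3),
                             dir = dir)
  expect_true(file.exists(file.path(dir, "samples.tsv")))
  expect_true(file.exists(file.path(dir, "truth_de.bed")))
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  cov <- read_coverage(sheet$file, "chrS", span = c(0, 800),
                       sample_ids = sheet$sample_id)
  expect_identical(cov$counts, sim$coverage$counts)
})

test_that("call scoring implements the matching conventions", {
  truth <- structure(list(
    regions = data.frame(start = c(100L, 400L), end = c(200L, 500L),
                         mu = 30, log2fc = 2, is_de = TRUE,
                         direction = "up"),
    genome_length = 1000L), class = "sim_truth")
  exact <- data.frame(start = c(100L, 400L), end = c(200L, 500L),
                      q = c(0.01, 0.01))
  ev <- evaluate_calls(exact, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$base_jaccard, 1)
  # one call overlapping one of two true regions
  half <- data.frame(start = 150L, end = 180L, q = 0.01)
  ev2 <- evaluate_calls(half, truth)
  expect_equal(ev2$sensitivity, 0.5)
  expect_equal(ev2$precision, 1)
  # no significant calls: precision reported 1 by convention, flagged
  none <- data.frame(start = 100L, end = 200L, q = 0.9)
  ev3 <- evaluate_calls(none, truth)
  expect_equal(ev3$sensitivity, 0)
  expect_equal(ev3$precision, 1)
  expect_true(ev3$no_calls)
  # jaccard matching is stricter than 1-bp matching
  sliver <- data.frame(start = 199L, end = 260L, q = 0.01)
  expect_equal(evaluate_calls(sliver, truth)$sensitivity, 0.5)
  expect_equal(evaluate_calls(sliver, truth,
                              match_rule = "jaccard0.5")$sensitivity, 0)
})
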