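test_that("pi0 is the fraction of bases with average coverage below c", {
  counts <- cbind(c(0, 0, 10, 10, 0, 3, 8, 0, 1, 12),
                  c(0, 2, 12, 10, 0, 5, 6, 0, 1, 10))
  cov <- coverage_matrix("c", 0:9, counts, c("a", "b"))
  expect_equal(estimate_pi0(cov, cutoff = 5),
               mean(rowMeans(counts) < 5))
  expect_equal(estimate_pi0(cov, cutoff = 0.5), 0.3)
  expect_equal(estimate_pi0(cov, cutoff = 100), 1)
  all_pos <- coverage_matrix("c", 0:2, cbind(1:3, 4:6), c("a", "b"))
  expect_equal(estimate_pi0(all_pos, cutoff = 1e-9), 0)
})

test_that("mixture EM recovers known two-component truth", {
  set.seed(1)
  s <- c(rnorm(45000), rnorm(5000, 3, 1.5))
  m <- fit_mixture(s)
  expect_lt(abs(m$pi2_star - 0.1), 0.01)
  expect_lt(abs(m$mu2 - 3), 0.1)
  expect_true(m$var2 >= m$var1)
  expect_equal(m$pi1_star + m$pi2_star, 1)
})

test_that("mixture on pure null degenerates to one component", {
  set.seed(2)
  s <- rnorm(50000)
  m <- suppressWarnings(fit_mixture(s))
  expect_lt(m$pi2_star, 0.05)
  expect_lt(abs(m$mu1), 0.05)
  expect_lt(abs(m$var1 - 1), 0.05)
  expect_true(isTRUE(m$collapsed))
  # symmetric heavy shoulders: the null component stays centered
  set.seed(3)
  s2 <- c(rnorm(20000), rnorm(2000, 3), rnorm(2000, -3))
  m2 <- fit_mixture(s2)
  expect_lt(abs(m2$mu1), 0.1)
})

test_that("mixture needs enough expressed-base statistics", {
  expect_error(fit_mixture(rnorm(20)), "at least 50")
})

test_that("HMM assembly scales mixture weights by pi0", {
  mix <- structure(list(pi1_star = 0.8, pi2_star = 0.2, mu1 = 0, var1 = 1,
                        mu2 = 3, var2 = 4), class = "mixture_fit")
  h <- build_hmm(0.5, mix, delta = 1e-4, retain_prob = 0.999)
  expect_equal(h$state_priors, c(0.5, 0.4, 0.1))
  expect_equal(sum(h$state_priors), 1)
  expect_equal(unname(h$transition[1, 2:3]), c(5e-4, 5e-4))
  expect_equal(rowSums(h$transition), rep(1, 3))
  for (p0 in c(0, 0.3, 1))
    expect_equal(sum(build_hmm(p0, mix)$state_priors), 1)
})

test_that("Viterbi picks the dominant emission on uniform tracks", {
  mix <- structure(list(pi1_star = 0.7, pi2_star = 0.3, mu1 = 0.2, var1 = 1,
                        mu2 = 5, var2 = 2), class = "mixture_fit")
  h <- build_hmm(0.6, mix)
  expect_true(all(viterbi_decode(rep(0, 50), h) == 0L))
  expect_true(all(viterbi_decode(rep(5, 50), h) == 2L))
  expect_error(viterbi_decode(c(0, NA, 1), h), "position 2")
})

test_that("Viterbi equals exhaustive enumeration on short random tracks", {
  set.seed(99)
  for (i in 1:60) {
    L <- sample(2:8, 1)
    h <- random_hmm()
    s <- rnorm(L, mean = sample(h$means, L, replace = TRUE), sd = 1)
    expect_identical(viterbi_decode(s, h), viterbi_brute(s, h))
  }
})

test_that("regions are maximal same-state runs partitioning the span", {
  path <- c(0L, 0L, 2L, 2L, 1L, 2L)
  pos <- 100:105
  s <- c(0, 0, 3, 1, 0.2, 4)
  r <- extract_regions(path, pos, s, chrom = "chrY")
  expect_equal(r$start, c(100, 102, 104, 105))
  expect_equal(r$end, c(102, 104, 105, 106))
  expect_equal(r$state, c(0L, 2L, 1L, 2L))
  expect_equal(sum(r$length), length(path))
  expect_true(all(diff(r$state) != 0))
  expect_equal(r$mean_stat[2], 2)           # mean of (3, 1)
  rs <- extract_regions(path, pos, s, stat_mode = "sum")
  expect_equal(rs$mean_stat[2], 4)
  # all-one path: a single region, no candidates
  r1 <- extract_regions(rep(1L, 5), 0:4, rnorm(5))
  expect_equal(nrow(r1), 1L)
  expect_equal(sum(r1$state == 2L), 0L)
})

test_that("raising retain_prob never fragments the segmentation more", {
  sim <- small_sim()
  y <- coverage_transform(sim$coverage)
  fit <- fit_base_models(y, sim$design)
  bs <- moderate_statistics(fit, sim$coverage)
  mix <- fit_mixture(bs$statistic[bs$expressed])
  pi0 <- estimate_pi0(sim$coverage)
  n_regions <- sapply(c(0.9, 0.99, 0.999, 0.9999), function(rp) {
    path <- viterbi_decode(bs$statistic, build_hmm(pi0, mix,
                                                   retain_prob = rp))
    length(rle(path)$lengths)
  })
  expect_true(all(diff(n_regions) <= 0))
})
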