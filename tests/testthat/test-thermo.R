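test_that("site affinity combines concentration, sequence, and marks", {
  p <- model_params(beta = c(TF = 2), gamma = c(mk = 4), sigma = 0)
  site <- list(rel_affinity = 0.5, tf = "TF")
  # beta * rel * gamma^I = 2 * 0.5 * 4^0.5 = 2
  expect_equal(site_affinity(site, c(mk = 0.5), p), 2)
  # intensity at or below sigma contributes nothing
  p2 <- model_params(beta = c(TF = 2), gamma = c(mk = 4), sigma = 1)
  expect_equal(site_affinity(site, c(mk = 0.5), p2), 1)
  # gamma = e multiplies the affinity by e at unit intensity
  p3 <- model_params(beta = c(TF = 1), gamma = c(mk = exp(1)))
  expect_equal(site_affinity(list(rel_affinity = 1, tf = "TF"),
                             c(mk = 1), p3), exp(1))
})

test_that("a 3-site region enumerates 2^3 configurations, empty weight 1", {
  region <- list(
    sites = data.frame(region = 1L, offset = c(0L, 20L, 40L), width = 8L,
                       strand = "+", score = 0, rel_affinity = c(1, .5, .2),
                       tf = "A", stringsAsFactors = FALSE),
    marks = matrix(0, 3, 0))
  p <- model_params(beta = c(A = 1))
  ew <- enumerate_weights(region, p)
  expect_equal(nrow(ew), 8L)
  expect_true(all(ew$admissible))
  expect_equal(ew$weight[ew$config == "000"], 1)
})

test_that("cooperativity multiplies consecutive bound pairs within range", {
  region <- list(
    sites = data.frame(region = 1L, offset = c(0L, 20L), width = 8L,
                       strand = "+", score = 0, rel_affinity = 1,
                       tf = "A", stringsAsFactors = FALSE),
    marks = matrix(0, 2, 0))
  p <- model_params(beta = c(A = 1), omega = 3, coop_distance = 100)
  ew <- enumerate_weights(region, p)
  expect_equal(ew$weight[ew$config == "11"], 3) # q1*q2*omega = 1*1*3
  # beyond the cooperativity range the pair weight is plain q1*q2
  p_far <- model_params(beta = c(A = 1), omega = 3, coop_distance = 5)
  ew_far <- enumerate_weights(region, p_far)
  expect_equal(ew_far$weight[ew_far$config == "11"], 1)
})

test_that("overlapping bound sites are sterically excluded", {
  region <- list(
    sites = data.frame(region = 1L, offset = c(0L, 4L), width = 8L,
                       strand = c("+", "-"), score = 0, rel_affinity = 1,
                       tf = "A", stringsAsFactors = FALSE),
    marks = matrix(0, 2, 0))
  p <- model_params(beta = c(A = 1))
  ew <- enumerate_weights(region, p)
  expect_equal(nrow(ew), 4L)
  expect_false(ew$admissible[ew$config == "11"])
  expect_equal(ew$weight[ew$config == "11"], 0)
  # DP agrees with the constrained sum
  expect_equal(partition_dp(region, p)$Z, sum(ew$weight))
})

test_that("DP partition function equals enumeration on random fixtures", {
  set.seed(101)
  worst <- 0
  for (i in 1:60) {
    n <- sample(1:12, 1)
    region <- random_region(n, two_tf = TRUE)
    params <- random_params(two_tf = TRUE, omega_matrix = (i %% 3 == 0))
    pd <- partition_dp(region, params)
    for (tf in unique(region$sites$tf)) {
      ref <- brute_force_reference(region, params, tf)
      worst <- max(worst,
                   abs(pd$Z - ref$Z) / ref$Z,
                   abs(pd$Z_excluding[[tf]] - ref$Zex) / ref$Zex,
                   abs(binding_probability(region, params, tf) - ref$P))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("configuration probabilities normalize and closed forms hold", {
  set.seed(7)
  region <- random_region(5)
  params <- random_params()
  ew <- enumerate_weights(region, params)
  Z <- partition_dp(region, params)$Z
  expect_equal(sum(ew$weight / Z), 1)

  # zero sites -> Z = 1; one site with q = 1 -> Z = 2, P = 1/2
  empty <- list(sites = region$sites[0, ], marks = region$marks[0, , drop = FALSE])
  expect_equal(partition_dp(empty, params)$Z, 1)
  one <- list(sites = data.frame(region = 1L, offset = 0L, width = 8L,
                                 strand = "+", score = 0, rel_affinity = 1,
                                 tf = "A"),
              marks = matrix(0, 1, 0))
  p1 <- model_params(beta = c(A = 1))
  expect_equal(partition_dp(one, p1)$Z, 2)
  expect_equal(binding_probability(one, p1, "A"), 0.5)
  expect_equal(binding_probability(one, p1, "B"), 0)
})

test_that("occupancy is monotone in beta, affinity, and gamma", {
  set.seed(11)
  region <- random_region(4)
  region$marks[] <- runif(length(region$marks), 0.5, 2)
  base <- model_params(beta = c(A = 1), gamma = c(m1 = 2, m2 = 1), sigma = 0)
  p0 <- binding_probability(region, base, "A")

  up_beta <- base; up_beta$beta["A"] <- 2
  expect_gt(binding_probability(region, up_beta, "A"), p0)

  r2 <- region; r2$sites$rel_affinity <- pmin(1, r2$sites$rel_affinity * 1.5)
  expect_gt(binding_probability(r2, base, "A"), p0)

  up_g <- base; up_g$gamma["m1", "A"] <- 3
  expect_gt(binding_probability(region, up_g, "A"), p0)
  down_g <- base; down_g$gamma["m1", "A"] <- 0.5
  expect_lt(binding_probability(region, down_g, "A"), p0)
})

test_that("neutral marks reproduce the sequence-only model exactly", {
  set.seed(13)
  region <- random_region(6)
  p_seq <- model_params(beta = c(A = 1.7), omega = 2, coop_distance = 80)
  p_neutral <- model_params(beta = c(A = 1.7), gamma = c(m1 = 1, m2 = 1),
                            omega = 2, coop_distance = 80)
  p_thresholded <- model_params(beta = c(A = 1.7), gamma = c(m1 = 3, m2 = 0.2),
                                omega = 2, sigma = Inf, coop_distance = 80)
  P0 <- binding_probability(region, p_seq, "A")
  expect_identical(binding_probability(region, p_neutral, "A"), P0)
  expect_identical(binding_probability(region, p_thresholded, "A"), P0)
})

test_that("occupancy is invariant to translating all sites", {
  set.seed(17)
  region <- random_region(5)
  params <- random_params()
  shifted <- region
  shifted$sites$offset <- shifted$sites$offset + 1000L
  expect_equal(binding_probability(shifted, params, "A"),
               binding_probability(region, params, "A"))
})

test_that("extreme affinities are handled in the log domain", {
  one <- list(sites = data.frame(region = 1L, offset = 0L, width = 8L,
                                 strand = "+", score = 0, rel_affinity = 1,
                                 tf = "A"),
              marks = matrix(0, 1, 0))
  p_huge <- model_params(beta = c(A = 1e200))
  expect_equal(binding_probability(one, p_huge, "A"), 1)
  p_tiny <- model_params(beta = c(A = 1e-200))
  expect_equal(binding_probability(one, p_tiny, "A"), 1e-200,
               tolerance = 1e-9)
  # two strong sites, enormous q: still finite and exact in log space
  two <- list(sites = data.frame(region = 1L, offset = c(0L, 50L), width = 8L,
                                 strand = "+", score = 0, rel_affinity = 1,
                                 tf = "A"),
              marks = matrix(0, 2, 0))
  p2 <- model_params(beta = c(A = 1e15), omega = 2)
  expect_equal(binding_probability(two, p2, "A"), 1)
})

test_that("batch prediction matches the per-region path", {
  ds <- small_synth(seed = 21, n_regions = 50)
  params <- ds$params_true
  batch <- predict_occupancy(ds$rs, params, "TF1")
  single <- vapply(seq_len(n_regions(ds$rs)), function(i)
    binding_probability(region_instance(ds$rs, i), params, "TF1"), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
  # and with cooperativity (general DP path in the kernel)
  params$omega <- 3.5
  batch2 <- predict_occupancy(ds$rs, params, "TF1")
  single2 <- vapply(seq_len(n_regions(ds$rs)), function(i)
    binding_probability(region_instance(ds$rs, i), params, "TF1"), numeric(1))
  expect_equal(batch2, single2, tolerance = 1e-12)
})

test_that("enumeration refuses oversized regions and points to the DP", {
  region <- random_region(21)
  expect_error(enumerate_weights(region, random_params()), "partition_dp")
})
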