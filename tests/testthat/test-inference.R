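test_that("objective reproduces textbook correlations and rejects constants", {
  ds <- small_synth(seed = 31, n_regions = 40)
  params <- ds$params_true
  pred <- predict_occupancy(ds$rs, params, "TF1")

  rs1 <- ds$rs
  rs1$regions$observed <- pred
  expect_equal(objective(rs1, params, "TF1"), 1)
  rs2 <- ds$rs
  rs2$regions$observed <- 3 + 10 * pred # affine invariance of Pearson r
  expect_equal(objective(rs2, params, "TF1"), 1)

  # five fixed pairs against the textbook formula
  obs <- c(2, 9, 4, 7, 1)
  rs3 <- subset_regions(ds$rs, 1:5)
  rs3$regions$observed <- obs
  prd <- predict_occupancy(rs3, params, "TF1")
  hand <- sum((obs - mean(obs)) * (prd - mean(prd))) /
    sqrt(sum((obs - mean(obs))^2) * sum((prd - mean(prd))^2))
  expect_equal(objective(rs3, params, "TF1"), hand)

  # constant predictions (one identical site per region): undefined correlation
  ds1 <- synth_dataset(synth_config(n_regions = 30, sites_per_region = 1,
                                    seed = 32))
  rs4 <- ds1$rs
  rs4$sites$rel_affinity <- 1
  rs4$marks[] <- 0
  expect_error(objective(rs4, ds1$params_true, "TF1"), "constant")
})

test_that("fits are deterministic under a fixed seed", {
  ds <- small_synth(seed = 37, n_regions = 120)
  f1 <- fit(ds$rs, "TF1", "mark_act", n_restarts = 4, seed = 9)
  f2 <- fit(ds$rs, "TF1", "mark_act", n_restarts = 4, seed = 9)
  expect_identical(f1$params$beta, f2$params$beta)
  expect_identical(f1$params$gamma, f2$params$gamma)
  expect_identical(f1$objective, f2$objective)
})

test_that("noise-free data from the model is fit to correlation 1", {
  ds <- synth_dataset(synth_config(n_regions = 150, noise_sd = 0, seed = 43))
  f <- fit(ds$rs, "TF1", "mark_act", n_restarts = 6, seed = 2)
  expect_gt(f$objective, 0.999)
})

test_that("ln gamma is recovered with small bias at the study scale", {
  # planted ln gamma = 1, n = 2000 regions, 10% multiplicative noise
  seeds <- 1:8
  lng <- vapply(seeds, function(s) {
    ds <- synth_dataset(synth_config(n_regions = 2000, seed = 1000 + s))
    f <- fit(ds$rs, "TF1", "mark_act", n_restarts = 6, seed = s)
    log(f$params$gamma["mark_act", "TF1"])
  }, numeric(1))
  expect_lt(abs(mean(lng) - 1), 0.1)
  expect_lt(sqrt(mean((lng - 1)^2)), 0.3)
})

test_that("a null mark fits to gamma near 1", {
  cfg <- synth_config(n_regions = 800, seed = 53,
                      marks = list(mark_null = list(rule = "on_site", gamma = 1,
                                                    mu = 1.2, sd = 0.8, max = 4)))
  ds <- synth_dataset(cfg)
  f <- fit(ds$rs, "TF1", "mark_null", n_restarts = 6, seed = 3)
  expect_lt(abs(log(f$params$gamma["mark_null", "TF1"])), 0.15)
})

test_that("shuffling a mark preserves the multiset of window intensities", {
  ds <- small_synth(seed = 59, n_regions = 60)
  before <- ds$rs$mark_windows[["mark_act"]]$intensity
  rs_b <- with_seed(4, shuffle_mark(ds$rs, "mark_act"))
  after <- rs_b$mark_windows[["mark_act"]]$intensity
  expect_equal(sort(before), sort(after))
  expect_false(identical(before, after))
  # per-site intensities are re-read from the permuted windows
  widx <- ds$rs$mark_windows[["mark_act"]]$site_window
  expect_equal(unname(rs_b$marks[, "mark_act"]),
               unname(pmax(after[widx], 0)))
})

test_that("mark scanning flags the causal mark and not the decoy", {
  ds <- synth_dataset(synth_config(n_regions = 600, seed = 61))
  sm <- scan_marks(ds$rs, "TF1", n_permutations = 50, seed = 5,
                   n_restarts = 6, null_restarts = 2)
  expect_s3_class(sm, "mark_scan")
  expect_equal(nrow(attr(sm, "null")$mark_act), 50L)
  act <- sm[sm$mark == "mark_act", ]
  dec <- sm[sm$mark == "mark_decoy", ]
  expect_lt(act$p_adj, 0.05)
  expect_gt(dec$p_adj, 0.05)
  expect_gt(act$gamma, 1.5)
  expect_gt(act$improvement, dec$improvement)
  expect_error(scan_marks(ds$rs, "TF1", n_permutations = 5), ">= 20")
})

test_that("the unified model nests the sequence-only baseline", {
  ds <- small_synth(seed = 67, n_regions = 250)
  uf <- unified_fit(ds$rs, "TF1", c("mark_act", "mark_decoy"),
                    n_restarts = 6, seed = 11)
  expect_gte(uf$objective, uf$r_seq - 1e-8)
  expect_gte(uf$improvement, -1e-8)
  # empty mark list degenerates to the sequence-only fit
  f0 <- unified_fit(ds$rs, "TF1", character(0), n_restarts = 6, seed = 11)
  expect_equal(f0$improvement, 0)
  expect_equal(length(f0$marks_used), 0L)
  # joint training objective is at least each single-mark objective
  f_act <- fit(ds$rs, "TF1", "mark_act", n_restarts = 6, seed = 11)
  expect_gte(uf$objective + 1e-6, f_act$objective)
})

test_that("epigenome-only fits ignore the sequence entirely", {
  ds <- small_synth(seed = 71, n_regions = 200)
  f <- epigenome_only_fit(ds$rs, "TF1", "mark_act", tracks = ds$tracks,
                          n_restarts = 6, seed = 3)
  expect_equal(length(f$marks_used), 1L)
  # scrambling the site affinities does not change the result
  ds2 <- ds
  ds2$rs$sites$rel_affinity <- with_seed(1, runif(nrow(ds$rs$sites)))
  f2 <- epigenome_only_fit(ds2$rs, "TF1", "mark_act", tracks = ds$tracks,
                           n_restarts = 6, seed = 3)
  expect_equal(f$objective, f2$objective)
})

test_that("cross-validation assigns balanced folds and sane test r", {
  ds <- synth_dataset(synth_config(n_regions = 100, noise_sd = 0.05, seed = 73))
  cv <- crossvalidate(ds$rs, "TF1", "mark_act", k_folds = 4, seed = 2,
                      n_restarts = 4)
  folds <- attr(cv, "folds")
  expect_equal(as.integer(table(folds)), rep(25L, 4))
  for (f in cv) {
    expect_false(is.na(f$test_objective))
    expect_gt(f$test_objective, 0.8) # near-clean data generalizes
  }
})

test_that("epigenomic motifs collect per-TF gammas with neutral gaps", {
  ds <- small_synth(seed = 79, n_regions = 150)
  f <- fit(ds$rs, "TF1", "mark_act", n_restarts = 4, seed = 1)
  m <- epigenomic_motif(list(TF1 = f))
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(m["mark_act", "TF1"],
               unname(f$params$gamma["mark_act", "TF1"]))
  # a second TF without that mark gets the neutral value
  f2 <- f; f2$tf <- "TF2"; f2$marks_used <- character(0)
  f2$params <- model_params(beta = c(TF2 = 1))
  m2 <- epigenomic_motif(list(TF1 = f, TF2 = f2))
  expect_equal(m2["mark_act", "TF2"], 1)
})

test_that("interaction networks keep only significant marks with signs", {
  scan <- data.frame(tf = "TF1", mark = c("a", "b", "c"),
                     gamma = c(2.5, 0.4, 1.8),
                     p_adj = c(0.001, 0.04, 0.6))
  net <- interaction_network(scan, alpha = 0.05)
  expect_equal(net$mark, c("a", "b"))
  expect_equal(net$sign, c("positive", "negative"))
  expect_equal(nrow(interaction_network(scan, alpha = 0.01)), 1L)
  none <- scan; none$p_adj <- 0.9
  expect_equal(nrow(interaction_network(none)), 0L)
})

test_that("fitted parameters round-trip through JSON", {
  ds <- small_synth(seed = 83, n_regions = 100)
  f <- fit(ds$rs, "TF1", "mark_act", n_restarts = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(f, path)
  p <- read_params(path)
  expect_equal(p$beta, f$params$beta)
  expect_equal(p$gamma, f$params$gamma)
  expect_equal(p$sigma, f$params$sigma)
})
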