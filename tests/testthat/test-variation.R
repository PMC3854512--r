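strength_fixture <- function(seed = 301, n_regions = 120) {
  synth_dataset(synth_config(
    n_regions = n_regions, seed = seed,
    marks = list(mark_cc = list(rule = "class_conditional", gamma = exp(1),
                                mu = 0.5, mu_weak = 2.5, sd = 0.3, max = 4))))
}

test_that("regions partition into strong/weak/mixed/none by site scores", {
  m <- default_motif()
  con <- m$consensus_score
  mk_rs <- function(scores) {
    sites <- data.frame(region = 1L, offset = seq(0, by = 30,
                                                   length.out = length(scores)),
                        width = 8L, strand = "+", score = scores,
                        rel_affinity = exp(scores - con), tf = "TF1")
    as_region_set(list(sites = sites, marks = matrix(0, length(scores), 0)))
  }
  expect_equal(classify_regions(mk_rs(con), m)$class, "strong_only")
  expect_equal(classify_regions(mk_rs(con - 5), m)$class, "weak_only")
  expect_equal(classify_regions(mk_rs(c(con - 1, con - 5)), m)$class, "mixed")
  expect_equal(classify_regions(mk_rs(con - 10), m)$class, "none")
  expect_error(classify_regions(mk_rs(con), m, strong_delta = 5, weak_delta = 4),
               "exceed")

  # partition property on a generated cohort
  ds <- strength_fixture()
  cls <- classify_regions(ds$rs, default_motif())
  expect_true(all(cls$class %in% c("strong_only", "weak_only", "mixed", "none")))
  expect_equal(nrow(cls), n_regions(ds$rs))
})

test_that("intensity profiles average the track around region midpoints", {
  ds <- strength_fixture()
  cls <- classify_regions(ds$rs, default_motif())$class
  # a constant track profiles flat at the constant for every class
  span <- max(ds$gen$regions$end)
  const <- track(data.frame(chrom = "chrS", start = 0L, end = span,
                            intensity = 1.3))
  prof <- intensity_profile(ds$rs, const, cls, halfwidth = 200, bin = 100)
  expect_true(all(abs(prof$mean - 1.3) < 1e-12))

  # a bump planted at the centers of weak-only regions only
  centers <- (ds$rs$regions$start + ds$rs$regions$end) / 2
  weak <- cls == "weak_only"
  expect_gt(sum(weak), 3)
  bump <- track(data.frame(chrom = "chrS",
                           start = floor(centers[weak] - 50),
                           end = floor(centers[weak] + 50),
                           intensity = 2))
  profb <- intensity_profile(ds$rs, bump, cls, halfwidth = 200, bin = 100)
  at0 <- function(cl) profb$mean[profb$class == cl & profb$position == -50]
  expect_gt(at0("weak_only"), at0("strong_only") + 1.5)

  expect_warning(
    intensity_profile(ds$rs, const, factor(cls, levels = c(unique(cls), "ghost")),
                      halfwidth = 200, bin = 100),
    "ghost")
})

test_that("the epigenomic boost concentrates on weak-site regions", {
  ds <- strength_fixture(seed = 307, n_regions = 400)
  cls <- classify_regions(ds$rs, default_motif())$class
  pw <- ds$params_true
  boost <- epigenomic_boost_delta(ds$rs, pw, neutral_marks(pw), "TF1", cls)
  expect_true(all(boost$delta >= 0))
  sm <- attr(boost, "summary")
  mean_of <- function(cl) sm$delta[sm$class == cl]
  expect_gt(mean_of("weak_only"), mean_of("mixed"))
  expect_gt(mean_of("mixed"), mean_of("strong_only"))

  # neutral marks give exactly zero boost; repression gives non-positive
  z <- epigenomic_boost_delta(ds$rs, neutral_marks(pw), neutral_marks(pw),
                              "TF1", cls)
  expect_true(all(z$delta == 0))
  prep <- pw; prep$gamma[] <- 0.5
  neg <- epigenomic_boost_delta(ds$rs, prep, neutral_marks(pw), "TF1", cls)
  expect_true(all(neg$delta <= 0))
})

test_that("accuracy improvements from marks favor weak-site regions", {
  ds <- strength_fixture(seed = 311, n_regions = 400)
  cls <- classify_regions(ds$rs, default_motif())$class
  labels <- ds$binding$p_true >= 0.35 # truth from the generating model
  pw <- ds$params_true
  tab <- accuracy_improvement(ds$rs, labels, pw, neutral_marks(pw), "TF1", cls,
                              cutoffs = c(0.3, 0.35, 0.4))
  imp <- function(cl, ct) tab$improvement[tab$class == cl & tab$cutoff == ct]
  expect_gte(imp("weak_only", 0.3), imp("strong_only", 0.3))
  expect_gte(imp("weak_only", 0.35), imp("strong_only", 0.35))

  # identical predictions improve nothing; an impossible cutoff is inert
  same <- accuracy_improvement(ds$rs, labels, pw, pw, "TF1", cls)
  expect_true(all(same$improvement == 0))
  high <- accuracy_improvement(ds$rs, labels, pw, neutral_marks(pw), "TF1",
                               cls, cutoffs = 1.0)
  expect_true(all(high$improvement == 0))
})

test_that("the difference ratio is symmetric, scale-free, and guarded", {
  expect_equal(difference_ratio(3, 1), 2)
  expect_equal(difference_ratio(1, 3), 2)
  expect_equal(difference_ratio(10 * 3, 10 * 1), 2)
  expect_equal(difference_ratio(5, 5), 0)
  expect_true(is.na(difference_ratio(0, 2)))
})

test_that("DSDB/DSNDB classification follows the DR threshold", {
  paired <- data.frame(region = c("a", "b", "c", "d"),
                       intensity_i = c(3, 5, 2, 0),
                       intensity_j = c(1, 5, 1.5, 2))
  out <- classify_dsdb(paired, dr_threshold = 1)
  expect_equal(out$class, c("DSDB", "DSNDB", "DSNDB", NA))
  expect_equal(out$dr[1:3], c(2, 0, 1/3))
  expect_true(out$excluded[4])
  # threshold sensitivity
  out2 <- classify_dsdb(paired, dr_threshold = 0.2)
  expect_equal(out2$class[3], "DSDB")
})

test_that("allele score differences reduce to single weight differences", {
  m <- default_motif()
  con <- consensus_sequence(m)
  swap <- function(s, p, b) { substr(s, p, p) <- b; s }
  alt <- swap(con, 3, "T") # motif position 3: C -> T
  pairs <- data.frame(region = c("same", "snp_in", "snp_out"),
                      seq_i = c(con, con, paste0(con, "A")),
                      seq_j = c(con, alt, paste0(con, "G")))
  d <- pswm_score_difference(pairs, m)
  expect_equal(d$abs_diff[1], 0)
  expect_equal(d$abs_diff[2], unname(abs(m$weights["C", 3] - m$weights["T", 3])))
  expect_equal(d$abs_diff[3], 0) # substitution outside the motif
})

test_that("a buffering mark planted on DSNDB regions is detected by profile", {
  ds <- strength_fixture(seed = 313, n_regions = 200)
  with_seed(8, {
    n <- n_regions(ds$rs)
    cls <- sample(c("DSDB", "DSNDB"), n, replace = TRUE)
    centers <- (ds$rs$regions$start + ds$rs$regions$end) / 2
    sel <- cls == "DSNDB"
    buffer <- track(data.frame(chrom = "chrS",
                               start = floor(centers[sel] - 100),
                               end = floor(centers[sel] + 100),
                               intensity = runif(sum(sel), 1, 2)))
    prof <- intensity_profile(ds$rs, buffer, cls, halfwidth = 300, bin = 100)
    m0 <- function(cl) prof$mean[prof$class == cl & prof$position == 50]
    expect_gt(m0("DSNDB"), m0("DSDB"))
    # and the group comparison is significant
    site_int <- ifelse(sel, 1.5, 0)
    ht <- compare_dsdb_groups(site_int, cls)
    expect_lt(ht$p.value, 1e-10)
  })
})
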