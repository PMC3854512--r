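# Strong/weak binding-site analyses and inter-individual binding variation.
#
# Sites are called strong or weak by their PSWM log-odds score relative to
# the consensus score; regions are classified by which site strengths they
# contain. Inter-individual comparisons classify SNP-containing sites into
# DSDB (different sequence, different binding) and DSNDB (different
# sequence, no difference in binding) by the difference ratio
# DR = |I_i - I_j| / min(I_i, I_j).

#' Classify regions by binding-site strength
#'
#' A site is strong iff `score >= consensus - strong_delta` and weak iff
#' `consensus - weak_delta <= score < consensus - strong_delta`. A region is
#' `strong_only`, `weak_only`, or `mixed` by the strengths of the sites it
#' contains; regions without any site at or above the weak threshold are
#' class `none` (excluded from downstream strength analyses).
#'
#' @param rs a `region_set`.
#' @param pswm the [pswm] used for scanning (supplies the consensus score).
#' @param strong_delta,weak_delta score offsets below the consensus defining
#'   the strong and weak thresholds (defaults 3.5 and 7.0).
#' @return data.frame `id`, `class`, `n_strong`, `n_weak`; thresholds in
#'   attributes.
#' @export
classify_regions <- function(rs, pswm, strong_delta = 3.5, weak_delta = 7.0) {
  if (weak_delta <= strong_delta) {
    stop("'weak_delta' must exceed 'strong_delta'", call. = FALSE)
  }
  con <- pswm$consensus_score
  s_thr <- con - strong_delta
  w_thr <- con - weak_delta
  strong <- rs$sites$score >= s_thr
  weak <- rs$sites$score >= w_thr & !strong
  nr <- n_regions(rs)
  n_strong <- tabulate(rs$sites$region[strong], nbins = nr)
  n_weak <- tabulate(rs$sites$region[weak], nbins = nr)
  cls <- ifelse(n_strong > 0 & n_weak > 0, "mixed",
         ifelse(n_strong > 0, "strong_only",
         ifelse(n_weak > 0, "weak_only", "none")))
  out <- data.frame(id = rs$regions$id, class = cls,
                    n_strong = n_strong, n_weak = n_weak,
                    stringsAsFactors = FALSE)
  attr(out, "strong_threshold") <- s_thr
  attr(out, "weak_threshold") <- w_thr
  out
}

#' Positional mark-intensity profile per region class
#'
#' Averages a track's intensity at binned positions centered on each
#' region's midpoint, separately per region class — the superposed-peak
#' profile used to compare mark levels around strong- versus weak-site
#' regions (and DSDB versus DSNDB regions).
#'
#' @param rs a `region_set` with genomic coordinates.
#' @param trk a [track].
#' @param classes character vector of per-region class labels (e.g. the
#'   `class` column of [classify_regions()]).
#' @param halfwidth profile half-width in bp around the region midpoint.
#' @param bin bin size in bp.
#' @return data.frame `class`, `position` (bin center, bp relative to the
#'   region midpoint), `mean`, `sd`, `n`. Classes without regions are
#'   omitted with a warning.
#' @export
intensity_profile <- function(rs, trk, classes, halfwidth = 1000, bin = 100) {
  stopifnot(length(classes) == n_regions(rs))
  if (anyNA(rs$regions$start)) stop("regions lack genomic coordinates", call. = FALSE)
  centers <- (rs$regions$start + rs$regions$end) / 2
  offsets <- seq(-halfwidth + bin / 2, halfwidth - bin / 2, by = bin)
  lev <- if (is.factor(classes)) levels(classes) else unique(classes)
  empty <- lev[!lev %in% as.character(classes[!is.na(classes)])]
  if (length(empty)) warning("empty classes omitted: ", paste(empty, collapse = ", "))
  rows <- list()
  for (cl in lev) {
    idx <- which(classes == cl)
    if (length(idx) == 0L) next
    m <- matrix(NA_real_, nrow = length(idx), ncol = length(offsets))
    for (r in seq_along(idx)) {
      pos <- centers[idx[r]] + offsets
      widx <- locate_window(trk, rep(rs$regions$chrom[idx[r]], length(pos)), pos)
      m[r, ] <- ifelse(is.na(widx), 0, trk$windows$intensity[widx])
    }
    rows[[cl]] <- data.frame(class = cl, position = offsets,
                             mean = colMeans(m),
                             sd = apply(m, 2L, sd),
                             n = length(idx), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class change in predicted occupancy from the epigenome
#'
#' `dP = P(with marks) - P(marks neutral)` per region, summarized by region
#' class — the quantity behind the observation that the epigenomic boost is
#' largest in weak-site-only regions.
#'
#' @param rs a `region_set`.
#' @param params_with a [model_params] including mark influences.
#' @param params_without the same model with all `gamma = 1` (pass e.g. the
#'   fitted params with `gamma` reset); predictions use it as the baseline.
#' @param tf TF identity.
#' @param classes per-region class labels.
#' @return data.frame `id`, `class`, `p_with`, `p_without`, `delta`; the
#'   per-class mean table in `attr(, "summary")`.
#' @export
epigenomic_boost_delta <- function(rs, params_with, params_without, tf,
                                   classes) {
  stopifnot(length(classes) == n_regions(rs))
  p1 <- predict_occupancy(rs, params_with, tf)
  p0 <- predict_occupancy(rs, params_without, tf)
  out <- data.frame(id = rs$regions$id, class = classes,
                    p_with = p1, p_without = p0, delta = p1 - p0,
                    stringsAsFactors = FALSE)
  sm <- stats::aggregate(delta ~ class, data = out, FUN = mean)
  attr(out, "summary") <- sm
  out
}

#' Set all mark influences of a parameter set to neutral
#' @param params a [model_params]
#' @return the same parameters with every `gamma = 1`
#' @export
neutral_marks <- function(params) {
  params$gamma[] <- 1
  params
}

#' Accuracy improvement from the epigenome per region class and cutoff
#'
#' Binarizes predicted binding probabilities at each cutoff with and without
#' the epigenomic marks and reports, per region class, the difference in the
#' proportion of correctly predicted regions
#' (`accuracy_with - accuracy_without`).
#'
#' @param rs a `region_set`.
#' @param labels logical vector: is each region truly bound.
#' @param params_with,params_without see [epigenomic_boost_delta()].
#' @param tf TF identity.
#' @param classes per-region class labels.
#' @param cutoffs probability cutoffs (defaults 0.3, 0.35, 0.4 — weak,
#'   medium, strong).
#' @return data.frame `class`, `cutoff`, `acc_with`, `acc_without`,
#'   `improvement`, `n`.
#' @export
accuracy_improvement <- function(rs, labels, params_with, params_without, tf,
                                 classes, cutoffs = c(0.3, 0.35, 0.4)) {
  stopifnot(length(labels) == n_regions(rs),
            length(classes) == n_regions(rs))
  p1 <- predict_occupancy(rs, params_with, tf)
  p0 <- predict_occupancy(rs, params_without, tf)
  rows <- list()
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    for (ct in cutoffs) {
      a1 <- mean((p1[idx] >= ct) == labels[idx])
      a0 <- mean((p0[idx] >= ct) == labels[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, cutoff = ct, acc_with = a1, acc_without = a0,
        improvement = a1 - a0, n = length(idx), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Difference ratio of paired binding intensities
#'
#' `DR = |I_i - I_j| / min(I_i, I_j)`; symmetric in the two individuals and
#' invariant to a common rescaling of both intensities.
#'
#' @param intensity_i,intensity_j per-region binding intensities of the two
#'   individuals (both > 0).
#' @return numeric DR values (NA where `min(I_i, I_j) = 0`).
#' @export
difference_ratio <- function(intensity_i, intensity_j) {
  mn <- pmin(intensity_i, intensity_j)
  out <- abs(intensity_i - intensity_j) / mn
  out[mn <= 0] <- NA_real_
  out
}

#' Classify SNP-containing sites into DSDB and DSNDB
#'
#' Regions with `DR >= dr_threshold` are DSDB (different sequence, different
#' binding); the rest are DSNDB. Records with a zero intensity in either
#' individual have undefined DR and are flagged `excluded`. Only
#' homozygous-SNP sites should be supplied (filter upstream).
#'
#' @param paired data.frame with columns `region`, `intensity_i`,
#'   `intensity_j` (and any others, carried through).
#' @param dr_threshold DR cutoff for DSDB (default 1).
#' @return the input with added columns `dr`, `class`
#'   (`"DSDB"`/`"DSNDB"`/`NA`), `excluded`.
#' @export
classify_dsdb <- function(paired, dr_threshold = 1) {
  stopifnot(all(c("intensity_i", "intensity_j") %in% names(paired)))
  if (any(paired$intensity_i < 0) || any(paired$intensity_j < 0)) {
    stop("binding intensities must be >= 0", call. = FALSE)
  }
  dr <- difference_ratio(paired$intensity_i, paired$intensity_j)
  paired$dr <- dr
  paired$excluded <- is.na(dr)
  paired$class <- ifelse(is.na(dr), NA_character_,
                         ifelse(dr >= dr_threshold, "DSDB", "DSNDB"))
  paired
}

#' Absolute PSWM score difference between paired alleles
#'
#' Scores each individual's site sequence with the PSWM (maximum over
#' strands) and returns the absolute difference of the two
#' sequence-determined binding energies per region. A substitution outside
#' the motif yields 0; a single substitution at motif position p yields
#' `|w[b1, p] - w[b2, p]|`.
#'
#' @param pairs data.frame with columns `region`, `seq_i`, `seq_j` (allele
#'   sequences of equal length, at least the motif length).
#' @param pswm a [pswm].
#' @return data.frame `region`, `score_i`, `score_j`, `abs_diff`.
#' @export
pswm_score_difference <- function(pairs, pswm) {
  best_score <- function(s) {
    idx <- seq_to_int(s)
    max(c(score_offsets(idx, pswm$weights),
          score_offsets(idx, revcomp_weights(pswm$weights))), na.rm = TRUE)
  }
  si <- vapply(pairs$seq_i, best_score, numeric(1), USE.NAMES = FALSE)
  sj <- vapply(pairs$seq_j, best_score, numeric(1), USE.NAMES = FALSE)
  data.frame(region = pairs$region, score_i = si, score_j = sj,
             abs_diff = abs(si - sj), stringsAsFactors = FALSE)
}

#' Rank-sum comparison of a statistic between DSDB and DSNDB groups
#'
#' Mann-Whitney test of `values` between the two classes.
#'
#' @param values numeric statistic per record (e.g. mark intensity or
#'   absolute PSWM score difference).
#' @param class class labels (`"DSDB"`/`"DSNDB"`), NA ignored.
#' @return the `htest` from [stats::wilcox.test()].
#' @export
compare_dsdb_groups <- function(values, class) {
  ok <- !is.na(class)
  wilcox.test(values[ok & class == "DSDB"], values[ok & class == "DSNDB"])
}
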