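# Thermodynamic occupancy core.
#
# A region with n binding sites occupies one of 2^n configurations c (each
# site bound or free). The Boltzmann weight of a configuration is
#
#   W(c) = prod_{i bound} q_i  *  prod_{consecutive bound pairs (i,j)} w(i,j)
#
# where q_i is the epigenome-modulated site affinity
#
#   q_i = beta_A * K(S_i)/K(S_con) * prod_k gamma_k^{I_k,i * [I_k,i > sigma]}
#
# with beta_A = [A] * K(S_con) (TF concentration times consensus association
# constant), and w(i,j) = omega if the gap between the two bound sites is at
# most coop_distance, else 1. Configurations with sterically overlapping
# bound sites are excluded; the empty configuration has weight 1. The
# partition function Z = sum_c W(c) and the probability that TF A is bound
# anywhere in the region is P_A = (Z - Z_excluding_A) / Z, where
# Z_excluding_A restricts the sum to configurations with no A-site bound.

#' Construct thermodynamic model parameters
#'
#' @param beta named numeric vector of `beta_A = [A] * K(S_con)` per TF
#'   (dimensionless; the TF concentration and the consensus association
#'   constant are not separately identifiable). All values > 0.
#' @param gamma mark-influence parameters `gamma_k^A` (> 0; 1 = neutral):
#'   either a marks x TFs matrix with dimnames, or a named numeric vector
#'   (mark names) when there is a single TF.
#' @param omega binding cooperativity (> 0; 1 = none): a scalar applied to
#'   every TF pair, or a symmetric TF x TF matrix with dimnames.
#' @param sigma intensity threshold below which a mark is treated as
#'   undetected noise (default 0: all measured intensities contribute).
#' @param coop_distance maximum gap in bp between two bound sites for the
#'   cooperativity weight to apply (default 100).
#' @return object of class `model_params`.
#' @export
model_params <- function(beta, gamma = NULL, omega = 1, sigma = 0,
                         coop_distance = 100) {
  if (is.null(names(beta)) || any(beta <= 0) || any(!is.finite(beta))) {
    stop("'beta' must be a named vector of positive finite values", call. = FALSE)
  }
  tfs <- names(beta)
  if (is.null(gamma)) {
    gamma <- matrix(numeric(0), nrow = 0, ncol = length(tfs),
                    dimnames = list(NULL, tfs))
  } else if (!is.matrix(gamma)) {
    if (length(gamma) > 0 && is.null(names(gamma))) {
      stop("'gamma' must be named by mark", call. = FALSE)
    }
    gamma <- matrix(rep(gamma, length(tfs)), ncol = length(tfs),
                    dimnames = list(names(gamma), tfs))
  }
  if (nrow(gamma) > 0 && (any(gamma <= 0) || any(!is.finite(gamma)))) {
    stop("'gamma' values must be positive and finite", call. = FALSE)
  }
  if (is.matrix(omega)) {
    if (!isSymmetric(unname(omega))) stop("'omega' matrix must be symmetric", call. = FALSE)
    if (any(omega <= 0)) stop("'omega' must be positive", call. = FALSE)
  } else if (length(omega) != 1L || omega <= 0 || !is.finite(omega)) {
    stop("'omega' must be a positive scalar or symmetric matrix", call. = FALSE)
  }
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, omega = omega,
                 sigma = sigma, coop_distance = coop_distance),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params\n  beta: ",
      paste(sprintf("%s=%.4g", names(x$beta), x$beta), collapse = ", "), "\n",
      sep = "")
  if (nrow(x$gamma) > 0) {
    cat("  gamma:\n")
    print(round(x$gamma, 4))
  }
  om <- if (is.matrix(x$omega)) "matrix" else sprintf("%.4g", x$omega)
  cat(sprintf("  omega: %s, sigma: %.3g, coop_distance: %d bp\n",
              om, x$sigma, as.integer(x$coop_distance)))
  invisible(x)
}

get_omega <- function(params, tf_a, tf_b) {
  if (!is.matrix(params$omega)) return(params$omega)
  om <- params$omega
  if (tf_a %in% rownames(om) && tf_b %in% colnames(om)) om[tf_a, tf_b] else 1
}

#' Epigenome-modulated affinity of a single binding site
#'
#' Computes `q_i = beta_tf * rel_affinity * prod_k f(k, i)` with
#' `f(k, i) = gamma_k^I_k,i` when the mark intensity exceeds the noise
#' threshold `sigma`, and 1 otherwise.
#'
#' @param site one-row data.frame (or list) with `rel_affinity` and `tf`.
#' @param mark_intensities named numeric vector of ln-enrichment intensities
#'   `I_k,i` at the site.
#' @param params a [model_params].
#' @param tf TF identity of the site (defaults to `site$tf`).
#' @return the scalar affinity `q_i`.
#' @export
site_affinity <- function(site, mark_intensities, params, tf = site$tf) {
  q <- params$beta[[tf]] * site$rel_affinity
  for (k in names(mark_intensities)) {
    I <- mark_intensities[[k]]
    if (I > params$sigma && k %in% rownames(params$gamma)) {
      q <- q * params$gamma[k, tf]^I
    }
  }
  unname(q)
}

# vectorized log q for all sites of a region (or a whole region_set's site
# table): log(beta) + log(rel_affinity) + sum_k I * log(gamma) over-threshold
site_log_affinities <- function(sites, marks, params) {
  if (nrow(sites) == 0L) return(numeric(0))
  tf <- sites$tf
  logq <- log(params$beta[tf]) + log(sites$rel_affinity)
  gm <- params$gamma
  for (k in rownames(gm)) {
    if (!k %in% colnames(marks)) next
    I <- marks[, k]
    eff <- ifelse(I > params$sigma, I, 0)
    logq <- logq + eff * log(gm[k, tf])
  }
  unname(logq)
}

# gap in bp between two sites given as (start, end) half-open intervals
site_gap <- function(end_i, start_j) start_j - end_i

#' Enumerate all occupancy configurations of a region (brute force)
#'
#' Lists every one of the 2^n occupancy configurations with its Boltzmann
#' weight. Configurations in which two bound sites overlap are sterically
#' excluded: they are kept in the listing (the physical state space is 2^n
#' before exclusion) but flagged inadmissible with weight 0. The empty
#' configuration has weight 1. Intended as the exact oracle for
#' [partition_dp()]; guarded to n <= 20 sites.
#'
#' @param region a region instance (see [region_instance()]) or any list with
#'   `sites` and `marks`.
#' @param params a [model_params].
#' @return data.frame with one row per configuration: columns `config`
#'   (occupancy string over sites in offset order), `n_bound`, `admissible`,
#'   `weight`.
#' @export
enumerate_weights <- function(region, params) {
  sites <- region$sites
  n <- nrow(sites)
  if (n > 20L) {
    stop("region has ", n, " sites; brute-force enumeration is limited to 20 ",
         "-- use partition_dp()", call. = FALSE)
  }
  logq <- site_log_affinities(sites, region$marks, params)
  starts <- sites$offset
  ends <- sites$offset + sites$width
  n_config <- 2L^n
  config <- character(n_config)
  weight <- numeric(n_config)
  admissible <- logical(n_config)
  n_bound <- integer(n_config)
  for (ci in seq_len(n_config)) {
    occ <- as.integer(intToBits(ci - 1L))[seq_len(max(n, 1L))]
    if (n == 0L) occ <- integer(0)
    bound <- which(occ == 1L)
    config[ci] <- paste(occ, collapse = "")
    n_bound[ci] <- length(bound)
    ok <- TRUE
    if (length(bound) > 1L) {
      for (u in seq_len(length(bound) - 1L)) {
        if (starts[bound[u + 1L]] < ends[bound[u]]) { ok <- FALSE; break }
      }
    }
    admissible[ci] <- ok
    if (!ok) { weight[ci] <- 0; next }
    lw <- sum(logq[bound])
    if (length(bound) > 1L) {
      for (u in seq_len(length(bound) - 1L)) {
        i <- bound[u]; j <- bound[u + 1L]
        if (site_gap(ends[i], starts[j]) <= params$coop_distance) {
          lw <- lw + log(get_omega(params, sites$tf[i], sites$tf[j]))
        }
      }
    }
    weight[ci] <- exp(lw)
  }
  data.frame(config = config, n_bound = n_bound, admissible = admissible,
             weight = weight, stringsAsFactors = FALSE)
}

# core DP over sorted sites: returns log Z for the site subset `keep`
# F(i) = q_i * (1 + sum_{j < i, end_j <= start_i} F(j) * w(j, i))
# Z = 1 + sum_i F(i); computed in the log domain for overflow safety.
dp_logZ <- function(sites, logq, params, keep = rep(TRUE, nrow(sites))) {
  idx <- which(keep)
  n <- length(idx)
  if (n == 0L) return(0)
  starts <- sites$offset[idx]
  ends <- sites$offset[idx] + sites$width[idx]
  tfs <- sites$tf[idx]
  lq <- logq[idx]
  logF <- numeric(n)
  for (i in seq_len(n)) {
    terms <- 0 # log(1): the term where i is the only bound site
    if (i > 1L) {
      j <- which(ends[seq_len(i - 1L)] <= starts[i])
      if (length(j) > 0L) {
        lw <- ifelse(site_gap(ends[j], starts[i]) <= params$coop_distance,
                     log(vapply(j, function(jj)
                       get_omega(params, tfs[jj], tfs[i]), numeric(1))),
                     0)
        terms <- c(terms, logF[j] + lw)
      }
    }
    logF[i] <- lq[i] + logsumexp(terms)
  }
  logsumexp(c(0, logF))
}

#' Partition function of a region by exact dynamic programming
#'
#' Computes `Z` and, for each TF present, `Z_excluding[tf]` (the partition
#' function restricted to configurations in which no site of that TF is
#' bound) in O(n^2) time via a linear-chain recursion over sites sorted by
#' offset. Exactly equals the brute-force enumeration sum. Accumulation is
#' carried in the log domain, so extreme affinities do not overflow.
#'
#' @param region a region instance (list with `sites`, `marks`).
#' @param params a [model_params].
#' @return list with `Z`, `logZ`, `Z_excluding` (named by TF), and
#'   `logZ_excluding`.
#' @export
partition_dp <- function(region, params) {
  sites <- region$sites
  logq <- site_log_affinities(sites, region$marks, params)
  logZ <- dp_logZ(sites, logq, params)
  tfs <- unique(sites$tf)
  logZex <- vapply(tfs, function(a)
    dp_logZ(sites, logq, params, keep = sites$tf != a), numeric(1))
  list(Z = exp(logZ), logZ = logZ,
       Z_excluding = stats::setNames(exp(logZex), tfs),
       logZ_excluding = stats::setNames(logZex, tfs))
}

#' Probability that a TF is bound anywhere in a region
#'
#' `P_A(O) = (Z - Z_excluding_A) / Z`. For a region whose sites all belong to
#' one TF this is `(Z - 1)/Z`; for a single site it reduces to the closed
#' form `q / (1 + q)`.
#'
#' @param region a region instance (list with `sites`, `marks`).
#' @param params a [model_params].
#' @param tf TF identity.
#' @return probability in [0, 1]; 0 if the region has no site of `tf`.
#' @export
binding_probability <- function(region, params, tf) {
  sites <- region$sites
  if (nrow(sites) == 0L || !any(sites$tf == tf)) return(0)
  logq <- site_log_affinities(sites, region$marks, params)
  logZ <- dp_logZ(sites, logq, params)
  logZex <- dp_logZ(sites, logq, params, keep = sites$tf != tf)
  p <- -expm1(logZex - logZ) # 1 - Zex/Z
  min(max(p, 0), 1)
}

#' Predicted binding probability for every region of a region set
#'
#' Batch evaluation of [binding_probability()] across a region set through a
#' compiled dynamic-programming kernel; used by the fitting routines. Applies
#' a scalar cooperativity to TF pairs (pass a `model_params` with scalar
#' `omega`; per-pair matrices are supported by the per-region R path).
#'
#' @param rs a `region_set`.
#' @param params a [model_params] with scalar `omega`.
#' @param tf TF whose occupancy is predicted.
#' @return numeric vector of P_A, one per region (0 for regions without
#'   sites of `tf`).
#' @export
predict_occupancy <- function(rs, params, tf) {
  stopifnot(inherits(rs, "region_set"))
  if (is.matrix(params$omega)) {
    return(vapply(seq_len(n_regions(rs)), function(i)
      binding_probability(region_instance(rs, i), params, tf), numeric(1)))
  }
  sites <- rs$sites
  nr <- n_regions(rs)
  if (nrow(sites) == 0L) return(numeric(nr))
  logq <- site_log_affinities(sites, rs$marks, params)
  # CSR-style pointer: sites are sorted by region then offset
  counts <- tabulate(sites$region, nbins = nr)
  ptr <- c(0L, cumsum(counts))
  dp_prob_batch(ptr, as.numeric(sites$offset),
                as.numeric(sites$offset + sites$width),
                logq, sites$tf == tf,
                params$omega, params$coop_distance)
}
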