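# Parameter estimation and mark-significance workflow.
#
# Parameters are learned by maximizing the correlation between observed
# binding intensities I(A) and model-predicted binding probabilities P_A(O)
# across regions, optimizing in unconstrained log space (ln beta, ln gamma,
# ln omega) by quasi-Newton (BFGS) from random restarts. Mark significance
# follows the two-step workflow: each mark is scanned individually against
# an empirical null of fits on intensity-shuffled tracks, then the retained
# marks are combined into one unified model.

#' Correlation objective between observed and predicted binding
#'
#' @param rs a `region_set` with observed intensities.
#' @param params a [model_params].
#' @param tf TF identity.
#' @param metric `"pearson"` or `"spearman"`.
#' @return the correlation `corr(I(A), P_A(O))` across regions.
#' @export
objective <- function(rs, params, tf, metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  obs <- rs$regions$observed
  ok <- !is.na(obs)
  if (sum(ok) < 3L) stop("need >= 3 regions with observed intensities", call. = FALSE)
  pred <- predict_occupancy(rs, params, tf)[ok]
  if (sd(pred) == 0) {
    stop("predicted binding probabilities are constant; correlation undefined",
         call. = FALSE)
  }
  cor(obs[ok], pred, method = metric)
}

new_fit_result <- function(params, objective, marks_used, n_restarts,
                           converged, seed, metric, tf,
                           test_objective = NA_real_) {
  structure(list(params = params, objective = objective,
                 test_objective = test_objective, marks_used = marks_used,
                 n_restarts = n_restarts, converged = converged, seed = seed,
                 metric = metric, tf = tf),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: %s r = %.4f%s (marks: %s; %d restarts%s)\n",
              x$tf, x$metric, x$objective,
              if (is.na(x$test_objective)) "" else
                sprintf(", test r = %.4f", x$test_objective),
              if (length(x$marks_used)) paste(x$marks_used, collapse = ",")
              else "none",
              x$n_restarts,
              if (x$converged) "" else "; NOT converged"))
  print(x$params)
  invisible(x)
}

# build model_params from an unconstrained log-parameter vector
theta_to_params <- function(theta, tf, marks, omega_free, sigma, coop_distance) {
  beta <- setNames(exp(theta[1L]), tf)
  gamma <- if (length(marks)) {
    setNames(exp(theta[1L + seq_along(marks)]), marks)
  } else NULL
  omega <- if (omega_free) exp(theta[length(theta)]) else 1
  model_params(beta = beta, gamma = gamma, omega = omega, sigma = sigma,
               coop_distance = coop_distance)
}

#' Fit model parameters by correlation maximization
#'
#' Maximizes `corr(I(A), P_A(O))` over `ln beta`, one `ln gamma` per supplied
#' mark, and optionally `ln omega`, by BFGS (Nelder-Mead for the
#' rank-correlation metric) from `n_restarts` random initial points; the
#' best restart is returned. Deterministic given `seed`. Cooperativity is
#' fixed to `omega = 1` unless `omega_free = TRUE` (set it free only when
#' TFBS cooperativity is itself of interest). Regions without sites
#' contribute P = 0.
#'
#' @param rs a `region_set` with observed intensities; only sites of `tf`
#'   enter the fit.
#' @param tf TF identity.
#' @param marks character vector of mark names whose influence parameters
#'   are fitted (subset of `colnames(rs$marks)`); empty for the
#'   sequence-only model.
#' @param n_restarts number of random restarts (500 for full-scale analyses;
#'   smaller values suffice for the few-parameter single-mark fits).
#' @param seed integer seed controlling the restart initial points.
#' @param metric correlation metric, `"pearson"` or `"spearman"`.
#' @param omega_free fit a homotypic cooperativity parameter.
#' @param sigma,coop_distance fixed model settings (see [model_params()]).
#' @param init_range range of the uniform random log-parameter
#'   initializations; the first restart always starts at 0 (all parameters
#'   neutral).
#' @return a `fit_result`: fitted [model_params], training `objective`,
#'   `marks_used`, `n_restarts`, `converged`, `seed`.
#' @export
fit <- function(rs, tf, marks = character(0), n_restarts = 50, seed = 1,
                metric = c("pearson", "spearman"), omega_free = FALSE,
                sigma = 0, coop_distance = 100, init_range = c(-3, 3)) {
  metric <- match.arg(metric)
  stopifnot(inherits(rs, "region_set"))
  if (!all(marks %in% colnames(rs$marks))) {
    stop("unknown marks: ",
         paste(setdiff(marks, colnames(rs$marks)), collapse = ", "),
         call. = FALSE)
  }
  if (!any(rs$sites$tf == tf)) stop("no sites of TF '", tf, "' in any region",
                                    call. = FALSE)
  obs <- rs$regions$observed
  ok <- !is.na(obs)
  if (sum(ok) < 3L) stop("need >= 3 regions with observed intensities", call. = FALSE)
  obs <- obs[ok]
  # restrict to this TF's sites: other TFs' parameters are not in the fit
  rs_fit <- rs
  keep <- rs$sites$tf == tf
  rs_fit$sites <- rs$sites[keep, , drop = FALSE]
  rs_fit$marks <- rs$marks[keep, , drop = FALSE]

  npar <- 1L + length(marks) + as.integer(omega_free)
  # static per-site quantities, hoisted out of the objective
  sites <- rs_fit$sites
  nr <- n_regions(rs_fit)
  ptr <- c(0L, cumsum(tabulate(sites$region, nbins = nr)))
  s_start <- as.numeric(sites$offset)
  s_end <- as.numeric(sites$offset + sites$width)
  lra <- log(sites$rel_affinity)
  me <- rs_fit$marks[, marks, drop = FALSE]
  me[me <= sigma] <- 0 # below-threshold intensities exert no influence
  is_target <- rep(TRUE, nrow(sites))
  negobj <- function(theta) {
    if (any(abs(theta) > 30)) return(1e6)
    logq <- theta[1L] + lra
    if (length(marks)) logq <- logq + drop(me %*% theta[1L + seq_along(marks)])
    omega <- if (omega_free) exp(theta[npar]) else 1
    pred <- dp_prob_batch(ptr, s_start, s_end, logq, is_target,
                          omega, coop_distance)[ok]
    if (anyNA(pred) || sd(pred) == 0) return(1e6)
    -cor(obs, pred, method = metric)
  }
  inits <- with_seed(seed, {
    m <- matrix(runif((n_restarts - 1L) * npar, init_range[1], init_range[2]),
                ncol = npar)
    rbind(rep(0, npar), m)
  })
  method <- if (metric == "pearson") "BFGS" else "Nelder-Mead"
  best <- NULL
  for (i in seq_len(nrow(inits))) {
    res <- tryCatch(
      optim(inits[i, ], negobj, method = method,
            control = list(maxit = 200, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer restarts failed", call. = FALSE)
  params <- theta_to_params(best$par, tf, marks, omega_free, sigma, coop_distance)
  new_fit_result(params = params, objective = -best$value,
                 marks_used = marks, n_restarts = n_restarts,
                 converged = best$convergence == 0, seed = seed,
                 metric = metric, tf = tf)
}

#' Shuffle one mark's intensities
#'
#' Permutes the assignment of intensities for one epigenomic mark and
#' recomputes per-site intensities. With `granularity = "window"` (the
#' default when the region set retains its track-window mapping) the
#' intensities of the track windows are permuted across the genome,
#' preserving the multiset of window intensities; `"site"` permutes per-site
#' intensities directly.
#'
#' @param rs a `region_set`.
#' @param mark mark name.
#' @param granularity `"window"` or `"site"`.
#' @return the region set with the mark's intensity column shuffled.
#' @export
shuffle_mark <- function(rs, mark, granularity = c("window", "site")) {
  granularity <- match.arg(granularity)
  if (!mark %in% colnames(rs$marks)) stop("unknown mark: ", mark, call. = FALSE)
  if (granularity == "window" && !is.null(rs$mark_windows[[mark]])) {
    mw <- rs$mark_windows[[mark]]
    perm <- sample(length(mw$intensity))
    shuffled <- mw$intensity[perm]
    v <- shuffled[mw$site_window]
    v[is.na(v)] <- 0
    rs$marks[, mark] <- pmax(v, 0)
    rs$mark_windows[[mark]]$intensity <- shuffled
  } else {
    rs$marks[, mark] <- rs$marks[sample(nrow(rs$marks)), mark]
  }
  rs
}

#' Scan each epigenomic mark for interaction with a TF
#'
#' Step one of the inference workflow: each mark is fitted individually
#' together with the sequence model, and its fitted influence `gamma` is
#' compared to an empirical null distribution of `gamma` values obtained by
#' refitting on intensity-shuffled tracks. The two-sided empirical p-value
#' for `gamma = 1` uses the add-one correction
#' `p = (1 + #{|ln gamma_null| >= |ln gamma_hat|}) / (1 + n_permutations)`;
#' p-values are Holm-adjusted across marks. The correlation attained on each
#' shuffled dataset is also recorded, so the improvement-based control
#' (sequence plus randomized epigenome) can be read from the same scan.
#'
#' @param rs a `region_set` with observed intensities.
#' @param tf TF identity.
#' @param marks marks to scan (default: all marks in `rs`).
#' @param n_permutations empirical-null size (200 for full-scale analyses).
#' @param seed integer seed; fits and shuffles are deterministic given it.
#' @param n_restarts restarts for the observed-data fits.
#' @param null_restarts restarts for each null fit (defaults to
#'   `n_restarts`).
#' @param granularity shuffle granularity, see [shuffle_mark()].
#' @param metric correlation metric.
#' @param sigma,coop_distance fixed model settings.
#' @return data.frame of class `mark_scan` with one row per mark: `tf`,
#'   `mark`, `gamma`, `r_seq` (sequence-only correlation), `r_epi`,
#'   `improvement = (r_epi - r_seq)/r_seq`, `p_raw`, `p_adj`. The per-mark
#'   null draws (fitted `gamma` and correlation per permutation) are in
#'   `attr(, "null")`.
#' @export
scan_marks <- function(rs, tf, marks = colnames(rs$marks),
                       n_permutations = 200, seed = 1, n_restarts = 50,
                       null_restarts = n_restarts,
                       granularity = c("window", "site"),
                       metric = c("pearson", "spearman"),
                       sigma = 0, coop_distance = 100) {
  metric <- match.arg(metric)
  granularity <- match.arg(granularity)
  if (n_permutations < 20L) {
    stop("'n_permutations' must be >= 20 for a usable empirical null", call. = FALSE)
  }
  fit0 <- fit(rs, tf, character(0), n_restarts = n_restarts, seed = seed,
              metric = metric, sigma = sigma, coop_distance = coop_distance)
  r_seq <- fit0$objective
  nulls <- list()
  rows <- vector("list", length(marks))
  for (km in seq_along(marks)) {
    m <- marks[km]
    fm <- fit(rs, tf, m, n_restarts = n_restarts, seed = seed + 97L * km,
              metric = metric, sigma = sigma, coop_distance = coop_distance)
    g_hat <- fm$params$gamma[m, tf]
    null_g <- numeric(n_permutations)
    null_r <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      sseed <- seed + 10000L * km + b
      rs_b <- with_seed(sseed, shuffle_mark(rs, m, granularity))
      fb <- fit(rs_b, tf, m, n_restarts = null_restarts, seed = sseed,
                metric = metric, sigma = sigma, coop_distance = coop_distance)
      null_g[b] <- fb$params$gamma[m, tf]
      null_r[b] <- fb$objective
    }
    p_raw <- (1 + sum(abs(log(null_g)) >= abs(log(g_hat)))) /
      (1 + n_permutations)
    rows[[km]] <- data.frame(
      tf = tf, mark = m, gamma = unname(g_hat), r_seq = r_seq,
      r_epi = fm$objective,
      improvement = (fm$objective - r_seq) / r_seq,
      p_raw = p_raw, stringsAsFactors = FALSE)
    nulls[[m]] <- data.frame(gamma = null_g, r = null_r)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_raw, method = "holm")
  attr(out, "null") <- nulls
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("mark_scan", class(out))
  out
}

#' Unified fit over the retained epigenomic marks
#'
#' Step two of the workflow: the marks retained by [scan_marks()] are
#' combined into one joint model; the result reports the improvement of the
#' training correlation over the sequence-only baseline,
#' `(r - r_seq) / r_seq`. With an empty mark list this degenerates to the
#' sequence-only fit.
#'
#' @param rs a `region_set` with observed intensities.
#' @param tf TF identity.
#' @param significant_marks marks to include (e.g. those with adjusted
#'   p below the cutoff in a [scan_marks()] table).
#' @param ... passed to [fit()].
#' @return a `fit_result` with extra fields `r_seq` and `improvement`.
#' @export
unified_fit <- function(rs, tf, significant_marks = character(0), ...) {
  f <- fit(rs, tf, marks = significant_marks, ...)
  f0 <- if (length(significant_marks)) fit(rs, tf, character(0), ...) else f
  f$r_seq <- f0$objective
  f$improvement <- (f$objective - f0$objective) / f0$objective
  f
}

#' Epigenome-only fit (sequence term ablated)
#'
#' Replaces each region's sites by a single nominal site with relative
#' affinity fixed to 1, so the prediction becomes invariant to the sequence;
#' only `beta` and the mark's `gamma` are fitted. The nominal site's mark
#' intensity is taken at the region midpoint from `tracks` when provided
#' (with region coordinates), otherwise as the maximum per-site intensity
#' observed in the region.
#'
#' @param rs a `region_set` with observed intensities.
#' @param tf TF identity.
#' @param mark single mark name.
#' @param tracks optional named list of [track]s to re-extract midpoint
#'   intensities from.
#' @param ... passed to [fit()].
#' @return a `fit_result`.
#' @export
epigenome_only_fit <- function(rs, tf, mark, tracks = NULL, ...) {
  nr <- n_regions(rs)
  reg <- rs$regions
  width <- 10L
  sites <- data.frame(region = seq_len(nr),
                      offset = pmax(0L, floor(reg$length / 2) - width %/% 2L),
                      width = width, strand = "+", score = 0,
                      rel_affinity = 1, tf = tf, stringsAsFactors = FALSE)
  if (!is.null(tracks) && !anyNA(reg$start)) {
    trk <- tracks[[mark]]
    mid <- reg$start + reg$length / 2
    widx <- locate_window(trk, reg$chrom, mid)
    v <- ifelse(is.na(widx), 0, trk$windows$intensity[widx])
    marks <- matrix(pmax(v, 0), ncol = 1, dimnames = list(NULL, mark))
    mw <- list(intensity = trk$windows$intensity, site_window = widx)
  } else {
    per_reg <- vapply(seq_len(nr), function(i) {
      v <- rs$marks[rs$sites$region == i, mark]
      if (length(v)) max(v) else 0
    }, numeric(1))
    marks <- matrix(per_reg, ncol = 1, dimnames = list(NULL, mark))
    mw <- NULL
  }
  rs2 <- structure(list(regions = reg, sites = sites, marks = marks,
                        mark_windows = if (is.null(mw)) list() else
                          setNames(list(mw), mark)),
                   class = "region_set")
  fit(rs2, tf, marks = mark, ...)
}

#' k-fold cross-validated fits
#'
#' Fold assignment is a seeded random permutation; each fold's model is
#' fitted on the complement and evaluated on the held-out regions.
#'
#' @param rs a `region_set` with observed intensities.
#' @param tf TF identity.
#' @param marks marks included in the model.
#' @param k_folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to [fit()].
#' @return list of `fit_result`, one per fold, each with `test_objective`
#'   and a `fold` field; fold assignments in `attr(, "folds")`.
#' @export
crossvalidate <- function(rs, tf, marks = character(0), k_folds = 4, seed = 1,
                          ...) {
  if (k_folds < 2L) stop("'k_folds' must be >= 2", call. = FALSE)
  nr <- n_regions(rs)
  folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = nr)))
  if (min(table(folds)) < 3L) stop("a fold has fewer than 3 regions", call. = FALSE)
  out <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    train <- subset_regions(rs, which(folds != f))
    test <- subset_regions(rs, which(folds == f))
    fr <- fit(train, tf, marks = marks, seed = seed + f, ...)
    fr$test_objective <- tryCatch(
      objective(test, fr$params, tf, metric = fr$metric),
      error = function(e) NA_real_)
    fr$fold <- f
    out[[f]] <- fr
  }
  attr(out, "folds") <- folds
  out
}

#' Epigenomic-motif matrix from per-TF fits
#'
#' Collects the fitted mark-influence parameters of several TFs into a
#' marks x TFs matrix — each column is the TF's epigenomic motif
#' `{gamma_1, ..., gamma_K}`. Marks absent from a TF's model are neutral
#' (gamma = 1).
#'
#' @param fits named list of `fit_result` objects (names = TF ids), or a
#'   single `fit_result`.
#' @return numeric matrix marks x TFs.
#' @export
epigenomic_motif <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- setNames(list(fits), fits$tf)
  tfs <- names(fits)
  marks <- unique(unlist(lapply(fits, function(f) f$marks_used)))
  out <- matrix(1, nrow = length(marks), ncol = length(tfs),
                dimnames = list(marks, tfs))
  for (tf in tfs) {
    g <- fits[[tf]]$params$gamma
    if (nrow(g) > 0) out[rownames(g), tf] <- g[, fits[[tf]]$tf]
  }
  out
}

#' TF-mark interaction network from scan results
#'
#' Edges connect a TF to every mark whose adjusted p-value is below `alpha`;
#' the edge sign is positive for `gamma > 1` (synergy) and negative for
#' `gamma < 1` (antagonism).
#'
#' @param scan_results a [scan_marks()] table, or a list of them (one per
#'   TF), or their `rbind`.
#' @param alpha adjusted p-value cutoff (default 0.05).
#' @return data.frame `tf`, `mark`, `sign`, `gamma`, `p_adj` (possibly empty).
#' @export
interaction_network <- function(scan_results, alpha = 0.05) {
  if (is.list(scan_results) && !is.data.frame(scan_results)) {
    scan_results <- do.call(rbind, lapply(scan_results, as.data.frame))
  }
  sel <- scan_results$p_adj < alpha
  data.frame(tf = scan_results$tf[sel], mark = scan_results$mark[sel],
             sign = ifelse(scan_results$gamma[sel] > 1, "positive", "negative"),
             gamma = scan_results$gamma[sel],
             p_adj = scan_results$p_adj[sel],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write fitted parameters to JSON
#' @param fit a `fit_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_params <- function(fit, path) {
  p <- fit$params
  obj <- list(tf = fit$tf, metric = fit$metric, objective = fit$objective,
              marks_used = fit$marks_used, seed = fit$seed,
              beta = as.list(p$beta),
              gamma = if (nrow(p$gamma)) as.list(setNames(p$gamma[, fit$tf],
                                                          rownames(p$gamma)))
                      else list(),
              omega = if (is.matrix(p$omega)) NULL else p$omega,
              sigma = p$sigma, coop_distance = p$coop_distance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read fitted parameters from JSON
#' @param path JSON written by [write_params()]
#' @return a [model_params]
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(beta = unlist(obj$beta),
               gamma = if (length(obj$gamma)) unlist(obj$gamma) else NULL,
               omega = obj$omega %||% 1, sigma = obj$sigma,
               coop_distance = obj$coop_distance)
}
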