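# Constraint-based simulation studies.
#
# Occupancy sigmoids versus TF concentration under activation/repression
# marks, the dynamic range of binding probability over the feasible
# concentration band (a proxy for transcriptional noise), and the
# cooperativity-boost experiment in which a pair of weak sites overtakes
# single medium/strong sites as the mark intensity rises.

#' Define a simulation scenario
#'
#' @param sites data.frame with `rel_affinity` (in (0, 1]) and `offset` (bp);
#'   `width` defaults to 10 bp.
#' @param gamma mark influence (> 1 activation, < 1 repression, 1 none).
#' @param intensity mark intensity at every site for concentration sweeps
#'   (ln enrichment; default 1).
#' @param omega homotypic cooperativity.
#' @param K_con association constant of the consensus site, per molecule
#'   (so `beta = conc * K_con`).
#' @param conc_grid TF concentrations (molecules per cell), log-spaced.
#' @param intensity_grid mark intensities for intensity sweeps, log-spaced
#'   over the plotted decades.
#' @param coop_distance cooperativity range in bp.
#' @param tf TF label.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(sites = data.frame(rel_affinity = 1, offset = 0),
                         gamma = 1, intensity = 1, omega = 1,
                         K_con = 1e-4,
                         conc_grid = 10^seq(1, 8, length.out = 141),
                         intensity_grid = 10^seq(-2, 2, length.out = 201),
                         coop_distance = 100, tf = "TF") {
  if (any(sites$rel_affinity <= 0) || any(sites$rel_affinity > 1)) {
    stop("rel_affinity must be in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(conc_grid, strictly = TRUE) ||
      is.unsorted(intensity_grid, strictly = TRUE)) {
    stop("grids must be strictly increasing", call. = FALSE)
  }
  if (is.null(sites$width)) sites$width <- 10L
  sites <- sites[order(sites$offset), , drop = FALSE]
  structure(list(sites = sites, gamma = gamma, intensity = intensity,
                 omega = omega, K_con = K_con, conc_grid = conc_grid,
                 intensity_grid = intensity_grid,
                 coop_distance = coop_distance, tf = tf),
            class = "sim_scenario")
}

# region instance + params for one (beta, intensity) evaluation point
scenario_region <- function(sc, intensity) {
  n <- nrow(sc$sites)
  sites <- data.frame(region = 1L, offset = sc$sites$offset,
                      width = sc$sites$width, strand = "+", score = 0,
                      rel_affinity = sc$sites$rel_affinity, tf = sc$tf,
                      stringsAsFactors = FALSE)
  marks <- matrix(intensity, nrow = n, ncol = 1,
                  dimnames = list(NULL, "mark"))
  list(sites = sites, marks = marks)
}

scenario_prob <- function(sc, conc, intensity) {
  params <- model_params(beta = setNames(conc * sc$K_con, sc$tf),
                        gamma = c(mark = sc$gamma), omega = sc$omega,
                        sigma = 0, coop_distance = sc$coop_distance)
  binding_probability(scenario_region(sc, intensity), params, sc$tf)
}

#' Binding probability as a function of TF concentration
#'
#' Sweeps the scenario's concentration grid at fixed mark intensity and
#' influence; `beta = conc * K_con` at each point.
#'
#' @param scenario a [sim_scenario].
#' @return data.frame `conc`, `P` (strictly increasing in `conc`), with the
#'   scenario attached as an attribute.
#' @export
binding_curve_vs_concentration <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  P <- vapply(scenario$conc_grid, function(a)
    scenario_prob(scenario, a, scenario$intensity), numeric(1))
  out <- data.frame(conc = scenario$conc_grid, P = P)
  attr(out, "scenario") <- scenario
  out
}

#' Concentration at half-maximal occupancy
#'
#' Locates by bisection the TF concentration at which the binding
#' probability reaches half of its asymptotic maximum (the maximum is
#' evaluated at a saturating concentration). For a single site the closed
#' form is `conc = 1 / (K_con * rel_affinity * gamma^I)`.
#'
#' @param scenario a [sim_scenario].
#' @param interval concentration search interval (molecules per cell).
#' @param tol relative bisection tolerance.
#' @return the half-maximum concentration in molecules per cell.
#' @export
half_max_concentration <- function(scenario, interval = c(1e-2, 1e12),
                                   tol = 1e-10) {
  pmax <- scenario_prob(scenario, interval[2] * 1e3, scenario$intensity)
  f <- function(lc) scenario_prob(scenario, exp(lc), scenario$intensity) - pmax / 2
  r <- uniroot(f, log(interval), tol = tol)
  exp(r$root)
}

#' Dynamic range of binding probability over a concentration band
#'
#' `dP = P(upper) - P(lower)` over the physiologically feasible band of TF
#' concentrations; the dynamic range of occupancy over this band is the
#' model's proxy for transcriptional noise.
#'
#' @param curve a curve from [binding_curve_vs_concentration()] (its attached
#'   scenario is used for exact evaluation at the band edges; otherwise the
#'   curve is interpolated linearly on log-concentration).
#' @param conc_band lower/upper concentrations in molecules per cell
#'   (default 10^4 to 3x10^5, the typical eukaryotic range).
#' @return the scalar dynamic range `dP`.
#' @export
noise_dynamic_range <- function(curve, conc_band = c(1e4, 3e5)) {
  sc <- attr(curve, "scenario")
  if (!is.null(sc)) {
    p <- vapply(conc_band, function(a) scenario_prob(sc, a, sc$intensity),
                numeric(1))
  } else {
    p <- stats::approx(log(curve$conc), curve$P, xout = log(conc_band))$y
  }
  p[2] - p[1]
}

#' Binding probability as a function of mark intensity
#'
#' Sweeps each scenario's intensity grid at a fixed TF concentration.
#'
#' @param scenarios named list of [sim_scenario]s (they share the first
#'   scenario's intensity grid).
#' @param conc_fixed TF concentration (molecules per cell).
#' @return data.frame `scenario`, `intensity`, `P`; per-scenario curves in
#'   `attr(, "curves")` each carrying its scenario.
#' @export
binding_curve_vs_intensity <- function(scenarios, conc_fixed) {
  stopifnot(length(scenarios) > 0, !is.null(names(scenarios)))
  grid <- scenarios[[1]]$intensity_grid
  curves <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    P <- vapply(grid, function(I) scenario_prob(sc, conc_fixed, I), numeric(1))
    out <- data.frame(intensity = grid, P = P)
    attr(out, "scenario") <- sc
    attr(out, "conc") <- conc_fixed
    out
  })
  names(curves) <- names(scenarios)
  flat <- do.call(rbind, lapply(names(curves), function(nm)
    cbind(scenario = nm, curves[[nm]], stringsAsFactors = FALSE)))
  attr(flat, "curves") <- curves
  flat
}

#' Locate the crossing of two binding curves
#'
#' Finds the smallest grid abscissa where the sign of `P_a - P_b` flips and
#' refines it by bisection — exactly, when both curves carry their scenario
#' and concentration (the model is re-evaluated inside the bracket), or on
#' the linear interpolant otherwise.
#'
#' @param curve_a,curve_b data.frames with `intensity` and `P` on a common
#'   grid, e.g. from [binding_curve_vs_intensity()].
#' @param tol absolute tolerance on the crossing intensity.
#' @return the crossing intensity, or `NULL` when the curves do not cross.
#' @export
find_crossing <- function(curve_a, curve_b, tol = 1e-6) {
  if (!isTRUE(all.equal(curve_a$intensity, curve_b$intensity))) {
    stop("curves must share their intensity grid", call. = FALSE)
  }
  d <- curve_a$P - curve_b$P
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(NULL)
  flips <- nz[which(diff(s[nz]) != 0)]
  if (length(flips) == 0L) return(NULL)
  i <- flips[1L]
  j <- nz[which(nz > i)[1L]]
  lo <- curve_a$intensity[i]
  hi <- curve_a$intensity[j]
  sa <- attr(curve_a, "scenario"); sb <- attr(curve_b, "scenario")
  ca <- attr(curve_a, "conc"); cb <- attr(curve_b, "conc")
  if (!is.null(sa) && !is.null(sb) && !is.null(ca) && !is.null(cb)) {
    f <- function(x) scenario_prob(sa, ca, x) - scenario_prob(sb, cb, x)
  } else {
    f <- function(x) {
      stats::approx(curve_a$intensity, d, xout = x)$y
    }
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Default cooperativity-boost scenario set
#'
#' The four genomic sequences compared in the weak-site cooperativity
#' experiment: single strong (relative affinity 1), medium (0.1), weak
#' (0.02) sites, and a pair of weak sites 60 bp apart with homotypic
#' cooperativity `omega`, all under the same activation mark. At the
#' package's default TF concentration (`beta = conc * K_con = 20`) and
#' `omega = 5`, the two-weak-site curve overtakes the medium and then the
#' strong single-site curve within the realistic enrichment-ratio range
#' [1, 40] (ln intensity in [0, ln 40]); with `omega = 1` no overtaking
#' occurs in that range.
#'
#' @param gamma activation-mark influence (default `exp(1)`, so the affinity
#'   factor at intensity I is the enrichment ratio `e^I`).
#' @param omega cooperativity of the weak-site pair.
#' @param strong,medium,weak relative affinities of the single sites.
#' @param pair_gap gap between the two weak sites in bp.
#' @param K_con consensus association constant per molecule.
#' @param intensity_grid shared intensity grid.
#' @return named list of [sim_scenario]s: `strong`, `medium`, `weak`,
#'   `two_weak`.
#' @export
coop_boost_scenarios <- function(gamma = exp(1), omega = 5,
                                 strong = 1, medium = 0.1, weak = 0.02,
                                 pair_gap = 60, K_con = 1e-4,
                                 intensity_grid = 10^seq(-2, 2, length.out = 201)) {
  single <- function(rel) sim_scenario(
    sites = data.frame(rel_affinity = rel, offset = 0),
    gamma = gamma, omega = 1, K_con = K_con,
    intensity_grid = intensity_grid)
  width <- 10L
  list(
    strong = single(strong),
    medium = single(medium),
    weak = single(weak),
    two_weak = sim_scenario(
      sites = data.frame(rel_affinity = c(weak, weak),
                         offset = c(0, width + pair_gap)),
      gamma = gamma, omega = omega, K_con = K_con,
      intensity_grid = intensity_grid)
  )
}
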