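# Seeded synthetic-data generator.
#
# Emulates the inputs of a genome-wide TF binding study: candidate regions
# with planted motif instances of controlled strength, windowed epigenomic
# mark tracks whose intensities are tied to sites (informative marks) or
# independent of them (decoys), and observed binding intensities simulated
# forward from the thermodynamic model with multiplicative log-normal noise
# (ChIP-seq peak intensities are positive and right-skewed).

#' Default synthetic motif
#'
#' A sharp 8 bp motif (70/10/10/10 counts per position) used by the
#' synthetic-data generator; per-position mismatch cost is about 1.9 in
#' log-odds units, so 2 mismatches give a relative affinity near 0.02 and 4
#' mismatches near 4e-4.
#'
#' @param tf TF identifier.
#' @return a [pswm].
#' @export
default_motif <- function(tf = "TF1") {
  consensus <- "TGCATAAC"
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(10, nrow = 4, ncol = length(bases),
                   dimnames = list(DNA_BASES, NULL))
  for (p in seq_along(bases)) counts[bases[p], p] <- 70
  pfm_to_pswm(counts, pseudocount = 1, tf_id = tf)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the package's analyses assume:
#' 2000 candidate regions of 500 bp scored against 200 bp mark windows, an
#' 8 bp motif planted at strong/medium/weak strength (0/2/3 mismatches to the
#' consensus), one informative activation mark with true influence
#' `gamma = e` (ln gamma = 1) placed on windows covering sites, one decoy
#' mark independent of sites, and 10% multiplicative log-normal noise on
#' observed intensities.
#'
#' @param n_regions number of candidate regions.
#' @param region_length region length in bp.
#' @param base_comp background base composition (A, C, G, T).
#' @param motif a [pswm] used both to plant and to score sites.
#' @param sites_per_region integer vector sampled uniformly for the number of
#'   planted sites per region.
#' @param site_class_probs named probabilities for site strength classes.
#' @param site_class_mutations named mismatch counts defining each class.
#' @param marks named list of mark specifications; each a list with `rule`
#'   (`"on_site"`, `"decoy"`, `"class_conditional"`, `"constant"`), true
#'   influence `gamma`, and intensity distribution parameters `mu`, `sd`,
#'   `max` (truncated normal on [0, max]), plus `prob` (decoy window rate),
#'   `mu_weak` (class-conditional mean on weak-only regions) or `value`
#'   (constant rule) where relevant.
#' @param window_size mark window size in bp.
#' @param beta,omega,sigma,coop_distance true thermodynamic parameters used
#'   to simulate binding (see [model_params()]).
#' @param noise_sd standard deviation of the log-normal observation noise.
#' @param scale multiplicative scale of observed intensities.
#' @param min_gap minimum gap in bp between planted sites.
#' @param seed mandatory integer seed; all generator output is a
#'   deterministic function of the configuration.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_regions = 2000,
                         region_length = 500,
                         base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         motif = default_motif(),
                         sites_per_region = 1:3,
                         site_class_probs = c(strong = 0.3, medium = 0.4, weak = 0.3),
                         site_class_mutations = c(strong = 0, medium = 2, weak = 3),
                         marks = list(
                           mark_act = list(rule = "on_site", gamma = exp(1),
                                           mu = 1.2, sd = 0.8, max = 4),
                           mark_decoy = list(rule = "decoy", gamma = 1,
                                             mu = 1.2, sd = 0.8, max = 4,
                                             prob = 0.3)
                         ),
                         window_size = 200,
                         beta = 5, omega = 1, sigma = 0, coop_distance = 100,
                         noise_sd = 0.1, scale = 100,
                         min_gap = 10,
                         seed) {
  if (missing(seed)) stop("'seed' is mandatory in synth_config()", call. = FALSE)
  if (abs(sum(site_class_probs) - 1) > 1e-8) {
    stop("site_class_probs must sum to 1", call. = FALSE)
  }
  if (abs(sum(base_comp) - 1) > 1e-8) stop("base_comp must sum to 1", call. = FALSE)
  structure(list(
    n_regions = as.integer(n_regions), region_length = as.integer(region_length),
    base_comp = base_comp, motif = motif,
    sites_per_region = sites_per_region,
    site_class_probs = site_class_probs,
    site_class_mutations = site_class_mutations,
    marks = marks, window_size = as.integer(window_size),
    beta = beta, omega = omega, sigma = sigma,
    coop_distance = coop_distance,
    noise_sd = noise_sd, scale = scale, min_gap = min_gap,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# truncated normal on [0, max] by clamping (point masses at the bounds are
# acceptable for intensity levels; keeps the generator dependency-free)
rint_level <- function(n, mu, sd, max) pmin(pmax(rnorm(n, mu, sd), 0), max)

mutate_consensus <- function(consensus, n_mut) {
  b <- strsplit(consensus, "")[[1]]
  if (n_mut > 0) {
    pos <- sample(length(b), n_mut)
    for (p in pos) b[p] <- sample(setdiff(DNA_BASES, b[p]), 1)
  }
  paste(b, collapse = "")
}

score_instance <- function(instance, motif) {
  idx <- seq_to_int(instance)
  sum(motif$weights[cbind(idx, seq_along(idx))])
}

#' Generate synthetic candidate regions with planted motif instances
#'
#' Regions tile a synthetic chromosome `chrS` contiguously. Site instances
#' are the motif consensus with a class-dependent number of mismatches,
#' inserted at non-overlapping offsets on a random strand; the truth table
#' records each planted site with its PSWM score and relative affinity.
#'
#' @param config a [synth_config].
#' @return list of class `synth_regions` with `sequences` (named character),
#'   `truth` (data.frame of planted sites), `regions` (data.frame `id`,
#'   `chrom`, `start`, `end`), and `config`.
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    L <- config$region_length
    ml <- motif_length(config$motif)
    consensus <- consensus_sequence(config$motif)
    tf <- config$motif$tf_id
    ids <- sprintf("region_%04d", seq_len(config$n_regions))
    seqs <- character(config$n_regions)
    truth <- vector("list", config$n_regions)
    for (r in seq_len(config$n_regions)) {
      bg <- sample(DNA_BASES, L, replace = TRUE, prob = config$base_comp)
      ns <- if (length(config$sites_per_region) == 1L) config$sites_per_region
            else sample(config$sites_per_region, 1L)
      if (ns == 0L) {
        truth[[r]] <- NULL
        seqs[r] <- paste(bg, collapse = "")
        next
      }
      offsets <- integer(0)
      for (tries in seq_len(200L)) {
        cand <- sort(sample(0:(L - ml), ns))
        if (ns == 1L || all(diff(cand) >= ml + config$min_gap)) {
          offsets <- cand; break
        }
      }
      if (length(offsets) == 0L) stop("could not place non-overlapping sites")
      cls <- sample(names(config$site_class_probs), ns, replace = TRUE,
                    prob = config$site_class_probs)
      strand <- sample(c("+", "-"), ns, replace = TRUE)
      rows <- vector("list", ns)
      for (s in seq_len(ns)) {
        inst <- mutate_consensus(consensus, config$site_class_mutations[[cls[s]]])
        planted <- if (strand[s] == "+") inst else revcomp(inst)
        bg[(offsets[s] + 1):(offsets[s] + ml)] <- strsplit(planted, "")[[1]]
        sc <- score_instance(inst, config$motif)
        rows[[s]] <- data.frame(
          region = ids[r], offset = offsets[s], width = ml,
          strand = strand[s], score = sc,
          rel_affinity = exp(sc - config$motif$consensus_score),
          tf = tf, class = cls[s], stringsAsFactors = FALSE)
      }
      truth[[r]] <- do.call(rbind, rows)
      seqs[r] <- paste(bg, collapse = "")
    }
    names(seqs) <- ids
    regions <- data.frame(
      id = ids, chrom = "chrS",
      start = (seq_len(config$n_regions) - 1L) * L,
      end = seq_len(config$n_regions) * L, stringsAsFactors = FALSE)
    structure(list(sequences = seqs, truth = do.call(rbind, truth),
                   regions = regions, config = config),
              class = "synth_regions")
  })
}

# regions whose planted sites are all sub-strong (medium or weak class);
# these are the regions called weak_only by score-threshold classification
weak_only_regions <- function(gen) {
  agg <- tapply(gen$truth$class, gen$truth$region,
                function(cl) all(cl != "strong"))
  names(agg)[unlist(agg)]
}

#' Generate windowed epigenomic tracks for synthetic regions
#'
#' Windows tile the synthetic chromosome at the configured window size.
#' `on_site` marks draw one intensity level per region (truncated normal)
#' and assign it to every window covering a planted site; `decoy` marks
#' assign levels to random windows independently of sites;
#' `class_conditional` marks behave like `on_site` with a higher mean level
#' (`mu_weak`) on regions whose planted sites are all weak; `constant` marks
#' set every window to `value`.
#'
#' @param config a [synth_config].
#' @param gen a `synth_regions` from [generate_regions()].
#' @return named list of [track] objects, one per configured mark.
#' @export
generate_tracks <- function(config, gen) {
  stopifnot(inherits(gen, "synth_regions"))
  with_seed(config$seed + 1L, {
    span <- max(gen$regions$end)
    ws <- config$window_size
    starts <- seq(0L, span - 1L, by = ws)
    ends <- pmin(starts + ws, span)
    nw <- length(starts)
    # global window index covering each planted site's midpoint
    site_reg <- match(gen$truth$region, gen$regions$id)
    site_mid <- gen$regions$start[site_reg] + gen$truth$offset + gen$truth$width / 2
    site_win <- pmin(nw, floor(site_mid / ws) + 1L)
    weak_ids <- weak_only_regions(gen)
    out <- list()
    for (mk in names(config$marks)) {
      spec <- config$marks[[mk]]
      intensity <- numeric(nw)
      if (spec$rule == "constant") {
        intensity[] <- spec$value
      } else if (spec$rule == "decoy") {
        on <- runif(nw) < (spec$prob %||% 0.3)
        intensity[on] <- rint_level(sum(on), spec$mu, spec$sd, spec$max)
      } else if (spec$rule %in% c("on_site", "class_conditional")) {
        mu <- rep(spec$mu, config$n_regions)
        if (spec$rule == "class_conditional") {
          mu[gen$regions$id %in% weak_ids] <- spec$mu_weak %||% (2 * spec$mu)
        }
        level <- rint_level(config$n_regions, mu, spec$sd, spec$max)
        intensity[site_win] <- pmax(intensity[site_win], level[site_reg])
      } else {
        stop("unknown mark rule: ", spec$rule, call. = FALSE)
      }
      out[[mk]] <- track(data.frame(chrom = "chrS", start = starts, end = ends,
                                    intensity = intensity),
                         window_size = ws)
    }
    out
  })
}

#' True model parameters of a synthetic configuration
#' @param config a [synth_config]
#' @return the [model_params] used to simulate binding
#' @export
true_params <- function(config) {
  tf <- config$motif$tf_id
  gm <- vapply(config$marks, function(m) m$gamma, numeric(1))
  model_params(beta = setNames(config$beta, tf), gamma = gm,
               omega = config$omega, sigma = config$sigma,
               coop_distance = config$coop_distance)
}

#' Simulate observed binding intensities from the model
#'
#' Computes the true binding probability of each region under the
#' configuration's true parameters and the generated tracks, then draws
#' `observed = scale * P * exp(eps)`, `eps ~ N(0, noise_sd^2)`.
#'
#' @param config a [synth_config].
#' @param gen a `synth_regions`.
#' @param tracks tracks from [generate_tracks()].
#' @return data.frame `id`, `chrom`, `start`, `end`, `observed`, `p_true`.
#' @export
simulate_binding <- function(config, gen, tracks) {
  rs <- assemble_regions(gen$sequences, gen$truth, tracks,
                         regions = gen$regions)
  p <- predict_occupancy(rs, true_params(config), config$motif$tf_id)
  with_seed(config$seed + 2L, {
    eps <- rnorm(length(p), 0, config$noise_sd)
    data.frame(id = gen$regions$id, chrom = gen$regions$chrom,
               start = gen$regions$start, end = gen$regions$end,
               observed = config$scale * p * exp(eps), p_true = p,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: regions, tracks, binding, and the assembled
#' [region_set] using the planted (truth-table) sites.
#'
#' @param config a [synth_config].
#' @return list with `rs` (region_set with observed intensities), `gen`,
#'   `tracks`, `binding`, `params_true`, `config`.
#' @export
synth_dataset <- function(config) {
  gen <- generate_regions(config)
  tracks <- generate_tracks(config, gen)
  binding <- simulate_binding(config, gen, tracks)
  rs <- assemble_regions(gen$sequences, gen$truth, tracks,
                         binding = binding[, c("id", "observed")],
                         regions = gen$regions)
  list(rs = rs, gen = gen, tracks = tracks, binding = binding,
       params_true = true_params(config), config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits FASTA sequences, one bedGraph per mark, a BED5 binding table, the
#' truth table as TSV, and the configuration as YAML.
#'
#' @param dataset output of [synth_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$gen$sequences, file.path(dir, "regions.fa"))
  for (mk in names(dataset$tracks)) {
    write_track(dataset$tracks[[mk]], file.path(dir, paste0(mk, ".bedgraph")))
  }
  b <- dataset$binding
  utils::write.table(
    data.frame(b$chrom, b$start, b$end, b$id, b$observed),
    file.path(dir, "binding.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$gen$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  cfg_out <- cfg[setdiff(names(cfg), "motif")]
  cfg_out$motif_consensus <- consensus_sequence(cfg$motif)
  cfg_out$marks <- lapply(cfg$marks, function(m) m)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}
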