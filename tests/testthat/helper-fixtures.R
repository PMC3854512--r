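# Shared fixtures, built in code at test time.

# a minimal two-position motif with unequal column preferences
tiny_pswm <- function(tf = "TF") {
  counts <- matrix(c(10, 0, 0, 0,
                     0, 0, 8, 2), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm_to_pswm(counts, pseudocount = 1, tf_id = tf)
}

# random region instance with n sites (possibly overlapping), for oracle checks
random_region <- function(n, two_tf = FALSE, span = 300, width = 8L) {
  offs <- sort(sample(0:span, n))
  sites <- data.frame(
    region = 1L, offset = offs, width = width, strand = "+",
    score = 0, rel_affinity = runif(n, 0.01, 1),
    tf = if (two_tf) sample(c("A", "B"), n, replace = TRUE) else "A",
    stringsAsFactors = FALSE)
  marks <- matrix(runif(n * 2, 0, 3), n, 2, dimnames = list(NULL, c("m1", "m2")))
  list(sites = sites, marks = marks)
}

random_params <- function(two_tf = FALSE, omega_matrix = FALSE) {
  tfs <- if (two_tf) c("A", "B") else "A"
  gamma <- matrix(runif(2 * length(tfs), 0.3, 3), nrow = 2,
                  dimnames = list(c("m1", "m2"), tfs))
  omega <- if (omega_matrix && two_tf) {
    v <- runif(3, 0.5, 4)
    matrix(v[c(1, 2, 2, 3)], 2, 2, dimnames = list(tfs, tfs))
  } else runif(1, 0.5, 4)
  model_params(beta = setNames(runif(length(tfs), 0.1, 5), tfs),
               gamma = gamma, omega = omega,
               sigma = runif(1, 0, 1), coop_distance = 50)
}

# partition function and P(tf bound) straight from the enumeration oracle
brute_force_reference <- function(region, params, tf) {
  ew <- enumerate_weights(region, params)
  occ <- strsplit(ew$config, "")
  bound_tf <- vapply(occ, function(o) any(o == "1" & region$sites$tf == tf),
                     logical(1))
  Z <- sum(ew$weight)
  list(Z = Z, Zex = sum(ew$weight[!bound_tf]),
       P = sum(ew$weight[bound_tf]) / Z)
}

# wrap a standalone region instance as a one-region region_set
as_region_set <- function(region, observed = NA_real_) {
  structure(list(
    regions = data.frame(id = "r1", chrom = NA_character_, start = NA_real_,
                         end = NA_real_,
                         length = max(region$sites$offset + region$sites$width,
                                      0) + 10,
                         observed = observed, stringsAsFactors = FALSE),
    sites = region$sites, marks = region$marks, mark_windows = list()),
    class = "region_set")
}

# small, fast synthetic dataset for inference tests
small_synth <- function(seed, n_regions = 300, ...) {
  synth_dataset(synth_config(n_regions = n_regions, seed = seed, ...))
}
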