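# Position-specific weight matrices (PSWM) and binding-site scanning.
#
# A PSWM stores natural-log odds weights w[b, pos] = ln P(b | motif, pos) -
# ln P(b | background). The consensus score is the maximal attainable score;
# a scanned site's relative affinity K(S_i)/K(S_con) = exp(score -
# consensus_score) = exp(-dE), where dE >= 0 is the extra binding energy (in
# kT units) paid for mismatches to the consensus.

#' Construct a PSWM object
#'
#' @param weights 4 x L numeric matrix of natural-log odds, rows in A,C,G,T
#'   order (rownames are set if missing).
#' @param tf_id transcription factor identifier.
#' @param background background base frequencies used to build the weights.
#' @return an object of class `pswm` with elements `weights`,
#'   `consensus_score`, `tf_id`, `background`.
#' @export
pswm <- function(weights, tf_id = "TF", background = rep(0.25, 4)) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 4L) stop("PSWM weights must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(weights) < 1L) stop("PSWM must have at least one column", call. = FALSE)
  if (any(!is.finite(weights))) stop("PSWM weights must be finite", call. = FALSE)
  rownames(weights) <- DNA_BASES
  obj <- list(
    weights = weights,
    consensus_score = sum(apply(weights, 2L, max)),
    tf_id = as.character(tf_id),
    background = background
  )
  class(obj) <- "pswm"
  obj
}

#' @export
print.pswm <- function(x, ...) {
  cat(sprintf("PSWM '%s': %d positions, consensus score %.4f\n",
              x$tf_id, ncol(x$weights), x$consensus_score))
  cat("consensus:", consensus_sequence(x), "\n")
  invisible(x)
}

#' Motif length of a PSWM
#' @param x a `pswm`
#' @return integer motif length
#' @export
motif_length <- function(x) ncol(x$weights)

#' Consensus sequence of a PSWM
#' @param x a `pswm`
#' @return character string of the highest-scoring base at each position
#' @export
consensus_sequence <- function(x) {
  paste(DNA_BASES[apply(x$weights, 2L, which.max)], collapse = "")
}

#' Build a PSWM from a position frequency (count) matrix
#'
#' @param counts 4 x L nonnegative matrix of base counts, rows A,C,G,T.
#' @param pseudocount total pseudocount distributed according to `background`.
#' @param background background base frequencies (length 4, sums to 1).
#' @param tf_id TF identifier.
#' @return a `pswm`. Weights are
#'   `ln((count + pseudocount * bg_b) / (colsum + pseudocount)) - ln(bg_b)`.
#' @export
pfm_to_pswm <- function(counts, pseudocount = 1, background = rep(0.25, 4),
                        tf_id = "TF") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A,C,G,T)", call. = FALSE)
  if (any(counts < 0)) stop("PFM counts must be nonnegative", call. = FALSE)
  if (length(background) != 4L || any(background <= 0)) {
    stop("'background' must be 4 positive frequencies", call. = FALSE)
  }
  background <- background / sum(background)
  colsum <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2L, colsum + pseudocount, "/")
  w <- log(prob) - log(background)
  pswm(w, tf_id = tf_id, background = background)
}

#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the JASPAR text formats: an optional `>` header line followed by
#' four rows of counts, either bare numbers or `A [ 4 19 0 ... ]` rows.
#'
#' @param path file path.
#' @param pseudocount,background passed to [pfm_to_pswm()].
#' @param tf_id TF identifier; defaults to the header token if present.
#' @return a `pswm`.
#' @export
read_pfm <- function(path, pseudocount = 1, background = rep(0.25, 4),
                     tf_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty PFM file: ", path, call. = FALSE)
  header <- NULL
  if (startsWith(lines[[1L]], ">")) {
    header <- sub("^>\\s*", "", lines[[1L]])
    lines <- lines[-1L]
  }
  if (length(lines) != 4L) {
    stop(sprintf("PFM file '%s' must have 4 count rows, found %d",
                 path, length(lines)), call. = FALSE)
  }
  parse_row <- function(ln, i) {
    ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
    ln <- gsub("[][]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
    if (anyNA(vals)) {
      stop(sprintf("PFM parse error in '%s' at count row %d", path, i),
           call. = FALSE)
    }
    vals
  }
  rows <- lapply(seq_along(lines), function(i) parse_row(lines[[i]], i))
  if (length(unique(lengths(rows))) != 1L) {
    stop("PFM rows have unequal lengths in ", path, call. = FALSE)
  }
  counts <- do.call(rbind, rows)
  if (is.null(tf_id)) {
    tf_id <- if (!is.null(header)) strsplit(header, "\\s+")[[1L]][1L] else
      tools::file_path_sans_ext(basename(path))
  }
  pfm_to_pswm(counts, pseudocount = pseudocount, background = background,
              tf_id = tf_id)
}

# score every offset of an integer-coded sequence against a weight matrix;
# windows containing non-ACGT bases score NA
score_offsets <- function(idx, w) {
  L <- ncol(w)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (l in seq_len(L)) {
    s <- s + w[(l - 1L) * 4L + idx[l:(l + n - 1L)]]
  }
  s
}

# weight matrix of the reverse complement motif
revcomp_weights <- function(w) {
  w[4:1, rev(seq_len(ncol(w))), drop = FALSE]
}

#' Scan a sequence for binding sites on both strands
#'
#' Scores every offset on the forward and reverse strand with the PSWM and
#' returns sites at or above `min_score`, sorted by offset. Overlapping hits
#' (including a forward and reverse hit at the same offset) are all kept;
#' steric exclusion between overlapping bound sites is handled in the
#' occupancy state space, not at scan time.
#'
#' @param sequence a single DNA string (A/C/G/T/N).
#' @param pswm a [pswm] object.
#' @param min_score minimum log-odds score for a reported site. May be given
#'   relative to the consensus as a negative offset via
#'   `min_score = consensus_score(pswm) - delta`.
#' @return data.frame of binding sites: `offset` (0-based start within the
#'   sequence), `width`, `strand`, `score`, `rel_affinity = exp(score -
#'   consensus_score)`, `tf`.
#' @export
scan_sites <- function(sequence, pswm, min_score = pswm$consensus_score - 7) {
  stopifnot(inherits(pswm, "pswm"))
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop("'sequence' must be a single string", call. = FALSE)
  }
  L <- motif_length(pswm)
  if (nchar(sequence) < L) {
    stop(sprintf("sequence (%d bp) shorter than motif (%d bp)",
                 nchar(sequence), L), call. = FALSE)
  }
  idx <- seq_to_int(sequence)
  fwd <- score_offsets(idx, pswm$weights)
  rev <- score_offsets(idx, revcomp_weights(pswm$weights))
  mk <- function(scores, strand) {
    keep <- which(!is.na(scores) & scores >= min_score)
    data.frame(offset = keep - 1L, width = rep(L, length(keep)),
               strand = rep(strand, length(keep)),
               score = scores[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(mk(fwd, "+"), mk(rev, "-"))
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  out$rel_affinity <- exp(out$score - pswm$consensus_score)
  out$tf <- rep(pswm$tf_id, nrow(out))
  rownames(out) <- NULL
  out
}
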