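# Input/output of external formats and assembly of region collections.
#
# Coordinates are 0-based half-open (BED convention) everywhere; wig input is
# converted on read. Track intensities are natural-log enrichment ratios
# (experimental reads / control reads), so an intensity of 1.32 corresponds
# to an enrichment ratio of exp(1.32) = 3.74.

#' Convert a ln-enrichment intensity to an enrichment ratio
#'
#' Track intensities are stored as natural-log ratios of experimental to
#' control read counts; the enrichment ratio is their exponential.
#' @param intensity ln-enrichment value(s)
#' @return enrichment ratio(s), `exp(intensity)`
#' @export
enrichment_ratio <- function(intensity) exp(intensity)

#' Read a FASTA file of candidate regions
#'
#' @param path FASTA file path.
#' @return named character vector of uppercased sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param sequences named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Construct a windowed intensity track
#'
#' @param windows data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `intensity` (ln enrichment).
#' @param window_size nominal window size in bp; inferred as the modal window
#'   width when `NULL`.
#' @return object of class `track` with elements `windows`, `window_size`.
#' @export
track <- function(windows, window_size = NULL) {
  req <- c("chrom", "start", "end", "intensity")
  if (!all(req %in% names(windows))) {
    stop("track windows need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  windows <- windows[, req]
  windows$chrom <- as.character(windows$chrom)
  if (any(!is.finite(windows$intensity))) {
    stop("track intensities must be finite", call. = FALSE)
  }
  if (any(windows$start < 0) || any(windows$end <= windows$start)) {
    stop("track windows must satisfy 0 <= start < end", call. = FALSE)
  }
  o <- order(windows$chrom, windows$start)
  windows <- windows[o, , drop = FALSE]
  same <- windows$chrom[-1L] == windows$chrom[-nrow(windows)]
  if (nrow(windows) > 1L &&
      any(same & windows$start[-1L] < windows$end[-nrow(windows)])) {
    stop("track windows overlap", call. = FALSE)
  }
  if (is.null(window_size)) {
    wd <- windows$end - windows$start
    window_size <- as.integer(names(sort(table(wd), decreasing = TRUE))[1L])
  }
  rownames(windows) <- NULL
  structure(list(windows = windows, window_size = as.integer(window_size)),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track: %d windows (nominal %d bp), intensity range [%.3f, %.3f]\n",
              nrow(x$windows), x$window_size,
              min(x$windows$intensity), max(x$windows$intensity)))
  invisible(x)
}

#' Read a windowed epigenomic intensity track
#'
#' bedGraph and wig files are parsed with `rtracklayer` and converted to
#' 0-based half-open coordinates; `tsv` expects a header line with columns
#' `chrom`, `start`, `end`, `intensity` already in 0-based half-open
#' convention. Intensities are ln enrichment ratios.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"bedgraph"`, `"wig"`, `"tsv"`; `"auto"`
#'   guesses from the file extension.
#' @return a [track].
#' @export
read_track <- function(path, format = c("auto", "bedgraph", "wig", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     bedgraph = , bg = , bedg = "bedgraph",
                     wig = "wig",
                     tsv = , txt = "tsv",
                     stop("cannot guess track format from extension '", ext,
                          "'; pass 'format'", call. = FALSE))
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!is.numeric(df$intensity)) stop("non-numeric intensity column", call. = FALSE)
    return(track(df))
  }
  gr <- rtracklayer::import(path, format = if (format == "bedgraph") "bedGraph" else "wig")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    intensity = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$intensity))) stop("non-numeric track score", call. = FALSE)
  track(df)
}

#' Write a track to bedGraph or TSV
#'
#' @param x a [track].
#' @param path output path.
#' @param format `"bedgraph"` (headerless 4 columns) or `"tsv"` (tab-separated
#'   with header).
#' @return `path`, invisibly
#' @export
write_track <- function(x, path, format = c("bedgraph", "tsv")) {
  stopifnot(inherits(x, "track"))
  format <- match.arg(format)
  w <- x$windows
  if (format == "bedgraph") {
    lines <- sprintf("%s\t%d\t%d\t%s", w$chrom, w$start, w$end,
                     formatC(w$intensity, digits = 10, format = "g"))
    writeLines(lines, path)
  } else {
    utils::write.table(w, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read observed per-region binding intensities
#'
#' Accepts BED4 (`chrom start end score`), BED5/BED6+ with the score in the
#' fifth column, or a TSV with a header containing `chrom`, `start`, `end`,
#' optional `id`, and `observed`/`score`.
#'
#' @param path file path.
#' @return data.frame with `id`, `chrom`, `start`, `end`, `observed`.
#' @export
read_binding_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    score_col <- intersect(c("observed", "score", "intensity"), names(df))[1]
    if (is.na(score_col)) stop("binding table missing score column", call. = FALSE)
    out <- data.frame(
      id = if ("id" %in% names(df)) as.character(df$id) else
        sprintf("%s:%d-%d", df$chrom, df$start, df$end),
      chrom = as.character(df$chrom), start = df$start, end = df$end,
      observed = df[[score_col]], stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 4L) stop("binding table missing score column", call. = FALSE)
    score <- if (ncol(df) >= 5L) df[[5L]] else df[[4L]]
    id <- if (ncol(df) >= 5L) as.character(df[[4L]]) else
      sprintf("%s:%d-%d", df[[1L]], df[[2L]], df[[3L]])
    out <- data.frame(id = id, chrom = as.character(df[[1L]]),
                      start = df[[2L]], end = df[[3L]], observed = score,
                      stringsAsFactors = FALSE)
  }
  if (!is.numeric(out$observed)) stop("binding table missing score column", call. = FALSE)
  if (any(out$observed < 0)) stop("binding intensities must be >= 0", call. = FALSE)
  out
}

# locate, per genomic point, the half-open track window containing it;
# returns window row indices (NA where no window covers the point)
locate_window <- function(trk, chrom, pos) {
  w <- trk$windows
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ws <- which(w$chrom == ch)
    if (length(ws) == 0L) next
    j <- findInterval(pos[sel], w$start[ws])
    jj <- pmax(j, 1L)
    ok <- j >= 1L & pos[sel] < w$end[ws[jj]]
    idx[sel[ok]] <- ws[jj[ok]]
  }
  idx
}

#' Assemble a region set from sequences, sites, tracks, and binding data
#'
#' Builds the central container for model fitting: one record per candidate
#' region with its scanned (or planted) binding sites, per-site epigenomic
#' mark intensities, and optional observed binding intensity. The per-site
#' intensity of a mark is the intensity of the track window containing the
#' site midpoint (half-open windows; midpoints exactly on a boundary fall in
#' the right window) and 0 where no window covers the midpoint; negative
#' intensities are floored at 0.
#'
#' @param sequences named character vector of region sequences.
#' @param sites data.frame of binding sites with columns `region` (sequence
#'   id), `offset`, `width`, `strand`, `score`, `rel_affinity`, `tf` — e.g.
#'   from [scan_sites()] applied per sequence.
#' @param tracks named list of [track] objects (one per epigenomic mark).
#' @param binding optional data.frame from [read_binding_table()] giving
#'   observed intensities; matched to sequences by `id`.
#' @param regions optional data.frame with `id`, `chrom`, `start`, `end`
#'   giving genomic coordinates of each region (required to extract mark
#'   intensities from tracks when `binding` lacks coordinates).
#' @return an object of class `region_set`: `regions` (data.frame `id`,
#'   `chrom`, `start`, `end`, `length`, `observed`), `sites` (data.frame with
#'   integer `region` index), `marks` (sites x marks intensity matrix), and
#'   the per-mark window mapping used for permutation shuffles.
#' @export
assemble_regions <- function(sequences, sites, tracks = list(),
                             binding = NULL, regions = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must be uniquely named by region id", call. = FALSE)
  }
  if (!is.null(sites) && nrow(sites) > 0 && !all(sites$region %in% ids)) {
    stop("region without sequence: ",
         paste(setdiff(unique(sites$region), ids)[1:3], collapse = ", "),
         call. = FALSE)
  }
  reg <- data.frame(id = ids, chrom = NA_character_, start = NA_real_,
                    end = NA_real_, length = nchar(sequences),
                    observed = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(regions)) {
    m <- match(reg$id, regions$id)
    reg$chrom <- regions$chrom[m]
    reg$start <- regions$start[m]
    reg$end <- regions$end[m]
  }
  if (!is.null(binding)) {
    m <- match(reg$id, binding$id)
    reg$observed <- binding$observed[m]
    if (is.null(regions) && all(c("chrom", "start", "end") %in% names(binding))) {
      reg$chrom <- binding$chrom[m]
      reg$start <- binding$start[m]
      reg$end <- binding$end[m]
    }
  }
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.frame(region = integer(0), offset = integer(0),
                        width = integer(0), strand = character(0),
                        score = numeric(0), rel_affinity = numeric(0),
                        tf = character(0), stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(region = match(sites$region, reg$id),
                        offset = sites$offset, width = sites$width,
                        strand = sites$strand, score = sites$score,
                        rel_affinity = sites$rel_affinity,
                        tf = as.character(sites$tf), stringsAsFactors = FALSE)
    sites <- sites[order(sites$region, sites$offset, sites$strand), , drop = FALSE]
    rownames(sites) <- NULL
  }
  mark_names <- names(tracks)
  marks <- matrix(0, nrow = nrow(sites), ncol = length(tracks),
                  dimnames = list(NULL, mark_names))
  mark_windows <- list()
  if (length(tracks) > 0L && nrow(sites) > 0L) {
    if (anyNA(reg$start[sites$region])) {
      stop("tracks supplied but region coordinates missing; pass 'regions' or ",
           "a binding table with coordinates", call. = FALSE)
    }
    mid <- reg$start[sites$region] + sites$offset + sites$width / 2
    chrom <- reg$chrom[sites$region]
    for (k in seq_along(tracks)) {
      trk <- tracks[[k]]
      stopifnot(inherits(trk, "track"))
      widx <- locate_window(trk, chrom, mid)
      wint <- trk$windows$intensity
      v <- ifelse(is.na(widx), 0, wint[widx])
      marks[, k] <- pmax(v, 0)
      mark_windows[[mark_names[k]]] <-
        list(intensity = wint, site_window = widx)
    }
  }
  structure(list(regions = reg, sites = sites, marks = marks,
                 mark_windows = mark_windows),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions, %d sites (%s), %d marks%s\n",
              nrow(x$regions), nrow(x$sites),
              paste(unique(x$sites$tf), collapse = ","),
              ncol(x$marks),
              if (all(is.na(x$regions$observed))) "" else ", observed intensities"))
  invisible(x)
}

#' Number of regions in a region set
#' @param rs a `region_set`
#' @return integer count
#' @export
n_regions <- function(rs) nrow(rs$regions)

#' Extract a single region instance
#'
#' @param rs a `region_set`.
#' @param i region index or id.
#' @return list with `id`, `length`, `observed`, `sites` (data.frame), and
#'   `marks` (sites x marks matrix) — the unit the thermodynamic core
#'   operates on.
#' @export
region_instance <- function(rs, i) {
  if (is.character(i)) i <- match(i, rs$regions$id)
  sel <- which(rs$sites$region == i)
  list(id = rs$regions$id[i],
       length = rs$regions$length[i],
       observed = rs$regions$observed[i],
       sites = rs$sites[sel, , drop = FALSE],
       marks = rs$marks[sel, , drop = FALSE])
}

#' Subset a region set by region index
#' @param rs a `region_set`
#' @param idx integer indices of regions to keep
#' @return a `region_set` containing only those regions
#' @export
subset_regions <- function(rs, idx) {
  idx <- sort(unique(idx))
  keep_sites <- which(rs$sites$region %in% idx)
  sites <- rs$sites[keep_sites, , drop = FALSE]
  sites$region <- match(sites$region, idx)
  mw <- lapply(rs$mark_windows, function(m) {
    list(intensity = m$intensity, site_window = m$site_window[keep_sites])
  })
  structure(list(regions = rs$regions[idx, , drop = FALSE],
                 sites = sites,
                 marks = rs$marks[keep_sites, , drop = FALSE],
                 mark_windows = mw),
            class = "region_set")
}
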