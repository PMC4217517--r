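#' @useDynLib replisim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd var
#' @importFrom utils write.table
NULL

stop_replisim <- function(msg, class = "replisim_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "replisim_error")))
}

#' Construct an Initiation Probability Landscape
#'
#' A landscape describes one chromosome as a sequence of contiguous bins
#' (0-based, half-open `[p, p + binsize)`), each carrying the probability
#' that a replication-initiation attempt at that bin fires. Optional
#' per-bin fork kinetics (`fork_progress`, `fork_release`) override the
#' global `pprogress` / `prelease` simulation settings.
#'
#' @param init_prob numeric vector of per-bin initiation probabilities in
#'   `[0, 1]`; at least one value must be positive, otherwise S phase could
#'   never complete.
#' @param binsize bin width in bp (default 500, the resolution at which
#'   timing predictions are well matched to population timing data).
#' @param chrom chromosome label (cosmetic; the simulator runs one
#'   chromosome at a time).
#' @param positions 0-based bin start coordinates; defaults to
#'   `0, binsize, 2*binsize, ...`. Must be contiguous multiples of
#'   `binsize` from the first position.
#' @param fork_progress,fork_release optional numeric vectors, same length
#'   as `init_prob`, of per-bin probabilities that an engaged fork advances
#'   (resp. is released) in one sweep.
#' @return an object of class `ipls_landscape`.
#' @seealso [read_ipls()], [bedgraph_to_ipls()], [synthetic_landscape()]
#' @export
landscape <- function(init_prob, binsize = 500L, chrom = "chr",
                      positions = NULL, fork_progress = NULL,
                      fork_release = NULL) {
  init_prob <- as.numeric(init_prob)
  n <- length(init_prob)
  if (n < 1L) stop_replisim("landscape needs at least one bin",
                            "replisim_validation_error")
  binsize <- as.integer(binsize)
  if (is.na(binsize) || binsize <= 0L)
    stop_replisim("binsize must be a positive integer",
                  "replisim_validation_error")
  if (is.null(positions)) {
    positions <- as.numeric(seq.int(0L, by = binsize, length.out = n))
  } else {
    positions <- as.numeric(positions)
  }
  obj <- structure(
    list(chrom = as.character(chrom)[1L], binsize = binsize,
         positions = positions, init_prob = init_prob,
         fork_progress = if (!is.null(fork_progress)) as.numeric(fork_progress),
         fork_release = if (!is.null(fork_release)) as.numeric(fork_release)),
    class = "ipls_landscape")
  validate_landscape(obj)
  obj
}

validate_landscape <- function(x) {
  if (!inherits(x, "ipls_landscape"))
    stop_replisim("not an ipls_landscape object", "replisim_validation_error")
  p <- x$init_prob
  n <- length(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_replisim("init_prob values must lie in [0, 1]",
                  "replisim_validation_error")
  if (all(p == 0))
    stop_replisim(
      "all initiation probabilities are zero: S phase can never complete",
      "replisim_validation_error")
  if (length(x$positions) != n)
    stop_replisim("positions and init_prob lengths differ",
                  "replisim_validation_error")
  if (n > 1L) {
    d <- diff(x$positions)
    if (any(d != x$binsize))
      stop_replisim("bin positions must be contiguous multiples of binsize",
                    "replisim_validation_error")
  }
  for (fld in c("fork_progress", "fork_release")) {
    v <- x[[fld]]
    if (is.null(v)) next
    if (length(v) != n)
      stop_replisim(sprintf("%s must have one value per bin", fld),
                    "replisim_validation_error")
    if (anyNA(v) || any(v < 0) || any(v > 1))
      stop_replisim(sprintf("%s values must lie in [0, 1]", fld),
                    "replisim_validation_error")
  }
  invisible(x)
}

n_bins <- function(landscape) length(landscape$init_prob)

#' @export
print.ipls_landscape <- function(x, ...) {
  cat(sprintf(
    "Initiation probability landscape: %s, %d bins of %d bp (%.3g Mb)\n",
    x$chrom, n_bins(x), x$binsize, n_bins(x) * x$binsize / 1e6))
  cat(sprintf("  init_prob: max %.4g, %d bins > 0%s\n",
              max(x$init_prob), sum(x$init_prob > 0),
              if (!is.null(x$fork_progress) || !is.null(x$fork_release))
                "; per-bin fork kinetics present" else ""))
  invisible(x)
}

#' Read an IPLS file
#'
#' IPLS files are plain text with 2-4 whitespace-delimited numeric columns
#' per line: bin start position, initiation probability, and optionally
#' per-bin fork-progress and fork-release probabilities. One file holds one
#' chromosome; the bin size is inferred from the spacing of consecutive
#' positions.
#'
#' @param path path to the landscape file.
#' @param chrom chromosome label to attach.
#' @param binsize bin width in bp; only required for single-line files,
#'   otherwise inferred.
#' @return an `ipls_landscape`.
#' @export
read_ipls <- function(path, chrom = "chr", binsize = NULL) {
  if (!file.exists(path))
    stop_replisim(sprintf("IPLS file not found: %s", path),
                  "replisim_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_replisim(sprintf("IPLS file is empty: %s", path),
                  "replisim_validation_error")
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncol <- lengths(fields)
  for (i in seq_along(fields)) {
    if (ncol[i] < 2L || ncol[i] > 4L)
      stop_replisim(sprintf("line %d: expected 2-4 columns, found %d",
                            i, ncol[i]), "replisim_parse_error")
    vals <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(vals))
      stop_replisim(sprintf("line %d: non-numeric field", i),
                    "replisim_parse_error")
    fields[[i]] <- vals
  }
  if (length(unique(ncol)) != 1L)
    stop_replisim("inconsistent number of columns across lines",
                  "replisim_parse_error")
  m <- do.call(rbind, fields)
  positions <- m[, 1L]
  if (is.null(binsize)) {
    if (nrow(m) < 2L)
      stop_replisim(
        "cannot infer binsize from a single-line file; pass binsize=",
        "replisim_validation_error")
    d <- unique(diff(positions))
    if (length(d) != 1L || d <= 0)
      stop_replisim("non-uniform position spacing; bins must be contiguous",
                    "replisim_validation_error")
    binsize <- d
  }
  landscape(init_prob = m[, 2L], binsize = binsize, chrom = chrom,
            positions = positions,
            fork_progress = if (ncol[1L] >= 3L) m[, 3L],
            fork_release = if (ncol[1L] >= 4L) m[, 4L])
}

#' Write an IPLS file
#'
#' Writes a landscape as 2-4 whitespace-delimited columns with full
#' precision, so that [read_ipls()] reproduces the object exactly.
#'
#' @param x an `ipls_landscape`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ipls <- function(x, path) {
  validate_landscape(x)
  cols <- list(x$positions, x$init_prob)
  if (!is.null(x$fork_progress) || !is.null(x$fork_release)) {
    np <- n_bins(x)
    cols <- c(cols, list(if (is.null(x$fork_progress)) rep(1, np)
                         else x$fork_progress))
    if (!is.null(x$fork_release)) cols <- c(cols, list(x$fork_release))
  }
  txt <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                          sep = "\t"))
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop_replisim(sprintf("cannot write IPLS file: %s", path),
                  "replisim_io_error")
  invisible(path)
}

#' Convert bedgraph signal into a landscape
#'
#' Bins a 4-column bedgraph track (e.g. DNase hypersensitivity) into
#' fixed-width bins and rescales the binned signal into initiation
#' probabilities. Each bin receives the coverage-weighted mean of the
#' interval values overlapping it; base pairs not covered by any interval
#' contribute 0 (such bins can only be replicated passively). With
#' `normalize = "max"` (default) the strongest bin gets probability 1; only
#' the relative amplitudes of the landscape shape the timing program, so
#' the overall scale is free. `normalize = "sum"` rescales so that the
#' probabilities sum to 1 instead.
#'
#' @param path bedgraph file (UCSC 4-column, 0-based half-open).
#' @param chrom chromosome to extract (one landscape per chromosome).
#' @param binsize bin width in bp.
#' @param normalize `"max"` or `"sum"`.
#' @return an `ipls_landscape`.
#' @export
bedgraph_to_ipls <- function(path, chrom, binsize = 500L,
                             normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  if (!file.exists(path))
    stop_replisim(sprintf("bedgraph file not found: %s", path),
                  "replisim_io_error")
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr) == 0L)
    stop_replisim(sprintf("no bedgraph intervals for chromosome '%s'", chrom),
                  "replisim_validation_error")
  score <- gr$score
  if (any(score < 0))
    stop_replisim("bedgraph values must be non-negative",
                  "replisim_validation_error")
  if (!GenomicRanges::isDisjoint(gr))
    stop_replisim("overlapping bedgraph intervals", "replisim_validation_error")
  last <- max(GenomicRanges::end(gr))          # 1-based inclusive end
  nb <- as.integer(ceiling(last / binsize))
  cov <- GenomicRanges::coverage(gr, weight = "score")[[chrom]]
  cov <- c(cov, S4Vectors::Rle(0, nb * binsize - length(cov)))
  v <- IRanges::Views(cov, start = seq.int(1L, by = binsize, length.out = nb),
                      width = binsize)
  signal <- IRanges::viewMeans(v)
  if (max(signal) <= 0)
    stop_replisim("bedgraph signal is zero everywhere on this chromosome",
                  "replisim_validation_error")
  p <- if (normalize == "max") signal / max(signal) else signal / sum(signal)
  landscape(init_prob = as.numeric(p), binsize = binsize, chrom = chrom)
}

#' Generate synthetic landscapes
#'
#' Deterministic landscape families used throughout the test-bench:
#' \describe{
#'   \item{delta}{probability 1 at a single `origin` bin, 0 elsewhere; the
#'     resulting timing profile is an exact V shape (one bin per sweep per
#'     fork away from the origin).}
#'   \item{multi_delta}{probability 1 at each bin in `origins`.}
#'   \item{uniform}{constant probability `p` everywhere, the random-origin
#'     limit resembling early Xenopus embryos.}
#'   \item{peaks}{a sum of Gaussian bumps
#'     `height * exp(-(b - center)^2 / (2 width^2))` plus `baseline`,
#'     clipped to `[0, 1]` -- a cartoon of DNase-hypersensitive origin
#'     clusters.}
#' }
#'
#' @param kind one of `"delta"`, `"multi_delta"`, `"uniform"`, `"peaks"`.
#' @param n_bins number of bins.
#' @param binsize bin width in bp.
#' @param chrom chromosome label.
#' @param origin,origins 1-based bin index/indices of origins (delta kinds).
#' @param p constant probability (uniform kind).
#' @param centers,widths,heights Gaussian bump parameters in bin units
#'   (peaks kind); `widths`/`heights` are recycled against `centers`.
#' @param baseline additive floor for the peaks kind.
#' @return an `ipls_landscape`.
#' @export
synthetic_landscape <- function(kind = c("delta", "multi_delta", "uniform",
                                         "peaks"),
                                n_bins, binsize = 500L, chrom = "chrS",
                                origin = 1L, origins = NULL, p = 0.5,
                                centers = NULL, widths = 3, heights = 1,
                                baseline = 0) {
  kind <- match.arg(kind)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    stop_replisim("n_bins must be >= 1", "replisim_validation_error")
  check_idx <- function(idx, what) {
    if (any(idx < 1L | idx > n_bins))
      stop_replisim(sprintf("%s index out of range [1, %d]", what, n_bins),
                    "replisim_validation_error")
  }
  prob <- switch(kind,
    delta = {
      origin <- as.integer(origin)
      check_idx(origin, "origin")
      v <- numeric(n_bins); v[origin] <- 1; v
    },
    multi_delta = {
      origins <- as.integer(origins)
      if (length(origins) == 0L)
        stop_replisim("multi_delta needs at least one origin",
                      "replisim_validation_error")
      check_idx(origins, "origin")
      v <- numeric(n_bins); v[origins] <- 1; v
    },
    uniform = rep(as.numeric(p), n_bins),
    peaks = {
      if (is.null(centers))
        stop_replisim("peaks landscape needs centers",
                      "replisim_validation_error")
      check_idx(as.integer(round(centers)), "center")
      widths <- rep_len(widths, length(centers))
      heights <- rep_len(heights, length(centers))
      b <- seq_len(n_bins)
      v <- rep(as.numeric(baseline), n_bins)
      for (k in seq_along(centers))
        v <- v + heights[k] * exp(-(b - centers[k])^2 / (2 * widths[k]^2))
      pmin(pmax(v, 0), 1)
    })
  landscape(init_prob = prob, binsize = binsize, chrom = chrom)
}

# Resolve effective per-bin fork kinetics: landscape columns, when present,
# override the global pprogress/prelease settings.
resolve_kinetics <- function(landscape, pprogress, prelease) {
  nb <- n_bins(landscape)
  list(
    pprog = if (is.null(landscape$fork_progress)) rep(pprogress, nb)
            else landscape$fork_progress,
    prel = if (is.null(landscape$fork_release)) rep(prelease, nb)
           else landscape$fork_release)
}
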