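# Minimal EDF (European Data Format) I/O: fixed-width ASCII header,
# 16-bit little-endian samples, one scaling (physical min/max vs digital
# min/max) per signal. Covers continuous single-rate recordings, which is
# all the mental-arithmetic layout needs.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 10)
  if (nchar(s) > width) s <- substr(s, 1, width)  # header fields are fixed width
  formatC(s, width = width, flag = "-")
}

# Outward-quantised channel bounds that survive the 8-char header field
# exactly: resolution 1e-4 of the range's decade, with a symmetric integer
# fallback when the decimal string would not fit.
.edf_quant_bounds <- function(pmin, pmax) {
  rng <- pmax - pmin
  e <- floor(log10(rng)) - 4L
  d <- 10^e
  digits <- max(0L, -e)
  snap <- function(v, up) {
    k <- if (up) ceiling(v / d) else floor(v / d)
    s <- sprintf("%.*f", digits, k * d)
    val <- as.numeric(s)
    # guard against float drift pulling the bound inside the data range
    if ((up && val < v) || (!up && val > v)) {
      k <- k + if (up) 1 else -1
      s <- sprintf("%.*f", digits, k * d)
      val <- as.numeric(s)
    }
    list(s = s, val = val)
  }
  lo <- snap(pmin, up = FALSE)
  hi <- snap(pmax, up = TRUE)
  if (nchar(lo$s) <= 8 && nchar(hi$s) <= 8 && hi$val > lo$val)
    return(c(lo$val, hi$val))
  m <- ceiling(max(abs(pmin), abs(pmax), 1))
  c(-m, m)
}

#' Write a Recording to an EDF file
#'
#' Samples are quantised to 16-bit integers with one physical/digital
#' scaling per channel (physical range = the channel's observed range),
#' the usual EDF convention. Round-tripping through [readRecording()]
#' therefore preserves values to the 16-bit quantisation step.
#'
#' @param rec a [Recording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readRecording()], [writeFixture()]
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  x <- samples(rec)
  fs <- samplingRate(rec)
  ns <- nrow(x)
  N <- ncol(x)
  # one-second records when the count allows, otherwise a single record
  if (fs == round(fs) && N %% fs == 0) {
    spr <- as.integer(fs); nrec <- N %/% spr; recdur <- 1
  } else {
    spr <- N; nrec <- 1L; recdur <- N / fs
  }

  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # the header stores bounds as <= 8 ASCII chars; quantise the bounds to a
  # short exact decimal FIRST and scale against the stored values, so the
  # reader's rescaling sees precisely the bounds the writer used
  qb <- vapply(seq_len(ns), function(i) .edf_quant_bounds(pmin[i], pmax[i]),
               numeric(2))
  pmin <- qb[1, ]; pmax <- qb[2, ]
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(subjectId(rec), 80),
    .edf_pad(paste("trial", trial(rec)), 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_num(256L * (ns + 1L), 8),
    .edf_pad("", 44),
    .edf_num(nrec, 8),
    .edf_num(recdur, 8),
    .edf_num(ns, 4)
  )
  sig <- paste0(
    paste(vapply(rownames(x), .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, .edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, .edf_num, "", width = 8), collapse = ""),
    paste(rep(.edf_num(dmin, 8), ns), collapse = ""),
    paste(rep(.edf_num(dmax, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_num(spr, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((x - pmin) * scale + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  storage.mode(dig) <- "integer"
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- t(dig[, idx, drop = FALSE])  # signal-major within a record
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

.edf_read_field <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1):(off + width)]))
}

.edf_read_header <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256)
    stop("EDF format error in '", path, "': file shorter than the 256-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "raw", 256)
  ns <- suppressWarnings(as.integer(.edf_read_field(h, 252, 4)))
  if (is.na(ns) || ns < 1)
    stop("EDF format error in '", path, "': invalid signal count field")
  nrec <- suppressWarnings(as.integer(.edf_read_field(h, 236, 8)))
  recdur <- suppressWarnings(as.numeric(.edf_read_field(h, 244, 8)))
  if (is.na(nrec) || nrec < 1 || is.na(recdur) || recdur <= 0)
    stop("EDF format error in '", path,
         "': invalid record count or record duration field")
  if (sz < 256 * (ns + 1))
    stop("EDF format error in '", path, "': truncated signal header")
  s <- readBin(con, "raw", 256 * ns)
  # field offsets within the signal-header block (per EDF layout):
  # label 0, transducer 16*ns, dim 96*ns, pmin 104*ns, pmax 112*ns,
  # dmin 120*ns, dmax 128*ns, prefilter 136*ns, spr 216*ns
  off <- function(field_start, width, i)
    .edf_read_field(s, field_start * ns + (i - 1) * width, width)
  labels <- vapply(seq_len(ns), function(i) off(0, 16, i), "")
  pminv <- as.numeric(vapply(seq_len(ns), function(i) off(104, 8, i), ""))
  pmaxv <- as.numeric(vapply(seq_len(ns), function(i) off(112, 8, i), ""))
  dminv <- as.numeric(vapply(seq_len(ns), function(i) off(120, 8, i), ""))
  dmaxv <- as.numeric(vapply(seq_len(ns), function(i) off(128, 8, i), ""))
  sprv <- as.integer(vapply(seq_len(ns), function(i) off(216, 8, i), ""))
  if (anyNA(c(pminv, pmaxv, dminv, dmaxv, sprv)))
    stop("EDF format error in '", path, "': unparseable signal scaling fields")
  if (any(sprv < 1))
    stop("EDF format error in '", path, "': samples-per-record must be positive")
  list(ns = ns, nrec = nrec, recdur = recdur, labels = labels,
       pmin = pminv, pmax = pmaxv, dmin = dminv, dmax = dmaxv, spr = sprv,
       patient = .edf_read_field(h, 8, 80))
}

#' Read an EDF file into a Recording
#'
#' Reads a continuous EDF recording as stored: no resampling, filtering
#' or re-referencing. The sampling rate is taken from the header (samples
#' per record / record duration); all signals must share one rate.
#'
#' @param path path to an EDF file.
#' @param trial `"baseline"` or `"task"`; the mental-arithmetic layout
#'   stores trial 1 (baseline) and trial 2 (task) as separate files, so
#'   the caller names which one this is.
#' @param subjectId subject identifier; defaults to the file name with
#'   the extension and a trailing `_1`/`_2` trial suffix stripped.
#' @return A [Recording-class].
#' @examples
#' rec <- Recording("s1", "task",
#'                  matrix(sin(1:100), 1, 100, dimnames = list("EEG Fp1", NULL)),
#'                  fs = 50)
#' f <- tempfile(fileext = ".edf")
#' writeRecording(rec, f)
#' readRecording(f, trial = "task")
#' @export
readRecording <- function(path, trial = c("baseline", "task"), subjectId = NULL) {
  trial <- match.arg(trial)
  if (!file.exists(path))
    stop("cannot read EDF file '", path, "': no such file")
  hdr <- .edf_read_header(path)
  ns <- hdr$ns
  spr <- hdr$spr
  if (length(unique(spr)) != 1L)
    stop("EDF format error in '", path,
         "': signals with differing sampling rates are not supported")
  spr <- spr[1]
  fs <- spr / hdr$recdur

  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 256 * (ns + 1)))
  need <- hdr$nrec * ns * spr
  d <- readBin(con, "integer", n = need, size = 2, signed = TRUE,
               endian = "little")
  if (length(d) < need)
    stop("EDF format error in '", path, "': truncated data records (",
         length(d), " of ", need, " samples present)")
  # records x (signal-major blocks) -> channels x time
  dim(d) <- c(spr, ns, hdr$nrec)
  x <- matrix(0, ns, spr * hdr$nrec)
  for (i in seq_len(ns)) {
    gain <- (hdr$pmax[i] - hdr$pmin[i]) / (hdr$dmax[i] - hdr$dmin[i])
    x[i, ] <- (as.vector(d[, i, ]) - hdr$dmin[i]) * gain + hdr$pmin[i]
  }
  rownames(x) <- hdr$labels
  if (is.null(subjectId)) {
    subjectId <- sub("\\.[^.]*$", "", basename(path))
    subjectId <- sub("_[12]$", "", subjectId)
  }
  Recording(subjectId, trial, x, fs)
}
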