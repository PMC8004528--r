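# Readers and writers. CSV is the native exchange format (time,value);
# minimal EDF and NPY readers cover the two common binary carriers of
# single-channel electrophysiology. Results are written as a plain-text
# directory bundle (CSV matrices + JSON metadata).

#' Read a time series from CSV, EDF or NPY
#'
#' CSV files carry either two numeric columns (`time_s, value`; the
#' sampling rate is inferred and checked for uniformity) or a single value
#' column with `fs` supplied. EDF files are read with a minimal EDF reader
#' (16-bit samples, physical scaling; pick a channel by index or label).
#' NPY files must hold a one-dimensional numeric array and require `fs`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"edf"` or `"npy"`.
#' @param fs sampling rate in Hz, required when the file does not carry one.
#' @param channel EDF channel index or label.
#' @return a [pac_ts()].
#' @export
read_timeseries <- function(path, format = c("auto", "csv", "edf", "npy"),
                            fs = NULL, channel = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", edf = "edf", npy = "npy",
                     stop("cannot infer format from extension: ", path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_timeseries_csv(path, fs),
         edf = read_timeseries_edf(path, channel),
         npy = {
           if (is.null(fs)) stop("`fs` is required for NPY input")
           pac_ts(read_npy(path), fs)
         })
}

read_timeseries_csv <- function(path, fs = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CSV file: ", path)
  start <- 1L
  first <- strsplit(lines[1], ",")[[1]]
  if (anyNA(suppressWarnings(as.numeric(first)))) start <- 2L  # header
  parts <- strsplit(lines[start:length(lines)], ",")
  ncol <- length(parts[[1]])
  if (!ncol %in% c(1L, 2L)) stop("CSV must have 1 or 2 columns")
  vals <- suppressWarnings(lapply(parts, as.numeric))
  bad <- which(vapply(vals, function(v) length(v) != ncol || anyNA(v),
                      logical(1)))
  if (length(bad))
    stop(sprintf("malformed CSV row at line %d of %s",
                 bad[1] + start - 1L, path))
  m <- do.call(rbind, vals)
  if (ncol == 1L) {
    if (is.null(fs)) stop("`fs` is required for single-column CSV")
    return(pac_ts(m[, 1], fs))
  }
  dt <- diff(m[, 1])
  if (length(dt) < 1 || any(dt <= 0) ||
      max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt) + 1e-12)
    stop("non-uniform sampling in time column of ", path)
  pac_ts(m[, 2], 1 / stats::median(dt))
}

#' Write a time series as two-column CSV
#'
#' @param x a [pac_ts()].
#' @param path output path; a `.json` sidecar with `fs`, `n_samples` and
#'   optional parameters is written alongside when `sidecar` is given.
#' @param sidecar optional named list serialised to JSON next to the CSV.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path, sidecar = NULL) {
  assert_ts(x)
  utils::write.csv(data.frame(time_s = ts_time(x), value = x$samples),
                   path, row.names = FALSE)
  if (!is.null(sidecar)) {
    meta <- c(list(fs = x$fs, n_samples = length(x$samples)), sidecar)
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- minimal EDF ------------------------------------------------------------

read_timeseries_edf <- function(path, channel = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                     # version
  hdr(80); hdr(80); hdr(8); hdr(8)  # patient, recording, date, time
  n_header <- as.integer(hdr(8))
  hdr(44)
  n_records <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  labels <- vapply(1:ns, function(i) hdr(16), character(1))
  for (i in 1:ns) hdr(80)    # transducer
  for (i in 1:ns) hdr(8)     # physical dimension
  pmin_ <- vapply(1:ns, function(i) as.numeric(hdr(8)), numeric(1))
  pmax_ <- vapply(1:ns, function(i) as.numeric(hdr(8)), numeric(1))
  dmin_ <- vapply(1:ns, function(i) as.numeric(hdr(8)), numeric(1))
  dmax_ <- vapply(1:ns, function(i) as.numeric(hdr(8)), numeric(1))
  for (i in 1:ns) hdr(80)    # prefiltering
  nsamp <- vapply(1:ns, function(i) as.integer(hdr(8)), integer(1))
  for (i in 1:ns) hdr(32)    # reserved
  ch <- if (is.character(channel)) {
    m <- which(labels == channel)
    if (!length(m)) stop("EDF channel not found: ", channel)
    m[1]
  } else {
    if (channel < 1 || channel > ns) stop("EDF channel index out of range")
    as.integer(channel)
  }
  seek(con, n_header)
  out <- numeric(n_records * nsamp[ch])
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (i in 1:ns) {
      d <- readBin(con, "integer", nsamp[i], size = 2, endian = "little")
      if (i == ch) {
        out[pos + seq_len(nsamp[i])] <- d
        pos <- pos + nsamp[i]
      }
    }
  }
  gain <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
  pac_ts(pmin_[ch] + gain * (out - dmin_[ch]), nsamp[ch] / rec_dur)
}

#' Write a single-channel EDF file
#'
#' Minimal EDF writer (one data record per second, 16-bit samples); mainly
#' for round-trip testing and export.
#'
#' @param x a [pac_ts()]; `fs` must be a positive integer.
#' @param path output path.
#' @param label channel label (up to 16 characters).
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, label = "chan1") {
  assert_ts(x)
  fs <- as.integer(round(x$fs))
  if (abs(fs - x$fs) > 1e-9) stop("EDF writer requires an integer fs")
  n_rec <- floor(length(x$samples) / fs)
  if (n_rec < 1) stop("signal shorter than one 1-s EDF record")
  v <- x$samples[seq_len(n_rec * fs)]
  pmin_ <- min(v); pmax_ <- max(v)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dig <- as.integer(round((v - pmin_) / (pmax_ - pmin_) * 65535 - 32768))
  pad <- function(s, n) formatC(as.character(s), width = -n)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(pad(substr(s, 1, n), n)), con)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 + 256), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr("1", 4)
  wr(label, 16); wr("", 80); wr("au", 8)
  wr(sprintf("%.8g", pmin_), 8); wr(sprintf("%.8g", pmax_), 8)
  wr("-32768", 8); wr("32767", 8)
  wr("", 80); wr(as.character(fs), 8); wr("", 32)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

# ---- minimal NPY ------------------------------------------------------------

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  dtype <- sub(".*'([^']+)'$", "\\1", descr)
  if (grepl("'fortran_order':\\s*True", header))
    stop("Fortran-ordered NPY not supported")
  shape <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  dims <- as.integer(strsplit(gsub("[^0-9,]", "", shape), ",")[[1]])
  if (length(dims) != 1) stop("NPY input must be one-dimensional")
  n <- dims[1]
  switch(dtype,
         "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
         "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
         "<i4" = as.numeric(readBin(con, "integer", n, size = 4,
                                    endian = "little")),
         "<i2" = as.numeric(readBin(con, "integer", n, size = 2,
                                    endian = "little")),
         stop("unsupported NPY dtype: ", dtype))
}

# ---- result bundle ----------------------------------------------------------

#' Write an eMI result as a plain-text directory bundle
#'
#' Writes the comodulogram, significance mask, percentiles, label matrix and
#' region table as CSV, per-frequency auxiliaries (averaged maps, averaged
#' signals, spectra, phase histograms) under `per_fp/`, and the full
#' configuration (grid, parameters, seeds, package version) as JSON.
#'
#' @param result an `emi_pac` object.
#' @param dir output directory (created; must not exist or be empty).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "emi_pac"))
  if (dir.exists(dir) && length(list.files(dir)))
    stop("output directory exists and is not empty: ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wmat <- function(m, name) {
    df <- as.data.frame(m)
    colnames(df) <- result$grid$f_A
    df <- cbind(f_P = result$grid$f_P, df)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wmat(result$values, "comodulogram.csv")
  wmat(result$mask * 1L, "mask.csv")
  wmat(result$P_vals, "pvals.csv")
  lm <- result$label_matrix
  lm[is.na(lm)] <- ""
  wmat(lm, "labels.csv")
  regions <- lapply(result$regions, function(r) data.frame(
    region_id = r$id,
    f_P_min = min(result$grid$f_P[r$cells[, 1]]),
    f_P_max = max(result$grid$f_P[r$cells[, 1]]),
    f_A_min = min(result$grid$f_A[r$cells[, 2]]),
    f_A_max = max(result$grid$f_A[r$cells[, 2]]),
    label = r$label, n_pairs = nrow(r$cells),
    modal_phase = if (anyNA(r$histogram)) NA_real_ else
      -pi + (which.max(r$histogram) - 0.5) * 2 * pi / length(r$histogram),
    mi_max = max(result$values[r$cells])))
  utils::write.csv(
    if (length(regions)) do.call(rbind, regions)
    else data.frame(region_id = integer()),
    file.path(dir, "regions.csv"), row.names = FALSE)
  pf <- file.path(dir, "per_fp")
  dir.create(pf)
  for (i in seq_along(result$grid$f_P)) {
    sec <- result$per_fp$sections[[i]]
    if (is.null(sec)) next
    d <- file.path(pf, sprintf("fP_%g", result$grid$f_P[i]))
    dir.create(d)
    utils::write.csv(data.frame(SP_A = sec$SP_A, phase_A = sec$phase_A),
                     file.path(d, "path_A_signal.csv"), row.names = FALSE)
    if (!is.null(sec$M_B)) {
      utils::write.csv(data.frame(SP_B = sec$SP_B, S_B = sec$S_B),
                       file.path(d, "path_B_signal.csv"), row.names = FALSE)
      mb <- as.data.frame(sec$M_B)
      colnames(mb) <- sec$freqs
      utils::write.csv(mb, file.path(d, "M_B.csv"), row.names = FALSE)
    }
    sp <- result$per_fp$spectra[[i]]
    if (!is.null(sp))
      utils::write.csv(data.frame(freq = sp$freq, AS = sp$AS, SA = sp$SA),
                       file.path(d, "spectra.csv"), row.names = FALSE)
  }
  cfg <- list(
    f_P = result$grid$f_P, f_A = result$grid$f_A,
    delta_f_P = result$grid$delta_f_P, w = result$w, J = result$J,
    n_surrogates = result$n_surrogates, p_C = result$p_C, p_PC = result$p_PC,
    seed = result$seed, threshold = result$threshold,
    status = result$status,
    version = as.character(utils::packageVersion("emipac")))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back the comodulogram matrices of a result bundle
#'
#' @param dir a directory written by [write_results()].
#' @return list with `values`, `mask`, `P_vals`, `f_P`, `f_A`, `config`.
#' @export
read_results <- function(dir) {
  rmat <- function(name) {
    df <- utils::read.csv(file.path(dir, name), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- NULL
    m
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  list(values = rmat("comodulogram.csv"),
       mask = rmat("mask.csv") == 1,
       P_vals = rmat("pvals.csv"),
       f_P = cfg$f_P, f_A = cfg$f_A, config = cfg)
}

#' Split a recording into fixed-length epochs with amplitude rejection
#'
#' Cuts the signal into contiguous non-overlapping epochs of `epoch_s`
#' seconds (a trailing partial epoch is discarded) and drops epochs
#' containing any sample further than `z_max` whole-signal SDs from the
#' whole-signal mean.
#'
#' @param x a [pac_ts()].
#' @param epoch_s epoch length in seconds (at most the signal duration).
#' @param z_max amplitude rejection threshold in SD units (default 5).
#' @return list of [pac_ts()] epochs; rejected epochs are dropped, and the
#'   attribute `rejected` records their indices.
#' @export
epoch_splitter <- function(x, epoch_s, z_max = 5) {
  assert_ts(x)
  if (epoch_s > x$duration) stop("`epoch_s` exceeds the signal duration")
  n_ep <- floor(x$duration / epoch_s)
  len <- round(epoch_s * x$fs)
  mu <- mean(x$samples)
  sigma <- stats::sd(x$samples)
  eps <- list()
  rejected <- integer()
  for (e in seq_len(n_ep)) {
    seg <- x$samples[((e - 1) * len + 1):(e * len)]
    if (any(abs(seg - mu) / sigma > z_max)) rejected <- c(rejected, e)
    else eps[[length(eps) + 1L]] <- pac_ts(seg, x$fs)
  }
  attr(eps, "rejected") <- rejected
  eps
}
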