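#' Construct a node-by-volume time-series matrix
#'
#' Container for one subject's regional BOLD signals: one row per node
#' (parcellated region), one column per retained volume.
#'
#' @param values numeric matrix, nodes in rows, volumes in columns. All
#'   entries must be finite and at least two volumes are required.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#'   Default 2.5, the EPI acquisition emulated by the synthetic generator.
#' @param node_ids character vector of region labels, one per row. Defaults
#'   to `rownames(values)`, or `"n001"`-style labels when absent.
#' @return An object of class `timeseries_matrix` with elements `values`,
#'   `tr_seconds`, and `node_ids`.
#' @export
timeseries_matrix <- function(values, tr_seconds = 2.5, node_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("time-series values must be a finite numeric matrix")
  if (ncol(values) < 2L)
    stop("a time series needs at least 2 volumes")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  if (is.null(node_ids)) {
    node_ids <- rownames(values)
    if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(nrow(values)))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(values))
    stop("node_ids must have one entry per row of values")
  if (anyDuplicated(node_ids))
    stop("node_ids must be unique")
  rownames(values) <- node_ids
  structure(list(values = values, tr_seconds = tr_seconds,
                 node_ids = node_ids),
            class = "timeseries_matrix")
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("<timeseries_matrix> %d nodes x %d volumes, TR = %gs\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Remove nuisance covariates from node time series by linear regression
#'
#' Each node series is replaced by its ordinary-least-squares residual
#' against an intercept plus the supplied covariates (e.g. motion
#' parameters, white-matter and CSF signals in the imaging setting).
#' With no covariates the series are simply mean-centred.
#'
#' @param ts a [timeseries_matrix()].
#' @param covariates numeric matrix with one row per volume and one column
#'   per covariate, or `NULL` for intercept-only regression.
#' @return A `timeseries_matrix` of residual series, orthogonal to the
#'   covariates.
#' @export
regress_nuisance <- function(ts, covariates = NULL) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  nv <- ncol(ts$values)
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0L)) {
    X <- matrix(1, nv, 1L, dimnames = list(NULL, "(intercept)"))
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nv)
      stop(sprintf("covariates have %d rows but the series has %d volumes",
                   nrow(covariates), nv))
    cn <- colnames(covariates)
    if (is.null(cn)) cn <- sprintf("cov%d", seq_len(ncol(covariates)))
    X <- cbind("(intercept)" = 1, covariates)
    colnames(X) <- c("(intercept)", cn)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("nuisance design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  resid <- t(qr.resid(qx, t(ts$values)))
  timeseries_matrix(resid, tr_seconds = ts$tr_seconds, node_ids = ts$node_ids)
}

# One biquad section applied in direct form II transposed... kept simple:
# direct difference equation, coefficients normalised to a[1] = 1.
iir2_filter <- function(x, b, a) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-(1:2)]
  as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
}

# Forward-backward (zero-phase) application of one biquad with odd
# reflection padding to suppress edge transients.
filtfilt2 <- function(x, b, a) {
  n <- length(x)
  npad <- min(n - 1L, 100L)
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- iir2_filter(c(pre, x, post), b, a)
  y <- rev(iir2_filter(rev(y), b, a))
  y[(npad + 1L):(npad + n)]
}

# Second-order Butterworth biquad coefficients (bilinear transform,
# Q = 1/sqrt(2)); type "low" or "high", cutoff in Hz at sampling rate fs.
butter2_coef <- function(cutoff_hz, fs, type) {
  w0 <- 2 * pi * cutoff_hz / fs
  cw <- cos(w0)
  alpha <- sin(w0) / (2 * (1 / sqrt(2)))
  a0 <- 1 + alpha
  a <- c(1, -2 * cw / a0, (1 - alpha) / a0)
  if (type == "low") {
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2) / a0
  } else {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2) / a0
  }
  list(b = b, a = a)
}

#' Band-pass filter node time series (zero phase)
#'
#' Retains the low-frequency fluctuation band conventionally used for
#' resting-state connectivity (default 0.01-0.1 Hz). The filter is a
#' cascade of second-order Butterworth high- and low-pass sections, each
#' applied forward and backward, so the passband is attenuated twice per
#' section (amplitude response squared) and the phase response is zero:
#' oscillation peaks are not shifted in time. Each series is mean-centred
#' before filtering, so a constant series maps exactly to zero.
#'
#' @param ts a [timeseries_matrix()].
#' @param low_hz lower passband edge in Hz (default 0.01).
#' @param high_hz upper passband edge in Hz (default 0.1). Must be below
#'   the Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return A filtered `timeseries_matrix`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0)) stop("low_hz must be positive")
  if (!(high_hz > low_hz)) stop("high_hz must exceed low_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyq))
  fs <- 1 / ts$tr_seconds
  hp <- butter2_coef(low_hz, fs, "high")
  lp <- butter2_coef(high_hz, fs, "low")
  vals <- ts$values - rowMeans(ts$values)
  out <- t(apply(vals, 1L, function(x) {
    filtfilt2(filtfilt2(x, hp$b, hp$a), lp$b, lp$a)
  }))
  timeseries_matrix(out, tr_seconds = ts$tr_seconds, node_ids = ts$node_ids)
}

#' Write / read a time-series matrix as TSV
#'
#' Plain-text interchange format: first column `node`, remaining columns
#' one per volume (`v1`, `v2`, ...). The repetition time is recorded in a
#' `# tr_seconds:` comment on the first line.
#'
#' @param ts a [timeseries_matrix()].
#' @param path file path.
#' @return `write_timeseries_tsv` returns `path` invisibly;
#'   `read_timeseries_tsv` returns a `timeseries_matrix`.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_seconds: %.17g", ts$tr_seconds), con)
  df <- data.frame(node = ts$node_ids, ts$values, check.names = FALSE)
  colnames(df) <- c("node", sprintf("v%d", seq_len(ncol(ts$values))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  tr <- 2.5
  if (grepl("^# tr_seconds:", first))
    tr <- as.numeric(sub("^# tr_seconds:", "", first))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  timeseries_matrix(vals, tr_seconds = tr, node_ids = df[[1L]])
}
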