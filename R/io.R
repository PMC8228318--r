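# Interop I/O: Bruker-style experiment directories (binary `fid` plus a
# key-value `acqus` file) and a minimal JCAMP-DX reader/writer for processed
# spectra. The Bruker reader honours the byte-order and data-type flags
# (BYTORDA, DTYPA) and maps the standard parameter keys.

required_acqus_keys <- c("SFO1", "TD", "SW", "NS", "RG", "P1", "D1")

#' Write an FID as a Bruker-style experiment directory
#'
#' Creates `<path>/acqus` (JCAMP-style `##$KEY= value` lines) and
#' `<path>/fid` (interleaved real/imaginary samples; float64 little-endian by
#' default, `DTYPA = 2`, or int32 with `DTYPA = 0`).
#'
#' @param fid An [new_fid()] object.
#' @param path Directory to create.
#' @param dtype `"float64"` (lossless round trip) or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_bruker <- function(fid, path, dtype = c("float64", "int32")) {
  dtype <- match.arg(dtype)
  stopifnot(inherits(fid, "nmr_fid"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  acq <- fid$acq
  lines <- c(
    "##TITLE= cannaqnmr export",
    "##JCAMPDX= 5.0",
    sprintf("##$SFO1= %.8f", acq$sf_mhz),
    sprintf("##$O1P= %.6f", acq$o1_ppm),
    sprintf("##$TD= %d", acq$td),
    sprintf("##$SI= %d", acq$si),
    sprintf("##$SW= %.6f", acq$sw_ppm),
    sprintf("##$NS= %d", acq$ns),
    sprintf("##$DS= %d", acq$ds),
    sprintf("##$RG= %.6f", acq$rg),
    sprintf("##$P1= %.6f", acq$p1_us),
    sprintf("##$D1= %.6f", acq$d1_s),
    sprintf("##$TE= %.2f", acq$temperature_k),
    sprintf("##$LB= %.4f", acq$lb_hz),
    sprintf("##$BYTORDA= 0"),
    sprintf("##$DTYPA= %d", if (dtype == "float64") 2L else 0L),
    "##END="
  )
  writeLines(lines, file.path(path, "acqus"))
  interleaved <- as.vector(rbind(Re(fid$data), Im(fid$data)))
  con <- file(file.path(path, "fid"), "wb")
  on.exit(close(con))
  if (dtype == "float64") {
    writeBin(interleaved, con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(round(interleaved)), con, size = 4, endian = "little")
  }
  invisible(path)
}

parse_acqus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^##\\$?([A-Za-z0-9_]+)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read a Bruker-style experiment directory or a JCAMP-DX file
#'
#' For a directory, decodes `fid` according to the `BYTORDA`/`DTYPA` flags of
#' `acqus` and maps the required keys (SFO1, TD, SW, NS, RG, P1, D1; a
#' missing required key is an error naming the key, missing optional keys are
#' defaulted with a warning), returning an [new_fid()]. For a `.dx`/`.jdx`
#' file, returns the [new_spectrum()] stored in it.
#'
#' @param path Directory (Bruker) or file (JCAMP-DX).
#' @return An `nmr_fid` or `nmr_spectrum`.
#' @export
read_fid <- function(path) {
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.(dx|jdx)$", path, ignore.case = TRUE)) {
      return(read_jcamp(path))
    }
    stop("not a Bruker directory or JCAMP-DX file: ", path, call. = FALSE)
  }
  acqus_path <- file.path(path, "acqus")
  fid_path <- file.path(path, "fid")
  if (!file.exists(acqus_path)) stop("missing acqus in ", path, call. = FALSE)
  if (!file.exists(fid_path)) stop("missing fid in ", path, call. = FALSE)
  kv <- parse_acqus(acqus_path)
  for (key in required_acqus_keys) {
    if (is.null(kv[[key]])) {
      stop("acqus is missing required key: ", key, call. = FALSE)
    }
  }
  num <- function(key, default = NULL) {
    if (!is.null(kv[[key]])) {
      return(as.numeric(kv[[key]]))
    }
    warning("acqus key ", key, " missing; using default ", default)
    default
  }
  td <- as.integer(num("TD"))
  acq <- acq_params(
    sf_mhz = num("SFO1"), td = td,
    si = as.integer(num("SI", default = 2 * td)),
    sw_ppm = num("SW"), o1_ppm = num("O1P", default = 6.0),
    ns = as.integer(num("NS")), ds = as.integer(num("DS", default = 4)),
    rg = num("RG"), p1_us = num("P1"), d1_s = num("D1"),
    lb_hz = num("LB", default = 0.30),
    temperature_k = num("TE", default = 300.0)
  )
  dtypa <- as.integer(kv[["DTYPA"]] %||% "0")
  bytorda <- as.integer(kv[["BYTORDA"]] %||% "0")
  endian <- if (bytorda == 0) "little" else "big"
  n_real <- 2L * (td %/% 2L)
  con <- file(fid_path, "rb")
  on.exit(close(con))
  raw_vals <- if (dtypa == 2) {
    readBin(con, "double", n = n_real, size = 8, endian = endian)
  } else {
    as.numeric(readBin(con, "integer", n = n_real, size = 4, endian = endian))
  }
  if (length(raw_vals) < n_real) {
    stop("truncated fid binary: expected ", n_real, " values, got ",
      length(raw_vals),
      call. = FALSE
    )
  }
  re <- raw_vals[seq(1, n_real, by = 2)]
  im <- raw_vals[seq(2, n_real, by = 2)]
  new_fid(complex(real = re, imaginary = im), acq,
    provenance = list(list(step = "read_bruker", path = path))
  )
}

#' Write / read a processed spectrum as JCAMP-DX
#'
#' Minimal JCAMP-DX (AFFN `XYDATA` table of the real part on the ppm axis)
#' sufficient for interop round trips; the acquisition context is carried in
#' `$`-prefixed private keys.
#'
#' @param spec An [new_spectrum()] object.
#' @param path File path (conventionally `.dx`).
#' @return `write_jcamp()` returns `path` invisibly; `read_jcamp()` returns
#'   the spectrum (imaginary part zero).
#' @export
write_jcamp <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  n <- length(spec$real)
  acq <- spec$acq
  header <- c(
    "##TITLE= cannaqnmr spectrum",
    "##JCAMPDX= 5.0",
    "##DATATYPE= NMR SPECTRUM",
    "##XUNITS= PPM",
    "##YUNITS= ARBITRARY",
    sprintf("##$SFO1= %.8f", acq$sf_mhz),
    sprintf("##$O1P= %.6f", acq$o1_ppm),
    sprintf("##$TD= %d", acq$td),
    sprintf("##$SW= %.6f", acq$sw_ppm),
    sprintf("##$NS= %d", acq$ns),
    sprintf("##$RG= %.6f", acq$rg),
    sprintf("##$P1= %.6f", acq$p1_us),
    sprintf("##$D1= %.6f", acq$d1_s),
    sprintf("##FIRSTX= %.10g", spec$ppm[1]),
    sprintf("##LASTX= %.10g", spec$ppm[n]),
    sprintf("##NPOINTS= %d", n),
    "##YFACTOR= 1",
    "##XYDATA= (X++(Y..Y))"
  )
  body <- vapply(seq(1, n, by = 6), function(i) {
    j <- min(i + 5, n)
    paste(
      sprintf("%.10g", spec$ppm[i]),
      paste(sprintf("%.10g", spec$real[i:j]), collapse = " ")
    )
  }, "")
  writeLines(c(header, body, "##END="), path)
  invisible(path)
}

#' @rdname write_jcamp
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines[startsWith(lines, "##")]) {
    m <- regmatches(ln, regexec("^##\\$?([A-Za-z0-9_]+)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  start <- grep("^##XYDATA", lines)
  if (!length(start)) stop("no XYDATA block in ", path, call. = FALSE)
  end <- grep("^##END", lines)
  end <- end[end > start][1]
  data_lines <- lines[(start + 1):(end - 1)]
  y <- numeric(0)
  x_first <- numeric(0)
  for (ln in data_lines) {
    vals <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    x_first <- c(x_first, vals[1])
    y <- c(y, vals[-1])
  }
  n <- as.integer(kv[["NPOINTS"]])
  firstx <- as.numeric(kv[["FIRSTX"]])
  lastx <- as.numeric(kv[["LASTX"]])
  ppm <- seq(firstx, lastx, length.out = n)
  td <- as.integer(kv[["TD"]] %||% n)
  acq <- acq_params(
    sf_mhz = as.numeric(kv[["SFO1"]]),
    td = td, si = max(2L * n, td),
    sw_ppm = as.numeric(kv[["SW"]]),
    o1_ppm = as.numeric(kv[["O1P"]] %||% "6.0"),
    ns = as.integer(kv[["NS"]] %||% "64"),
    rg = as.numeric(kv[["RG"]] %||% "16"),
    p1_us = as.numeric(kv[["P1"]] %||% "8"),
    d1_s = as.numeric(kv[["D1"]] %||% "6")
  )
  if (length(y) != n) {
    stop("JCAMP XYDATA length mismatch: NPOINTS=", n, " but ", length(y),
      " Y values",
      call. = FALSE
    )
  }
  new_spectrum(y, numeric(n), ppm, acq,
    provenance = list(list(step = "read_jcamp", path = path))
  )
}
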