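# Plain-text serialization: columnar waveform files (gradients and
# complex multi-channel RF), columnar GIRF spectra, and a sectioned text
# container for field maps. All numeric output is written with 17
# significant digits so round trips are lossless in double precision.

.fmt <- function(x) formatC(x, format = "g", digits = 17)

#' Write a waveform to a columnar text file
#'
#' Header lines `# dt_s=`, `# units=` (`mT/m` for gradients, `uT` for RF)
#' and `# channels=`, followed by whitespace-separated sample columns (time
#' index implicit). Complex RF is stored as alternating real/imaginary
#' columns. Round trips through [read_waveform()] are lossless at 17
#' significant digits.
#'
#' @param w A [gradient_waveform] or [mc_rf].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  if (inherits(w, "gradient_waveform")) {
    hdr <- c(sprintf("# dt_s=%s", .fmt(w$dt)), "# units=mT/m", "# channels=3")
    body <- apply(t(w$samples), 1, function(r) paste(.fmt(r), collapse = " "))
  } else if (inherits(w, "mc_rf")) {
    C <- nrow(w$samples)
    hdr <- c(sprintf("# dt_s=%s", .fmt(w$dt)), "# units=uT", sprintf("# channels=%d", C))
    m <- matrix(0, ncol(w$samples), 2 * C)
    for (cc in 1:C) {
      m[, 2 * cc - 1] <- Re(w$samples[cc, ])
      m[, 2 * cc] <- Im(w$samples[cc, ])
    }
    body <- apply(m, 1, function(r) paste(.fmt(r), collapse = " "))
  } else {
    stop("w must be a gradient_waveform or mc_rf")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

.read_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Read a waveform from a columnar text file
#'
#' @param path File written by [write_waveform()].
#' @return A [gradient_waveform] (units mT/m) or [mc_rf] (units uT)
#'   depending on the file's `units` header.
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  kv <- .read_header(lines)
  if (is.null(kv$dt_s) || is.null(kv$units)) stop("missing dt_s/units header in ", path)
  dt <- as.numeric(kv$dt_s)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (kv$units == "mT/m") {
    gradient_waveform(t(m), dt)
  } else if (kv$units == "uT") {
    C <- as.integer(kv$channels)
    s <- matrix(0 + 0i, C, nrow(m))
    for (cc in 1:C) s[cc, ] <- complex(real = m[, 2 * cc - 1], imaginary = m[, 2 * cc])
    mc_rf(s, dt)
  } else {
    stop("unknown units '", kv$units, "' in ", path)
  }
}

#' Write a GIRF spectrum to a columnar text file
#'
#' Columns: frequency_Hz, Re(Hx), Im(Hx), Re(Hy), Im(Hy), Re(Hz), Im(Hz),
#' preceded by a `# df_hz=` header.
#'
#' @param H A [girf_spectrum].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_girf <- function(H, path) {
  stopifnot(inherits(H, "girf_spectrum"))
  m <- cbind(
    H$freqs,
    Re(H$H[, 1]), Im(H$H[, 1]),
    Re(H$H[, 2]), Im(H$H[, 2]),
    Re(H$H[, 3]), Im(H$H[, 3])
  )
  writeLines(
    c(
      sprintf("# df_hz=%s", .fmt(H$df)),
      "# columns=frequency_Hz ReHx ImHx ReHy ImHy ReHz ImHz",
      apply(m, 1, function(r) paste(.fmt(r), collapse = " "))
    ),
    path
  )
  invisible(path)
}

#' Read a GIRF spectrum written by [write_girf()]
#'
#' @param path File path.
#' @return A [girf_spectrum].
#' @export
read_girf <- function(path) {
  lines <- readLines(path)
  kv <- .read_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  H <- cbind(
    complex(real = m[, 2], imaginary = m[, 3]),
    complex(real = m[, 4], imaginary = m[, 5]),
    complex(real = m[, 6], imaginary = m[, 7])
  )
  df <- if (!is.null(kv$df_hz)) as.numeric(kv$df_hz) else diff(m[1:2, 1])
  girf_spectrum(m[, 1], H, df = df)
}

#' Write field maps to a sectioned text container
#'
#' Grid metadata in header lines, then one labelled block per plane
#' (`b1_real_<c>`, `b1_imag_<c>`, `domega`, `mask`), each `nx` rows of `ny`
#' values.
#'
#' @param maps A [field_maps].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_maps <- function(maps, path) {
  stopifnot(inherits(maps, "field_maps"))
  out <- c(
    sprintf("# nx=%d", maps$nx), sprintf("# ny=%d", maps$ny),
    sprintf("# nc=%d", maps$nc), sprintf("# fov_m=%s", .fmt(maps$fov)),
    sprintf("# m0=%s", .fmt(maps$m0))
  )
  block <- function(name, m) {
    c(sprintf("@%s", name), apply(m, 1, function(r) paste(.fmt(r), collapse = " ")))
  }
  for (cc in seq_len(maps$nc)) {
    out <- c(out, block(sprintf("b1_real_%d", cc), Re(maps$b1[, , cc])))
    out <- c(out, block(sprintf("b1_imag_%d", cc), Im(maps$b1[, , cc])))
  }
  out <- c(out, block("domega", maps$domega))
  out <- c(out, block("mask", maps$mask * 1))
  writeLines(out, path)
  invisible(path)
}

#' Read field maps written by [write_field_maps()]
#'
#' @param path File path.
#' @return A [field_maps].
#' @export
read_field_maps <- function(path) {
  lines <- readLines(path)
  kv <- .read_header(lines)
  nx <- as.integer(kv$nx); ny <- as.integer(kv$ny); nc <- as.integer(kv$nc)
  starts <- grep("^@", lines)
  blocks <- list()
  for (i in seq_along(starts)) {
    name <- sub("^@", "", lines[starts[i]])
    rows <- lines[(starts[i] + 1):(starts[i] + nx)]
    blocks[[name]] <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  }
  b1 <- array(0 + 0i, c(nx, ny, nc))
  for (cc in 1:nc) {
    b1[, , cc] <- blocks[[sprintf("b1_real_%d", cc)]] +
      1i * blocks[[sprintf("b1_imag_%d", cc)]]
  }
  field_maps(
    b1, blocks$domega, as.numeric(kv$fov_m),
    mask = blocks$mask > 0.5, m0 = as.numeric(kv$m0)
  )
}
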