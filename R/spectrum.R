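#' Construct a processed 1D 1H NMR spectrum
#'
#' Container for a processed (real-part) 1D spectrum plus the acquisition
#' metadata the quantification equations need: the 1H Larmor frequency
#' (`field_mhz`), the receiver gain and the number of scans. The ppm axis
#' is stored strictly descending (NMR display convention); ascending input
#' is reversed on construction.
#'
#' @param ppm_axis chemical shift per point (ppm), strictly monotone.
#' @param intensity real part per point (arbitrary units).
#' @param field_mhz spectrometer 1H frequency (MHz), `> 0`.
#' @param receiver_gain dimensionless receiver gain, `> 0`.
#' @param num_scans number of scans, `>= 1`.
#' @param label sample identifier.
#' @param metadata free-form named list.
#' @return an object of class `nmr_spectrum`.
#' @export
#' @examples
#' sp <- nmr_spectrum(seq(10, 0, length.out = 64), rnorm(64), field_mhz = 500.13)
nmr_spectrum <- function(ppm_axis, intensity, field_mhz,
                         receiver_gain = 1, num_scans = 1L,
                         label = "spectrum", metadata = list()) {
  ppm_axis <- as.numeric(ppm_axis)
  intensity <- as.numeric(intensity)
  if (length(ppm_axis) != length(intensity) || length(ppm_axis) < 2) {
    stop("ppm_axis and intensity must have equal length >= 2")
  }
  d <- diff(ppm_axis)
  if (all(d > 0)) {                    # store descending
    ppm_axis <- rev(ppm_axis)
    intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("ppm_axis must be strictly monotone")
  }
  if (!is.finite(field_mhz) || field_mhz <= 0) stop("field_mhz must be > 0")
  if (!is.finite(receiver_gain) || receiver_gain <= 0) {
    stop("receiver_gain must be > 0")
  }
  if (num_scans < 1) stop("num_scans must be >= 1")
  structure(list(ppm_axis = ppm_axis, intensity = intensity,
                 field_mhz = field_mhz, receiver_gain = receiver_gain,
                 num_scans = as.integer(num_scans), label = label,
                 metadata = metadata),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum '%s': %d points, %.4f..%.4f ppm, %.2f MHz, RG %g, NS %d>\n",
              x$label, length(x$ppm_axis), min(x$ppm_axis), max(x$ppm_axis),
              x$field_mhz, x$receiver_gain, x$num_scans))
  invisible(x)
}

# median absolute point spacing of the (uniform) ppm axis
ppm_spacing <- function(spectrum) {
  stats::median(abs(diff(spectrum$ppm_axis)))
}

# indices whose ppm falls inside (low, high); region is a length-2 numeric
region_indices <- function(spectrum, region) {
  lo <- min(region); hi <- max(region)
  which(spectrum$ppm_axis >= lo & spectrum$ppm_axis <= hi)
}

#' Extract intensity over a ppm interval
#'
#' @param spectrum an [nmr_spectrum()].
#' @param region `(low, high)` ppm pair.
#' @return list with `ppm`, `intensity` for the points inside the interval.
#' @export
spectrum_region <- function(spectrum, region) {
  idx <- region_indices(spectrum, region)
  list(ppm = spectrum$ppm_axis[idx], intensity = spectrum$intensity[idx],
       idx = idx)
}

# ---------------------------------------------------------------------------
# readers / writers
# ---------------------------------------------------------------------------

#' Read a processed 1D spectrum
#'
#' Supported dialects: `tsv` (two tab-separated columns, ppm then
#' intensity, with optional `# key: value` header lines), `jcamp`
#' (JCAMP-DX 1D, AFFN-encoded `(X++(Y..Y))` tables) and `bruker_proc`
#' (a Bruker processed-data directory: `pdata/<procno>/1r` plus `procs`,
#' and `acqus` at the top level). Only the parameter keys required for
#' quantification are consumed (point count, spectral width, offset,
#' field, receiver gain, scans); no FID processing is performed.
#'
#' When `rg_normalize = TRUE` (the default) intensities are divided by
#' the receiver gain at load time so that spectra acquired at different
#' gains are directly comparable.
#'
#' @param path file (tsv/jcamp) or experiment directory (bruker_proc).
#' @param format one of `"tsv"`, `"jcamp"`, `"bruker_proc"`.
#' @param field_mhz,receiver_gain,num_scans overrides for metadata the
#'   file may not carry (required for `tsv` files without header lines).
#' @param rg_normalize divide intensities by receiver gain (default TRUE).
#' @param label sample label; defaults to the file name.
#' @return an [nmr_spectrum()]. The `receiver_gain` field of the returned
#'   object is set to 1 after normalization (the raw gain is kept in
#'   `metadata$raw_receiver_gain`).
#' @export
load_spectrum <- function(path, format = c("tsv", "jcamp", "bruker_proc"),
                          field_mhz = NULL, receiver_gain = NULL,
                          num_scans = NULL, rg_normalize = TRUE,
                          label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- switch(format,
                tsv = read_tsv_spectrum(path),
                jcamp = read_jcamp_spectrum(path),
                bruker_proc = read_bruker_spectrum(path))
  fm <- field_mhz %||% raw$field_mhz
  if (is.null(fm)) {
    stop("field_mhz not present in '", path, "' and no override given")
  }
  rg <- receiver_gain %||% raw$receiver_gain %||% 1
  ns <- num_scans %||% raw$num_scans %||% 1L
  intensity <- raw$intensity
  meta <- list(source = path, format = format, raw_receiver_gain = rg,
               rg_normalized = rg_normalize)
  if (rg_normalize) {
    intensity <- intensity / rg
    rg_store <- 1
  } else {
    rg_store <- rg
  }
  nmr_spectrum(raw$ppm, intensity, field_mhz = fm, receiver_gain = rg_store,
               num_scans = ns, label = label %||% basename(path),
               metadata = meta)
}

#' Write a spectrum
#'
#' `tsv` writes a `# key: value` header (field_mhz, receiver_gain,
#' num_scans, label) followed by two tab-separated columns; `jcamp`
#' writes a minimal JCAMP-DX 5.01 file with an AFFN `(X++(Y..Y))` table.
#' `load_spectrum()` round-trips both.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param path output file.
#' @param format `"tsv"` or `"jcamp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("tsv", "jcamp")) {
  format <- match.arg(format)
  if (format == "tsv") {
    hdr <- c(sprintf("# field_mhz: %.17g", spectrum$field_mhz),
             sprintf("# receiver_gain: %.17g", spectrum$receiver_gain),
             sprintf("# num_scans: %d", spectrum$num_scans),
             sprintf("# label: %s", spectrum$label))
    body <- sprintf("%.17g\t%.17g", spectrum$ppm_axis, spectrum$intensity)
    writeLines(c(hdr, body), path)
  } else {
    n <- length(spectrum$ppm_axis)
    lines <- c("##TITLE= " %+% spectrum$label,
               "##JCAMP-DX= 5.01",
               "##DATA TYPE= NMR SPECTRUM",
               "##DATA CLASS= XYDATA",
               "##XUNITS= PPM",
               "##YUNITS= ARBITRARY UNITS",
               sprintf("##.OBSERVE FREQUENCY= %.17g", spectrum$field_mhz),
               sprintf("##$RECEIVERGAIN= %.17g", spectrum$receiver_gain),
               sprintf("##$NUMBEROFSCANS= %d", spectrum$num_scans),
               sprintf("##FIRSTX= %.17g", spectrum$ppm_axis[1]),
               sprintf("##LASTX= %.17g", spectrum$ppm_axis[n]),
               sprintf("##NPOINTS= %d", n),
               "##YFACTOR= 1",
               "##XYDATA= (X++(Y..Y))",
               sprintf("%.17g %.17g", spectrum$ppm_axis, spectrum$intensity),
               "##END=")
    writeLines(lines, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%+%` <- function(a, b) paste0(a, b)

read_tsv_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "[\t ]+")
  bad <- vapply(parts, length, 1L) < 2
  if (any(bad)) stop("malformed two-column spectrum file: '", path, "'")
  ppm <- as.numeric(vapply(parts, `[[`, "", 1L))
  y <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(ppm) || anyNA(y)) stop("non-numeric data in '", path, "'")
  list(ppm = ppm, intensity = y,
       field_mhz = if (!is.null(meta$field_mhz)) as.numeric(meta$field_mhz),
       receiver_gain = if (!is.null(meta$receiver_gain)) as.numeric(meta$receiver_gain),
       num_scans = if (!is.null(meta$num_scans)) as.integer(meta$num_scans))
}

jcamp_field <- function(lines, key) {
  hit <- grep(paste0("^##", key, "="), lines, value = TRUE, fixed = FALSE)
  if (!length(hit)) return(NULL)
  sub("\\$\\$.*$", "", sub("^[^=]*=\\s*", "", hit[1]))
}

read_jcamp_spectrum <- function(path) {
  lines <- readLines(path)
  npoints <- as.integer(jcamp_field(lines, "NPOINTS"))
  firstx <- as.numeric(jcamp_field(lines, "FIRSTX"))
  lastx <- as.numeric(jcamp_field(lines, "LASTX"))
  yfac <- as.numeric(jcamp_field(lines, "YFACTOR") %||% "1")
  freq <- jcamp_field(lines, "\\.OBSERVE FREQUENCY")
  rg <- jcamp_field(lines, "\\$RECEIVERGAIN")
  ns <- jcamp_field(lines, "\\$NUMBEROFSCANS")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA table in '", path, "'")
  end <- grep("^##END=", lines)
  end <- if (length(end)) end[end > start[1]][1] else length(lines) + 1L
  tab <- lines[(start[1] + 1L):(end - 1L)]
  tab <- tab[nzchar(tab) & !grepl("^\\$\\$", tab)]
  ppm <- numeric(0); y <- numeric(0)
  for (ln in tab) {
    vals <- as.numeric(strsplit(trimws(ln), "[\t ]+")[[1]])
    if (anyNA(vals) || length(vals) < 2) {
      stop("unsupported (non-AFFN) JCAMP data line in '", path, "'")
    }
    x0 <- vals[1]
    ys <- vals[-1]
    ppm <- c(ppm, rep(x0, length(ys)))   # provisional; re-gridded below
    y <- c(y, ys)
  }
  n <- length(y)
  if (!is.null(npoints) && !is.na(npoints) && npoints != n) {
    stop("JCAMP NPOINTS (", npoints, ") disagrees with data length (", n, ")")
  }
  axis <- seq(firstx, lastx, length.out = n)
  list(ppm = axis, intensity = y * yfac,
       field_mhz = if (!is.null(freq)) as.numeric(freq),
       receiver_gain = if (!is.null(rg)) as.numeric(rg),
       num_scans = if (!is.null(ns)) as.integer(ns))
}

bruker_param <- function(lines, key) {
  hit <- grep(paste0("^##\\$", key, "="), lines, value = TRUE)
  if (!length(hit)) return(NULL)
  as.numeric(sub("^[^=]*=\\s*", "", hit[1]))
}

read_bruker_spectrum <- function(path, procno = 1) {
  procs_path <- file.path(path, "pdata", procno, "procs")
  r1_path <- file.path(path, "pdata", procno, "1r")
  if (!file.exists(procs_path) || !file.exists(r1_path)) {
    stop("'", path, "' is not a Bruker processed-data directory")
  }
  procs <- readLines(procs_path, warn = FALSE)
  si <- as.integer(bruker_param(procs, "SI"))
  offset <- bruker_param(procs, "OFFSET")        # ppm of first point
  swp <- bruker_param(procs, "SW_p")             # processed width, Hz
  sf <- bruker_param(procs, "SF")                # MHz
  nc <- bruker_param(procs, "NC_proc") %||% 0
  byt <- bruker_param(procs, "BYTORDP") %||% 0   # 0 = little endian
  endian <- if (byt == 0) "little" else "big"
  con <- file(r1_path, "rb")
  on.exit(close(con))
  y <- readBin(con, integer(), n = si, size = 4L, endian = endian)
  if (length(y) != si) stop("truncated 1r file in '", path, "'")
  y <- y * 2^nc
  spacing <- (swp / sf) / si
  ppm <- offset - spacing * seq.int(0L, si - 1L)
  acqus_path <- file.path(path, "acqus")
  rg <- ns <- NULL
  if (file.exists(acqus_path)) {
    acqus <- readLines(acqus_path, warn = FALSE)
    rg <- bruker_param(acqus, "RG")
    ns <- as.integer(bruker_param(acqus, "NS"))
  }
  list(ppm = ppm, intensity = y, field_mhz = sf,
       receiver_gain = rg, num_scans = ns)
}

#' Write a synthetic Bruker-style processed-data directory
#'
#' Serializes a spectrum as a minimal Bruker processed-data layout
#' (`acqus`, `pdata/1/procs`, `pdata/1/1r` as little-endian int32) so the
#' `bruker_proc` reader can be exercised without vendor data. Intensities
#' are scaled to use the int32 range; the scale is recorded in `NC_proc`
#' semantics (stored here with `NC_proc = 0` and pre-scaled integers).
#'
#' @param spectrum an [nmr_spectrum()].
#' @param dir output experiment directory (created).
#' @return `dir`, invisibly.
#' @export
write_bruker_fixture <- function(spectrum, dir) {
  pd <- file.path(dir, "pdata", "1")
  dir.create(pd, recursive = TRUE, showWarnings = FALSE)
  n <- length(spectrum$ppm_axis)
  spacing <- ppm_spacing(spectrum)
  swp <- spacing * n * spectrum$field_mhz
  scale <- max(abs(spectrum$intensity), 1e-300)
  yint <- as.integer(round(spectrum$intensity / scale * 2^30))
  nc <- log2(scale / 2^30)
  procs <- c("##TITLE= Parameter file, synthetic fixture",
             sprintf("##$SI= %d", n),
             sprintf("##$OFFSET= %.12g", spectrum$ppm_axis[1]),
             sprintf("##$SW_p= %.12g", swp),
             sprintf("##$SF= %.12g", spectrum$field_mhz),
             sprintf("##$NC_proc= %.12g", nc),
             "##$BYTORDP= 0",
             "##$DTYPP= 0",
             "##END=")
  writeLines(procs, file.path(pd, "procs"))
  acqus <- c("##TITLE= Parameter file, synthetic fixture",
             sprintf("##$NS= %d", spectrum$num_scans),
             sprintf("##$RG= %.12g", spectrum$receiver_gain),
             sprintf("##$SFO1= %.12g", spectrum$field_mhz),
             "##END=")
  writeLines(acqus, file.path(dir, "acqus"))
  con <- file(file.path(pd, "1r"), "wb")
  writeBin(yint, con, size = 4L, endian = "little")
  close(con)
  invisible(dir)
}

# ---------------------------------------------------------------------------
# low-level spectral utilities
# ---------------------------------------------------------------------------

#' Estimate spectral noise
#'
#' Sample standard deviation of the intensities in a signal-free region,
#' by default 13.0--14.0 ppm (downfield of any resonance in serum
#' spectra). This is the noise sigma_f entering the spectrometer
#' sensitivity.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param region `(low, high)` ppm pair, default `c(13, 14)`.
#' @return scalar noise standard deviation (intensity units).
#' @export
estimate_noise <- function(spectrum, region = c(13, 14)) {
  rng <- range(spectrum$ppm_axis)
  if (min(region) < rng[1] || max(region) > rng[2]) {
    stop("noise region lies outside the spectrum axis")
  }
  idx <- region_indices(spectrum, region)
  if (length(idx) < 16) stop("noise region contains fewer than 16 points")
  stats::sd(spectrum$intensity[idx])
}

#' Bin spectra and mean-center the bin table
#'
#' Integrates each spectrum over contiguous half-open ppm bins (sum of
#' intensities times point spacing) and mean-centers every column, the
#' conventional preprocessing before PCA of 1H NMR profiles (0.02 ppm
#' bins). Bin edges are aligned to the start of `region`; bins follow the
#' descending axis convention, i.e. the first bin is the most downfield.
#'
#' @param spectra list of [nmr_spectrum()] sharing `field_mhz`.
#' @param bin_width bin width (ppm), default 0.02.
#' @param region `(low, high)` ppm pair to bin over; default the common
#'   axis range of the first spectrum.
#' @param center mean-center columns (default TRUE).
#' @return list with `matrix` (samples x bins), `centers` (bin center
#'   ppm), `edges`, and `col_means` (the subtracted means; zeros when
#'   `center = FALSE`).
#' @export
bin_and_center <- function(spectra, bin_width = 0.02, region = NULL,
                           center = TRUE) {
  if (inherits(spectra, "nmr_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1, bin_width > 0)
  fields <- vapply(spectra, `[[`, numeric(1), "field_mhz")
  if (max(fields) - min(fields) > 1e-9) {
    stop("all spectra must share field_mhz for joint binning")
  }
  if (is.null(region)) region <- range(spectra[[1]]$ppm_axis)
  lo <- min(region); hi <- max(region)
  nbins <- floor((hi - lo) / bin_width + 1e-9)
  if (nbins < 1) stop("region narrower than one bin")
  edges <- hi - bin_width * seq.int(0, nbins)   # descending, aligned to start
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mat <- t(vapply(spectra, function(sp) {
    dx <- ppm_spacing(sp)
    # half-open [hi_edge, lo_edge) bins along the descending axis
    bin_of <- floor((hi - sp$ppm_axis) / bin_width) + 1L
    keep <- bin_of >= 1L & bin_of <= nbins & sp$ppm_axis <= hi
    v <- vapply(split(sp$intensity[keep], factor(bin_of[keep], levels = seq_len(nbins))),
                sum, numeric(1))
    unname(v) * dx
  }, numeric(nbins)))
  if (nbins == 1) mat <- matrix(mat, ncol = 1)
  cm <- if (center) colMeans(mat) else numeric(nbins)
  list(matrix = sweep(mat, 2, cm), centers = centers, edges = edges,
       col_means = cm)
}
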