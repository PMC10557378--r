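# Spectrum container: a tibble with one row per scan and list-columns for
# the peak arrays, so scan streams compose with dplyr verbs.
#   scan            integer scan number (1-based, acquisition order)
#   ms_level        1 = full/SIM, 2/3 = tandem stages
#   scan_time       seconds from run start
#   analyzer        "high_res" (orbitrap-like) or "low_res" (ion-trap-like)
#   precursor_chain list of isolation m/z, length ms_level - 1
#   mz, intensity   list columns, equal-length ascending centroid arrays

#' Build a spectrum table
#'
#' @param ms_level Integer vector of MS levels (>= 1).
#' @param scan_time Numeric vector, seconds from run start.
#' @param mz,intensity Lists of equal-length numeric vectors; m/z strictly
#'   increasing within each scan, intensities non-negative.
#' @param precursor_chain List of numeric isolation m/z vectors; each must
#'   have length `ms_level - 1` (empty for MS1).
#' @param analyzer `"high_res"` or `"low_res"`, recycled.
#' @return A tibble of scans (one row per scan).
#' @examples
#' mass_spectra(ms_level = 3, scan_time = 0.5,
#'              mz = list(c(331.01, 333.21, 341.03)),
#'              intensity = list(c(10, 60, 25)),
#'              precursor_chain = list(c(459.13, 441.12)))
#' @export
mass_spectra <- function(ms_level, scan_time, mz, intensity,
                         precursor_chain = NULL, analyzer = "low_res") {
  n <- length(ms_level)
  if (is.null(precursor_chain)) {
    if (any(ms_level != 1L)) abort("precursor_chain required for MS level > 1")
    precursor_chain <- rep(list(numeric()), n)
  }
  out <- tibble::tibble(
    scan = seq_len(n),
    ms_level = as.integer(ms_level),
    scan_time = as.numeric(scan_time),
    analyzer = rep_len(analyzer, n),
    precursor_chain = precursor_chain,
    mz = mz,
    intensity = intensity
  )
  validate_spectra(out)
  out
}

validate_spectra <- function(x) {
  need <- c("ms_level", "scan_time", "analyzer", "precursor_chain", "mz", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("not a spectrum table; missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ok_len <- mapply(function(m, i) length(m) == length(i), x$mz, x$intensity)
  if (!all(ok_len)) abort("mz and intensity arrays differ in length")
  ok_sorted <- vapply(x$mz, function(m) !is.unsorted(m, strictly = TRUE),
                      logical(1))
  if (!all(ok_sorted)) abort("m/z arrays must be strictly increasing")
  ok_chain <- mapply(function(l, ch) length(ch) == l - 1L,
                     x$ms_level, x$precursor_chain)
  if (!all(ok_chain)) abort("precursor chain length must equal ms_level - 1")
  if (!all(x$analyzer %in% c("high_res", "low_res"))) {
    abort("analyzer must be 'high_res' or 'low_res'")
  }
  invisible(x)
}

#' Read centroided mzML into a spectrum table
#'
#' Peak arrays and scan metadata are read with `mzR`; the full MS3 precursor
#' chain (e.g. 459.13 -> 441.12) is taken from the mzML precursor list via a
#' secondary XML pass, since the scan header carries only a single precursor
#' m/z. Profile-mode files are rejected: centroid during conversion.
#'
#' @param path Path to a centroided mzML file.
#' @param analyzer `NULL` (infer: MS3 scans are tagged `"low_res"`,
#'   reflecting ion-trap acquisition of the diagnostic product ions, all
#'   other levels `"high_res"`), or a value/vector overriding the tag.
#' @return A spectrum tibble (zero rows for an empty run).
#' @seealso [write_mzml()], [mass_spectra()]
#' @export
read_mzml <- function(path, analyzer = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read mzML file: ", path))
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("package 'mzR' is required to read mzML files")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  n <- length(fh)
  if (n == 0L) {
    return(mass_spectra(integer(), numeric(), list(), list(), list()))
  }
  h <- mzR::header(fh)
  if (any(!is.na(h$centroided) & !h$centroided)) {
    abort("profile-mode spectra found; convert with centroiding first")
  }
  pk <- mzR::peaks(fh)
  if (n == 1L) pk <- list(pk)
  chains <- mzml_precursor_chains(path)
  if (length(chains) != n) {
    # fall back to the single precursor the header exposes
    chains <- lapply(seq_len(n), function(i) {
      if (h$msLevel[i] > 1L && !is.na(h$precursorMZ[i])) h$precursorMZ[i] else numeric()
    })
  }
  anl <- analyzer %||% ifelse(h$msLevel >= 3L, "low_res", "high_res")
  mass_spectra(
    ms_level = h$msLevel,
    scan_time = h$retentionTime,
    mz = lapply(pk, function(p) as.numeric(p[, 1L])),
    intensity = lapply(pk, function(p) as.numeric(p[, 2L])),
    precursor_chain = chains,
    analyzer = anl
  )
}

# Full isolation chain per spectrum from the mzML precursorList elements.
mzml_precursor_chains <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- tryCatch(xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m"),
                 error = function(e) NULL)
  q <- function(node, xp) xml2::xml_find_all(node, xp, ns)
  sp <- q(doc, ".//m:run//m:spectrum")
  lapply(sp, function(s) {
    iso <- q(s, paste0(".//m:precursor/m:isolationWindow/",
                       "m:cvParam[@accession='MS:1000827']"))
    v <- as.numeric(xml2::xml_attr(iso, "value"))
    if (!length(v)) {
      sel <- q(s, paste0(".//m:precursor//m:selectedIon/",
                         "m:cvParam[@accession='MS:1000744']"))
      v <- as.numeric(xml2::xml_attr(sel, "value"))
    }
    v
  })
}

#' Write a spectrum table as centroided mzML
#'
#' Minimal standard-conforming mzML (uncompressed 64-bit float arrays) used
#' to serialize simulated runs; files written here round-trip through
#' [read_mzml()] and standard mzML readers.
#'
#' @param spectra A spectrum tibble ([mass_spectra()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  validate_spectra(spectra)
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L, endian = "little"))
  prec_xml <- function(chain) {
    if (!length(chain)) return("")
    pl <- paste(vapply(chain, function(p) paste0(
      '        <precursor>\n',
      '          <isolationWindow>\n',
      sprintf('            <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n', p),
      '          </isolationWindow>\n',
      '          <selectedIonList count="1">\n            <selectedIon>\n',
      sprintf('              <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n', p),
      '            </selectedIon>\n          </selectedIonList>\n',
      '          <activation>\n',
      '            <cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>\n',
      '          </activation>\n        </precursor>'
    ), character(1)), collapse = "\n")
    sprintf('      <precursorList count="%d">\n%s\n      </precursorList>\n',
            length(chain), pl)
  }
  one <- function(i) {
    mzb <- enc(spectra$mz[[i]]); inb <- enc(spectra$intensity[[i]])
    paste0(
      sprintf('    <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
              i - 1L, i, length(spectra$mz[[i]])),
      sprintf('      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>\n',
              spectra$ms_level[i]),
      '      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>\n',
      '      <scanList count="1">\n',
      '        <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>\n',
      '        <scan>\n',
      sprintf('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>\n',
              spectra$scan_time[i]),
      '        </scan>\n      </scanList>\n',
      prec_xml(spectra$precursor_chain[[i]]),
      '      <binaryDataArrayList count="2">\n',
      sprintf('        <binaryDataArray encodedLength="%d">\n', nchar(mzb)),
      '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      sprintf('          <binary>%s</binary>\n', mzb),
      '        </binaryDataArray>\n',
      sprintf('        <binaryDataArray encodedLength="%d">\n', nchar(inb)),
      '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
      sprintf('          <binary>%s</binary>\n', inb),
      '        </binaryDataArray>\n      </binaryDataArrayList>\n    </spectrum>'
    )
  }
  body <- paste(vapply(seq_len(nrow(spectra)), one, character(1)), collapse = "\n")
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="2">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n    <fileContent>\n',
    '      <cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
    '    </fileContent>\n  </fileDescription>\n',
    '  <softwareList count="1">\n    <software id="pgms3" version="0.1">\n',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="pgms3 simulator"/>\n',
    '    </software>\n  </softwareList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1">\n',
    '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>\n',
    '    </instrumentConfiguration>\n  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n    <dataProcessing id="dp1">\n',
    '      <processingMethod order="1" softwareRef="pgms3">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '      </processingMethod>\n    </dataProcessing>\n  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="dp1">\n', nrow(spectra)),
    body,
    '\n    </spectrumList>\n  </run>\n</mzML>'
  )
  writeLines(doc, path)
  invisible(path)
}

#' Select scans by MS level and precursor chain
#'
#' Keeps scans of the requested MS level whose isolation chain matches
#' `chain` element-wise within `chain_tol` (amu). A pure filter: the output
#' is a subsequence of the input in original order.
#'
#' @param spectra A spectrum tibble.
#' @param ms_level Required MS level.
#' @param chain Numeric isolation m/z chain of length `ms_level - 1`, e.g.
#'   `c(459.13, 441.12)` for the PG MS3 scans.
#' @param chain_tol Match tolerance in amu (default 0.5).
#' @return The filtered spectrum tibble.
#' @export
select_scans <- function(spectra, ms_level, chain = numeric(), chain_tol = 0.5) {
  validate_spectra(spectra)
  if (length(chain) != ms_level - 1L) {
    abort("chain length must equal ms_level - 1")
  }
  keep <- spectra$ms_level == ms_level &
    vapply(spectra$precursor_chain, function(pc) {
      length(pc) == length(chain) &&
        (length(chain) == 0L || all(abs(pc - chain) <= chain_tol))
    }, logical(1))
  spectra[keep, ]
}

#' Diagnostic MS3 product-ion channels
#'
#' The three channels whose relative abundances encode the isomer
#' composition: m/z 331.0096 (PGE2), 333.2060 (all three isomers,
#' abundance-graded) and 341.0301 (delta12-PGD2). Default tolerances follow
#' the analyzer: 5 ppm for high-resolution scans, 0.4 amu for ion-trap
#' scans (where 331.0096 and 331.1905 are not resolved and are read as one
#' channel).
#'
#' @param analyzer `"low_res"` (default) or `"high_res"`.
#' @return A tibble with columns `label`, `target_mz`, `tol_mode`, `tol_value`.
#' @export
pg_channels <- function(analyzer = c("low_res", "high_res")) {
  analyzer <- match.arg(analyzer)
  tibble::tibble(
    label = c("i331", "i333", "i341"),
    target_mz = c(331.0096, 333.2060, 341.0301),
    tol_mode = if (analyzer == "low_res") "amu" else "ppm",
    tol_value = if (analyzer == "low_res") 0.4 else 5
  )
}

# Intensity of the most intense peak inside a tolerance window,
# [target - tol, target + tol) with inclusive lower bound; ties by nearest
# m/z. Returns 0 when the window is empty.
window_intensity <- function(mz, intensity, target, tol_mode, tol_value) {
  tol <- if (tol_mode == "ppm") target * tol_value * 1e-6 else tol_value
  if (tol <= 0) abort("tolerance must be positive")
  inwin <- mz >= target - tol & mz < target + tol
  if (!any(inwin)) return(0)
  w_mz <- mz[inwin]; w_in <- intensity[inwin]
  best <- which(w_in == max(w_in))
  if (length(best) > 1L) best <- best[which.min(abs(w_mz[best] - target))]
  w_in[best]
}

#' Extract channel intensities per scan
#'
#' For each scan and channel, the intensity of the most intense centroid
#' inside the channel's tolerance window (0 when none). Ties in intensity
#' are broken by proximity to the target m/z.
#'
#' @param spectra A spectrum tibble.
#' @param channels A channel tibble as from [pg_channels()]; `tol_mode`
#'   may be `"ppm"` or `"amu"` per channel.
#' @return A tibble with `scan`, `scan_time` and one intensity column per
#'   channel label.
#' @export
extract_channels <- function(spectra, channels = pg_channels()) {
  validate_spectra(spectra)
  stopifnot(all(c("label", "target_mz", "tol_mode", "tol_value") %in% names(channels)))
  if (any(channels$tol_value <= 0)) abort("tolerance must be positive")
  out <- tibble::tibble(
    scan = if ("scan" %in% names(spectra)) spectra$scan else seq_len(nrow(spectra)),
    scan_time = spectra$scan_time
  )
  for (k in seq_len(nrow(channels))) {
    out[[channels$label[k]]] <- mapply(
      window_intensity, spectra$mz, spectra$intensity,
      MoreArgs = list(target = channels$target_mz[k],
                      tol_mode = channels$tol_mode[k],
                      tol_value = channels$tol_value[k])
    )
  }
  out
}

# Relative abundances of the three diagnostic channels; undefined (NA)
# when the summed intensity is zero.
triplet_relative <- function(x) {
  stopifnot(all(c("i331", "i333", "i341") %in% names(x)))
  tot <- x$i331 + x$i333 + x$i341
  x$r331 <- ifelse(tot > 0, x$i331 / tot, NA_real_)
  x$r333 <- ifelse(tot > 0, x$i333 / tot, NA_real_)
  x$r341 <- ifelse(tot > 0, x$i341 / tot, NA_real_)
  x
}

#' Average a flow-injection signal into one channel triplet
#'
#' Averages per-scan channel intensities over a time window, then derives
#' relative abundances (each channel divided by the three-channel sum).
#' When `window` is `NULL` the contiguous window of length `duration`
#' maximizing the total extracted ion current is used, emulating averaging
#' over the electrospray plateau of a flow-injection run.
#'
#' @param spectra A spectrum tibble (typically MS3 scans of one injection).
#' @param channels Channel table, see [extract_channels()].
#' @param window `c(start, end)` in seconds, or `NULL` to auto-detect.
#' @param duration Auto-detection window length in seconds (default 138,
#'   i.e. 2.3 min).
#' @return A one-row tibble: `i331`, `i333`, `i341` (mean intensities),
#'   `r331`, `r333`, `r341`, `n_scans`, `window_start`, `window_end`.
#' @export
average_fia <- function(spectra, channels = pg_channels(), window = NULL,
                        duration = 138) {
  ext <- extract_channels(spectra, channels)
  if (!nrow(ext)) abort("no scans to average")
  if (is.null(window)) {
    tic <- ext$i331 + ext$i333 + ext$i341
    starts <- ext$scan_time
    tot <- vapply(starts, function(s) {
      sum(tic[ext$scan_time >= s & ext$scan_time <= s + duration])
    }, numeric(1))
    s <- starts[which.max(tot)]
    window <- c(s, s + duration)
  }
  if (window[1] > max(ext$scan_time) || window[2] < min(ext$scan_time)) {
    abort("averaging window lies outside the run time span")
  }
  inwin <- ext$scan_time >= window[1] & ext$scan_time <= window[2]
  if (!any(inwin)) abort("no scans fall inside the averaging window")
  m <- dplyr::summarise(ext[inwin, ], dplyr::across(c("i331", "i333", "i341"), mean))
  m <- triplet_relative(m)
  m$n_scans <- sum(inwin)
  m$window_start <- window[1]
  m$window_end <- window[2]
  m
}
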