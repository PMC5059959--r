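#' Read a centroided peak list
#'
#' Delimited files must have two numeric columns (m/z, intensity); a
#' header line is detected and skipped. mzML files are read through the
#' mzR package (first MS1 spectrum unless `scan` is given). Peaks are
#' returned sorted by m/z with exact duplicate m/z merged by intensity
#' sum.
#'
#' @param path file to read.
#' @param dialect one of `"tsv"`, `"csv"`, `"mzml"`; default guesses from
#'   the file extension.
#' @param sampleId,replicate metadata attached to the returned spectrum;
#'   default to the file name and 1.
#' @param scan scan number for mzML input.
#' @return A [RawSpectrum-class].
#' @export
readPeakList <- function(path, dialect = NULL,
                         sampleId = sub("\\.[^.]+$", "", basename(path)),
                         replicate = 1L, scan = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    ext <- tolower(sub(".*\\.", "", path))
    dialect <- switch(ext, csv = "csv", mzml = "mzml", "tsv")
  }
  dialect <- match.arg(dialect, c("tsv", "csv", "mzml"))
  if (dialect == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, scan)
    return(RawSpectrum(sampleId, replicate, pk[, 1], pk[, 2]))
  }
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peak list: ", path)
  start <- 1L
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L
  if (start > length(lines)) stop("empty peak list: ", path)
  n <- length(lines) - start + 1L
  mz <- numeric(n)
  inten <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[start + i - 1L], sep, fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || any(is.na(vals[1:2])))
      stop("malformed peak list row at line ", start + i - 1L,
           " of ", path, ": '", lines[start + i - 1L], "'")
    mz[i] <- vals[1]
    inten[i] <- vals[2]
  }
  RawSpectrum(sampleId, replicate, mz, inten)
}

#' Write a peak list as two-column delimited text
#'
#' @param spectrum a [RawSpectrum-class].
#' @param path output file.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
writePeakList <- function(spectrum, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(mz = spectrum@mz, intensity = spectrum@intensity)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write spectra to a minimal mzML file
#'
#' Emits centroided MS1 spectra with uncompressed 64-bit little-endian
#' binary arrays; the output is readable by proteowizard-based readers
#' (mzR).
#'
#' @param spectra a list of [RawSpectrum-class] objects.
#' @param path output file.
#' @export
writeMzML <- function(spectra, path) {
  if (is(spectra, "RawSpectrum")) spectra <- list(spectra)
  enc <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  arr <- function(b64, acc, name, unitAcc, unitName) {
    paste0(
      '<binaryDataArray encodedLength="', nchar(b64), '">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="', acc, '" name="', name,
      '" value="" unitCvRef="MS" unitAccession="', unitAcc,
      '" unitName="', unitName, '"/>\n',
      "<binary>", b64, "</binary>\n</binaryDataArray>")
  }
  blocks <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    paste0(
      '<spectrum index="', i - 1L, '" id="scan=', i,
      '" defaultArrayLength="', length(sp@mz), '">\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '<binaryDataArrayList count="2">\n',
      arr(enc(sp@mz), "MS:1000514", "m/z array", "MS:1000040", "m/z"),
      arr(enc(sp@intensity), "MS:1000515", "intensity array",
          "MS:1000131", "number of detector counts"),
      "</binaryDataArrayList>\n</spectrum>")
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>\n',
    '<run id="run1">\n<spectrumList count="', length(spectra),
    '" defaultDataProcessingRef="dp">\n',
    paste(blocks, collapse = "\n"),
    "\n</spectrumList>\n</run>\n</mzML>\n")
  writeLines(doc, path)
  invisible(path)
}

#' Apply the import filters of the peak-table import step
#'
#' Retains peaks whose intensity is at least `minResponse` (inclusive)
#' and, if more than `maxPeaks` remain, the `maxPeaks` most intense
#' (ties at the boundary keep the lower m/z). Output stays sorted by
#' m/z; the operation is idempotent.
#'
#' @param spectrum a [RawSpectrum-class].
#' @param minResponse minimum retained intensity (default 10.0).
#' @param maxPeaks maximum number of retained peaks (default 10000).
#' @return The filtered [RawSpectrum-class].
#' @export
applyImportFilters <- function(spectrum, minResponse = 10.0,
                               maxPeaks = 10000L) {
  stopifnot(minResponse >= 0, maxPeaks >= 1)
  keep <- spectrum@intensity >= minResponse
  mz <- spectrum@mz[keep]
  inten <- spectrum@intensity[keep]
  if (length(mz) > maxPeaks) {
    o <- order(-inten, mz)[seq_len(maxPeaks)]
    o <- sort(o)
    mz <- mz[o]
    inten <- inten[o]
  }
  new("RawSpectrum", sampleId = spectrum@sampleId,
      replicate = spectrum@replicate, mz = mz, intensity = inten)
}

#' Write / read an aligned peak table as wide CSV
#'
#' Serialization is a wide CSV: four metadata header rows (`#sample_id`,
#' `#class`, `#set`, `#replicate`) followed by a header line and one row
#' per reference ion with a leading m/z column and one intensity column
#' per sample-measurement. Values round-trip at full double precision.
#'
#' @param table a [PeakTable-class].
#' @param path file path.
#' @return `readPeakTable` returns the reconstructed [PeakTable-class].
#' @export
writePeakTable <- function(table, path) {
  cd <- columnMeta(table)
  x <- peakIntensities(table)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- function(tag, v) paste(c(tag, as.character(v)), collapse = ",")
  writeLines(c(
    meta("#sample_id", cd$sample_id),
    meta("#class", cd$class),
    meta("#set", cd$set),
    meta("#replicate", cd$replicate),
    paste(c("mz", sprintf("c%d", seq_len(ncol(x)))), collapse = ",")
  ), con)
  if (nrow(x)) {
    body <- cbind(format(axisMz(table), digits = 17, trim = TRUE),
                  matrix(format(x, digits = 17, trim = TRUE), nrow = nrow(x)))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !startsWith(lines[1], "#sample_id"))
    stop("not a peak-table file (missing metadata header): ", path)
  splitRow <- function(i) strsplit(lines[i], ",", fixed = TRUE)[[1]][-1]
  sample_id <- splitRow(1)
  cls <- splitRow(2)
  set <- splitRow(3)
  repl <- as.integer(splitRow(4))
  nc <- length(sample_id)
  body <- lines[-(1:5)]
  if (length(body)) {
    vals <- lapply(strsplit(body, ",", fixed = TRUE), as.numeric)
    bad <- which(lengths(vals) != nc + 1L | vapply(vals, anyNA, logical(1)))
    if (length(bad))
      stop("malformed peak-table row at line ", bad[1] + 5L, " of ", path)
    m <- do.call(rbind, vals)
    mz <- m[, 1]
    x <- m[, -1, drop = FALSE]
  } else {
    mz <- numeric(0)
    x <- matrix(numeric(0), nrow = 0, ncol = nc)
  }
  PeakTable(mz, x, sample_id = sample_id, class = cls, set = set,
            replicate = repl)
}

#' Write / read a cohort manifest CSV
#'
#' Columns: sample_id, class, replicate, set and (optionally) path of the
#' corresponding peak-list file.
#'
#' @param manifest data.frame.
#' @param path file path.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "replicate")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (!"set" %in% colnames(m)) m$set <- "none"
  m$replicate <- as.integer(m$replicate)
  m
}

#' Write a generated cohort to disk
#'
#' One delimited peak list per measurement plus a manifest CSV (with file
#' paths) and a JSON truth file listing the planted ions.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @param dialect peak-list dialect, `"tsv"` or `"csv"`.
#' @return The manifest data.frame (invisibly), with a `path` column.
#' @export
writeCohort <- function(cohort, dir, dialect = "tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  ext <- if (dialect == "csv") "csv" else "tsv"
  man$path <- sprintf("%s_r%d.%s", man$sample_id, man$replicate, ext)
  for (i in seq_along(cohort$spectra))
    writePeakList(cohort$spectra[[i]], file.path(dir, man$path[i]), dialect)
  writeManifest(man, file.path(dir, "manifest.csv"))
  jsonlite::write_json(cohort$truth,
                       file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(man)
}

#' Read a cohort (manifest + peak lists) from disk
#'
#' @param dir directory containing `manifest.csv` and the peak lists it
#'   references.
#' @return list with `spectra` and `manifest`, as [generateCohort()].
#' @export
readCohort <- function(dir) {
  man <- readManifest(file.path(dir, "manifest.csv"))
  if (!"path" %in% colnames(man))
    stop("manifest has no 'path' column; cannot locate peak lists")
  locate <- function(p) if (startsWith(p, "/")) p else file.path(dir, p)
  spectra <- lapply(seq_len(nrow(man)), function(i)
    readPeakList(locate(man$path[i]),
                 sampleId = man$sample_id[i],
                 replicate = man$replicate[i]))
  list(spectra = spectra, manifest = man)
}
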