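#' Read fragmentation spectra from an MGF file
#'
#' Parses Mascot Generic Format: `BEGIN IONS`/`END IONS` blocks with
#' `KEY=value` headers (`PEPMASS`, `CHARGE`, `TITLE`, `COLLISION_ENERGY`,
#' `ADDUCT`) followed by whitespace-separated `mz intensity` peak lines.
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum()] objects (empty list for an empty file).
#' @seealso [write_mgf()], [read_msp()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  hdr <- list()
  mz <- numeric()
  int <- numeric()
  begin_line <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (toupper(ln) == "BEGIN IONS") {
      if (in_block)
        stop("malformed MGF: BEGIN IONS inside open block at line ", i)
      in_block <- TRUE
      begin_line <- i
      hdr <- list(); mz <- numeric(); int <- numeric()
    } else if (toupper(ln) == "END IONS") {
      if (!in_block)
        stop("malformed MGF: END IONS without BEGIN IONS at line ", i)
      ce <- hdr[["COLLISION_ENERGY"]]
      ce <- if (is.null(ce)) NA
            else if (identical(tolower(ce), "merged")) "merged"
            else suppressWarnings(as.numeric(ce))
      charge <- hdr[["CHARGE"]]
      ion_mode <- if (!is.null(charge) && grepl("-", charge, fixed = TRUE))
        "negative" else "positive"
      pep <- hdr[["PEPMASS"]]
      pre <- if (is.null(pep)) NA_real_
             else as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])
      spectra[[length(spectra) + 1L]] <- spectrum(
        mz, int,
        id = if (is.null(hdr[["TITLE"]]))
          paste0("spectrum_", length(spectra) + 1L) else hdr[["TITLE"]],
        precursor_mz = pre,
        adduct = if (is.null(hdr[["ADDUCT"]])) "[M+H]+" else hdr[["ADDUCT"]],
        collision_energy = ce,
        ion_mode = ion_mode)
      in_block <- FALSE
    } else if (in_block) {
      if (grepl("=", ln, fixed = TRUE)) {
        kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
        hdr[[toupper(trimws(kv[1]))]] <- trimws(kv[2])
      } else {
        xs <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
        if (length(xs) < 2 || anyNA(xs[1:2]))
          stop("malformed MGF peak line at line ", i, ": '", ln, "'")
        mz <- c(mz, xs[1]); int <- c(int, xs[2])
      }
    }
    # lines outside blocks other than comments are ignored (common in MGF)
  }
  if (in_block)
    stop("malformed MGF: BEGIN IONS at line ", begin_line,
         " never closed by END IONS")
  spectra
}

#' Write fragmentation spectra to an MGF file
#'
#' @param spectra A single [spectrum()] or a list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot_spectrum(s)
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    if (!is.na(s$precursor_mz))
      writeLines(sprintf("PEPMASS=%.8f", s$precursor_mz), con)
    writeLines(paste0("CHARGE=1", if (s$ion_mode == "negative") "-" else "+"),
               con)
    if (!is.null(s$adduct)) writeLines(paste0("ADDUCT=", s$adduct), con)
    if (length(s$collision_energy) == 1 && !is.na(s$collision_energy))
      writeLines(paste0("COLLISION_ENERGY=", s$collision_energy), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.8f %.8g", s$peaks$mz, s$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read spectra from an MSP library file
#'
#' Minimal NIST-style MSP dialect: records start with `Name:`, carry
#' `PrecursorMZ:`/`Collision_energy:` style headers and `Num Peaks:`
#' followed by `mz intensity` pairs; records are blank-line separated.
#'
#' @param path Path to an MSP file.
#' @return A list of [spectrum()] objects.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- c(readLines(path, warn = FALSE), "")
  spectra <- list()
  hdr <- list(); mz <- numeric(); int <- numeric(); have <- FALSE
  flush <- function() {
    ce <- hdr[["COLLISION_ENERGY"]]
    ce <- if (is.null(ce)) NA
          else if (identical(tolower(ce), "merged")) "merged"
          else suppressWarnings(as.numeric(gsub("[^0-9.]", "", ce)))
    spectra[[length(spectra) + 1L]] <<- spectrum(
      mz, int,
      id = if (is.null(hdr[["NAME"]])) paste0("msp_", length(spectra) + 1L)
           else hdr[["NAME"]],
      precursor_mz = if (is.null(hdr[["PRECURSORMZ"]])) NA_real_
                     else as.numeric(hdr[["PRECURSORMZ"]]),
      collision_energy = ce)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") {
      if (have) { flush(); hdr <- list(); mz <- numeric(); int <- numeric()
                  have <- FALSE }
      next
    }
    if (grepl("^[A-Za-z][A-Za-z_ ]*:", ln)) {
      kv <- regmatches(ln, regexpr(":", ln, fixed = TRUE), invert = TRUE)[[1]]
      key <- toupper(gsub(" ", "_", trimws(kv[1])))
      hdr[[key]] <- trimws(kv[2])
      have <- TRUE
    } else {
      xs <- suppressWarnings(as.numeric(strsplit(ln, "[ \t;]+")[[1]]))
      xs <- xs[!is.na(xs)]
      if (length(xs) >= 2) { mz <- c(mz, xs[1]); int <- c(int, xs[2])
                             have <- TRUE }
    }
  }
  spectra
}
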