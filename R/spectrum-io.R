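#' Construct a raw spectrum
#'
#' @param mz Ascending numeric vector of peak m/z (Th).
#' @param intensity Non-negative numeric vector, same length as `mz`.
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Integer charge, or `NA` if unknown.
#' @param nce Normalized collision energy (unitless), `NA` if unknown.
#' @param analyzer `"FTMS"` or `"ITMS"`.
#' @param scan Integer scan number.
#' @param rawfile Raw-file identifier.
#' @param rt Retention time in seconds (`NA` if unknown).
#' @return Object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, precursor_mz, precursor_charge = NA_integer_,
                         nce = NA_real_, analyzer = "FTMS", scan = NA_integer_,
                         rawfile = "unknown", rt = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
    keep <- c(TRUE, diff(mz) > 0)
    mz <- mz[keep]
    intensity <- intensity[keep]
  }
  stopifnot(all(intensity >= 0))
  structure(
    list(
      mz = mz, intensity = intensity, precursor_mz = precursor_mz,
      precursor_charge = as.integer(precursor_charge), nce = nce,
      analyzer = match.arg(analyzer, c("FTMS", "ITMS")),
      scan = as.integer(scan), rawfile = rawfile, rt = rt
    ),
    class = "raw_spectrum"
  )
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat("<raw_spectrum> ", x$rawfile, " scan ", x$scan, ": ", length(x$mz),
    " peaks, precursor ", round(x$precursor_mz, 4), " (", x$precursor_charge,
    "+), NCE ", x$nce, ", ", x$analyzer, "\n",
    sep = ""
  )
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Supports the BEGIN IONS / END IONS dialect with TITLE, PEPMASS, CHARGE and
#' RTINSECONDS headers. NCE, analyzer, scan and rawfile have no standard MGF
#' slot and are carried as `key=value` tokens inside TITLE. Unparseable blocks
#' are reported via warnings, never silently dropped; a block missing CHARGE is
#' kept with unknown charge and flagged.
#'
#' @param path Path to an MGF file.
#' @param verbose Log counts at the end.
#' @return List of `raw_spectrum`.
#' @export
read_mgf <- function(path, verbose = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  spectra <- list()
  block <- NULL
  block_start <- NA_integer_
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      if (!is.null(block)) {
        stop("nested BEGIN IONS at line ", i, call. = FALSE)
      }
      block <- character()
      block_start <- i
    } else if (line == "END IONS") {
      if (is.null(block)) stop("END IONS without BEGIN at line ", i, call. = FALSE)
      sp <- parse_mgf_block(block, block_start)
      if (!is.null(sp)) spectra[[length(spectra) + 1L]] <- sp
      block <- NULL
    } else if (!is.null(block) && nzchar(line)) {
      block <- c(block, line)
    }
  }
  if (!is.null(block)) {
    stop("BEGIN IONS at line ", block_start, " never closed", call. = FALSE)
  }
  log_counts("read_mgf", length(spectra), length(spectra), verbose)
  spectra
}

parse_mgf_block <- function(block, start_line) {
  header <- grepl("=", block, fixed = TRUE)
  kv <- strsplit(block[header], "=", fixed = TRUE)
  keys <- toupper(vapply(kv, `[`, "", 1L))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(key) if (key %in% keys) vals[which(keys == key)[1]] else NA_character_

  title <- get("TITLE")
  title_tok <- if (!is.na(title)) {
    toks <- strsplit(strsplit(title, "\\s+")[[1]], "=", fixed = TRUE)
    toks <- toks[lengths(toks) == 2L]
    setNames(vapply(toks, `[`, "", 2L), vapply(toks, `[`, "", 1L))
  } else {
    character()
  }
  tfield <- function(key, default = NA_character_) {
    if (key %in% names(title_tok)) title_tok[[key]] else default
  }

  charge_raw <- get("CHARGE")
  charge <- if (is.na(charge_raw)) {
    warning("MGF block at line ", start_line,
      " has no CHARGE; charge set unknown",
      call. = FALSE
    )
    NA_integer_
  } else {
    as.integer(gsub("[^0-9]", "", charge_raw))
  }

  peaks <- block[!header]
  pm <- do.call(rbind, lapply(strsplit(peaks, "\\s+"), function(x) {
    suppressWarnings(as.numeric(x[1:2]))
  }))
  if (is.null(pm)) pm <- matrix(numeric(), ncol = 2)
  if (anyNA(pm)) {
    warning("unparseable peak line(s) in MGF block at line ", start_line,
      call. = FALSE
    )
    pm <- pm[stats::complete.cases(pm), , drop = FALSE]
  }
  raw_spectrum(
    mz = pm[, 1], intensity = pm[, 2],
    precursor_mz = suppressWarnings(as.numeric(strsplit(
      get("PEPMASS"), "\\s+"
    )[[1]][1])),
    precursor_charge = charge,
    nce = suppressWarnings(as.numeric(tfield("nce"))),
    analyzer = tfield("analyzer", "FTMS"),
    scan = suppressWarnings(as.integer(tfield("scan"))),
    rawfile = tfield("rawfile", "unknown"),
    rt = suppressWarnings(as.numeric(get("RTINSECONDS")))
  )
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: peak lists round-trip to 6 decimals.
#'
#' @param spectra List of `raw_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    title <- sprintf(
      "rawfile=%s scan=%s nce=%s analyzer=%s",
      sp$rawfile, sp$scan, sp$nce, sp$analyzer
    )
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", title),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      if (!is.na(sp$precursor_charge)) sprintf("CHARGE=%d+", sp$precursor_charge),
      if (!is.na(sp$rt)) sprintf("RTINSECONDS=%.3f", sp$rt),
      sprintf("%.6f %.6f", sp$mz, sp$intensity),
      "END IONS",
      ""
    ), con)
  }
  invisible(path)
}

#' Read a tab-separated PSM table
#'
#' Parses generic or MaxQuant-like msms.txt dialects into the package's PSM
#' tibble. Rows outside the supported domain (peptide length 7-30, precursor
#' charge < 7) are filtered out and counted; the counts are attached as the
#' `exclusions` attribute and logged.
#'
#' Mandatory columns (generic dialect): `rawfile`, `scan`, `modified_sequence`,
#' `charge`, `engine_score`; optional: `engine`, `is_decoy` (or a
#' reverse-prefix `REV_` on a `proteins` column), `retention_time` (minutes),
#' `rank`. The maxquant-like dialect maps `Raw file`, `Scan number`,
#' `Modified sequence`, `Charge`, `Score`, `Reverse`, `Retention time`.
#'
#' @param path Path to a TSV file.
#' @param dialect `"generic"` or `"maxquant"`.
#' @param verbose Log counts.
#' @return Tibble of PSM records, one row per (rawfile, scan, peptide, engine).
#' @export
read_psm_table <- function(path, dialect = c("generic", "maxquant"),
                           verbose = FALSE) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "maxquant") {
    map <- c(
      "Raw file" = "rawfile", "Scan number" = "scan",
      "Modified sequence" = "modified_sequence", "Charge" = "charge",
      "Score" = "engine_score", "Reverse" = "reverse",
      "Retention time" = "retention_time"
    )
    present <- intersect(names(map), names(df))
    df <- dplyr::rename(df, !!!setNames(present, map[present]))
    if ("reverse" %in% names(df)) {
      df$is_decoy <- !is.na(df$reverse) & df$reverse == "+"
    }
    if ("modified_sequence" %in% names(df)) {
      df$modified_sequence <- gsub("^_|_$", "", df$modified_sequence)
    }
  }
  mandatory <- c("rawfile", "scan", "modified_sequence", "charge", "engine_score")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("PSM table is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"is_decoy" %in% names(df)) {
    df$is_decoy <- if ("proteins" %in% names(df)) {
      grepl("^REV_", df$proteins)
    } else {
      FALSE
    }
  }
  if (!"engine" %in% names(df)) df$engine <- "unknown"
  if (!"retention_time" %in% names(df)) df$retention_time <- NA_real_
  if (!"rank" %in% names(df)) df$rank <- 1L

  plain <- unname(vapply(
    df$modified_sequence,
    function(s) parse_modified_sequence(s)$sequence, ""
  ))
  len <- nchar(plain)
  bad_len <- len < 7L | len > 30L
  bad_charge <- df$charge >= 7L
  keep <- !bad_len & !bad_charge
  out <- tibble::as_tibble(df[keep, c(
    "rawfile", "scan", "modified_sequence", "charge", "engine",
    "engine_score", "is_decoy", "retention_time", "rank"
  )])
  out$sequence <- plain[keep]
  attr(out, "exclusions") <- c(
    length = sum(bad_len),
    charge = sum(bad_charge & !bad_len)
  )
  log_counts("read_psm_table", nrow(df), nrow(out), verbose)
  out
}

#' Write a PSM tibble to TSV
#' @param psms PSM tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_tsv(psms, path, progress = FALSE)
  invisible(path)
}

#' Write a percolator-input (PIN) file
#'
#' Serializes one feature vector per PSM into the tab-separated PIN layout:
#' `SpecId`, `Label` (+1 target / -1 decoy), `ScanNr`, the feature columns,
#' `Peptide`, `Proteins`. Rows are ordered deterministically by
#' (rawfile, scan, peptide) so re-runs are byte-identical.
#'
#' @param psms PSM tibble (needs `rawfile`, `scan`, `modified_sequence`,
#'   `is_decoy`; `proteins` optional).
#' @param features Data frame of finite numeric features, same row count.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pin <- function(psms, features, path) {
  stopifnot(nrow(psms) == nrow(features))
  features <- tibble::as_tibble(features)
  fin <- vapply(features, is.finite, logical(nrow(features)))
  if (!all(fin)) {
    bad <- which(!fin, arr.ind = TRUE)
    stop(sprintf(
      "non-finite feature '%s' for PSM %s scan %s",
      names(features)[bad[1, 2]],
      psms$rawfile[bad[1, 1]], psms$scan[bad[1, 1]]
    ), call. = FALSE)
  }
  pin <- dplyr::bind_cols(
    tibble::tibble(
      SpecId = sprintf("%s.%d.%s", psms$rawfile, psms$scan, psms$modified_sequence),
      Label = ifelse(psms$is_decoy, -1L, 1L),
      ScanNr = psms$scan
    ),
    features,
    tibble::tibble(
      Peptide = psms$modified_sequence,
      Proteins = if ("proteins" %in% names(psms)) psms$proteins else "-"
    )
  )
  ord <- order(psms$rawfile, psms$scan, psms$modified_sequence)
  readr::write_tsv(pin[ord, ], path, progress = FALSE)
  invisible(path)
}
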