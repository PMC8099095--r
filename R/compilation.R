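#' Load a collagen d34S compilation
#'
#' Reads a tabular compilation of collagen sulfur isotope analyses into the
#' canonical record layout used by the screening and averaging steps. Required
#' columns are site, latitude, longitude and d34S; everything else (carbon and
#' nitrogen isotopes, elemental percentages and ratios, quality flags) is
#' optional and filled with `NA`/`FALSE` when absent.
#'
#' Elemental ratios follow the reporting conventions of the collagen
#' preservation literature: C/S and N/S are weight-percent ratios
#' (`pctC/pctS`, `pctN/pctS`) while C/N is atomic
#' (`(pctC/12.011)/(pctN/14.007)`). Ratios already present in the file take
#' precedence; otherwise they are derived from the percentages when possible.
#'
#' @param path path to a CSV (UTF-8, header row) or XLSX file.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`. XLSX support
#'   requires the readxl package.
#' @param columns named list mapping canonical names (`site_id`, `latitude`,
#'   `longitude`, `d34S`, and optionally `record_id`, `species`, `period`,
#'   `d13C`, `d15N`, `pctC`, `pctN`, `pctS`, `CS_ratio`, `NS_ratio`,
#'   `CN_ratio`, `diagenesis_reported`, `nonlocal_reported`,
#'   `aquatic_or_fish_consumer`, `s_only`) to the column names used in the
#'   file. Unmapped canonical names are looked up verbatim.
#' @param coords `"wgs84"` (default) validates latitude/longitude against
#'   their WGS84 ranges; `"projected"` accepts coordinates already expressed
#'   in projected units (as the synthetic world emits).
#' @return A data.frame with one row per analyzed specimen and the canonical
#'   columns above; flag columns are logical.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(site_id = "A", latitude = 48, longitude = -2,
#'                      d34S = c(10, 12, 14)), f, row.names = FALSE)
#' records <- loadCompilation(f)
#' @export
loadCompilation <- function(path, format = c("auto", "csv", "xlsx"),
                            columns = list(),
                            coords = c("wgs84", "projected")) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the 'readxl' package", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }

  canon <- c("record_id", "site_id", "latitude", "longitude", "species",
             "period", "d34S", "d13C", "d15N", "pctC", "pctN", "pctS",
             "CS_ratio", "NS_ratio", "CN_ratio", "diagenesis_reported",
             "nonlocal_reported", "aquatic_or_fish_consumer", "s_only")
  pick <- function(nm) {
    src <- if (!is.null(columns[[nm]])) columns[[nm]] else nm
    if (src %in% names(raw)) raw[[src]] else NULL
  }
  required <- c("site_id", "latitude", "longitude", "d34S")
  for (nm in required)
    if (is.null(pick(nm)))
      stop("required column missing from compilation: '", nm, "'",
           call. = FALSE)

  n <- nrow(raw)
  out <- data.frame(row.names = seq_len(n))
  for (nm in canon) {
    v <- pick(nm)
    if (is.null(v)) {
      v <- if (nm %in% c("diagenesis_reported", "nonlocal_reported",
                         "aquatic_or_fish_consumer", "s_only")) {
        rep(FALSE, n)
      } else if (nm %in% c("record_id", "site_id", "species", "period")) {
        rep(NA_character_, n)
      } else rep(NA_real_, n)
    }
    out[[nm]] <- v
  }

  numCols <- c("latitude", "longitude", "d34S", "d13C", "d15N",
               "pctC", "pctN", "pctS", "CS_ratio", "NS_ratio", "CN_ratio")
  for (nm in numCols) {
    v <- out[[nm]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop("unparseable value in column '", nm, "' at row ", bad[1L],
             ": '", v[bad[1L]], "'", call. = FALSE)
      v <- conv
    }
    out[[nm]] <- v
  }
  for (nm in c("diagenesis_reported", "nonlocal_reported",
               "aquatic_or_fish_consumer", "s_only")) {
    v <- out[[nm]]
    if (!is.logical(v)) v <- tolower(as.character(v)) %in%
        c("true", "t", "1", "yes", "y")
    v[is.na(v)] <- FALSE
    out[[nm]] <- v
  }

  if (all(is.na(out$record_id)))
    out$record_id <- sprintf("rec%04d", seq_len(n))
  out$site_id <- as.character(out$site_id)
  # fall back to coordinates rounded to 4 decimals as the site identity
  noSite <- is.na(out$site_id) | out$site_id == ""
  if (any(noSite))
    out$site_id[noSite] <- sprintf("site_%.4f_%.4f",
                                   round(out$latitude[noSite], 4),
                                   round(out$longitude[noSite], 4))

  if (coords == "wgs84") {
    badLat <- which(!is.na(out$latitude) & abs(out$latitude) > 90)
    if (length(badLat))
      stop("latitude out of [-90, 90] at row ", badLat[1L], call. = FALSE)
    badLon <- which(!is.na(out$longitude) & abs(out$longitude) > 180)
    if (length(badLon))
      stop("longitude out of [-180, 180] at row ", badLon[1L], call. = FALSE)
  }
  badVal <- which(is.na(out$d34S) | is.na(out$latitude) | is.na(out$longitude))
  if (length(badVal))
    stop("missing/unparseable site, coordinate or d34S at row ", badVal[1L],
         call. = FALSE)

  # derive weight-ratio C/S, N/S and atomic C/N from percentages when absent
  der <- is.na(out$CS_ratio) & !is.na(out$pctC) & !is.na(out$pctS)
  out$CS_ratio[der] <- out$pctC[der] / out$pctS[der]
  der <- is.na(out$NS_ratio) & !is.na(out$pctN) & !is.na(out$pctS)
  out$NS_ratio[der] <- out$pctN[der] / out$pctS[der]
  der <- is.na(out$CN_ratio) & !is.na(out$pctC) & !is.na(out$pctN)
  out$CN_ratio[der] <- (out$pctC[der] / 12.011) / (out$pctN[der] / 14.007)

  neg <- which(out$CS_ratio < 0 | out$NS_ratio < 0 | out$CN_ratio < 0)
  if (length(neg))
    stop("negative elemental ratio at row ", neg[1L], call. = FALSE)
  out
}

#' Screen compilation records for preservation and locality
#'
#' Applies the compilation quality screens: records are kept only if their
#' collagen elemental ratios satisfy C/S < `csMax` and N/S < `nsMax`
#' (strict inequalities; records carrying only sulfur data — `s_only` — are
#' exempt from the ratio screen), and none of the exclusion flags
#' (reported diagenesis/contamination, explicit non-local designation,
#' aquatic animal or fish consumer) is set.
#'
#' Every rejected record carries exactly one primary reason, evaluated in the
#' fixed order `diagenesis`, `nonlocal`, `aquatic`, `elemental-ratio`.
#' Records lacking both elemental ratios and the `s_only` flag are treated as
#' sulfur-only (kept), with a warning: the ratio screen only ever applied
#' where C/N/S data were reported.
#'
#' @param records data.frame from [loadCompilation()].
#' @param csMax,nsMax screening thresholds (defaults 300 and 100).
#' @param nonlocalKm documentation-only threshold defining "non-local"
#'   (individuals from a locality more than this far away, default 100 km);
#'   non-locality itself is consumed as the pre-annotated
#'   `nonlocal_reported` flag, never recomputed from coordinates.
#' @return A list with elements `kept` (data.frame of retained records) and
#'   `rejected` (data.frame of excluded records with a `reason` column).
#'   Together they partition the input.
#' @export
screenRecords <- function(records, csMax = 300, nsMax = 100,
                          nonlocalKm = 100) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  noRatio <- is.na(records$CS_ratio) & is.na(records$NS_ratio) &
    !records$s_only
  if (any(noRatio)) {
    warning(sum(noRatio), " record(s) lack elemental ratios and the s_only ",
            "flag; treated as sulfur-only (kept)", call. = FALSE)
  }
  exemptRatio <- records$s_only | noRatio
  ratioFail <- !exemptRatio &
    (is.na(records$CS_ratio) | records$CS_ratio >= csMax |
       is.na(records$NS_ratio) | records$NS_ratio >= nsMax)

  # fixed precedence: one primary reason per rejection
  reason[ratioFail] <- "elemental-ratio"
  reason[records$aquatic_or_fish_consumer] <- "aquatic"
  reason[records$nonlocal_reported] <- "nonlocal"
  reason[records$diagenesis_reported] <- "diagenesis"

  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Average screened records per site
#'
#' Collapses the screened compilation to one row per site: arithmetic mean of
#' d34S, sample standard deviation (n - 1 denominator; undefined for
#' single-record sites) and record count. Sites are the distinct `site_id`
#' values. If records of one site disagree on coordinates by more than
#' `coordTol` degrees a warning is issued and the coordinates are averaged.
#'
#' @param kept data.frame of screened records (the `kept` element of
#'   [screenRecords()]).
#' @param coordTol coordinate consistency tolerance in decimal degrees.
#' @return A data.frame with columns `site_id`, `latitude`, `longitude`,
#'   `mean_d34S`, `sd_d34S`, `n_records`, ordered by `site_id`.
#' @export
siteAverage <- function(kept, coordTol = 1e-4) {
  if (nrow(kept) == 0L) stop("no records to average", call. = FALSE)
  sites <- split(kept, kept$site_id)
  inconsistent <- character(0)
  rows <- lapply(sites, function(g) {
    if (nrow(g) > 1L &&
        (diff(range(g$latitude)) > coordTol ||
         diff(range(g$longitude)) > coordTol))
      inconsistent <<- c(inconsistent, g$site_id[1L])
    data.frame(site_id = g$site_id[1L],
               latitude = mean(g$latitude),
               longitude = mean(g$longitude),
               mean_d34S = mean(g$d34S),
               sd_d34S = if (nrow(g) > 1L) stats::sd(g$d34S) else NA_real_,
               n_records = nrow(g))
  })
  if (length(inconsistent))
    warning("inconsistent coordinates within site(s) ",
            paste(inconsistent, collapse = ", "), "; averaged",
            call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of a site-averaged compilation
#'
#' Computes the headline statistics of the screened, site-averaged
#' compilation: site and record counts, mean and range of the site means, and
#' mean/range of the within-site standard deviations (over multi-record sites
#' only). A Shapiro-Wilk statistic on the site means is included as a
#' normality diagnostic when the site count allows it.
#'
#' @param sites data.frame from [siteAverage()].
#' @return A list of class `CompilationSummary` with elements `n_sites`,
#'   `n_records`, `mean_of_site_means`, `min_site_mean`, `max_site_mean`,
#'   `mean_site_sd`, `min_site_sd`, `max_site_sd`, `shapiro_W`, `shapiro_p`.
#' @export
summarizeCompilation <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L)
    stop("empty site table", call. = FALSE)
  sds <- sites$sd_d34S[sites$n_records >= 2L & !is.na(sites$sd_d34S)]
  sw <- if (nrow(sites) >= 3L && nrow(sites) <= 5000L)
    stats::shapiro.test(sites$mean_d34S) else NULL
  out <- list(
    n_sites = nrow(sites),
    n_records = sum(sites$n_records),
    mean_of_site_means = mean(sites$mean_d34S),
    min_site_mean = min(sites$mean_d34S),
    max_site_mean = max(sites$mean_d34S),
    mean_site_sd = if (length(sds)) mean(sds) else NA_real_,
    min_site_sd = if (length(sds)) min(sds) else NA_real_,
    max_site_sd = if (length(sds)) max(sds) else NA_real_,
    shapiro_W = if (is.null(sw)) NA_real_ else unname(sw$statistic),
    shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value)
  class(out) <- "CompilationSummary"
  out
}

#' @export
print.CompilationSummary <- function(x, ...) {
  cat(sprintf("Compilation: %d records at %d sites\n", x$n_records, x$n_sites))
  cat(sprintf("  site means: %.2f permil on average, range [%.1f, %.1f]\n",
              x$mean_of_site_means, x$min_site_mean, x$max_site_mean))
  if (!is.na(x$mean_site_sd))
    cat(sprintf("  within-site SD: %.2f permil on average, range [%.2f, %.2f]\n",
                x$mean_site_sd, x$min_site_sd, x$max_site_sd))
  if (!is.na(x$shapiro_W))
    cat(sprintf("  Shapiro-Wilk on site means: W = %.3f, p = %.3g\n",
                x$shapiro_W, x$shapiro_p))
  invisible(x)
}
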