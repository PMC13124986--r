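# FAERS quarterly ASCII dialect: dollar-sign delimited, no quoting, one
# header row per file, dates as 8-digit YYYYMMDD integers, missing = empty
# field. Files are named <TABLE><yy>Q<q>.txt, e.g. DEMO13Q4.txt.

.faers_table_names <- c("demo", "drug", "reac", "outc", "ther")

.faers_schema <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
           "age", "age_cod", "sex", "wt", "wt_cod", "occp_cod",
           "occr_country"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt")
)

.faers_numeric_cols <- c("primaryid", "caseid", "caseversion", "age", "wt",
                         "drug_seq", "dsg_drug_seq")
.faers_date_cols <- c("fda_dt", "event_dt", "start_dt")

#' Convert 8-digit YYYYMMDD date fields to Date
#'
#' Values that are not 8 digits or not valid calendar dates become `NA`.
#'
#' @param x integer or character vector of YYYYMMDD values.
#' @return `Date` vector.
#' @export
faers_date <- function(x) {
  x <- as.character(x)
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

.quarter_suffix <- function(quarter) {
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", quarter))
  paste0(substr(quarter, 3, 4), substr(quarter, 5, 6))
}

.suffix_quarter <- function(suffix) {
  if (length(suffix) == 0) return(character(0))
  paste0("20", substr(suffix, 1, 2), substr(suffix, 3, 4))
}

#' Write tables in the FAERS quarterly ASCII dialect
#'
#' Each table must carry a `quarter` column (`"2013Q4"` style); one file per
#' table per quarter is written. The dialect has no quoting mechanism, so a
#' field containing the `$` delimiter is rejected.
#'
#' @param tables named list with elements `demo`, `drug`, `reac`, `outc`,
#'   `ther`, each a data.frame conforming to the FAERS column schema.
#' @param dir output directory (created if needed).
#' @param quarters quarters to emit files for; default those present in
#'   the data. Must be given explicitly for empty tables (which then get
#'   valid header-only files).
#' @return invisibly, the character vector of files written.
#' @export
write_faers_ascii <- function(tables, dir, quarters = NULL) {
  stopifnot(all(.faers_table_names %in% names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(quarters)) {
    quarters <- sort(unique(unlist(lapply(
      tables[.faers_table_names],
      function(x) unique(as.character(x$quarter))))))
  }
  if (length(quarters) == 0) {
    stop("tables carry no 'quarter' values; pass quarters explicitly")
  }
  paths <- character(0)
  for (tab in .faers_table_names) {
    x <- as.data.table(tables[[tab]])
    cols <- .faers_schema[[tab]]
    missing_cols <- setdiff(c(cols, "quarter"), names(x))
    if (length(missing_cols)) {
      stop("table '", tab, "' lacks columns: ",
           paste(missing_cols, collapse = ", "))
    }
    for (q in quarters) {
      xq <- x[x$quarter == q, cols, with = FALSE]
      out <- xq[, lapply(.SD, function(col) {
        col <- as.character(col)
        col[is.na(col)] <- ""
        col
      })]
      if (any(vapply(out, function(col) any(grepl("$", col, fixed = TRUE)),
                     logical(1)))) {
        stop("field value contains the '$' delimiter; ",
             "the FAERS ASCII dialect has no quoting")
      }
      path <- file.path(dir, paste0(toupper(tab), .quarter_suffix(q), ".txt"))
      lines <- c(paste(cols, collapse = "$"),
                 if (nrow(out)) do.call(paste, c(unname(as.list(out)),
                                                 sep = "$")))
      writeLines(lines, path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Read FAERS quarterly ASCII tables
#'
#' Reads the five table files (`DEMO`, `DRUG`, `REAC`, `OUTC`, `THER`) for
#' every requested quarter and stacks them with a `quarter` column.
#' Malformed dates are set missing with a warning (the row is retained);
#' missing mandatory files raise an error that names them.
#'
#' @param dir directory holding the quarterly files.
#' @param quarters optional character vector (`"2013Q4"` style) restricting
#'   the quarters read; default all quarters found in `dir`.
#' @return named list of `data.table`s (`demo`, `drug`, `reac`, `outc`,
#'   `ther`) with an attribute `ingest_log`: rows read per file and counts
#'   of malformed date fields.
#' @export
read_faers_ascii <- function(dir, quarters = NULL) {
  if (!dir.exists(dir)) stop("input directory does not exist: ", dir)
  files <- list.files(dir, pattern = "^(DEMO|DRUG|REAC|OUTC|THER)[0-9]{2}Q[1-4]\\.txt$")
  found_q <- sort(unique(.suffix_quarter(sub("^[A-Z]{4}", "", sub("\\.txt$", "", files)))))
  if (is.null(quarters)) quarters <- found_q
  if (length(quarters) == 0) {
    stop("no FAERS quarterly files found in ", dir,
         "; expected files like DEMO13Q4.txt, DRUG13Q4.txt, REAC13Q4.txt, ",
         "OUTC13Q4.txt, THER13Q4.txt")
  }
  expected <- as.vector(outer(toupper(.faers_table_names),
                              vapply(quarters, .quarter_suffix, ""),
                              function(t, q) paste0(t, q, ".txt")))
  absent <- setdiff(expected, files)
  if (length(absent)) {
    stop("missing mandatory FAERS table file(s): ",
         paste(absent, collapse = ", "))
  }
  log <- list(files = character(0), rows = integer(0),
              bad_dates = integer(0))
  out <- list()
  for (tab in .faers_table_names) {
    pieces <- vector("list", length(quarters))
    for (i in seq_along(quarters)) {
      q <- quarters[i]
      path <- file.path(dir, paste0(toupper(tab), .quarter_suffix(q), ".txt"))
      x <- fread(path, sep = "$", header = TRUE, colClasses = "character",
                 quote = "", fill = TRUE, na.strings = NULL)
      bad <- 0L
      for (col in intersect(.faers_date_cols, names(x))) {
        v <- x[[col]]
        nonempty <- nzchar(v)
        ok <- !nonempty | (!is.na(faers_date(v)))
        bad <- bad + sum(!ok)
        v[!ok | !nonempty] <- NA_character_
        set(x, j = col, value = suppressWarnings(as.integer(v)))
      }
      if (bad > 0) {
        warning(bad, " malformed date field(s) in ", basename(path),
                " set missing; rows retained")
      }
      for (col in intersect(.faers_numeric_cols, names(x))) {
        set(x, j = col, value = suppressWarnings(as.numeric(x[[col]])))
      }
      for (col in setdiff(names(x), c(.faers_date_cols, .faers_numeric_cols))) {
        v <- x[[col]]
        v[!nzchar(v)] <- NA_character_
        set(x, j = col, value = v)
      }
      x[, quarter := q]
      log$files <- c(log$files, basename(path))
      log$rows <- c(log$rows, nrow(x))
      log$bad_dates <- c(log$bad_dates, bad)
      pieces[[i]] <- x
    }
    out[[tab]] <- rbindlist(pieces, use.names = TRUE)
  }
  attr(out, "ingest_log") <- log
  out
}
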