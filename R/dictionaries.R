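#' Bundled dictionaries
#'
#' The package ships three small plain-text dictionaries used by the
#' synthetic generator, the examples and the test-suite:
#'
#' * a miniature synthetic PT-to-SOC map (30 preferred terms in 5 system
#'   organ classes). MedDRA itself is licensed and cannot be redistributed,
#'   so real analyses must supply their own two-column map via
#'   [read_pt_soc_map()]; this synthetic stand-in exists so that every
#'   pipeline stage can be exercised without it.
#' * the seven suicide-related preferred terms used for subgroup labelling.
#' * the six trade/laboratory synonyms under which vortioxetine appears in
#'   spontaneous-report drug tables.
#'
#' @return `pv_example_pt_soc()` a `data.table` with columns `pt`, `soc`;
#'   `pv_suicide_pts()` and `pv_vortioxetine_synonyms()` character vectors.
#' @export
pv_example_pt_soc <- function() {
  read_pt_soc_map(system.file("extdata", "pt_soc_synthetic.tsv",
                              package = "pvsignal", mustWork = TRUE))
}

#' @rdname pv_example_pt_soc
#' @export
pv_suicide_pts <- function() {
  read_term_list(system.file("extdata", "suicide_pts.txt",
                             package = "pvsignal", mustWork = TRUE))
}

#' @rdname pv_example_pt_soc
#' @export
pv_vortioxetine_synonyms <- function() {
  read_term_list(system.file("extdata", "vortioxetine_synonyms.txt",
                             package = "pvsignal", mustWork = TRUE))
}

#' Read a preferred-term to system-organ-class map
#'
#' Reads a two-column tab-separated file (`pt`, `soc`) such as an export of
#' the MedDRA PT-to-primary-SOC assignment. Matching elsewhere in the
#' package is case-insensitive after whitespace normalization.
#'
#' @param path path to a 2-column TSV with a header row.
#' @return `data.table` with character columns `pt` and `soc`.
#' @export
read_pt_soc_map <- function(path) {
  map <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               quote = "")
  if (!all(c("pt", "soc") %in% names(map))) {
    stop("PT->SOC map must have columns 'pt' and 'soc': ", path)
  }
  map[, c("pt", "soc")]
}

#' Read a one-term-per-line list (drug synonyms, PT lists)
#'
#' @param path path to a plain-text file, one term per line; blank lines and
#'   lines starting with `#` are ignored.
#' @return character vector of terms.
#' @export
read_term_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Normalize free-text terms for dictionary matching
#'
#' Case-folds, trims, and collapses internal whitespace so that
#' `"VORTIOXETINE  HBR "` and `"Vortioxetine hbr"` compare equal. Matching
#' throughout the package is exact-after-normalization, never substring.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  toupper(gsub("\\s+", " ", trimws(x)))
}

#' Map preferred terms to system organ classes
#'
#' Unmapped PTs are routed to the sentinel SOC `"UNMAPPED"` so that no
#' event silently disappears from a SOC-level analysis; callers can inspect
#' the returned vector for that sentinel.
#'
#' @param pts character vector of preferred terms.
#' @param pt_soc map as returned by [read_pt_soc_map()].
#' @param warn warn when any PT is unmapped (default `TRUE`).
#' @return character vector of SOC names, same length as `pts`.
#' @export
map_pt_to_soc <- function(pts, pt_soc, warn = TRUE) {
  lookup <- setNames(pt_soc$soc, normalize_term(pt_soc$pt))
  soc <- unname(lookup[normalize_term(pts)])
  miss <- is.na(soc)
  if (any(miss)) {
    if (warn) {
      warning(sum(miss), " reaction rows with PTs outside the PT->SOC map ",
              "routed to SOC 'UNMAPPED' (e.g. ",
              paste(head(unique(pts[miss]), 3), collapse = ", "), ")")
    }
    soc[miss] <- "UNMAPPED"
  }
  soc
}
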