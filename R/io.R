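# Dataset round-tripping: NONMEM-style flat tables with columns
# ID, TIME, DV, TRT, BMMS (one row per observation).

#' Write a cohort to a flat table
#'
#' Comma-delimited with header \code{ID,TIME,DV,TRT,BMMS}; numeric fields
#' are written with full (round-trippable) precision. Generator truth
#' records are not written (they exist only for generated cohorts).
#'
#' @param cohort a \code{trt_cohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "trt_cohort"))
  d <- cohort$data
  out <- data.table::data.table(
    ID = d$ID,
    TIME = sprintf("%.17g", d$TIME),
    DV = sprintf("%.17g", d$DV),
    TRT = as.integer(d$TRT),
    BMMS = sprintf("%.17g", d$BMMS))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read a cohort from a flat table
#'
#' Accepts comma- or whitespace-delimited files with a header containing
#' (case-insensitively, in any order) ID, TIME, DV, TRT, BMMS. Subjects are
#' grouped by ID preserving the row order within each subject.
#'
#' @param path input file path.
#' @return a \code{trt_cohort} (no truth record; provenance "file").
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- data.table::fread(path, header = TRUE)
  names(d) <- toupper(names(d))
  need <- c("ID", "TIME", "DV", "TRT", "BMMS")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  d <- as.data.frame(d)[, need]
  for (col in c("TIME", "DV", "TRT", "BMMS")) {
    v <- d[[col]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stopf("non-numeric value '%s' in column %s at data row %d",
              v[bad[1]], col, bad[1])
      }
      d[[col]] <- vn
    }
    if (anyNA(d[[col]])) {
      stopf("missing value in column %s at data row %d", col,
            which(is.na(d[[col]]))[1])
    }
  }
  badtrt <- which(!d$TRT %in% c(0, 1))
  if (length(badtrt)) {
    stopf("invalid TRT value %s at data row %d (must be 0 or 1)",
          format(d$TRT[badtrt[1]]), badtrt[1])
  }
  key <- paste(d$ID, d$TIME, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("duplicate (ID, TIME) row: ID=%s TIME=%s at data row %d",
          format(d$ID[dup[1]]), format(d$TIME[dup[1]]), dup[1])
  }
  trt_by_id <- tapply(d$TRT, d$ID, function(x) length(unique(x)))
  if (any(trt_by_id > 1)) {
    stopf("TRT must be constant within subject (ID=%s)",
          names(trt_by_id)[which(trt_by_id > 1)[1]])
  }
  d$TRT <- as.integer(d$TRT)
  allocated <- any(d$TRT == 1)
  new_cohort(d, truth = NULL,
             meta = list(provenance = "file", allocated = allocated,
                         path = path))
}
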