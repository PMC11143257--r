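#' Read a PLUMED-style HILLS log
#'
#' Whitespace-delimited columns: time, two collective-variable values, two
#' Gaussian widths, hill height and bias factor. A `#! FIELDS` header fixes
#' column meanings when present; otherwise positional order is assumed.
#' Time is converted from ps to ns at parse time; heights are kJ/mol.
#'
#' @param path path to the hills file.
#' @return data.frame of class `hills_log` with columns `time` (ns), `cv1`,
#'   `cv2`, `sigma1`, `sigma2`, `height`, `biasf`.
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop("hills file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(trimws(lines), "#") | !nzchar(trimws(lines))
  cols <- c("time", "cv1", "cv2", "sigma1", "sigma2", "height", "biasf")
  header <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  col_map <- seq_along(cols)
  if (length(header)) {
    fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", header[1])), "\\s+")[[1]]
    fields <- tolower(fields)
    # map PLUMED conventions onto our names
    canon <- fields
    canon[grepl("^sigma", fields)] <- paste0("sigma", cumsum(grepl("^sigma", fields))[grepl("^sigma", fields)])
    canon[fields %in% c("biasf", "biasfactor")] <- "biasf"
    cv_cols <- which(!fields %in% c("time", "height", "biasf", "biasfactor") &
                       !grepl("^sigma", fields))
    canon[cv_cols] <- paste0("cv", seq_along(cv_cols))
    col_map <- match(cols, canon)
    if (anyNA(col_map)) stop("hills header in ", path,
                             " lacks required fields: ",
                             paste(cols[is.na(col_map)], collapse = ", "))
  }
  data_lines <- which(!is_comment)
  if (!length(data_lines)) stop("no data records in hills file ", path)
  recs <- strsplit(trimws(lines[data_lines]), "\\s+")
  mat <- matrix(NA_real_, length(recs), length(cols))
  for (i in seq_along(recs)) {
    v <- suppressWarnings(as.numeric(recs[[i]][col_map]))
    if (anyNA(v)) {
      stop("non-numeric field in hills file ", path, " line ", data_lines[i])
    }
    mat[i, ] <- v
  }
  out <- as.data.frame(mat)
  names(out) <- cols
  out$time <- out$time / 1000  # ps -> ns
  validate_hills(out, path)
  class(out) <- c("hills_log", "data.frame")
  out
}

validate_hills <- function(h, path = "<hills>") {
  if (any(h$height < 0)) stop("negative hill height in ", path)
  if (any(h$sigma1 <= 0 | h$sigma2 <= 0)) stop("non-positive sigma in ", path)
  if (any(h$biasf <= 1)) stop("bias factor must exceed 1 in ", path)
  if (is.unsorted(h$time)) stop("hill times must be nondecreasing in ", path)
  invisible(h)
}

#' Write a hills log in PLUMED layout
#'
#' Inverse of [read_hills()]: times are written in ps with a `#! FIELDS`
#' header, so write-then-read round-trips.
#'
#' @param hills a `hills_log` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf", con)
  writeLines(sprintf("%.6f %.8f %.8f %.8f %.8f %.8f %.4f",
                     hills$time * 1000, hills$cv1, hills$cv2,
                     hills$sigma1, hills$sigma2, hills$height, hills$biasf),
             con)
  invisible(path)
}
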