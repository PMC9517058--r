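# PLUMED-dialect HILLS bookkeeping and file I/O.

new_hills_log <- function(df, bias_factor, hill_height0, periodic, lo, hi,
                          cv_name = "cv", potential = NULL,
                          temperature = default_temperature, run_id = NULL) {
  stopifnot(all(c("time", "center", "sigma", "height") %in% names(df)))
  if (nrow(df) > 1 && any(diff(df$time) <= 0))
    stop("hill times must be strictly increasing")
  if (any(df$height > hill_height0 + 1e-9))
    stop("hill heights cannot exceed the initial height")
  structure(df, class = c("hills_log", "data.frame"),
            bias_factor = bias_factor, hill_height0 = hill_height0,
            periodic = periodic, lo = lo, hi = hi, cv_name = cv_name,
            potential = potential, temperature = temperature,
            run_id = run_id)
}

#' @export
print.hills_log <- function(x, ...) {
  cat(sprintf("<hills_log: %d hills on '%s', bias factor %g>\n",
              nrow(x), attr(x, "cv_name"), attr(x, "bias_factor")))
  invisible(x)
}

#' Write / read a HILLS file (PLUMED dialect)
#'
#' The header is the bit-exact grammar
#' `#! FIELDS time <cv> sigma_<cv> height biasf`; rows are
#' whitespace-separated numbers, comment lines (`#`) are skipped on read.
#' Round-trips are lossless to 12 significant digits.
#'
#' @param hills A `hills_log`.
#' @param path File path.
#' @return `read_hills()` returns a `hills_log`. Domain attributes
#'   (`periodic`, `lo`, `hi`) default to a periodic dihedral domain on read
#'   and can be overridden.
#' @param periodic,lo,hi Domain context attached on read (the file format
#'   itself does not carry it).
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hills_log"))
  cv <- attr(hills, "cv_name")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#! FIELDS time %s sigma_%s height biasf", cv, cv), con)
  bf <- attr(hills, "bias_factor")
  writeLines(sprintf("%.12g %.12g %.12g %.12g %.12g",
                     hills$time, hills$center, hills$sigma, hills$height,
                     rep(bf, nrow(hills))), con)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path, periodic = TRUE, lo = -pi, hi = pi) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^#! FIELDS ", lines[1]))
    stop("malformed HILLS header at line 1: expected '#! FIELDS ...'")
  fields <- strsplit(sub("^#! FIELDS ", "", lines[1]), "\\s+")[[1]]
  if (length(fields) != 5 || fields[1] != "time" ||
      !identical(fields[3], paste0("sigma_", fields[2])) ||
      fields[4] != "height" || fields[5] != "biasf")
    stop(sprintf("malformed HILLS header at line 1: fields '%s'",
                 paste(fields, collapse = " ")))
  body <- lines[-1]
  keep <- !grepl("^\\s*#", body) & nzchar(trimws(body))
  body <- body[keep]
  rowno <- which(keep) + 1
  if (length(body) == 0) {
    df <- data.frame(time = numeric(0), center = numeric(0),
                     sigma = numeric(0), height = numeric(0))
    return(new_hills_log(df, bias_factor = NA_real_, hill_height0 = Inf,
                         periodic = periodic, lo = lo, hi = hi,
                         cv_name = fields[2]))
  }
  parts <- strsplit(trimws(body), "\\s+")
  nc <- lengths(parts)
  if (any(nc != 5))
    stop(sprintf("ragged HILLS row at line %d: %d fields (expected 5)",
                 rowno[which(nc != 5)[1]], nc[nc != 5][1]))
  m <- matrix(as.numeric(unlist(parts)), ncol = 5, byrow = TRUE)
  if (anyNA(m))
    stop(sprintf("non-numeric HILLS value at line %d",
                 rowno[which(rowSums(is.na(m)) > 0)[1]]))
  df <- data.frame(time = m[, 1], center = m[, 2], sigma = m[, 3],
                   height = m[, 4])
  new_hills_log(df, bias_factor = m[1, 5], hill_height0 = max(df$height),
                periodic = periodic, lo = lo, hi = hi, cv_name = fields[2])
}

#' Write / read a COLVAR file (PLUMED dialect)
#'
#' Two-column `time <cv>` trace of a trajectory, same header grammar as
#' HILLS.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @return `read_colvar()` returns a data.frame with `time` and the CV
#'   column.
#' @export
write_colvar <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  cv <- traj$potential$kind
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#! FIELDS time %s", cv), con)
  writeLines(sprintf("%.12g %.12g", traj$times, traj$cv), con)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^#! FIELDS ", lines[1]))
    stop("malformed COLVAR header at line 1")
  fields <- strsplit(sub("^#! FIELDS ", "", lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              ncol = length(fields), byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- fields
  df
}
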