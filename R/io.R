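#' Read a perceived/expected matrix pair from wide CSV files
#'
#' Each file is a square table: the header row and first column carry the
#' agency identifiers, cells are integer ratings or empty for missing, and
#' the diagonal must be empty (agencies do not rate themselves). The agency
#' order is taken from the perceived file; the expected file must carry the
#' same labels in the same order.
#'
#' @param perceived_path,expected_path paths to the two CSV files
#' @param bounds inclusive rating-scale bounds, default `c(1, 5)`
#' @return a validated [rating_pair()]
#' @export
read_matrix_pair <- function(perceived_path, expected_path, bounds = c(1L, 5L)) {
  p <- read_wide_matrix(perceived_path)
  e <- read_wide_matrix(expected_path)
  if (!identical(dim(p), dim(e)))
    stop(sprintf("dimension mismatch: perceived is %dx%d, expected is %dx%d",
                 nrow(p), ncol(p), nrow(e), ncol(e)), call. = FALSE)
  if (!identical(rownames(p), rownames(e)) || !identical(colnames(p), colnames(e)))
    stop("agency labels differ between the perceived and expected files", call. = FALSE)
  rating_pair(p, e, bounds = bounds)
}

read_wide_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop(sprintf("%s: not a wide rating matrix", path), call. = FALSE)
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop(sprintf("%s: matrix is not square (%d rows, %d columns)",
                 path, nrow(m), ncol(m)), call. = FALSE)
  if (!identical(ids, colnames(m)))
    stop(sprintf("%s: row labels do not match column labels", path), call. = FALSE)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = list(ids, ids))
  cells <- trimws(m)
  filled <- !is.na(cells) & cells != ""
  if (any(filled & row(m) == col(m)))
    stop(sprintf("%s: non-empty diagonal cell (malformed export)", path), call. = FALSE)
  vals <- suppressWarnings(as.numeric(cells[filled]))
  if (anyNA(vals) || any(vals != round(vals)))
    stop(sprintf("%s: non-integer cell value", path), call. = FALSE)
  out[filled] <- vals
  out
}

#' Write a matrix pair to wide CSV files
#'
#' Produces files that [read_matrix_pair()] reconstructs exactly, including
#' the missingness pattern: missing and diagonal cells are written as empty
#' strings.
#'
#' @param pair a [rating_pair()]
#' @param perceived_path,expected_path output paths
#' @return invisibly, the two paths
#' @export
write_matrix_pair <- function(pair, perceived_path, expected_path) {
  write_wide_matrix(pair$perceived, perceived_path)
  write_wide_matrix(pair$expected, expected_path)
  invisible(c(perceived_path, expected_path))
}

write_wide_matrix <- function(m, path) {
  chr <- ifelse(is.na(m), "", format(m, trim = TRUE, scientific = FALSE))
  df <- data.frame(agency = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("agency", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read per-representative ratings from a long CSV
#'
#' Long format: one row per representative per directed pair, with columns
#' `respondent`, `partner`, `representative`, `perceived`, `expected`.
#' Agencies with several representatives contribute several rows per pair;
#' [collapse_representatives()] averages them.
#'
#' @param path CSV path
#' @param bounds inclusive rating-scale bounds
#' @return a data.frame of validated records
#' @export
read_representative_records <- function(path, bounds = c(1L, 5L)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent", "partner", "representative", "perceived", "expected")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("long CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$respondent <- as.character(df$respondent)
  df$partner <- as.character(df$partner)
  validate_records(df, bounds)
  df[need]
}

validate_records <- function(records, bounds) {
  if (any(records$respondent == records$partner))
    stop("a representative record rates an agency's involvement with itself",
         call. = FALSE)
  for (nm in c("perceived", "expected")) {
    v <- records[[nm]]
    if (anyNA(v) || !is.numeric(v))
      stop(sprintf("non-numeric or missing %s rating in records", nm), call. = FALSE)
    if (any(v < bounds[1] | v > bounds[2]))
      stop(sprintf("%s rating outside [%g, %g]", nm, bounds[1], bounds[2]),
           call. = FALSE)
  }
  invisible(records)
}

#' Collapse per-representative ratings into a rating matrix pair
#'
#' When an agency fields more than one representative, the ratings from all
#' representatives for each directed pair are averaged and rounded to the
#' nearest integer. Ties at .5 round half away from zero by default (so a
#' mean of 3.5 stores 4); set `ties = "even"` for banker's rounding. The
#' averaged rating of respondent `r` about partner `p` is stored at cell
#' `[p, r]` (column = respondent's self-ratings).
#'
#' @param records a data.frame as returned by [read_representative_records()]
#' @param agencies optional closed set of agency ids fixing matrix order;
#'   defaults to the sorted union of ids seen in the records
#' @param bounds inclusive rating-scale bounds
#' @param ties `"away"` (default, half away from zero) or `"even"`
#' @return a [rating_pair()]; directed pairs with no records are missing
#' @export
collapse_representatives <- function(records, agencies = NULL,
                                     bounds = c(1L, 5L),
                                     ties = c("away", "even")) {
  ties <- match.arg(ties)
  validate_records(records, bounds)
  if (is.null(agencies))
    agencies <- sort(unique(c(records$respondent, records$partner)))
  agencies <- as.character(agencies)
  unknown <- setdiff(unique(c(records$respondent, records$partner)), agencies)
  if (length(unknown))
    stop("records reference agencies outside the closed set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(agencies)
  p <- e <- matrix(NA_real_, n, n, dimnames = list(agencies, agencies))
  key <- interaction(records$respondent, records$partner, drop = TRUE)
  for (k in levels(key)) {
    sub <- records[key == k, , drop = FALSE]
    i <- match(sub$partner[1], agencies)   # row = rated agency
    j <- match(sub$respondent[1], agencies) # column = responding agency
    p[i, j] <- round_rating(mean(sub$perceived), ties)
    e[i, j] <- round_rating(mean(sub$expected), ties)
  }
  rating_pair(p, e, agencies = agencies, bounds = bounds)
}

round_rating <- function(x, ties = "away") {
  if (ties == "even") return(round(x))
  sign(x) * floor(abs(x) + 0.5)
}
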