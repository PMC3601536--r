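#' Paired perceived/expected rating matrices for a service network
#'
#' The central data structure: two square agency-by-agency matrices holding
#' involvement ratings on an ordinal scale (1-5 by default). Cell
#' `[i, j]` (for `i != j`) is agency `j`'s rating of its involvement with
#' agency `i`, so each *column* holds one agency's self-ratings on every
#' partner and each *row* holds the group's ratings on one agency. Diagonal
#' cells (self-with-self) are undefined and always `NA`. An agency that
#' returned no ratings (a non-respondent) has an entirely empty column in
#' both matrices but may still be rated by others along its row.
#'
#' @param perceived,expected square numeric matrices of identical dimension,
#'   with matching agency identifiers as both row and column names. Entries
#'   are integers within `bounds` or `NA` for missing; the diagonal must be
#'   `NA`.
#' @param agencies optional character vector of agency identifiers; defaults
#'   to the dimnames of `perceived`. Must be unique.
#' @param bounds length-2 integer vector giving the inclusive rating-scale
#'   bounds. The instrument is a 5-point scale, hence `c(1, 5)`, but the
#'   bounds are configurable for variants coded e.g. 0-4.
#' @return an object of class `rating_pair`: a list with elements
#'   `agencies`, `perceived`, `expected`, `respondent` (logical per agency:
#'   does its column contain any rating in either matrix?) and `bounds`.
#' @examples
#' m <- matrix(NA_real_, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' p <- e <- m
#' p[2, 1] <- 3; e[2, 1] <- 3  # A rates its involvement with B
#' pair <- rating_pair(p, e)
#' respondents(pair)
#' @export
rating_pair <- function(perceived, expected, agencies = NULL, bounds = c(1L, 5L)) {
  perceived <- as.matrix(perceived)
  expected <- as.matrix(expected)
  storage.mode(perceived) <- "double"
  storage.mode(expected) <- "double"
  if (is.null(agencies)) {
    agencies <- rownames(perceived)
    if (is.null(agencies)) agencies <- colnames(perceived)
  }
  agencies <- as.character(agencies)
  n <- length(agencies)
  if (n < 2L) stop("a network needs at least 2 agencies", call. = FALSE)
  if (anyDuplicated(agencies)) stop("agency identifiers must be unique", call. = FALSE)
  for (m in list(perceived, expected)) {
    if (nrow(m) != n || ncol(m) != n)
      stop(sprintf("rating matrices must be %d x %d", n, n), call. = FALSE)
  }
  dimnames(perceived) <- dimnames(expected) <- list(agencies, agencies)
  obj <- structure(
    list(
      agencies = agencies,
      perceived = perceived,
      expected = expected,
      respondent = logical(n),
      bounds = as.numeric(bounds)
    ),
    class = "rating_pair"
  )
  obj$respondent <- derive_respondents(obj)
  validate_rating_pair(obj)
  obj
}

derive_respondents <- function(x) {
  has_p <- colSums(!is.na(x$perceived)) > 0
  has_e <- colSums(!is.na(x$expected)) > 0
  stats::setNames(has_p | has_e, x$agencies)
}

#' Validate a rating_pair's structural invariants
#'
#' Checks squareness, matching dimensions and labels, an all-`NA` diagonal,
#' integer ratings within the configured scale bounds, and respondent flags
#' consistent with column completeness. Called by [rating_pair()]; exported
#' so callers that assemble objects by hand can re-check them.
#'
#' @param x a `rating_pair`
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_rating_pair <- function(x) {
  n <- length(x$agencies)
  for (nm in c("perceived", "expected")) {
    m <- x[[nm]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop(sprintf("%s matrix must be %d x %d", nm, n, n), call. = FALSE)
    if (!identical(rownames(m), x$agencies) || !identical(colnames(m), x$agencies))
      stop(sprintf("%s matrix dimnames must equal the agency list", nm), call. = FALSE)
    if (any(!is.na(diag(m))))
      stop(sprintf("diagonal of the %s matrix must be empty (no self-rating)", nm),
           call. = FALSE)
    vals <- m[!is.na(m)]
    if (any(vals != round(vals)))
      stop(sprintf("%s matrix contains non-integer ratings", nm), call. = FALSE)
    if (any(vals < x$bounds[1] | vals > x$bounds[2]))
      stop(sprintf("%s matrix contains ratings outside [%g, %g]",
                   nm, x$bounds[1], x$bounds[2]), call. = FALSE)
  }
  if (!identical(unname(x$respondent), unname(derive_respondents(x))))
    stop("respondent flags inconsistent with column completeness", call. = FALSE)
  invisible(x)
}

#' @export
print.rating_pair <- function(x, ...) {
  n <- length(x$agencies)
  cat(sprintf("rating_pair: %d agencies, %d respondents, scale [%g, %g]\n",
              n, sum(x$respondent), x$bounds[1], x$bounds[2]))
  filled <- sum(!is.na(x$perceived)) + sum(!is.na(x$expected))
  cat(sprintf("  %d of %d off-diagonal cells rated\n", filled, 2 * n * (n - 1)))
  invisible(x)
}

#' Number of agencies in a network
#' @param pair a `rating_pair`
#' @return integer count
#' @export
n_agencies <- function(pair) length(pair$agencies)

#' Respondent flags
#'
#' An agency counts as a respondent when its column contains at least one
#' rating in either matrix; non-respondents are still rated by others along
#' their row, so they can receive a group-vs-group (P1) score but none of
#' the self-rating perspectives.
#'
#' @param pair a `rating_pair`
#' @return named logical vector over agencies
#' @export
respondents <- function(pair) pair$respondent
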