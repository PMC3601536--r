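#' Four-perspective integration scores for one agency
#'
#' An agency's integration with the network is the fraction of complete
#' perceived/expected rating pairs that agree exactly. For agency X with
#' partner j, writing `P[i, j]` for cell `[i, j]` of the perceived matrix
#' and `E[i, j]` likewise, the four perspectives pair the ratings as:
#'
#' * P1 (group-perceived vs group-expected): `(P[X, j], E[X, j])`
#' * P2 (self-perceived vs group-expected):  `(P[j, X], E[X, j])`
#' * P3 (group-perceived vs self-expected):  `(P[X, j], E[j, X])`
#' * P4 (self-perceived vs self-expected):   `(P[j, X], E[j, X])`
#'
#' A pair with either member missing enters neither the numerator nor the
#' denominator (pairwise deletion), so a non-respondent — whose column is
#' empty — has no defined P2, P3, or P4, while P1 can still be computed
#' from the group's ratings along its row.
#'
#' @param pair a [rating_pair()]
#' @param agency one agency identifier present in the network
#' @param tolerance non-negative integer; ratings differing by at most this
#'   amount count as agreeing. The default 0 is exact ordinal equality — no
#'   partial credit for adjacent categories.
#' @return an object of class `agency_score_set`: a list with `agency` and
#'   elements `p1`..`p4`, each a list of `agreed`, `valid` and `score`
#'   (`agreed/valid`, or `NA` when no complete pair exists).
#' @examples
#' pair <- simulate_network(synth_config(n_agencies = 5, seed = 1))
#' agency_scores(pair, pair$agencies[1])
#' @export
agency_scores <- function(pair, agency, tolerance = 0) {
  i <- match(as.character(agency), pair$agencies)
  if (is.na(i)) stop("unknown agency id: ", agency, call. = FALSE)
  idx <- setdiff(seq_along(pair$agencies), i)
  gp <- pair$perceived[i, idx]  # group's perceived ratings on X (row)
  ge <- pair$expected[i, idx]   # group's expected ratings on X
  sp <- pair$perceived[idx, i]  # X's own perceived ratings (column)
  se <- pair$expected[idx, i]   # X's own expected ratings
  structure(
    list(
      agency = pair$agencies[i],
      p1 = agreement(gp, ge, tolerance),
      p2 = agreement(sp, ge, tolerance),
      p3 = agreement(gp, se, tolerance),
      p4 = agreement(sp, se, tolerance)
    ),
    class = "agency_score_set"
  )
}

agreement <- function(a, b, tolerance = 0) {
  ok <- !is.na(a) & !is.na(b)
  valid <- sum(ok)
  agreed <- sum(abs(a[ok] - b[ok]) <= tolerance)
  list(agreed = agreed, valid = valid,
       score = if (valid > 0) agreed / valid else NA_real_)
}

#' @export
print.agency_score_set <- function(x, ...) {
  cat(sprintf("integration scores for agency %s\n", x$agency))
  for (p in c("p1", "p2", "p3", "p4")) {
    s <- x[[p]]
    cat(sprintf("  %s: %s (%d/%d pairs)\n", toupper(p),
                if (is.na(s$score)) "undefined" else sprintf("%.1f%%", 100 * s$score),
                s$agreed, s$valid))
  }
  invisible(x)
}

#' Integration score table for every agency
#'
#' Applies [agency_scores()] to each agency in network order and lays the
#' results out one row per agency, with the score fractions, the
#' agreed/valid pair counts behind each, and the respondent flag.
#' Undefined scores (no complete pair, e.g. P2-P4 for non-respondents)
#' are `NA`.
#'
#' @inheritParams agency_scores
#' @return a data.frame with columns `agency`, `respondent`, `p1`..`p4`
#'   (fractions in `[0, 1]` or `NA`), and `p<k>_agreed` / `p<k>_valid`
#'   count columns.
#' @export
score_table <- function(pair, tolerance = 0) {
  rows <- lapply(pair$agencies, function(a) {
    s <- agency_scores(pair, a, tolerance)
    out <- data.frame(agency = s$agency,
                      respondent = unname(pair$respondent[a]),
                      stringsAsFactors = FALSE)
    for (p in c("p1", "p2", "p3", "p4")) {
      out[[p]] <- s[[p]]$score
      out[[paste0(p, "_agreed")]] <- s[[p]]$agreed
      out[[paste0(p, "_valid")]] <- s[[p]]$valid
    }
    out
  })
  do.call(rbind, rows)
}

#' Write a score table as CSV with percentage formatting
#'
#' Scores are written as whole-number percentages (rounded half away from
#' zero, display only — internal values stay fractions); undefined scores
#' become empty cells.
#'
#' @param tab a data.frame from [score_table()]
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_score_table <- function(tab, path) {
  out <- data.frame(agency = tab$agency,
                    respondent = tab$respondent,
                    stringsAsFactors = FALSE)
  for (p in c("p1", "p2", "p3", "p4")) {
    out[[paste0(p, "_pct")]] <- round_rating(100 * tab[[p]])
    out[[paste0(p, "_valid")]] <- tab[[paste0(p, "_valid")]]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

new_global_estimate <- function(perspective, method, estimate, low, high,
                                interval_kind, n, replicates = NA_integer_,
                                seed = NA_integer_) {
  structure(
    list(perspective = perspective, method = method,
         estimate = clip01(estimate),
         interval = c(low = clip01(low), high = clip01(high)),
         interval_kind = interval_kind, n = n,
         replicates = replicates, seed = seed),
    class = "global_estimate"
  )
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' @export
print.global_estimate <- function(x, ...) {
  cat(sprintf("global integration score (%s, %s): %.1f%% [%s %.1f%%, %.1f%%], n = %d\n",
              if (is.na(x$perspective)) "?" else x$perspective, x$method,
              100 * x$estimate, x$interval_kind,
              100 * x$interval[1], 100 * x$interval[2], x$n))
  invisible(x)
}

#' Global integration score as the plain mean of agency scores
#'
#' The network-level score for one perspective is the average of the
#' defined agency scores; graphically it is the filled fraction of the
#' integration-area diagram. The confidence interval is the normal
#' approximation `mean +/- z * sd/sqrt(n)`, clipped to the unit interval.
#'
#' @param scores numeric vector of defined agency scores (fractions); `NA`s
#'   are rejected — drop undefined scores before calling.
#' @param confidence confidence level, default 0.95
#' @param perspective optional label ("P1".."P4") carried into the result
#' @return a `global_estimate` with `method = "mean"`
#' @export
global_mean <- function(scores, confidence = 0.95, perspective = NA_character_) {
  scores <- check_scores(scores)
  n <- length(scores)
  est <- mean(scores)
  if (n >= 2) {
    z <- stats::qnorm((1 + confidence) / 2)
    half <- z * stats::sd(scores) / sqrt(n)
  } else {
    half <- NA_real_
  }
  new_global_estimate(perspective, "mean", est, est - half, est + half,
                      "normal", n)
}

check_scores <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0) stop("no defined scores", call. = FALSE)
  if (anyNA(scores)) stop("scores contain NA; drop undefined scores first",
                          call. = FALSE)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  scores
}

#' Inverse-variance-weighted global integration score
#'
#' Each agency's score is weighted by the inverse of its estimated
#' variance, so agencies whose scores rest on more complete rating pairs
#' (and less extreme proportions) contribute more. The variance of score
#' `s_i = agreed_i / valid_i` is estimated as `pt_i (1 - pt_i) / valid_i`
#' with the shrunken proportion `pt_i = (agreed_i + 0.5) / (valid_i + 1)`;
#' the shrinkage only enters the weight — never the score itself — and
#' keeps weights finite when a score is exactly 0 or 1. The interval is
#' `estimate +/- z * sqrt(1 / sum(w))`, clipped to the unit interval.
#'
#' @param agreed,valid integer vectors of agreeing and complete pair counts
#'   per agency; every `valid` must be >= 1.
#' @inheritParams global_mean
#' @return a `global_estimate` with `method = "weighted"`
#' @export
global_weighted <- function(agreed, valid, confidence = 0.95,
                            perspective = NA_character_) {
  if (length(agreed) != length(valid) || length(valid) == 0)
    stop("agreed and valid must be non-empty vectors of equal length", call. = FALSE)
  if (any(valid < 1)) stop("every agency needs at least one complete pair",
                           call. = FALSE)
  if (any(agreed < 0 | agreed > valid))
    stop("agreed counts must satisfy 0 <= agreed <= valid", call. = FALSE)
  s <- agreed / valid
  pt <- (agreed + 0.5) / (valid + 1)
  w <- 1 / (pt * (1 - pt) / valid)
  est <- sum(w * s) / sum(w)
  z <- stats::qnorm((1 + confidence) / 2)
  half <- z * sqrt(1 / sum(w))
  new_global_estimate(perspective, "weighted", est, est - half, est + half,
                      "normal", length(s))
}
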