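#' Configuration for the synthetic network generator
#'
#' Describes a generative model for a service network with a known
#' agreement structure, so every estimator in the package can be validated
#' against analytic truth without any survey data. Two models:
#'
#' * **independent**: every off-diagonal cell gets an expected rating drawn
#'   from `rating_distribution`; with probability `agreement_prob` the
#'   perceived rating equals it, otherwise the perceived rating is uniform
#'   over the remaining 4 categories. Cells are independent of one another,
#'   so `agreement_prob` is exactly the expected P1 and P4 score.
#' * **consensus**: each unordered agency pair shares one latent true
#'   rating drawn from `rating_distribution`; each of the four cell values
#'   touching that pair (perceived/expected for both directions) reports
#'   the latent value with probability `1 - consensus_noise`, otherwise a
#'   uniform other category. All four perspectives then share the same
#'   expected agreement.
#'
#' Finally each agency is independently marked non-respondent with
#' probability `1 - response_rate` and its column blanked in both matrices
#' — emulating survey non-response, under which only the group-vs-group
#' perspective survives. The response rates observed in the motivating
#' networks (0.89 and 0.64) are natural presets.
#'
#' @param n_agencies number of agencies (>= 2)
#' @param rating_distribution probability vector over the 5 rating
#'   categories; default uniform
#' @param agreement_prob probability that a perceived rating equals its
#'   same-cell expected rating (independent model)
#' @param response_rate probability that an agency responds, in `(0, 1]`
#' @param model `"independent"` or `"consensus"`
#' @param consensus_noise per-report probability of deviating from the
#'   latent pair-level rating (consensus model only)
#' @param seed integer seed; the same seed reproduces the same network
#' @return a `synth_config` list
#' @export
synth_config <- function(n_agencies = 30,
                         rating_distribution = rep(0.2, 5),
                         agreement_prob = 0.6,
                         response_rate = 1,
                         model = c("independent", "consensus"),
                         consensus_noise = 0.1,
                         seed = NULL) {
  model <- match.arg(model)
  if (n_agencies < 2) stop("n_agencies must be at least 2", call. = FALSE)
  p <- as.numeric(rating_distribution)
  if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("rating_distribution must be 5 non-negative probabilities summing to 1",
         call. = FALSE)
  if (agreement_prob < 0 || agreement_prob > 1)
    stop("agreement_prob must lie in [0, 1]", call. = FALSE)
  if (response_rate <= 0 || response_rate > 1)
    stop("response_rate must lie in (0, 1]", call. = FALSE)
  if (consensus_noise < 0 || consensus_noise > 1)
    stop("consensus_noise must lie in [0, 1]", call. = FALSE)
  structure(
    list(n_agencies = as.integer(n_agencies), rating_distribution = p,
         agreement_prob = agreement_prob, response_rate = response_rate,
         model = model, consensus_noise = consensus_noise, seed = seed),
    class = "synth_config"
  )
}

draw_other <- function(value, k = 5) {
  # uniform over the k-1 categories != value (not distance-weighted)
  offset <- sample.int(k - 1, length(value), replace = TRUE)
  ((value - 1 + offset) %% k) + 1
}

#' Generate a synthetic rating network
#'
#' Draws a [rating_pair()] from the generative model described by a
#' [synth_config()]. Agency identifiers are `A01`, `A02`, ...
#'
#' @param config a `synth_config`
#' @return a [rating_pair()]
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_agencies
  ids <- sprintf("A%02d", seq_len(n))
  perceived <- expected <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  off <- which(row(perceived) != col(perceived))
  m <- length(off)
  if (config$model == "independent") {
    e <- sample.int(5, m, replace = TRUE, prob = config$rating_distribution)
    agree <- stats::runif(m) < config$agreement_prob
    p <- e
    p[!agree] <- draw_other(e[!agree])
    expected[off] <- e
    perceived[off] <- p
  } else {
    nu <- config$consensus_noise
    pairs <- which(upper.tri(perceived), arr.ind = TRUE)
    latent <- sample.int(5, nrow(pairs), replace = TRUE,
                         prob = config$rating_distribution)
    channel <- function(l) {
      out <- l
      flip <- stats::runif(length(l)) < nu
      out[flip] <- draw_other(l[flip])
      out
    }
    for (mat in c("perceived", "expected")) {
      m1 <- get(mat)
      m1[pairs] <- channel(latent)                 # cell [i, j], i < j
      m1[pairs[, c(2, 1), drop = FALSE]] <- channel(latent)  # cell [j, i]
      assign(mat, m1)
    }
  }
  non_resp <- stats::runif(n) >= config$response_rate
  perceived[, non_resp] <- NA_real_
  expected[, non_resp] <- NA_real_
  rating_pair(perceived, expected, agencies = ids)
}

#' Analytic expected integration scores under a synthetic model
#'
#' Computes the exact expected per-pair agreement probability for each
#' perspective by enumerating the generative joint distribution over the
#' 5 x 5 category lattice (no simulation).
#'
#' Independent model: P1 and P4 pair a perceived and an expected rating
#' from the *same* cell, whose joint distribution has `agreement_prob` on
#' the diagonal — so both equal `agreement_prob` for any rating
#' distribution. P2 and P3 pair ratings from two *different* (independent)
#' cells, so their agreement is the cross-product of the perceived
#' marginal `q` and the expected marginal (the rating distribution `p`):
#' `sum_k q_k p_k`, with `q_k = theta p_k + (1 - theta)(1 - p_k)/4`.
#'
#' Consensus model: every perspective pairs two independent noisy reports
#' of the same latent rating, so all four share
#' `sum_l p_l * sum_k C(l,k)^2` with channel
#' `C(l, k) = 1 - nu` if `k = l`, else `nu/4`.
#'
#' @param config a `synth_config`
#' @return named numeric vector `c(p1, p2, p3, p4)` of expected fractions
#' @export
expected_scores <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  p <- config$rating_distribution
  if (config$model == "independent") {
    theta <- config$agreement_prob
    # joint over one cell: P(expected = b, perceived = a)
    joint <- outer(1:5, 1:5, function(a, b) {
      ifelse(a == b, theta, (1 - theta) / 4)
    }) * rep(p, each = 5)  # row a = perceived, col b = expected, weight p_b
    same_cell <- sum(diag(joint))
    q <- rowSums(joint)  # perceived marginal
    cross <- sum(q * p)
    c(p1 = same_cell, p2 = cross, p3 = cross, p4 = same_cell)
  } else {
    nu <- config$consensus_noise
    channel <- matrix(nu / 4, 5, 5)
    diag(channel) <- 1 - nu
    agree <- sum(p * rowSums(channel^2))
    c(p1 = agree, p2 = agree, p3 = agree, p4 = agree)
  }
}
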