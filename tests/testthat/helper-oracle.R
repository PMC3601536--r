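# Brute-force scoring oracle: materialises every (perspective, partner)
# rating pair with explicit loops and counts equalities. Kept deliberately
# independent of the vectorised implementation in the package.
oracle_scores <- function(pair, agency, tolerance = 0) {
  X <- match(agency, pair$agencies)
  out <- list()
  for (persp in c("p1", "p2", "p3", "p4")) {
    agreed <- 0L
    valid <- 0L
    for (j in seq_along(pair$agencies)) {
      if (j == X) next
      a <- switch(persp,
                  p1 = pair$perceived[X, j], p2 = pair$perceived[j, X],
                  p3 = pair$perceived[X, j], p4 = pair$perceived[j, X])
      b <- switch(persp,
                  p1 = pair$expected[X, j], p2 = pair$expected[X, j],
                  p3 = pair$expected[j, X], p4 = pair$expected[j, X])
      if (!is.na(a) && !is.na(b)) {
        valid <- valid + 1L
        if (abs(a - b) <= tolerance) agreed <- agreed + 1L
      }
    }
    out[[persp]] <- list(agreed = agreed, valid = valid,
                         score = if (valid > 0) agreed / valid else NA_real_)
  }
  out
}

# Random small network with cell-level missingness and possibly whole
# non-respondent columns; used for property-style checks.
random_pair <- function(n, cell_miss = 0.2, nonresp_prob = 0.2) {
  ids <- paste0("G", seq_len(n))
  p <- e <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  off <- which(row(p) != col(p))
  p[off] <- sample(1:5, length(off), replace = TRUE)
  e[off] <- sample(1:5, length(off), replace = TRUE)
  drop_p <- off[runif(length(off)) < cell_miss]
  drop_e <- off[runif(length(off)) < cell_miss]
  p[drop_p] <- NA_real_
  e[drop_e] <- NA_real_
  blank <- runif(n) < nonresp_prob
  p[, blank] <- NA_real_
  e[, blank] <- NA_real_
  rating_pair(p, e, agencies = ids)
}

# The illustrative 4-agency network: agency A's own perceived ratings are
# (1,1,1) and expected (1,2,3); the group perceives A at (2,3,4) but
# expects (1,1,1). Remaining cells among B, C, D are filled with a
# constant so only A's scores are of interest.
worked_example_pair <- function() {
  ids <- c("A", "B", "C", "D")
  p <- e <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  p[2:4, 1] <- c(1, 1, 1)
  e[2:4, 1] <- c(1, 2, 3)
  p[1, 2:4] <- c(2, 3, 4)
  e[1, 2:4] <- c(1, 1, 1)
  for (i in 2:4) for (j in 2:4) if (i != j) {
    p[i, j] <- 3
    e[i, j] <- 3
  }
  rating_pair(p, e, agencies = ids)
}

# Network in which a stated fraction of the raters' group-perceived ratings
# on one focal agency equal their group-expected ratings; only the focal
# agency's row is populated, so it is a pure P1 construction.
fraction_agree_pair <- function(n_raters, n_agree) {
  ids <- c("X", paste0("R", seq_len(n_raters)))
  n <- length(ids)
  p <- e <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  e[1, -1] <- 3
  p[1, -1] <- c(rep(3, n_agree), rep(4, n_raters - n_agree))
  rating_pair(p, e, agencies = ids)
}
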