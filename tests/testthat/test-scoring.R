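test_that("the illustrative 4-agency network yields the four hand-enumerated scores", {
  pair <- worked_example_pair()
  s <- agency_scores(pair, "A")
  expect_equal(s$p1$score, 0)        # (2,1) (3,1) (4,1): no agreement
  expect_equal(s$p2$score, 1)        # (1,1) (1,1) (1,1): full agreement
  expect_equal(s$p3$score, 0)        # (2,1) (3,2) (4,3)
  expect_equal(s$p4$score, 1 / 3)    # (1,1) (1,2) (1,3)
  expect_identical(c(s$p1$valid, s$p2$valid, s$p3$valid, s$p4$valid),
                   rep(3L, 4))
  # and the brute-force oracle agrees pair-for-pair
  o <- oracle_scores(pair, "A")
  for (p in c("p1", "p2", "p3", "p4")) expect_equal(s[[p]], o[[p]])
})

test_that("a stated fraction of agreeing raters is returned verbatim as the P1 score", {
  pair <- fraction_agree_pair(n_raters = 10, n_agree = 8)
  s <- agency_scores(pair, "X")
  expect_identical(s$p1$agreed, 8L)
  expect_identical(s$p1$valid, 10L)
  expect_equal(s$p1$score, 0.8)
})

test_that("identical perceived and expected matrices give 100% on the same-cell perspectives", {
  # P1 and P4 pair a perceived with an expected rating from the same cell,
  # so they hit 100% whenever the two matrices coincide. P2 and P3 pair
  # cell [j, X] with cell [X, j]; they reach 100% too once the shared
  # matrix is also symmetric (both directions of a dyad rated alike).
  set.seed(202)
  for (rep in 1:10) {
    pair <- random_pair(sample(3:7, 1))
    pair2 <- rating_pair(pair$perceived, pair$perceived, pair$agencies)
    tab <- score_table(pair2)
    for (p in c("p1", "p4")) {
      defined <- !is.na(tab[[p]])
      expect_true(all(tab[[p]][defined] == 1))
    }
  }
  ids <- paste0("S", 1:5)
  m <- matrix(NA_real_, 5, 5, dimnames = list(ids, ids))
  off <- which(row(m) != col(m))
  m[off] <- sample(1:5, length(off), TRUE)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]  # symmetrise
  tab <- score_table(rating_pair(m, m, ids))
  for (p in c("p1", "p2", "p3", "p4")) expect_true(all(tab[[p]] == 1))
})

test_that("scores match the brute-force pair-enumeration oracle on random networks", {
  set.seed(303)
  for (rep in 1:40) {
    pair <- random_pair(sample(3:6, 1))
    tol <- sample(0:1, 1)
    for (a in pair$agencies) {
      got <- agency_scores(pair, a, tolerance = tol)
      want <- oracle_scores(pair, a, tolerance = tol)
      for (p in c("p1", "p2", "p3", "p4")) {
        expect_identical(got[[p]]$agreed, as.integer(want[[p]]$agreed))
        expect_identical(got[[p]]$valid, as.integer(want[[p]]$valid))
        expect_equal(got[[p]]$score, want[[p]]$score)
      }
    }
  }
})

test_that("agreed and valid are well-formed counts and scores sit in [0, 1]", {
  set.seed(17)
  pair <- random_pair(6)
  tab <- score_table(pair)
  n <- n_agencies(pair)
  for (p in c("p1", "p2", "p3", "p4")) {
    agreed <- tab[[paste0(p, "_agreed")]]
    valid <- tab[[paste0(p, "_valid")]]
    expect_true(all(agreed >= 0 & agreed <= valid & valid <= n - 1))
    defined <- !is.na(tab[[p]])
    expect_true(all(tab[[p]][defined] >= 0 & tab[[p]][defined] <= 1))
    expect_equal(tab[[p]][defined], (agreed / valid)[defined])
  }
})

test_that("relabeling agencies permutes rows but changes no score", {
  set.seed(404)
  pair <- random_pair(6, nonresp_prob = 0)
  perm <- sample(6)
  relab <- rating_pair(pair$perceived[perm, perm], pair$expected[perm, perm],
                       agencies = pair$agencies[perm])
  t1 <- score_table(pair)
  t2 <- score_table(relab)
  reordered <- t2[match(t1$agency, t2$agency), ]
  rownames(reordered) <- NULL
  expect_equal(reordered, t1)
  # global estimates are invariant too
  g1 <- global_mean(t1$p1[!is.na(t1$p1)])
  g2 <- global_mean(t2$p1[!is.na(t2$p1)])
  expect_equal(g1$estimate, g2$estimate)
  expect_equal(g1$interval, g2$interval)
})

test_that("non-respondents get a P1 score but no self-rating perspectives", {
  ids <- c("A", "B", "C", "D")
  p <- e <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  off <- which(row(p) != col(p))
  set.seed(5)
  p[off] <- sample(1:5, length(off), TRUE)
  e[off] <- sample(1:5, length(off), TRUE)
  p[, 4] <- NA; e[, 4] <- NA  # D returned nothing
  pair <- rating_pair(p, e)
  tab <- score_table(pair)
  drow <- tab[tab$agency == "D", ]
  expect_false(drow$respondent)
  expect_false(is.na(drow$p1))
  expect_true(is.na(drow$p2) && is.na(drow$p3) && is.na(drow$p4))
})

test_that("unknown agency ids are rejected", {
  pair <- worked_example_pair()
  expect_error(agency_scores(pair, "Z"), "unknown agency")
})

test_that("the plain-mean global estimate is the arithmetic mean with a normal interval", {
  expect_equal(global_mean(c(0.4, 0.6))$estimate, 0.5)
  # degenerate variance: zero-width interval
  g <- global_mean(rep(0.7, 5))
  expect_equal(unname(g$interval), c(0.7, 0.7))
  # direct-summation oracle on simulated scores
  set.seed(6)
  s <- runif(30)
  g <- global_mean(s, confidence = 0.95)
  expect_equal(g$estimate, sum(s) / 30)
  half <- qnorm(0.975) * sd(s) / sqrt(30)
  expect_equal(unname(g$interval), c(mean(s) - half, mean(s) + half))
  expect_true(is.na(global_mean(0.5)$interval[1]))  # one score: no interval
  expect_error(global_mean(c(0.2, NA)), "NA")
  expect_error(global_mean(numeric(0)), "no defined scores")
})

test_that("the inverse-variance-weighted mean honours precision and degenerates correctly", {
  # identical (agreed, valid) counts: weights cancel, equals the plain mean
  g <- global_weighted(agreed = c(3, 3, 3), valid = c(9, 9, 9))
  expect_equal(g$estimate, 1 / 3)
  # equal scores with unequal counts still give the shared score
  expect_equal(global_weighted(c(5, 1), c(10, 2))$estimate, 0.5)
  # hand-computed: precise low score pulls the estimate below the midpoint
  agreed <- c(10, 4); valid <- c(50, 5)
  pt <- (agreed + 0.5) / (valid + 1)
  w <- valid / (pt * (1 - pt))
  expect_equal(global_weighted(agreed, valid)$estimate,
               sum(w * agreed / valid) / sum(w))
  expect_lt(global_weighted(agreed, valid)$estimate, 0.5)
  # a score of exactly 0 or 1 keeps a finite weight via shrinkage
  expect_true(is.finite(global_weighted(c(0, 9), c(9, 9))$estimate))
  expect_error(global_weighted(c(1), c(0)), "at least one")
  expect_error(global_weighted(c(5), c(3)), "agreed <= valid")
})

test_that("weighted and unweighted estimators coincide when all counts are identical", {
  set.seed(9)
  for (rep in 1:5) {
    agreed <- rep(sample(0:8, 1), 6)
    valid <- rep(9L, 6)
    expect_equal(global_weighted(agreed, valid)$estimate,
                 global_mean(agreed / valid)$estimate)
  }
})

test_that("an agreement tolerance grants credit to adjacent categories", {
  ids <- c("A", "B", "C")
  p <- e <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  p[1, 2:3] <- c(2, 5); e[1, 2:3] <- c(3, 1)
  pair <- rating_pair(p, e)
  expect_equal(agency_scores(pair, "A")$p1$score, 0)
  expect_equal(agency_scores(pair, "A", tolerance = 1)$p1$score, 0.5)
})
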