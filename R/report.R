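PERSPECTIVES <- c("P1", "P2", "P3", "P4")
METHODS <- c("mean", "weighted", "boot_standard", "boot_balanced", "boot_bayes")

#' Global integration scores for every perspective and method
#'
#' Assembles the network-level summary: for each requested perspective the
#' defined agency scores are pooled (for P1 that is every agency with a
#' defined score, respondent or not; for P2-P4 only respondents have
#' defined scores, so the pooling is complete-case by construction) and
#' each requested estimator is applied.
#'
#' Bootstrap estimators are seeded deterministically from `seed` with a
#' distinct offset per perspective-method cell, so a fixed `seed`
#' reproduces the whole table bit-identically.
#'
#' @param pair a [rating_pair()]
#' @param perspectives subset of `"P1".."P4"`
#' @param methods subset of `"mean"`, `"weighted"`, `"boot_standard"`,
#'   `"boot_balanced"`, `"boot_bayes"`
#' @param B bootstrap replicates (bootstrap methods only)
#' @param confidence interval level
#' @param seed base integer seed for the bootstrap methods
#' @param tolerance agreement tolerance passed to [score_table()]
#' @return a data.frame with one row per perspective x method:
#'   `perspective`, `method`, `estimate`, `low`, `high`, `interval_kind`,
#'   `n`, `B`, `seed` (estimates and interval endpoints as fractions).
#' @export
global_table <- function(pair, perspectives = PERSPECTIVES, methods = METHODS,
                         B = 40000, confidence = 0.95, seed = 1,
                         tolerance = 0) {
  perspectives <- match.arg(perspectives, PERSPECTIVES, several.ok = TRUE)
  methods <- match.arg(methods, METHODS, several.ok = TRUE)
  tab <- score_table(pair, tolerance)
  rows <- list()
  for (pi in seq_along(perspectives)) {
    persp <- perspectives[pi]
    col <- tolower(persp)
    keep <- !is.na(tab[[col]])
    scores <- tab[[col]][keep]
    for (mi in seq_along(methods)) {
      meth <- methods[mi]
      cell_seed <- seed + 101L * (match(persp, PERSPECTIVES) - 1L) +
        match(meth, METHODS)
      est <- switch(
        meth,
        mean = global_mean(scores, confidence, persp),
        weighted = global_weighted(tab[[paste0(col, "_agreed")]][keep],
                                   tab[[paste0(col, "_valid")]][keep],
                                   confidence, persp),
        boot_standard = as_global_estimate(
          bootstrap_standard(scores, B, confidence, cell_seed), persp),
        boot_balanced = as_global_estimate(
          bootstrap_balanced(scores, B, confidence, cell_seed), persp),
        boot_bayes = as_global_estimate(
          bootstrap_bayes(scores, B, confidence, cell_seed), persp)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        perspective = persp, method = meth,
        estimate = est$estimate, low = est$interval[1], high = est$interval[2],
        interval_kind = est$interval_kind, n = est$n,
        B = est$replicates, seed = est$seed,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a global score table to CSV or JSON
#'
#' CSV and JSON carry percentages at one-decimal precision (`estimate_pct`,
#' `ci_low_pct`, `ci_high_pct`) alongside `n`, `replicates` and `seed`.
#'
#' @param gt a data.frame from [global_table()]
#' @param path output path; format chosen by extension (`.json` or CSV)
#' @return invisibly, `path`
#' @export
write_global_table <- function(gt, path) {
  out <- data.frame(
    perspective = gt$perspective, method = gt$method,
    estimate_pct = round(100 * gt$estimate, 1),
    ci_low_pct = round(100 * gt$low, 1),
    ci_high_pct = round(100 * gt$high, 1),
    interval_kind = gt$interval_kind,
    n = gt$n, replicates = gt$B, seed = gt$seed,
    stringsAsFactors = FALSE
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Polygon coordinates for a spider (radar) plot
#'
#' Places the four perspectives on orthogonal axes (P1 up, P2 right, P3
#' down, P4 left) at radius equal to the score. Undefined scores yield no
#' vertex, leaving a gap in the polygon. Plots are views of the scores:
#' the radii returned here are exactly the score fractions.
#'
#' @param score_set an `agency_score_set` from [agency_scores()]
#' @return data.frame with `perspective`, `score`, `x`, `y` (defined
#'   scores only)
#' @export
spider_coords <- function(score_set) {
  stopifnot(inherits(score_set, "agency_score_set"))
  angles <- c(p1 = pi / 2, p2 = 0, p3 = -pi / 2, p4 = pi)
  s <- vapply(c("p1", "p2", "p3", "p4"), function(p) score_set[[p]]$score,
              numeric(1))
  keep <- !is.na(s)
  data.frame(
    perspective = toupper(names(s))[keep],
    score = unname(s[keep]),
    x = unname(s[keep] * cos(angles[keep])),
    y = unname(s[keep] * sin(angles[keep])),
    stringsAsFactors = FALSE
  )
}

#' Spider plot of one agency's four integration scores
#'
#' A radar chart with one axis per perspective, radial range 0-100%. An
#' agency at 100% on every perspective draws the complete diamond; any
#' dent marks imperfect integration from that viewpoint.
#'
#' @param score_set an `agency_score_set`
#' @param out_path optional file path (png/svg/pdf); when given the figure
#'   is saved there and the path returned invisibly
#' @return the ggplot object (or invisibly `out_path` when saving)
#' @export
spider_plot <- function(score_set, out_path = NULL) {
  coords <- spider_coords(score_set)
  if (nrow(coords) == 0) stop("no defined scores to plot", call. = FALSE)
  grid_r <- c(0.25, 0.5, 0.75, 1)
  circle <- data.frame(
    r = rep(grid_r, each = 5),
    angle = rep(c(pi / 2, 0, -pi / 2, pi, pi / 2), times = length(grid_r))
  )
  circle$x <- circle$r * cos(circle$angle)
  circle$y <- circle$r * sin(circle$angle)
  axis_lab <- data.frame(
    perspective = c("P1", "P2", "P3", "P4"),
    x = c(0, 1.15, 0, -1.15), y = c(1.15, 0, -1.15, 0)
  )
  gg <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circle, ggplot2::aes(group = .data$r),
                       colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(data = axis_lab, ggplot2::aes(label = .data$perspective),
                       size = 3.5) +
    ggplot2::coord_equal(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(sprintf("Agency %s", score_set$agency))
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, gg, width = 4, height = 4, dpi = 150)
    return(invisible(out_path))
  }
  gg
}

#' Step profile underlying the integration-area diagram
#'
#' Agencies are sorted by score (decreasing) and given equal widths on the
#' unit horizontal axis; each gets a rectangle of height equal to its
#' score. The filled fraction of the unit box is then exactly the
#' arithmetic mean of the scores — the global integration score — and the
#' blank remainder is the integration gap.
#'
#' @param scores numeric vector of defined agency scores (fractions)
#' @return data.frame with `xmin`, `xmax`, `height` per agency (sorted),
#'   carrying the filled fraction in attribute `"filled_fraction"`
#' @export
area_profile <- function(scores) {
  scores <- check_scores(scores)
  s <- sort(scores, decreasing = TRUE)
  n <- length(s)
  out <- data.frame(
    xmin = (seq_len(n) - 1) / n,
    xmax = seq_len(n) / n,
    height = s
  )
  attr(out, "filled_fraction") <- sum((out$xmax - out$xmin) * out$height)
  out
}

#' Integration-area diagram for one perspective
#'
#' Draws the sorted score profile as a filled step area inside the unit
#' box: the shaded area equals the mean agency score (the global
#' integration score) and the blank area above it depicts the gap to full
#' integration.
#'
#' @param scores numeric vector of defined agency scores (fractions)
#' @param out_path optional file path; when given the figure is saved and
#'   the path returned invisibly
#' @param perspective optional label used in the title
#' @return the ggplot object (or invisibly `out_path` when saving)
#' @export
integration_area_plot <- function(scores, out_path = NULL,
                                  perspective = NULL) {
  prof <- area_profile(scores)
  filled <- attr(prof, "filled_fraction")
  title <- sprintf("%sglobal integration %.1f%%",
                   if (is.null(perspective)) "" else paste0(perspective, ": "),
                   100 * filled)
  gg <- ggplot2::ggplot(prof) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = 0, ymax = .data$height),
                       fill = "steelblue", alpha = 0.6) +
    ggplot2::annotate("rect", xmin = 0, xmax = 1, ymin = 0, ymax = 1,
                      fill = NA, colour = "grey30") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "agencies (sorted by score)", y = "integration score",
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, gg, width = 5, height = 4, dpi = 150)
    return(invisible(out_path))
  }
  gg
}
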