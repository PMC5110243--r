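#' Mitotic phase durations from event-annotated tracks
#'
#' Computes per-track phase durations from the six ordered event times:
#' prophase = congression start - prophase start; prometaphase = plate
#' formation - congression start; metaphase = anaphase onset - plate
#' formation; anaphase = telophase start - anaphase onset; telophase =
#' interphase restored - telophase start. `prometa_meta` is prometaphase +
#' metaphase and `total` the sum of all phases, so cumulative sums of the
#' output reproduce the event times exactly.
#'
#' @param tracks data.frame of tracks as produced by [gen_mitosis_tracks()]
#'   (columns `cell_id`, `group`, `t_prophase_start`, `t_congression_start`,
#'   `t_plate_formed`, `t_anaphase_onset`, `t_telophase_start`,
#'   `t_interphase_restored`).
#' @return data.frame with `cell_id`, `group` and the seven duration columns
#'   (minutes).
#' @export
phase_durations <- function(tracks) {
  ev_cols <- c("t_prophase_start", "t_congression_start", "t_plate_formed",
               "t_anaphase_onset", "t_telophase_start", "t_interphase_restored")
  missing <- setdiff(ev_cols, names(tracks))
  if (length(missing)) stop("missing event column: ", missing[1])
  ev <- as.matrix(tracks[, ev_cols])
  if (any(ev < 0)) stop("event times must be >= 0")
  for (k in seq_len(length(ev_cols) - 1)) {
    bad <- which(ev[, k + 1] < ev[, k] - 1e-9)
    if (length(bad)) {
      stop(sprintf("track %s: %s (%.3f) precedes %s (%.3f)",
                   tracks$cell_id[bad[1]], ev_cols[k + 1], ev[bad[1], k + 1],
                   ev_cols[k], ev[bad[1], k]))
    }
  }
  d <- ev[, -1, drop = FALSE] - ev[, -ncol(ev), drop = FALSE]
  data.frame(
    cell_id = tracks$cell_id,
    group = tracks$group,
    prophase = d[, 1],
    prometaphase = d[, 2],
    metaphase = d[, 3],
    prometa_meta = d[, 2] + d[, 3],
    anaphase = d[, 4],
    telophase = d[, 5],
    total = ev[, 6] - ev[, 1],
    stringsAsFactors = FALSE
  )
}

# tie-corrected Dunn post-hoc z-tests on rank means
dunn_test <- function(x, g, method = "none") {
  g <- droplevels(factor(g))
  r <- rank(x)
  N <- length(x)
  tt <- table(r)
  sigma2 <- (N * (N + 1) / 12) - sum(tt^3 - tt) / (12 * (N - 1))
  rb <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    se <- sqrt(sigma2 * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- (rb[[i]] - rb[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(
    group_i = pairs[1, ], group_j = pairs[2, ], z = z,
    p_value = stats::p.adjust(p, method = method),
    stringsAsFactors = FALSE
  )
}

#' Compare a phase duration between groups
#'
#' Two groups: two-sided Mann-Whitney U test (exact when sample sizes permit
#' and there are no ties). Three or more: Kruskal-Wallis ANOVA followed by
#' Dunn's pairwise post-hoc test (unadjusted by default; set `p_adjust`).
#' Groups with fewer than 3 observations are excluded with a warning.
#' Significance is declared at p < 0.05.
#'
#' @param durations data.frame from [phase_durations()] (or any data.frame
#'   with the phase column and a group column).
#' @param phase Column to compare (e.g. `"prometa_meta"`).
#' @param group_col Grouping column (default `"group"`).
#' @param p_adjust Multiplicity adjustment for Dunn's test
#'   (a [stats::p.adjust()] method; default `"none"`).
#' @return A `group_comparison` list: `test`, `statistic`, `p_value`,
#'   `significant`, `summary` (n, mean, sem, median per group), and for >= 3
#'   groups a `pairwise` Dunn table.
#' @export
compare_groups <- function(durations, phase, group_col = "group",
                           p_adjust = "none") {
  if (!phase %in% names(durations)) stop("unknown phase column: ", phase)
  x <- durations[[phase]]
  g <- factor(durations[[group_col]])
  sizes <- table(g)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("groups with < 3 observations excluded: ", paste(small, collapse = ", "))
    keep <- !(g %in% small)
    x <- x[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop("need >= 2 groups with >= 3 observations")
  summ <- do.call(rbind, lapply(levels(g), function(lv) {
    xi <- x[g == lv]
    data.frame(group = lv, n = length(xi), mean = mean(xi),
               sem = stats::sd(xi) / sqrt(length(xi)), median = stats::median(xi),
               stringsAsFactors = FALSE)
  }))
  if (nlevels(g) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(x ~ g, exact = NULL))
    res <- list(test = "Mann-Whitney U", statistic = unname(wt$statistic),
                p_value = wt$p.value, significant = wt$p.value < 0.05,
                summary = summ, pairwise = NULL, phase = phase)
  } else {
    kw <- stats::kruskal.test(x ~ g)
    pw <- dunn_test(x, g, method = p_adjust)
    pw$significant <- pw$p_value < 0.05
    res <- list(test = "Kruskal-Wallis + Dunn", statistic = unname(kw$statistic),
                p_value = kw$p.value, significant = kw$p.value < 0.05,
                summary = summ, pairwise = pw, phase = phase)
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s on '%s': statistic = %.4g, p = %.4g%s\n", x$test, x$phase,
              x$statistic, x$p_value, if (x$significant) " (significant)" else ""))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Dunn pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Maximal range of spindle orientations during metaphase
#'
#' The maximal range of chromosome-plate orientations between metaphase-plate
#' formation and anaphase onset: max angle - min angle over the samples in
#' the window (inclusive bounds, nearest-frame; no sub-frame interpolation).
#'
#' @param track An `OrientationTrack` (see [gen_orientation_tracks()]).
#' @return Range in degrees.
#' @export
orientation_range <- function(track) {
  s <- track$samples
  inw <- s$time_min >= track$t_plate_formed - 1e-9 &
    s$time_min <= track$t_anaphase_onset + 1e-9
  if (!any(inw)) stop("no orientation samples between plate formation and anaphase onset")
  max(s$angle_deg[inw]) - min(s$angle_deg[inw])
}

#' Chromosome-plate angle at a fixed offset after anaphase onset
#'
#' The predicted cleavage-plane orientation: the angle at the sample nearest
#' to `t_anaphase_onset + offset` (default 2.2 min, two frames at ~1.1
#' min/frame). Equidistant samples resolve to the earlier one.
#'
#' @param track An `OrientationTrack`.
#' @param offset Minutes after anaphase onset (default 2.2).
#' @return Angle in degrees.
#' @export
cleavage_angle <- function(track, offset = 2.2) {
  s <- track$samples
  target <- track$t_anaphase_onset + offset
  if (max(s$time_min) < target - 1e-9) {
    stop("insufficient post-anaphase samples: track ends before the offset")
  }
  d <- round(abs(s$time_min - target), 6)  # rounded so float noise cannot break ties
  ord <- order(d, s$time_min)  # ties -> earlier sample
  s$angle_deg[ord[1]]
}
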