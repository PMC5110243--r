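track_row <- function(events, cell_id = "t1", group = "g") {
  data.frame(cell_id = cell_id, group = group,
             t_prophase_start = events[1], t_congression_start = events[2],
             t_plate_formed = events[3], t_anaphase_onset = events[4],
             t_telophase_start = events[5], t_interphase_restored = events[6])
}

test_that("phase durations are the event-time differences", {
  d <- phase_durations(track_row(c(0, 5.5, 9.9, 16.5, 19.8, 26.4)))
  expect_equal(unlist(d[, c("prophase", "prometaphase", "metaphase",
                            "anaphase", "telophase")], use.names = FALSE),
               c(5.5, 4.4, 6.6, 3.3, 6.6))
  expect_equal(d$prometa_meta, 4.4 + 6.6)
  expect_equal(d$total, 26.4)

  z <- phase_durations(track_row(rep(3, 6)))
  expect_true(all(unlist(z[, 3:9]) == 0))

  expect_error(phase_durations(track_row(c(0, 9.9, 5.5, 16.5, 19.8, 26.4))),
               "t_plate_formed.*precedes|precedes.*t_congression_start")
})

test_that("phase durations invert exactly to the event times", {
  tr <- gen_mitosis_tracks(mitosis_groups_2sp(n = 25), seed = 3)
  d <- phase_durations(tr)
  rebuilt <- t(apply(as.matrix(d[, c("prophase", "prometaphase", "metaphase",
                                     "anaphase", "telophase")]), 1, cumsum))
  ev <- as.matrix(tr[, c("t_congression_start", "t_plate_formed",
                         "t_anaphase_onset", "t_telophase_start",
                         "t_interphase_restored")])
  expect_equal(unname(rebuilt), unname(ev - tr$t_prophase_start))
})

test_that("two-group comparisons are exact Mann-Whitney tests", {
  # a group compared to an identical copy of itself is non-significant
  d <- data.frame(group = rep(c("a", "b"), each = 5),
                  metaphase = rep(c(4.4, 5.5, 6.6, 7.7, 8.8), 2))
  cmp <- compare_groups(d, "metaphase")
  expect_gte(cmp$p_value, 0.99)
  expect_false(cmp$significant)

  # 4-vs-4 toys match exhaustive enumeration of the U statistic
  set.seed(61)
  for (i in 1:10) {
    x <- runif(4, 2, 10)
    y <- runif(4, 2, 10) + runif(1, -3, 3)
    dd <- data.frame(group = rep(c("a", "b"), each = 4), metaphase = c(x, y))
    cmp <- compare_groups(dd, "metaphase")
    expect_equal(cmp$p_value, oracle_exact_ranksum_p(x, y), tolerance = 1e-12)
  }

  # summary statistics: sem uses sd/sqrt(n)
  s <- cmp$summary
  expect_equal(s$sem[s$group == "a"], sd(x) / sqrt(4))
})

test_that("three-group comparisons run Kruskal-Wallis with Dunn post-hoc", {
  set.seed(62)
  d <- data.frame(
    group = rep(c("a", "b", "c"), each = 20),
    metaphase = c(rnorm(20, 5, 1), rnorm(20, 5, 1), rnorm(20, 12, 1)))
  cmp <- compare_groups(d, "metaphase")
  expect_identical(cmp$test, "Kruskal-Wallis + Dunn")
  expect_true(cmp$significant)
  pw <- cmp$pairwise
  shifted <- pw$group_i == "c" | pw$group_j == "c"
  expect_true(all(pw$significant[shifted]))    # only the planted pairs flag
  expect_false(any(pw$significant[!shifted]))

  # undersized groups are excluded with a warning
  d2 <- rbind(d, data.frame(group = "tiny", metaphase = c(1, 2)))
  expect_warning(cmp2 <- compare_groups(d2, "metaphase"), "excluded")
  expect_identical(sort(cmp2$summary$group), c("a", "b", "c"))

  expect_error(compare_groups(d, "nonexistent"), "unknown phase")
})

test_that("orientation range is the max-min angle within the metaphase window", {
  tr <- structure(list(
    cell_id = "t", t_plate_formed = 2.2, t_anaphase_onset = 8.8,
    samples = data.frame(time_min = c(0, 1.1, 2.2, 4.4, 6.6, 8.8, 9.9),
                         angle_deg = c(10, 20, 60, 75, 88, 70, 5))
  ), class = "OrientationTrack")
  expect_equal(orientation_range(tr), 88 - 60)  # pre-window samples ignored

  const <- tr
  const$samples$angle_deg <- rep(80, 7)
  expect_equal(orientation_range(const), 0)

  empty <- tr
  empty$samples <- data.frame(time_min = c(0, 9.9), angle_deg = c(1, 2))
  expect_error(orientation_range(empty), "no orientation samples")
})

test_that("cleavage angle reads the sample nearest 2.2 min after anaphase", {
  tr <- structure(list(
    cell_id = "t", t_plate_formed = 0, t_anaphase_onset = 8.8,
    samples = data.frame(time_min = seq(0, 13.2, by = 1.1),
                         angle_deg = 80 + seq(0, 13.2, by = 1.1) - 8.8)
  ), class = "OrientationTrack")
  # a sample sits exactly at 8.8 + 2.2 = 11 min; drift 1 deg/min from 80
  expect_equal(cleavage_angle(tr, offset = 2.2), 82.2)

  # equidistant samples resolve to the earlier one
  tie <- structure(list(
    cell_id = "t", t_plate_formed = 0, t_anaphase_onset = 0,
    samples = data.frame(time_min = c(2.2 - 0.55, 2.2 + 0.55), angle_deg = c(70, 75))
  ), class = "OrientationTrack")
  expect_equal(cleavage_angle(tie, offset = 2.2), 70)

  short <- tie
  short$samples <- data.frame(time_min = c(0, 1.1), angle_deg = c(70, 75))
  expect_error(cleavage_angle(short, offset = 2.2), "insufficient")
})
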