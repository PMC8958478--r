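mk_metrics <- function(density, condition = "DM", n_edges = NULL) {
  n <- length(density)
  data.frame(practice_id = sprintf("P%02d", seq_len(n)), condition = condition,
             n_nodes = 5, n_edges = if (is.null(n_edges)) round(10 * density)
               else n_edges,
             density = density, centralization = 0.1,
             reciprocity = 1, stringsAsFactors = FALSE)
}

test_that("condition summary computes mean/SD/median/IQR and totals", {
  s <- condition_summary(mk_metrics(c(1.0, 1.0, 0.4)), "DM")
  expect_equal(s$density$mean, 0.8)
  expect_equal(s$density$median, 1.0)
  expect_equal(s$density$sd, stats::sd(c(1, 1, 0.4)))
  expect_equal(s$density$q25, 0.7)  # linear interpolation between 0.4 and 1.0

  # 25 practices whose edge counts sum to 201 connections
  edges <- c(rep(8, 24), 9)
  s2 <- condition_summary(mk_metrics(rep(0.8, 25), n_edges = edges), "DM")
  expect_equal(s2$total_connections, 201)

  s3 <- condition_summary(mk_metrics(0.5), "DM")
  expect_true(is.na(s3$density$sd))
  expect_error(condition_summary(mk_metrics(0.5, condition = "CHD"), "DM"),
               "no metric rows")
})

test_that("reciprocity summaries skip undefined values and report n", {
  m <- mk_metrics(c(0.5, 0.6, 0.7))
  m$reciprocity <- c(1, NA, 0.5)
  s <- condition_summary(m, "DM")
  expect_equal(s$reciprocity$n, 2)
  expect_equal(s$reciprocity$mean, 0.75)
})

test_that("Friedman statistic is 6.0 on the perfectly ordered 3x3 example", {
  m <- rbind(c(3, 2, 1), c(30, 20, 10), c(0.9, 0.5, 0.1))
  f <- friedman_rank_test(m)
  expect_equal(f$statistic, 6.0)
  expect_equal(f$df, 2)
  expect_false(f$tie_corrected)
})

test_that("all-tied rows give statistic 0 and p = 1", {
  m <- matrix(1, nrow = 4, ncol = 3)
  f <- friedman_rank_test(m)
  expect_equal(f$statistic, 0)
  expect_equal(f$p_value, 1)
})

test_that("Friedman handles missing rows and small n as specified", {
  m <- rbind(c(1, 2, 3), c(2, NA, 1), c(3, 1, 2))
  expect_warning(f <- friedman_rank_test(m), "dropped")
  expect_equal(f$n_blocks, 2)
  expect_error(suppressWarnings(friedman_rank_test(rbind(c(1, 2, 3)))),
               "at least 2")
})

test_that("Friedman agrees with stats::friedman.test including ties", {
  set.seed(601)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    m <- matrix(sample(1:5, n * 3, replace = TRUE), n, 3)
    ref <- tryCatch(stats::friedman.test(m), error = function(e) NULL)
    if (is.null(ref)) next
    f <- friedman_rank_test(m)
    if (is.nan(ref$statistic)) {
      expect_equal(f$statistic, 0)
    } else {
      expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(f$p_value, unname(ref$p.value), tolerance = 1e-9)
    }
  }
})

test_that("Friedman is invariant under row-wise monotone transforms", {
  set.seed(602)
  m <- matrix(runif(30), 10, 3)
  f0 <- friedman_rank_test(m)$statistic
  m2 <- t(apply(m, 1, function(r) exp(3 * r) + 1))
  expect_equal(friedman_rank_test(m2)$statistic, f0, tolerance = 1e-12)
})

test_that("Spearman rho hits the exact extremes and matches cor.test", {
  x <- c(0.2, 0.5, 0.9, 0.1, 0.7)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  expect_error(spearman_rho(rep(1, 5), x), "constant")
  expect_error(spearman_rho(x[1:2], x[1:2]), ">= 3")
  set.seed(603)
  for (rep in 1:20) {
    a <- runif(10); b <- runif(10)
    mine <- spearman_rho(a, b)
    expect_equal(mine$rho, unname(stats::cor(a, b, method = "spearman")),
                 tolerance = 1e-12)
    ref <- stats::cor.test(a, b, method = "spearman")
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("external exchange percentages use respondent denominators", {
  practices <- lapply(1:51, function(i) {
    mk <- function(j, groups) {
      member(sprintf("M%d", j),
             if (j == 1) "physician" else "practice_assistant",
             responded = j <= 3,
             external_groups = if (j <= 3) list(DM = groups) else list())
    }
    # 3 respondents + 1 non-respondent per practice; pharmacists marked by
    # the first respondent of the first 26 practices plus 2nd of practice 1...
    groups1 <- if (i <= 26) "pharmacists" else character(0)
    practice_roster(sprintf("PR%02d", i), list(
      mk(1, groups1),
      mk(2, if (i <= 26) "pharmacists" else character(0)),
      mk(3, if (i <= 25) "pharmacists" else character(0)),
      mk(4, character(0))))
  })
  coh <- cohort(practices)
  tab <- external_exchange_table(coh)
  expect_equal(attr(tab, "n_respondents"), 153)
  ph <- tab[tab$group == "pharmacists" & tab$condition == "DM", ]
  expect_equal(ph$n_overall, 77)
  expect_equal(round(ph$pct_overall, 1), 50.3)
  # a group never marked stays at 0 (0.0%)
  occ <- tab[tab$group == "occupational_health_physicians" &
               tab$condition == "DM", ]
  expect_equal(occ$n_overall, 0)
  expect_equal(occ$pct_overall, 0)
  # counts never exceed the stratum size
  expect_true(all(tab$n_overall <= attr(tab, "n_respondents")))
  expect_true(all(tab$n_physician <= attr(tab, "n_physicians")))
})

test_that("cardiologist summary aggregates at practice level and by role", {
  mkp <- function(pid, counts, roles) {
    practice_roster(pid, lapply(seq_along(counts), function(i) {
      member(sprintf("M%d", i), roles[i], responded = !is.na(counts[i]),
             cardiologists_monthly = if (!is.na(counts[i]))
               list(CHD = counts[i]) else list())
    }))
  }
  coh <- cohort(list(
    mkp("A", c(4, 2, 2), c("physician", "practice_assistant",
                           "practice_assistant")),
    mkp("B", c(5, 1, NA), c("physician", "practice_assistant",
                            "practice_assistant"))))
  s <- cardiologist_summary(coh, "CHD")
  expect_equal(s$practice$n, 2)
  expect_equal(s$practice$mean, mean(c(mean(c(4, 2, 2)), mean(c(5, 1)))))
  expect_equal(round(mean(c(4, 2, 2)), 2), 2.67)
  expect_equal(s$by_role$physician$mean, 4.5)
  expect_equal(s$by_role$non_physician$mean, mean(c(2, 2, 1)))

  none <- cohort(list(mkp("C", NA, "physician")))
  expect_error(cardiologist_summary(none, "CHF"), "no cardiologist counts")
})

test_that("a cohort built to the stratified physician mean reproduces it", {
  counts <- c(rep(4, 13), rep(3, 1))  # mean 3.93 to 2 decimals
  coh <- cohort(list(practice_roster("A", lapply(seq_along(counts), function(i)
    member(sprintf("P%d", i), "physician",
           cardiologists_monthly = list(CHD = counts[i]))))))
  s <- cardiologist_summary(coh, "CHD")
  expect_equal(round(s$by_role$physician$mean, 2), 3.93)
})
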