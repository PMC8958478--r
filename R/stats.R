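METRIC_COLS <- c("n_edges", "density", "centralization", "reciprocity")

#' Per-condition summary of network metrics
#'
#' Mean with sample SD (n-1 denominator) and median with interquartile range
#' (25th-75th percentile, linear interpolation) for each of the four network
#' properties, plus the total number of connections. Undefined reciprocity
#' values are skipped and the effective n reported.
#'
#' @param metrics Metric rows from [cohort_metrics()] (included practices).
#' @param condition One of `"DM"`, `"CHD"`, `"CHF"`.
#' @return A list of class `praxnet_condition_summary`: `condition`,
#'   `n_networks`, `total_connections`, and per metric a list with `n`,
#'   `mean`, `sd`, `median`, `q25`, `q75`, `min`, `max`.
#' @export
condition_summary <- function(metrics, condition) {
  condition <- match.arg(condition, CONDITIONS)
  sub <- metrics[metrics$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no metric rows for condition ", condition,
                            call. = FALSE)
  summ <- function(x) {
    x <- x[!is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(n = length(x), mean = mean(x),
         sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
         median = q[2], q25 = q[1], q75 = q[3], min = min(x), max = max(x))
  }
  out <- list(condition = condition, n_networks = nrow(sub),
              total_connections = sum(sub$n_edges))
  for (mc in METRIC_COLS) out[[mc]] <- summ(sub[[mc]])
  structure(out, class = "praxnet_condition_summary")
}

#' @export
print.praxnet_condition_summary <- function(x, ...) {
  cat("Network characteristics, ", x$condition, " (n = ", x$n_networks,
      " networks; total connections = ", x$total_connections, ")\n", sep = "")
  for (mc in METRIC_COLS) {
    s <- x[[mc]]
    cat(sprintf("  %-16s mean %s (SD %s), median %s (IQR %s-%s)%s\n", mc,
                fmt2(s$mean), if (is.na(s$sd)) "NA" else fmt2(s$sd),
                fmt2(s$median), fmt2(s$q25), fmt2(s$q75),
                if (s$n < x$n_networks)
                  sprintf(" [n = %d defined]", s$n) else ""))
  }
  invisible(x)
}

#' Friedman rank test across the three conditions
#'
#' Nonparametric comparison of a network property across the three related
#' condition networks measured on the same practices. Values are mid-ranked
#' within each practice; the statistic
#' \deqn{\chi^2 = \frac{12}{nk(k+1)} \sum_j R_j^2 - 3n(k+1)}
#' is divided by the tie-correction factor
#' \eqn{1 - \sum (t^3 - t) / (n k (k^2 - 1))} and referred to the chi-square
#' distribution with \eqn{k - 1} degrees of freedom (asymptotic p-value).
#' When every practice ties across all conditions the statistic is 0 and the
#' p-value 1.
#'
#' @param values Numeric matrix, practices in rows, conditions in columns
#'   (k >= 2). Rows containing `NA` are dropped with a warning.
#' @return A list of class `praxnet_friedman`: `statistic`, `df`, `p_value`,
#'   `n_blocks`, `tie_corrected`.
#' @export
friedman_rank_test <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need at least 2 conditions", call. = FALSE)
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    warning(sum(!complete), " practice(s) dropped: missing condition values")
    values <- values[complete, , drop = FALSE]
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 2L) stop("need at least 2 complete practices", call. = FALSE)
  ranks <- t(apply(values, 1L, rank))
  Rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  tie_term <- sum(vapply(seq_len(n), function(i) {
    t <- table(values[i, ])
    sum(t^3 - t)
  }, numeric(1)))
  corr <- 1 - tie_term / (n * k * (k^2 - 1))
  tie_corrected <- tie_term > 0
  if (corr <= 0) {
    stat <- 0
  } else {
    stat <- stat / corr
  }
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(statistic = stat, df = k - 1L, p_value = p, n_blocks = n,
                 tie_corrected = tie_corrected),
            class = "praxnet_friedman")
}

#' @export
print.praxnet_friedman <- function(x, ...) {
  cat(sprintf("Friedman chi^2 = %.2f, df = %d, p = %.3g (n = %d practices%s)\n",
              x$statistic, x$df, x$p_value, x$n_blocks,
              if (x$tie_corrected) ", tie-corrected" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rho is the product-moment correlation of the mid-ranks; the p-value uses
#' the t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} with
#' \eqn{n - 2} degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("rho undefined: constant input vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}

#' External information-exchange table
#'
#' For every external occupational group and condition: the number and
#' percentage of responding practice members who report weekly information
#' exchange with that group, overall and stratified by role. Denominators
#' are responding individuals (not practices).
#'
#' @param coh A validated [cohort()].
#' @return Data frame: `group`, `condition`, `n_overall`, `pct_overall`,
#'   `n_physician`, `pct_physician`, `n_assistant`, `pct_assistant`, plus the
#'   denominators as attributes `n_respondents`, `n_physicians`,
#'   `n_assistants`.
#' @export
external_exchange_table <- function(coh) {
  stopifnot(inherits(coh, "praxnet_cohort"))
  resp <- list(); roles <- character(0)
  for (pr in coh$practices) {
    for (m in pr$members) {
      if (m$responded) {
        resp[[length(resp) + 1L]] <- m
        roles <- c(roles, m$role)
      }
    }
  }
  n_all <- length(resp)
  n_phy <- sum(roles == "physician")
  n_pa <- sum(roles == "practice_assistant")
  rows <- list()
  for (g in OCCUPATIONAL_GROUPS) {
    for (cn in CONDITIONS) {
      marked <- vapply(resp, function(m) g %in% m$external_groups[[cn]],
                       logical(1))
      no <- sum(marked)
      np <- sum(marked & roles == "physician")
      na_ <- sum(marked & roles == "practice_assistant")
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, condition = cn,
        n_overall = no, pct_overall = if (n_all) 100 * no / n_all else 0,
        n_physician = np, pct_physician = if (n_phy) 100 * np / n_phy else 0,
        n_assistant = na_, pct_assistant = if (n_pa) 100 * na_ / n_pa else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_respondents") <- n_all
  attr(out, "n_physicians") <- n_phy
  attr(out, "n_assistants") <- n_pa
  out
}

#' Monthly cardiologist exchange summary
#'
#' Number of cardiologists with whom information about CHD or CHF patients is
#' exchanged at least monthly: mean/SD/range of practice-level means (mean of
#' member counts per practice, missing counts excluded) and individual-level
#' means stratified by role (physicians vs non-physicians).
#'
#' @param coh A validated [cohort()].
#' @param condition `"CHD"` or `"CHF"`.
#' @return List with `condition`, `practice` (mean, sd, min, max, n) and
#'   `by_role` (mean, sd, n for physicians and non-physicians).
#' @export
cardiologist_summary <- function(coh, condition = c("CHD", "CHF")) {
  condition <- match.arg(condition)
  stopifnot(inherits(coh, "praxnet_cohort"))
  practice_means <- numeric(0)
  indiv <- numeric(0); indiv_role <- character(0)
  for (pr in coh$practices) {
    counts <- vapply(pr$members, function(m) {
      v <- m$cardiologists_monthly[[condition]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    rl <- member_roles(pr)
    keep <- !is.na(counts)
    if (any(keep)) practice_means <- c(practice_means, mean(counts[keep]))
    indiv <- c(indiv, counts[keep])
    indiv_role <- c(indiv_role, rl[keep])
  }
  if (!length(indiv)) stop("no cardiologist counts available for ", condition,
                           call. = FALSE)
  strat <- function(sel) {
    x <- indiv[sel]
    list(mean = if (length(x)) mean(x) else NA_real_,
         sd = if (length(x) > 1L) stats::sd(x) else NA_real_, n = length(x))
  }
  list(
    condition = condition,
    practice = list(mean = mean(practice_means),
                    sd = if (length(practice_means) > 1L)
                      stats::sd(practice_means) else NA_real_,
                    min = min(practice_means), max = max(practice_means),
                    n = length(practice_means)),
    by_role = list(physician = strat(indiv_role == "physician"),
                   non_physician = strat(indiv_role != "physician"))
  )
}
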