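msr <- function(x) {
  # mean / sample SD / range, NA-free input expected
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
       min = min(x), max = max(x), n = length(x))
}

freq_table <- function(x, levels) {
  # counts and percentages over non-missing records (per-item denominators)
  x <- x[!is.na(x)]
  n <- length(x)
  counts <- vapply(levels, function(l) sum(x == l), integer(1))
  data.frame(level = levels, n = counts,
             pct = if (n > 0) 100 * counts / n else rep(0, length(levels)),
             stringsAsFactors = FALSE, row.names = NULL)
}

meetings_band <- function(m) {
  # Bands used for team meetings per quarter: 0..4 and ">4"
  ifelse(is.na(m), NA_character_, ifelse(m > 4L, ">4", as.character(m)))
}

#' Summarize practice characteristics of a cohort
#'
#' Cohort-level description in the style of a practice-characteristics table:
#' mean/SD/range of team size, physicians and assistants per practice,
#' frequency tables (n, %) for practice type, caseload band, documentation
#' mode, case management and team meetings per quarter, and the individual
#' response rate. Missing metadata are excluded item-wise from denominators;
#' each frequency table therefore carries its own `n_item`.
#'
#' @param coh A validated [cohort()].
#' @return A list of class `praxnet_characteristics` with elements
#'   `n_practices`, `members`, `physicians`, `assistants` (each mean/sd/range),
#'   `response` (member counts and percentage), and the frequency tables
#'   `practice_type`, `cases_band`, `documentation`, `case_manager`,
#'   `meetings`.
#' @export
summarize_practice_characteristics <- function(coh) {
  stopifnot(inherits(coh, "praxnet_cohort"))
  if (length(coh$practices) == 0L) stop("empty cohort", call. = FALSE)
  sizes <- vapply(coh$practices, function(p) length(p$members), integer(1))
  phys <- vapply(coh$practices, function(p) sum(member_roles(p) == "physician"),
                 integer(1))
  asst <- vapply(coh$practices,
                 function(p) sum(member_roles(p) == "practice_assistant"),
                 integer(1))
  n_members <- sum(sizes)
  n_resp <- sum(vapply(coh$practices, function(p) sum(member_responded(p)),
                       integer(1)))
  meta <- function(field) vapply(coh$practices, function(p) {
    v <- p[[field]]
    if (is.na(v)) NA_character_ else as.character(v)
  }, character(1))
  cm <- meta("case_manager")
  cm <- ifelse(is.na(cm), NA_character_, ifelse(cm == "TRUE", "yes", "no"))
  mq <- vapply(coh$practices, `[[`, integer(1), "meetings_per_quarter")
  structure(list(
    n_practices = length(coh$practices),
    members = msr(sizes),
    physicians = msr(phys),
    assistants = msr(asst),
    response = list(n_members = n_members, n_respondents = n_resp,
                    rate_pct = 100 * n_resp / n_members),
    practice_type = freq_table(meta("practice_type"), PRACTICE_TYPES),
    cases_band = freq_table(meta("cases_band"), CASES_BANDS),
    documentation = freq_table(meta("documentation"), DOCUMENTATION_MODES),
    case_manager = freq_table(cm, c("no", "yes")),
    meetings = freq_table(meetings_band(mq), c("0", "1", "2", "3", "4", ">4"))
  ), class = "praxnet_characteristics")
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' @export
print.praxnet_characteristics <- function(x, ...) {
  cat("Practice characteristics (N =", x$n_practices, "practices)\n")
  row <- function(lab, s) {
    cat(sprintf("  %-28s %s (%s), range %d-%d\n", lab, fmt1(s$mean),
                if (is.na(s$sd)) "NA" else fmt2(s$sd), s$min, s$max))
  }
  row("Health workers per practice", x$members)
  row("Physicians", x$physicians)
  row("Practice assistants", x$assistants)
  cat(sprintf("  Individual response rate:    %s%% (%d/%d)\n",
              fmt1(x$response$rate_pct), x$response$n_respondents,
              x$response$n_members))
  for (tab in c("practice_type", "cases_band", "documentation",
                "case_manager", "meetings")) {
    tt <- x[[tab]]
    cat("  ", tab, " (n = ", sum(tt$n), "):\n", sep = "")
    for (i in seq_len(nrow(tt))) {
      cat(sprintf("    %-28s %d (%s)\n", tt$level[i], tt$n[i], fmt1(tt$pct[i])))
    }
  }
  invisible(x)
}

#' Individual response rate of a cohort
#'
#' Percentage of practice members who returned the questionnaire, optionally
#' restricted to the practices admitted by the inclusion filter (at least
#' three members, at most one non-respondent).
#'
#' @param coh A validated [cohort()].
#' @param included_only If `TRUE`, compute the rate over members of included
#'   practices only.
#' @return List with `n_members`, `n_respondents` and `rate_pct`.
#' @export
response_rate <- function(coh, included_only = FALSE) {
  stopifnot(inherits(coh, "praxnet_cohort"))
  prs <- coh$practices
  if (included_only) {
    dec <- apply_inclusion_filter(coh)
    prs <- prs[dec$included]
  }
  n_members <- sum(vapply(prs, function(p) length(p$members), integer(1)))
  n_resp <- sum(vapply(prs, function(p) sum(member_responded(p)), integer(1)))
  if (n_members == 0L) stop("no members in scope", call. = FALSE)
  list(n_members = n_members, n_respondents = n_resp,
       rate_pct = 100 * n_resp / n_members)
}
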