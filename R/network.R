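#' Build the directed nomination network of one practice and condition
#'
#' Nodes are all practice members (respondents and non-respondents); a
#' directed tie \code{a -> b} is present when respondent \code{a} nominated
#' \code{b} as a weekly information-exchange partner for the condition.
#' Non-respondents cannot send nominations but may receive them.
#'
#' @param roster A [practice_roster()].
#' @param condition One of `"DM"`, `"CHD"`, `"CHF"`.
#' @return A list of class `praxnet_directed` with `practice_id`, `condition`,
#'   `nodes` (data frame: member_id, role, responded) and `ties` (data frame:
#'   from, to).
#' @export
build_directed_network <- function(roster, condition) {
  stopifnot(inherits(roster, "praxnet_practice"))
  condition <- match.arg(condition, CONDITIONS)
  nodes <- data.frame(member_id = member_ids(roster),
                      role = member_roles(roster),
                      responded = member_responded(roster),
                      stringsAsFactors = FALSE)
  from <- character(0); to <- character(0)
  for (m in roster$members) {
    tg <- m$nominations[[condition]]
    if (length(tg)) {
      from <- c(from, rep(m$member_id, length(tg)))
      to <- c(to, tg)
    }
  }
  structure(list(practice_id = roster$practice_id, condition = condition,
                 nodes = nodes,
                 ties = data.frame(from = from, to = to,
                                   stringsAsFactors = FALSE)),
            class = "praxnet_directed")
}

#' Symmetrize a directed network
#'
#' Converts the directed nomination network to an undirected one. Under the
#' `"union"` (weak) rule an edge \{a, b\} exists when at least one of the two
#' directions was reported; this simultaneously reconstructs the ties of a
#' single non-respondent from the nominations pointing at them. The
#' `"intersection"` (strong) rule, retaining only mutual dyads, is provided
#' for sensitivity analyses.
#'
#' @param net A `praxnet_directed` network.
#' @param rule `"union"` (default) or `"intersection"`.
#' @return A list of class `praxnet_undirected` with `nodes` and `edges`
#'   (data frame: a, b; each unordered pair once, `a < b`).
#' @export
symmetrize <- function(net, rule = c("union", "intersection")) {
  stopifnot(inherits(net, "praxnet_directed"))
  rule <- match.arg(rule)
  t <- net$ties
  if (nrow(t) == 0L) {
    edges <- data.frame(a = character(0), b = character(0))
  } else {
    a <- pmin(t$from, t$to)
    b <- pmax(t$from, t$to)
    key <- paste(a, b, sep = "\r")
    if (rule == "union") {
      keep <- !duplicated(key)
      edges <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
    } else {
      fwd <- paste(t$from, t$to, sep = "\r")
      rev <- paste(t$to, t$from, sep = "\r")
      mutual <- fwd %in% rev
      keep <- mutual & !duplicated(key)
      edges <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
    }
    o <- order(edges$a, edges$b)
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(practice_id = net$practice_id, condition = net$condition,
                 nodes = net$nodes, edges = edges),
            class = "praxnet_undirected")
}

#' @export
print.praxnet_directed <- function(x, ...) {
  cat("Directed nomination network: practice '", x$practice_id, "', ",
      x$condition, ": ", nrow(x$nodes), " nodes, ", nrow(x$ties), " ties\n",
      sep = "")
  invisible(x)
}

#' @export
print.praxnet_undirected <- function(x, ...) {
  cat("Undirected network: practice '", x$practice_id, "', ", x$condition,
      ": ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Pooled cohort reciprocity
#'
#' The fraction of directed ties between two respondents whose reverse tie is
#' also reported, pooled over all practices and all three conditions. Ties
#' pointing at non-respondents are excluded from numerator and denominator
#' because the reverse nomination is unobservable. This pooled value feeds
#' the [reciprocity_gate()].
#'
#' @param coh A validated [cohort()].
#' @param included_only If `TRUE` (default), pool over practices admitted by
#'   the inclusion filter only; the all-practice value is useful for
#'   transparency.
#' @return List with `reciprocity`, `n_assessable_ties`, `n_reciprocated`.
#'   Errors when no assessable tie exists (undefined reciprocity is never a
#'   silent pass).
#' @export
cohort_reciprocity <- function(coh, included_only = TRUE) {
  stopifnot(inherits(coh, "praxnet_cohort"))
  prs <- coh$practices
  if (included_only) {
    dec <- apply_inclusion_filter(coh)
    prs <- prs[dec$included]
  }
  num <- 0L; den <- 0L
  for (pr in prs) {
    for (cn in CONDITIONS) {
      net <- build_directed_network(pr, cn)
      r <- reciprocity_counts(net)
      num <- num + r$n_reciprocated
      den <- den + r$n_assessable
    }
  }
  if (den == 0L) {
    stop("cohort reciprocity is undefined: no assessable respondent-respondent ties",
         call. = FALSE)
  }
  list(reciprocity = num / den, n_assessable_ties = den, n_reciprocated = num)
}

#' Reciprocity gate
#'
#' Decides whether reported ties are mutual enough to justify the undirected
#' (symmetrized, reconstruction-capable) representation: the pipeline
#' proceeds only when the pooled cohort reciprocity is strictly above the
#' threshold (default 0.6).
#'
#' @param cohort_reciprocity Pooled reciprocity in \[0, 1\].
#' @param threshold Gate threshold; strict inequality is used.
#' @return `TRUE` (proceed with undirected networks) or `FALSE` (stop with a
#'   diagnostic).
#' @export
reciprocity_gate <- function(cohort_reciprocity, threshold = 0.6) {
  if (length(cohort_reciprocity) != 1L || is.na(cohort_reciprocity)) {
    stop("cohort reciprocity is undefined; cannot apply the gate", call. = FALSE)
  }
  if (cohort_reciprocity < 0 || cohort_reciprocity > 1) {
    stop("reciprocity must lie in [0, 1]", call. = FALSE)
  }
  cohort_reciprocity > threshold
}

#' Apply the network inclusion filter
#'
#' A practice enters the network analysis only if it has at least three
#' members and at most one non-respondent; otherwise too much of the network
#' would be unobserved. Inclusion is practice-level (member and
#' non-respondent counts do not vary by condition). When both rules are
#' violated, `too_few_members` is reported (size is the more fundamental
#' defect).
#'
#' @param coh A validated [cohort()].
#' @return Data frame with one row per practice: `practice_id`, `n_members`,
#'   `n_nonrespondents`, `included`, `reason`
#'   (`ok` / `too_few_members` / `too_many_missing`).
#' @export
apply_inclusion_filter <- function(coh) {
  stopifnot(inherits(coh, "praxnet_cohort"))
  n <- vapply(coh$practices, function(p) length(p$members), integer(1))
  miss <- vapply(coh$practices, function(p) sum(!member_responded(p)), integer(1))
  reason <- ifelse(n < 3L, "too_few_members",
                   ifelse(miss > 1L, "too_many_missing", "ok"))
  data.frame(practice_id = practice_ids(coh), n_members = n,
             n_nonrespondents = miss, included = reason == "ok",
             reason = reason, stringsAsFactors = FALSE, row.names = NULL)
}
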