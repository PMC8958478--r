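# Fixture builders and independent brute-force oracles used across tests.

# --- quick member/practice builders -----------------------------------------

# respondent nominating the same targets for every condition
resp_member <- function(id, targets = character(0), role = "practice_assistant",
                        ...) {
  member(id, role, responded = TRUE,
         nominations = list(DM = targets, CHD = targets, CHF = targets), ...)
}

nonresp_member <- function(id, role = "practice_assistant") {
  member(id, role, responded = FALSE)
}

# practice of n members where every respondent nominates all others
# (first member is the physician); nonresp = ids of non-respondents
complete_practice <- function(pid, n, nonresp = integer(0)) {
  ids <- sprintf("M%d", seq_len(n))
  members <- lapply(seq_len(n), function(i) {
    role <- if (i == 1) "physician" else "practice_assistant"
    if (i %in% nonresp) nonresp_member(ids[i], role)
    else resp_member(ids[i], setdiff(ids, ids[i]), role)
  })
  practice_roster(pid, members)
}

# undirected network object built directly (bypasses symmetrize), for metric
# unit tests; edges is a 2-column matrix/data.frame of node indices
und_net <- function(n, edges, pid = "PX", condition = "DM") {
  ids <- sprintf("N%02d", seq_len(n))
  nodes <- data.frame(member_id = ids,
                      role = c("physician", rep("practice_assistant", n - 1)),
                      responded = TRUE, stringsAsFactors = FALSE)
  if (length(edges) == 0) {
    ed <- data.frame(a = character(0), b = character(0))
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    ed <- data.frame(a = ids[pmin(edges[, 1], edges[, 2])],
                     b = ids[pmax(edges[, 1], edges[, 2])],
                     stringsAsFactors = FALSE)
  }
  structure(list(practice_id = pid, condition = condition, nodes = nodes,
                 edges = ed),
            class = "praxnet_undirected")
}

# directed network object built directly; ties is a 2-column index matrix
dir_net <- function(n, ties, responded = rep(TRUE, n), pid = "PX",
                    condition = "DM") {
  ids <- sprintf("N%02d", seq_len(n))
  nodes <- data.frame(member_id = ids,
                      role = c("physician", rep("practice_assistant", n - 1)),
                      responded = responded, stringsAsFactors = FALSE)
  if (length(ties) == 0) {
    tt <- data.frame(from = character(0), to = character(0))
  } else {
    ties <- matrix(as.integer(ties), ncol = 2)
    tt <- data.frame(from = ids[ties[, 1]], to = ids[ties[, 2]],
                     stringsAsFactors = FALSE)
  }
  structure(list(practice_id = pid, condition = condition, nodes = nodes,
                 ties = tt),
            class = "praxnet_directed")
}

complete_edges <- function(n) t(combn(n, 2))
star_edges <- function(n) cbind(1L, 2:n)

# --- brute-force adjacency-matrix oracles -----------------------------------

adj_of <- function(net) {
  ids <- net$nodes$member_id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      A[net$edges$a[i], net$edges$b[i]] <- 1L
      A[net$edges$b[i], net$edges$a[i]] <- 1L
    }
  }
  A
}

density_oracle <- function(A) {
  n <- nrow(A)
  sum(A[upper.tri(A)]) / (n * (n - 1) / 2)
}

centralization_oracle <- function(A) {
  n <- nrow(A)
  d <- rowSums(A)
  sum(max(d) - d) / ((n - 1) * (n - 2))
}

# directed reciprocity oracle: enumerate assessable ordered pairs
reciprocity_oracle <- function(net) {
  resp <- net$nodes$member_id[net$nodes$responded]
  t <- net$ties
  t <- t[t$from %in% resp & t$to %in% resp, , drop = FALSE]
  if (nrow(t) == 0) return(NA_real_)
  back <- mapply(function(f, to) any(t$from == to & t$to == f), t$from, t$to)
  mean(back)
}

random_und_net <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1)
  all_e <- complete_edges(n)
  keep <- runif(nrow(all_e)) < p
  und_net(n, all_e[keep, , drop = FALSE])
}

# --- the worked 40-practice filter fixture ----------------------------------
# 25 included practices (121 members, 108 respondents), 6 with two members,
# 9 with >= 2 non-respondents: cohort totals 208 members, 153 respondents.
fixture_40 <- function() {
  practices <- list()
  inc_sizes <- c(rep(5, 21), rep(4, 4))               # 121 members
  for (i in seq_along(inc_sizes)) {
    nr <- if (i <= 13) 2L else integer(0)             # 13 non-respondents
    practices[[length(practices) + 1L]] <-
      complete_practice(sprintf("INC%02d", i), inc_sizes[i], nonresp = nr)
  }
  for (i in 1:6) {                                     # 12 members, too few
    practices[[length(practices) + 1L]] <-
      complete_practice(sprintf("SMALL%d", i), 2)
  }
  big_sizes <- c(8, 8, 8, 8, 8, 8, 9, 9, 9)            # 75 members
  big_nr <- c(6, 5, 5, 5, 5, 4, 4, 4, 4)               # 42 non-respondents
  for (i in seq_along(big_sizes)) {
    practices[[length(practices) + 1L]] <-
      complete_practice(sprintf("MISS%d", i), big_sizes[i],
                        nonresp = seq_len(big_nr[i]))
  }
  cohort(practices, provenance = "worked filter fixture")
}
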