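#' @keywords internal
"_PACKAGE"

#' Chronic conditions covered by the roster instrument
#'
#' The fixed, ordered vocabulary of conditions for which information-exchange
#' nominations are collected: type 2 diabetes mellitus (`DM`), coronary heart
#' disease (`CHD`) and chronic heart failure (`CHF`). The ordering
#' DM < CHD < CHF is used in every tabulation.
#'
#' @format Character vector of length 3.
#' @export
CONDITIONS <- c("DM", "CHD", "CHF")

#' Team roles in the study vocabulary
#'
#' Practice members are either physicians or practice assistants (medical
#' employees with three-year professional training). Other role strings are
#' rejected at parse time.
#'
#' @format Character vector of length 2.
#' @export
ROLES <- c("physician", "practice_assistant")

#' External occupational groups listed on the questionnaire
#'
#' The closed vocabulary of 13 occupational groups outside the practice with
#' whom weekly information exchange can be reported.
#'
#' @format Character vector of length 13.
#' @export
OCCUPATIONAL_GROUPS <- c(
  "pharmacists",
  "nutritionists",
  "physiotherapists",
  "nursing_home_nurses",
  "ambulatory_nursing_service_nurses",
  "rehabilitation_exercise_classes",
  "cardiology_exercise_classes",
  "rehabilitation_centres",
  "external_physician_assistants",
  "psychologists",
  "respiratory_physicians",
  "internists",
  "occupational_health_physicians"
)

PRACTICE_TYPES <- c("single_handed", "group", "shared",
                    "ambulatory_health_care_centre")
CASES_BANDS <- c("<500", "500-1000", "1001-1500", ">1500")
DOCUMENTATION_MODES <- c("digital", "paper", "both")

CARDIO_CONDITIONS <- c("CHD", "CHF")

empty_condition_list <- function(conditions = CONDITIONS) {
  out <- rep(list(character(0)), length(conditions))
  names(out) <- conditions
  out
}

#' Construct a practice member
#'
#' A member of a practice roster: identity, role, response status, and (for
#' respondents) per-condition nominations of other members, external
#' occupational groups, and monthly cardiologist contact counts.
#'
#' @param member_id Character scalar, unique within the practice.
#' @param role One of `"physician"` or `"practice_assistant"`.
#' @param responded Logical; `FALSE` marks a non-respondent, whose nomination
#'   and external sets must be empty and cardiologist counts missing.
#' @param nominations Named list (`DM`, `CHD`, `CHF`) of character vectors of
#'   nominated member ids. Missing conditions are filled with empty sets.
#' @param external_groups Named list (`DM`, `CHD`, `CHF`) of character vectors
#'   drawn from [OCCUPATIONAL_GROUPS].
#' @param cardiologists_monthly Named list (`CHD`, `CHF`) of non-negative
#'   integer counts or `NA`.
#' @return A list of class `praxnet_member`.
#' @export
member <- function(member_id, role, responded = TRUE,
                   nominations = list(), external_groups = list(),
                   cardiologists_monthly = list()) {
  stopifnot(is.character(member_id), length(member_id) == 1L, nzchar(member_id))
  if (!role %in% ROLES) {
    stop("unknown role '", role, "' for member '", member_id,
         "': must be one of ", paste(ROLES, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.logical(responded), length(responded) == 1L, !is.na(responded))
  nom <- empty_condition_list()
  for (cn in names(nominations)) {
    if (!cn %in% CONDITIONS) {
      stop("unknown condition '", cn, "' in nominations of '", member_id, "'",
           call. = FALSE)
    }
    nom[[cn]] <- sort(unique(as.character(nominations[[cn]])))
  }
  ext <- empty_condition_list()
  for (cn in names(external_groups)) {
    if (!cn %in% CONDITIONS) {
      stop("unknown condition '", cn, "' in external groups of '", member_id,
           "'", call. = FALSE)
    }
    g <- as.character(external_groups[[cn]])
    bad <- setdiff(g, OCCUPATIONAL_GROUPS)
    if (length(bad)) {
      stop("unknown occupational group(s) for member '", member_id, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ext[[cn]] <- sort(unique(g))
  }
  card <- list(CHD = NA_integer_, CHF = NA_integer_)
  for (cn in names(cardiologists_monthly)) {
    if (!cn %in% CARDIO_CONDITIONS) {
      stop("cardiologist counts are collected for CHD and CHF only", call. = FALSE)
    }
    v <- cardiologists_monthly[[cn]]
    if (length(v) != 1L) stop("cardiologist count must be a scalar", call. = FALSE)
    if (!is.na(v)) {
      v <- as.integer(v)
      if (is.na(v) || v < 0L) {
        stop("cardiologist count for '", member_id,
             "' must be a non-negative integer or NA", call. = FALSE)
      }
    } else {
      v <- NA_integer_
    }
    card[[cn]] <- v
  }
  structure(
    list(member_id = member_id, role = role, responded = responded,
         nominations = nom, external_groups = ext,
         cardiologists_monthly = card),
    class = "praxnet_member"
  )
}

na_or_in <- function(x, vocab, what) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_character_)
  x <- as.character(x)
  if (length(x) != 1L || !x %in% vocab) {
    stop("invalid ", what, ": '", paste(x, collapse = ","),
         "' (expected one of ", paste(vocab, collapse = ", "), " or NA)",
         call. = FALSE)
  }
  x
}

#' Construct a practice roster
#'
#' One practice: its members plus practice-level metadata (type, caseload
#' band, documentation mode, case manager, team meetings per quarter). Any
#' metadata item may be missing (`NA`).
#'
#' @param practice_id Character scalar, unique within a cohort.
#' @param members List of [member()] objects (at least one).
#' @param practice_type One of `"single_handed"`, `"group"`, `"shared"`,
#'   `"ambulatory_health_care_centre"`, or `NA`.
#' @param cases_band One of `"<500"`, `"500-1000"`, `"1001-1500"`, `">1500"`,
#'   or `NA` (cases per quarter).
#' @param documentation One of `"digital"`, `"paper"`, `"both"`, or `NA`.
#' @param case_manager Logical or `NA`.
#' @param meetings_per_quarter Non-negative integer or `NA`.
#' @return A list of class `praxnet_practice`.
#' @export
practice_roster <- function(practice_id, members,
                            practice_type = NA, cases_band = NA,
                            documentation = NA, case_manager = NA,
                            meetings_per_quarter = NA) {
  stopifnot(is.character(practice_id), length(practice_id) == 1L,
            nzchar(practice_id))
  if (!is.list(members) || length(members) < 1L) {
    stop("practice '", practice_id, "' must have at least one member",
         call. = FALSE)
  }
  if (!all(vapply(members, inherits, logical(1), "praxnet_member"))) {
    stop("members must be praxnet_member objects", call. = FALSE)
  }
  cm <- case_manager
  if (!is.na(cm[1]) && !is.logical(cm)) stop("case_manager must be logical or NA",
                                             call. = FALSE)
  mq <- meetings_per_quarter
  if (!is.na(mq[1])) {
    mq <- as.integer(mq)
    if (is.na(mq) || mq < 0L) stop("meetings_per_quarter must be >= 0 or NA",
                                   call. = FALSE)
  } else {
    mq <- NA_integer_
  }
  structure(
    list(practice_id = practice_id, members = members,
         practice_type = na_or_in(practice_type, PRACTICE_TYPES, "practice_type"),
         cases_band = na_or_in(cases_band, CASES_BANDS, "cases_band"),
         documentation = na_or_in(documentation, DOCUMENTATION_MODES,
                                  "documentation"),
         case_manager = if (is.na(cm[1])) NA else isTRUE(cm),
         meetings_per_quarter = mq),
    class = "praxnet_practice"
  )
}

#' Construct a cohort of practices
#'
#' @param practices List of [practice_roster()] objects.
#' @param provenance Free-text label describing where the cohort came from
#'   (e.g. `"synthetic, seed=1"`).
#' @return A list of class `praxnet_cohort`.
#' @export
cohort <- function(practices, provenance = "") {
  stopifnot(is.list(practices))
  if (!all(vapply(practices, inherits, logical(1), "praxnet_practice"))) {
    stop("practices must be praxnet_practice objects", call. = FALSE)
  }
  structure(list(practices = practices,
                 provenance = as.character(provenance)[1]),
            class = "praxnet_cohort")
}

practice_ids <- function(coh) {
  vapply(coh$practices, `[[`, character(1), "practice_id")
}

member_ids <- function(practice) {
  vapply(practice$members, `[[`, character(1), "member_id")
}

member_responded <- function(practice) {
  vapply(practice$members, `[[`, logical(1), "responded")
}

member_roles <- function(practice) {
  vapply(practice$members, `[[`, character(1), "role")
}

#' Validate a cohort against the roster invariants
#'
#' Checks uniqueness of practice and member ids, the closed role and
#' occupational-group vocabularies, absence of self-ties, that every
#' nomination points at an existing member of the same practice, and that
#' non-respondents carry no outgoing data.
#'
#' @param coh A [cohort()] object.
#' @return Invisibly `TRUE`; otherwise an error naming the offending
#'   practice/member.
#' @export
validate_cohort <- function(coh) {
  stopifnot(inherits(coh, "praxnet_cohort"))
  pids <- practice_ids(coh)
  if (anyDuplicated(pids)) {
    stop("duplicate practice_id: ",
         paste(unique(pids[duplicated(pids)]), collapse = ", "), call. = FALSE)
  }
  for (pr in coh$practices) {
    ids <- member_ids(pr)
    if (anyDuplicated(ids)) {
      stop("duplicate member_id in practice '", pr$practice_id, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
    for (m in pr$members) {
      for (cn in CONDITIONS) {
        nom <- m$nominations[[cn]]
        if (m$member_id %in% nom) {
          stop("self-tie: member '", m$member_id, "' in practice '",
               pr$practice_id, "' nominates itself (", cn, ")", call. = FALSE)
        }
        dangling <- setdiff(nom, ids)
        if (length(dangling)) {
          stop("dangling nomination: member '", m$member_id, "' in practice '",
               pr$practice_id, "' nominates unknown id(s) ",
               paste(dangling, collapse = ", "), " (", cn, ")", call. = FALSE)
        }
      }
      if (!m$responded) {
        if (any(lengths(m$nominations) > 0) || any(lengths(m$external_groups) > 0)) {
          stop("non-respondent '", m$member_id, "' in practice '",
               pr$practice_id, "' carries nominations or external groups",
               call. = FALSE)
        }
        if (any(!is.na(unlist(m$cardiologists_monthly)))) {
          stop("non-respondent '", m$member_id, "' in practice '",
               pr$practice_id, "' carries cardiologist counts", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.praxnet_cohort <- function(x, ...) {
  np <- length(x$practices)
  nm <- sum(vapply(x$practices, function(p) length(p$members), integer(1)))
  nr <- sum(vapply(x$practices, function(p) sum(member_responded(p)), integer(1)))
  cat("Practice cohort: ", np, " practices, ", nm, " members (",
      nr, " respondents)\n", sep = "")
  if (nzchar(x$provenance)) cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.praxnet_practice <- function(x, ...) {
  cat("Practice '", x$practice_id, "': ", length(x$members), " members (",
      sum(member_roles(x) == "physician"), " physicians), ",
      sum(!member_responded(x)), " non-respondent(s)\n", sep = "")
  invisible(x)
}
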