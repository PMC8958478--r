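#' Read a cohort from disk
#'
#' Two dialects are supported. `format = "json"` reads the canonical nested
#' schema (`provenance`, `practices`, each with metadata and `members`
#' carrying nominations, external groups, and cardiologist counts).
#' `format = "csv"` reads a directory containing the flat pair
#' `members.csv` (one row per member, with practice metadata repeated and
#' external groups as semicolon-separated codes) and `nominations.csv`
#' (`practice_id, source_id, target_id, condition`).
#'
#' The result is validated with [validate_cohort()] before it is returned.
#'
#' @param path File path (JSON) or directory (CSV).
#' @param format `"json"` or `"csv"`.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") coh <- read_cohort_json(path) else coh <- read_cohort_csv(path)
  validate_cohort(coh)
  coh
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c, path))` returns a
#' cohort identical to `c` in either format.
#'
#' @param coh A validated [cohort()].
#' @param path Output file (JSON) or directory (CSV; created if needed).
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(coh, path, format = c("json", "csv")) {
  format <- match.arg(format)
  validate_cohort(coh)
  if (format == "json") write_cohort_json(coh, path) else write_cohort_csv(coh, path)
  invisible(path)
}

scalar_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA else x[[1]]

read_cohort_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$practices)) stop("malformed cohort JSON: no 'practices' field",
                                   call. = FALSE)
  practices <- lapply(raw$practices, function(p) {
    if (is.null(p$practice_id)) stop("malformed practice record: no practice_id",
                                     call. = FALSE)
    members <- lapply(p$members, function(m) {
      card <- m$cardiologists_monthly
      card <- lapply(card[intersect(names(card), CARDIO_CONDITIONS)],
                     function(v) if (is.null(v)) NA_integer_ else v)
      member(
        member_id = m$member_id,
        role = m$role,
        responded = isTRUE(m$responded),
        nominations = lapply(m$nominations, function(v) unlist(v, use.names = FALSE)),
        external_groups = lapply(m$external_groups,
                                 function(v) unlist(v, use.names = FALSE)),
        cardiologists_monthly = card
      )
    })
    practice_roster(
      practice_id = p$practice_id, members = members,
      practice_type = scalar_or_na(p$practice_type),
      cases_band = scalar_or_na(p$cases_band),
      documentation = scalar_or_na(p$documentation),
      case_manager = scalar_or_na(p$case_manager),
      meetings_per_quarter = scalar_or_na(p$meetings_per_quarter)
    )
  })
  cohort(practices, provenance = if (is.null(raw$provenance)) "" else raw$provenance)
}

write_cohort_json <- function(coh, path) {
  as_json_member <- function(m) {
    list(
      member_id = jsonlite::unbox(m$member_id),
      role = jsonlite::unbox(m$role),
      responded = jsonlite::unbox(m$responded),
      nominations = m$nominations,
      external_groups = m$external_groups,
      cardiologists_monthly = lapply(m$cardiologists_monthly, jsonlite::unbox)
    )
  }
  as_json_practice <- function(p) {
    list(
      practice_id = jsonlite::unbox(p$practice_id),
      practice_type = jsonlite::unbox(p$practice_type),
      cases_band = jsonlite::unbox(p$cases_band),
      documentation = jsonlite::unbox(p$documentation),
      case_manager = jsonlite::unbox(p$case_manager),
      meetings_per_quarter = jsonlite::unbox(p$meetings_per_quarter),
      members = lapply(p$members, as_json_member)
    )
  }
  obj <- list(provenance = jsonlite::unbox(coh$provenance),
              practices = lapply(coh$practices, as_json_practice))
  ok <- tryCatch({
    jsonlite::write_json(obj, path, null = "null", na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("failed to write cohort to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

join_codes <- function(x) paste(x, collapse = ";")
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

write_cohort_csv <- function(coh, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", path, "'", call. = FALSE)
  }
  mem_rows <- list()
  nom_rows <- list()
  for (p in coh$practices) {
    for (m in p$members) {
      mem_rows[[length(mem_rows) + 1L]] <- data.frame(
        practice_id = p$practice_id,
        member_id = m$member_id,
        role = m$role,
        responded = m$responded,
        external_DM = join_codes(m$external_groups$DM),
        external_CHD = join_codes(m$external_groups$CHD),
        external_CHF = join_codes(m$external_groups$CHF),
        cardiologists_CHD = m$cardiologists_monthly$CHD,
        cardiologists_CHF = m$cardiologists_monthly$CHF,
        practice_type = p$practice_type,
        cases_band = p$cases_band,
        documentation = p$documentation,
        case_manager = p$case_manager,
        meetings_per_quarter = p$meetings_per_quarter,
        provenance = coh$provenance,
        stringsAsFactors = FALSE
      )
      for (cn in CONDITIONS) {
        tg <- m$nominations[[cn]]
        if (length(tg)) {
          nom_rows[[length(nom_rows) + 1L]] <- data.frame(
            practice_id = p$practice_id, source_id = m$member_id,
            target_id = tg, condition = cn, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  members_df <- do.call(rbind, mem_rows)
  nominations_df <- if (length(nom_rows)) do.call(rbind, nom_rows) else
    data.frame(practice_id = character(0), source_id = character(0),
               target_id = character(0), condition = character(0))
  utils::write.csv(members_df, file.path(path, "members.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(nominations_df, file.path(path, "nominations.csv"),
                   row.names = FALSE, na = "")
  invisible(path)
}

read_cohort_csv <- function(path) {
  mfile <- file.path(path, "members.csv")
  nfile <- file.path(path, "nominations.csv")
  for (f in c(mfile, nfile)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  mdf <- utils::read.csv(mfile, stringsAsFactors = FALSE,
                         colClasses = c(practice_id = "character",
                                        member_id = "character"))
  ndf <- utils::read.csv(nfile, stringsAsFactors = FALSE,
                         colClasses = "character")
  blank_to_na <- function(x) ifelse(is.na(x) | x == "", NA, x)
  practices <- lapply(split(seq_len(nrow(mdf)), factor(mdf$practice_id,
                                                       levels = unique(mdf$practice_id))),
                      function(idx) {
    sub <- mdf[idx, , drop = FALSE]
    pid <- sub$practice_id[1]
    nom_sub <- ndf[ndf$practice_id == pid, , drop = FALSE]
    members <- lapply(seq_len(nrow(sub)), function(i) {
      r <- sub[i, ]
      noms <- lapply(CONDITIONS, function(cn) {
        nom_sub$target_id[nom_sub$source_id == r$member_id &
                            nom_sub$condition == cn]
      })
      names(noms) <- CONDITIONS
      member(
        member_id = r$member_id, role = r$role,
        responded = isTRUE(as.logical(r$responded)),
        nominations = noms,
        external_groups = list(DM = split_codes(r$external_DM),
                               CHD = split_codes(r$external_CHD),
                               CHF = split_codes(r$external_CHF)),
        cardiologists_monthly = list(
          CHD = if (is.na(r$cardiologists_CHD)) NA_integer_ else
            as.integer(r$cardiologists_CHD),
          CHF = if (is.na(r$cardiologists_CHF)) NA_integer_ else
            as.integer(r$cardiologists_CHF))
      )
    })
    practice_roster(
      practice_id = pid, members = members,
      practice_type = blank_to_na(sub$practice_type[1]),
      cases_band = blank_to_na(sub$cases_band[1]),
      documentation = blank_to_na(sub$documentation[1]),
      case_manager = if (is.na(blank_to_na(as.character(sub$case_manager[1])))) NA
        else as.logical(sub$case_manager[1]),
      meetings_per_quarter = sub$meetings_per_quarter[1]
    )
  })
  names(practices) <- NULL
  prov <- if ("provenance" %in% names(mdf)) blank_to_na(as.character(mdf$provenance[1])) else NA
  cohort(practices, provenance = if (is.na(prov)) "" else prov)
}
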