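BAND_TOL <- 1e-9

#' Classify a density or centralization value into the low/medium/high bands
#'
#' Thresholds: low \eqn{\le 0.33}, medium \eqn{> 0.33} and \eqn{\le 0.67},
#' high \eqn{> 0.67}. Boundaries are compared with an absolute tolerance of
#' 1e-9 so that rational values such as 2/3 land in the intended band.
#'
#' @param value Numeric vector of fractions in \[0, 1\].
#' @return Character vector (`"low"`, `"medium"`, `"high"`).
#' @export
band_of <- function(value) {
  if (any(is.na(value)) || any(value < -BAND_TOL | value > 1 + BAND_TOL)) {
    stop("band_of expects values in [0, 1]", call. = FALSE)
  }
  ifelse(value <= 0.33 + BAND_TOL, "low",
         ifelse(value <= 0.67 + BAND_TOL, "medium", "high"))
}

NETWORK_TYPES <- c("A", "B", "C", "D", "unmapped")

#' Classify networks into the four-type density/centralization typology
#'
#' The typology combines the density and centralization bands:
#' \itemize{
#'   \item type A — highly connected (density high, centralization low), of
#'     which fully connected networks (density exactly 1) are a special case;
#'   \item type B — medium connected with medium hierarchy;
#'   \item type C — medium connected with low hierarchy;
#'   \item type D — lowly connected (low density, whatever the
#'     centralization, which is low as a practical consequence).
#' }
#' Band combinations the typology does not define (high centralization with
#' medium or high density, and medium centralization with high density) are
#' labelled `"unmapped"` rather than forced into a type.
#'
#' @param metrics Data frame with columns `density` and `centralization`
#'   (e.g. from [cohort_metrics()]); other columns are carried through.
#' @return The input with columns `density_band`, `centralization_band`,
#'   `network_type` and `fully_connected` appended.
#' @export
classify_networks <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("density", "centralization") %in% names(metrics)))
  if (any(is.na(metrics$density)) || any(is.na(metrics$centralization))) {
    bad <- which(is.na(metrics$density) | is.na(metrics$centralization))[1]
    stop("undefined density/centralization for row ", bad,
         if ("practice_id" %in% names(metrics))
           paste0(" (practice '", metrics$practice_id[bad], "')") else "",
         call. = FALSE)
  }
  db <- band_of(metrics$density)
  cb <- band_of(metrics$centralization)
  type <- rep("unmapped", nrow(metrics))
  type[db == "high" & cb == "low"] <- "A"
  type[db == "medium" & cb == "medium"] <- "B"
  type[db == "medium" & cb == "low"] <- "C"
  type[db == "low"] <- "D"
  metrics$density_band <- db
  metrics$centralization_band <- cb
  metrics$network_type <- type
  metrics$fully_connected <- metrics$density >= 1 - BAND_TOL
  metrics
}

#' Typology count table per condition
#'
#' Per-condition counts and percentages of the density bands (highly /
#' medium / lowly connected), centralization bands (highly / medium / lowly
#' centralized), network types A-D, and the fully connected special case.
#' Percentages are over the included networks of that condition.
#'
#' @param labels Data frame from [classify_networks()] with a `condition`
#'   column.
#' @return Long data frame: `condition`, `dimension`
#'   (`density` / `centralization` / `type` / `fully_connected`), `level`,
#'   `n`, `pct`.
#' @export
typology_counts <- function(labels) {
  stopifnot(is.data.frame(labels))
  rows <- list()
  for (cn in CONDITIONS) {
    sub <- labels[labels$condition == cn, , drop = FALSE]
    n_tot <- nrow(sub)
    add <- function(dimension, level, n) {
      rows[[length(rows) + 1L]] <<- data.frame(
        condition = cn, dimension = dimension, level = level, n = n,
        pct = if (n_tot > 0) 100 * n / n_tot else 0,
        stringsAsFactors = FALSE)
    }
    for (b in c("high", "medium", "low")) {
      add("density", b, sum(sub$density_band == b))
    }
    for (b in c("high", "medium", "low")) {
      add("centralization", b, sum(sub$centralization_band == b))
    }
    for (tp in NETWORK_TYPES) add("type", tp, sum(sub$network_type == tp))
    add("fully_connected", "yes", sum(sub$fully_connected))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
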