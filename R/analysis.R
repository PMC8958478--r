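#' Run the full information-exchange network analysis on a cohort
#'
#' The three-phase procedure: (1) validation of reported ties via the pooled
#' reciprocity of the directed networks and the [reciprocity_gate()];
#' (2) symmetrization (with single-non-respondent reconstruction) and native
#' network metrics for every practice admitted by the inclusion filter;
#' (3) the density/centralization typology, per-condition summaries,
#' Friedman comparisons across the three conditions, the
#' density-centralization Spearman correlation per condition, and the
#' external-exchange and cardiologist tabulations.
#'
#' If the gate fails (pooled reciprocity not strictly above `gate_threshold`)
#' the returned object has `gate_passed = FALSE` and carries diagnostics but
#' no network metrics: without mutual reporting the undirected representation
#' is not justified.
#'
#' @param coh A validated [cohort()].
#' @param rule Symmetrization rule, `"union"` (default) or `"intersection"`.
#' @param gate_threshold Reciprocity gate threshold (default 0.6).
#' @return A list of class `praxnet_analysis`.
#' @export
analyze_cohort <- function(coh, rule = c("union", "intersection"),
                           gate_threshold = 0.6) {
  rule <- match.arg(rule)
  validate_cohort(coh)
  inclusion <- apply_inclusion_filter(coh)
  recip_inc <- cohort_reciprocity(coh, included_only = TRUE)
  recip_all <- tryCatch(cohort_reciprocity(coh, included_only = FALSE),
                        error = function(e) NULL)
  gate_passed <- reciprocity_gate(recip_inc$reciprocity, gate_threshold)
  out <- list(
    n_practices = length(coh$practices),
    inclusion = inclusion,
    characteristics = summarize_practice_characteristics(coh),
    response = list(all = response_rate(coh, included_only = FALSE),
                    included = response_rate(coh, included_only = TRUE)),
    reciprocity_included = recip_inc,
    reciprocity_all = recip_all,
    gate_threshold = gate_threshold,
    gate_passed = gate_passed,
    rule = rule,
    external_exchange = external_exchange_table(coh),
    cardiologists = list(
      CHD = tryCatch(cardiologist_summary(coh, "CHD"), error = function(e) NULL),
      CHF = tryCatch(cardiologist_summary(coh, "CHF"), error = function(e) NULL))
  )
  if (!gate_passed) {
    out$metrics <- NULL
    class(out) <- "praxnet_analysis"
    return(out)
  }
  metrics <- cohort_metrics(coh, rule = rule)
  labels <- classify_networks(metrics)
  out$metrics <- metrics
  out$labels <- labels
  out$typology <- typology_counts(labels)
  out$condition_summaries <- lapply(CONDITIONS, function(cn)
    condition_summary(metrics, cn))
  names(out$condition_summaries) <- CONDITIONS
  out$friedman <- friedman_by_metric(metrics)
  out$spearman <- spearman_by_condition(metrics)
  class(out) <- "praxnet_analysis"
  out
}

metric_matrix <- function(metrics, col) {
  # practices x conditions matrix of one metric
  pids <- unique(metrics$practice_id)
  m <- sapply(CONDITIONS, function(cn) {
    sub <- metrics[metrics$condition == cn, , drop = FALSE]
    sub[[col]][match(pids, sub$practice_id)]
  })
  m <- matrix(as.numeric(m), nrow = length(pids),
              dimnames = list(pids, CONDITIONS))
  m
}

friedman_by_metric <- function(metrics) {
  out <- lapply(METRIC_COLS, function(col) {
    m <- metric_matrix(metrics, col)
    tryCatch(suppressWarnings(friedman_rank_test(m)), error = function(e) NULL)
  })
  names(out) <- METRIC_COLS
  out
}

spearman_by_condition <- function(metrics) {
  out <- lapply(CONDITIONS, function(cn) {
    sub <- metrics[metrics$condition == cn, , drop = FALSE]
    tryCatch(spearman_rho(sub$density, sub$centralization),
             error = function(e) NULL)
  })
  names(out) <- CONDITIONS
  out
}

#' @export
print.praxnet_analysis <- function(x, ...) {
  cat("Information-exchange network analysis\n")
  cat(sprintf("  Practices: %d read, %d included (%d too few members, %d too many missing)\n",
              x$n_practices, sum(x$inclusion$included),
              sum(x$inclusion$reason == "too_few_members"),
              sum(x$inclusion$reason == "too_many_missing")))
  cat(sprintf("  Pooled reciprocity (included practices): %.2f -> gate %s (threshold %.2f)\n",
              x$reciprocity_included$reciprocity,
              if (x$gate_passed) "passed: undirected networks postulated"
              else "FAILED: analysis stopped", x$gate_threshold))
  if (!x$gate_passed) return(invisible(x))
  for (cn in CONDITIONS) {
    s <- x$condition_summaries[[cn]]
    cat(sprintf("  %s: %d connections total; density mean %.2f, median %.2f; centralization mean %.2f\n",
                cn, s$total_connections, s$density$mean, s$density$median,
                s$centralization$mean))
  }
  fr <- x$friedman$density
  if (!is.null(fr)) {
    cat(sprintf("  Friedman (density across conditions): chi^2 = %.2f, df = %d, p = %.3g\n",
                fr$statistic, fr$df, fr$p_value))
  }
  ty <- x$typology
  tyA <- ty[ty$dimension == "type" & ty$level == "A", ]
  cat("  Type A networks: ",
      paste(sprintf("%s %d (%.1f%%)", tyA$condition, tyA$n, tyA$pct),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.praxnet_analysis <- function(object, ...) {
  print(object)
  if (object$gate_passed) {
    cat("\nTypology counts per condition:\n")
    print(object$typology, row.names = FALSE)
    for (cn in CONDITIONS) {
      sp <- object$spearman[[cn]]
      if (!is.null(sp)) {
        cat(sprintf("Spearman density~centralization, %s: rho = %.2f, p = %.3g\n",
                    cn, sp$rho, sp$p_value))
      }
    }
  }
  invisible(object)
}

fnv1a_hash <- function(x) {
  # small stable hash for manifests (no external digest dependency)
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(path, manifest) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Thin command wrapper over [generate_cohort()]: reads a JSON generator
#' config (missing keys fall back to the [generator_config()] defaults),
#' draws the cohort, writes `cohort.json` and a run manifest.
#'
#' @param config_path Path to a JSON config file, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's seed.
#' @return Invisibly, the generated cohort.
#' @export
cmd_simulate <- function(config_path = NULL, out_dir = ".", seed = NULL) {
  args <- list()
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) stop("config file not found: ", config_path,
                                        call. = FALSE)
    args <- jsonlite::fromJSON(config_path, simplifyVector = TRUE)
    known <- names(formals(generator_config))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!is.null(args$retention) && !identical(args$retention, "independent")) {
      args$retention <- unlist(args$retention)
    }
    if (!is.null(args$external_group_probs)) {
      args$external_group_probs <- unlist(args$external_group_probs)
    }
    if (!is.null(args$cardiologist_prob)) {
      args$cardiologist_prob <- lapply(args$cardiologist_prob, unlist)
    }
  }
  if (!is.null(seed)) args$seed <- as.integer(seed)
  cfg <- do.call(generator_config, args)
  coh <- generate_cohort(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cohort_file <- file.path(out_dir, "cohort.json")
  write_cohort(coh, cohort_file, format = "json")
  write_manifest(file.path(out_dir, "manifest.json"), list(
    command = "simulate",
    config_path = if (is.null(config_path)) NA else config_path,
    config_hash = fnv1a_hash(unclass(cfg)),
    seed = cfg$seed,
    n_practices = length(coh$practices),
    outputs = "cohort.json",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ))
  invisible(coh)
}

analysis_files <- c("inclusion.csv", "metrics.csv", "labels.csv",
                    "typology_counts.csv", "condition_summary.csv",
                    "friedman.csv", "spearman.csv", "external_exchange.csv")

condition_summary_df <- function(summaries) {
  rows <- list()
  for (s in summaries) {
    for (mc in METRIC_COLS) {
      m <- s[[mc]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = s$condition, metric = mc, n = m$n, mean = m$mean,
        sd = m$sd, median = m$median, q25 = m$q25, q75 = m$q75,
        min = m$min, max = m$max,
        total_connections = if (mc == "n_edges") s$total_connections else NA,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyze a cohort file and write all result tables
#'
#' Runs [analyze_cohort()] on a cohort read from disk and writes the
#' inclusion decisions, per-network metrics, typology labels and counts,
#' per-condition summaries, Friedman and Spearman results, the
#' external-exchange table, GraphML exports of every included undirected
#' network, and a run manifest. If the reciprocity gate fails, the
#' diagnostics written so far are kept and the analysis stops.
#'
#' @param cohort_path Path to a cohort JSON file (or CSV directory).
#' @param out_dir Output directory (created if needed).
#' @param format Cohort file format, `"json"` or `"csv"`.
#' @param rule Symmetrization rule.
#' @param gate_threshold Reciprocity gate threshold.
#' @return Invisibly, the `praxnet_analysis` object.
#' @export
cmd_analyze <- function(cohort_path, out_dir = ".", format = "json",
                        rule = "union", gate_threshold = 0.6) {
  coh <- read_cohort(cohort_path, format = format)
  an <- analyze_cohort(coh, rule = rule, gate_threshold = gate_threshold)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE, na = "")
  wcsv(an$inclusion, "inclusion.csv")
  manifest <- list(
    command = "analyze",
    cohort_path = cohort_path,
    rule = rule,
    gate_threshold = gate_threshold,
    n_read = an$n_practices,
    n_included = sum(an$inclusion$included),
    n_excluded_too_few_members = sum(an$inclusion$reason == "too_few_members"),
    n_excluded_too_many_missing = sum(an$inclusion$reason == "too_many_missing"),
    reciprocity_included = an$reciprocity_included$reciprocity,
    gate_passed = an$gate_passed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!an$gate_passed) {
    writeLines(c("Reciprocity gate FAILED:",
                 sprintf("  pooled reciprocity %.3f <= threshold %.2f",
                         an$reciprocity_included$reciprocity, gate_threshold),
                 "  undirected networks are not justified; analysis stopped."),
               file.path(out_dir, "gate_diagnostic.txt"))
    manifest$outputs <- c("inclusion.csv", "gate_diagnostic.txt")
    write_manifest(file.path(out_dir, "manifest.json"), manifest)
    return(invisible(an))
  }
  wcsv(an$metrics, "metrics.csv")
  wcsv(an$labels[, c("practice_id", "condition", "density_band",
                     "centralization_band", "network_type", "fully_connected")],
       "labels.csv")
  wcsv(an$typology, "typology_counts.csv")
  wcsv(condition_summary_df(an$condition_summaries), "condition_summary.csv")
  fr <- do.call(rbind, lapply(names(an$friedman), function(mc) {
    f <- an$friedman[[mc]]
    if (is.null(f)) return(NULL)
    data.frame(metric = mc, statistic = f$statistic, df = f$df,
               p_value = f$p_value, n_blocks = f$n_blocks,
               tie_corrected = f$tie_corrected, stringsAsFactors = FALSE)
  }))
  wcsv(fr, "friedman.csv")
  sp <- do.call(rbind, lapply(names(an$spearman), function(cn) {
    s <- an$spearman[[cn]]
    if (is.null(s)) return(NULL)
    data.frame(condition = cn, rho = s$rho, p_value = s$p_value, n = s$n,
               stringsAsFactors = FALSE)
  }))
  wcsv(sp, "spearman.csv")
  wcsv(an$external_exchange, "external_exchange.csv")
  gdir <- file.path(out_dir, "graphml")
  if (!dir.exists(gdir)) dir.create(gdir)
  dec <- an$inclusion
  coh_included <- coh$practices[dec$included]
  for (pr in coh_included) {
    for (cn in CONDITIONS) {
      un <- symmetrize(build_directed_network(pr, cn), rule = rule)
      export_graphml(un, file.path(gdir, sprintf("%s_%s.graphml",
                                                 pr$practice_id, cn)))
    }
  }
  manifest$outputs <- c(analysis_files, "graphml/")
  write_manifest(file.path(out_dir, "manifest.json"), manifest)
  invisible(an)
}

#' Assemble a human-readable report from analysis outputs
#'
#' Reads the CSV tables written by [cmd_analyze()] and writes a single
#' markdown report with footnotes on the conventions used (union
#' symmetrization, band thresholds, tie-corrected Friedman test).
#'
#' @param out_dir Directory holding the outputs of [cmd_analyze()].
#' @return Invisibly, the path of the written report.
#' @export
cmd_report <- function(out_dir = ".") {
  need <- c("inclusion.csv", "manifest.json")
  for (f in need) {
    if (!file.exists(file.path(out_dir, f))) {
      stop("missing analysis output: ", file.path(out_dir, f), call. = FALSE)
    }
  }
  man <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"))
  inc <- utils::read.csv(file.path(out_dir, "inclusion.csv"))
  lines <- c("# Information-exchange network analysis report", "",
             sprintf("Cohort: `%s`", man$cohort_path),
             sprintf("Practices read: %d; included: %d (excluded: %d with <3 members, %d with >1 non-respondent)",
                     man$n_read, man$n_included,
                     man$n_excluded_too_few_members,
                     man$n_excluded_too_many_missing),
             sprintf("Pooled reciprocity (included practices): %.3f; gate threshold %.2f -> %s",
                     man$reciprocity_included, man$gate_threshold,
                     if (isTRUE(man$gate_passed)) "undirected networks postulated"
                     else "STOPPED"),
             "")
  if (!isTRUE(man$gate_passed)) {
    lines <- c(lines, "Reciprocity gate failed; no network metrics computed.",
               sprintf("Zero included networks analysed (of %d practices read).",
                       man$n_read))
    out <- file.path(out_dir, "report.md")
    writeLines(lines, out)
    return(invisible(out))
  }
  for (f in c("condition_summary.csv", "typology_counts.csv", "friedman.csv")) {
    if (!file.exists(file.path(out_dir, f))) {
      stop("missing analysis output: ", file.path(out_dir, f), call. = FALSE)
    }
  }
  if (man$n_included == 0) {
    lines <- c(lines, "Zero included networks; nothing to summarize.")
  } else {
    cs <- utils::read.csv(file.path(out_dir, "condition_summary.csv"))
    ty <- utils::read.csv(file.path(out_dir, "typology_counts.csv"))
    fr <- utils::read.csv(file.path(out_dir, "friedman.csv"))
    md_table <- function(df) {
      cols <- names(df)
      fmt <- function(v) ifelse(is.na(v), "",
                                ifelse(is.numeric(v), formatC(v, format = "fg",
                                                              digits = 4),
                                       as.character(v)))
      body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |"))
      c(paste0("| ", paste(cols, collapse = " | "), " |"),
        paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
        body)
    }
    lines <- c(lines,
               "## Network characteristics per condition", "",
               md_table(cs), "",
               "## Typology counts", "", md_table(ty), "",
               "## Friedman comparisons across conditions", "",
               md_table(fr), "",
               "### Conventions",
               "- Undirected networks by union symmetrization; a single non-respondent's ties are reconstructed from incoming nominations.",
               "- Bands: low <= 0.33, medium > 0.33-0.67, high > 0.67 (tolerance 1e-9 at the boundaries).",
               "- Friedman test with mid-ranks and tie correction; asymptotic chi-square p-values; alpha = 0.05.",
               "- SD uses the n-1 denominator; IQR is the 25th-75th percentile with linear interpolation.")
  }
  out <- file.path(out_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
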