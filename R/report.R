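#' Assemble a group-level report
#'
#' Aggregates per-ROI junction-census values to one value per animal (the
#' mean of its ROIs, matching the hearts-as-unit-of-analysis convention),
#' tabulates mean +/- SEM per group x condition, and runs the group
#' statistics: two-way ANOVA with Bonferroni post-tests on the imaging
#' metric, Fisher's exact test on tachyarrhythmia incidence, and
#' Mann-Whitney U tests on tachyarrhythmia duration and PVC counts. The
#' report is deterministic: the same inputs always produce byte-identical
#' output (no timestamps).
#'
#' @param quantTable \code{data.frame} with columns \code{animal_id},
#'   \code{group}, \code{condition}, \code{value} (one row per ROI or per
#'   animal); \code{metric} attribute or \code{config$metric} names the
#'   metric (default \code{"end_to_end_pct"}).
#' @param ecgTable Optional \code{data.frame} with columns \code{animal_id},
#'   \code{group}, \code{incidence} (logical), \code{tachyarrhythmia_duration_s},
#'   \code{total_pvcs}; \code{NULL} or empty omits the ECG section with a
#'   notice.
#' @param config Optional list; supported entry \code{metric}.
#'
#' @return List of class \code{"gjlat_report"} with elements
#'   \code{quant_summary}, \code{quant_tests}, \code{ecg_summary},
#'   \code{ecg_tests}, \code{notices}, \code{provenance}.
#' @export
buildReport <- function(quantTable, ecgTable = NULL, config = list()) {
  metric <- config$metric
  if (is.null(metric)) metric <- attr(quantTable, "metric")
  if (is.null(metric)) metric <- "end_to_end_pct"
  need <- c("animal_id", "group", "condition", "value")
  if (!all(need %in% names(quantTable)))
    stop("quantTable must have columns ", paste(need, collapse = ", "))
  notices <- character(0)

  # one value per animal per metric: pre-average ROI-level rows
  perAnimal <- stats::aggregate(value ~ animal_id + group + condition,
                                data = quantTable, FUN = mean)
  perAnimal <- perAnimal[order(perAnimal$group, perAnimal$condition,
                               perAnimal$animal_id), ]

  grp <- split(perAnimal$value,
               list(perAnimal$group, perAnimal$condition), drop = FALSE)
  qs <- do.call(rbind, lapply(names(grp), function(k) {
    v <- grp[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    s <- if (length(v)) summarizeGroup(v) else list(mean = NA_real_,
                                                    sem = NA_real_, n = 0L)
    data.frame(metric = metric, group = parts[1], condition = parts[2],
               mean = s$mean, sem = s$sem, n = s$n, stringsAsFactors = FALSE)
  }))
  qTests <- tryCatch(testResultsToDf(twoWayAnovaBonferroni(perAnimal)),
                     error = function(e) {
                       notices <<- c(notices, paste("ANOVA skipped:",
                                                    conditionMessage(e)))
                       NULL
                     })

  ecgSummary <- NULL; ecgTests <- NULL
  if (is.null(ecgTable) || nrow(ecgTable) == 0L) {
    notices <- c(notices, "ECG section omitted: no input")
  } else {
    needE <- c("animal_id", "group", "incidence",
               "tachyarrhythmia_duration_s", "total_pvcs")
    if (!all(needE %in% names(ecgTable)))
      stop("ecgTable must have columns ", paste(needE, collapse = ", "))
    groups <- sort(unique(ecgTable$group))
    ecgSummary <- do.call(rbind, lapply(groups, function(g) {
      sub <- ecgTable[ecgTable$group == g, ]
      d <- summarizeGroup(sub$tachyarrhythmia_duration_s)
      p <- summarizeGroup(sub$total_pvcs)
      data.frame(group = g, n = nrow(sub),
                 incidence_n = sum(sub$incidence),
                 incidence_pct = 100 * mean(sub$incidence),
                 duration_mean_s = d$mean, duration_sem_s = d$sem,
                 pvcs_mean = p$mean, pvcs_sem = p$sem,
                 stringsAsFactors = FALSE)
    }))
    if (length(groups) == 2L) {
      g1 <- ecgTable[ecgTable$group == groups[1], ]
      g2 <- ecgTable[ecgTable$group == groups[2], ]
      inc <- matrix(c(sum(g1$incidence), sum(!g1$incidence),
                      sum(g2$incidence), sum(!g2$incidence)),
                    2, 2, byrow = TRUE)
      tests <- list(fisherExact(inc),
                    mannWhitney(g1$tachyarrhythmia_duration_s,
                                g2$tachyarrhythmia_duration_s),
                    mannWhitney(g1$total_pvcs, g2$total_pvcs))
      tests[[1]]@comparison <- paste0("incidence: ", groups[1], " vs ", groups[2])
      tests[[2]]@comparison <- paste0("tachyarrhythmia duration: ",
                                      groups[1], " vs ", groups[2])
      tests[[3]]@comparison <- paste0("total PVCs: ", groups[1], " vs ",
                                      groups[2])
      ecgTests <- testResultsToDf(tests)
    } else {
      notices <- c(notices,
                   "ECG tests skipped: exactly two groups are required")
    }
  }
  structure(list(quant_summary = qs, quant_tests = qTests,
                 ecg_summary = ecgSummary, ecg_tests = ecgTests,
                 notices = notices,
                 provenance = list(metric = metric,
                                   package_version =
                                     as.character(utils::packageVersion("gjlat")))),
            class = "gjlat_report")
}

#' Write a report bundle to disk
#'
#' Writes \code{quant_summary.csv}, \code{quant_tests.csv},
#' \code{ecg_summary.csv}, \code{ecg_tests.csv} (as available) and
#' \code{report.json} into \code{dir}. Deterministic for identical input.
#'
#' @param report A \code{"gjlat_report"} from [buildReport()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- character(0)
  for (nm in c("quant_summary", "quant_tests", "ecg_summary", "ecg_tests")) {
    df <- report[[nm]]
    if (is.null(df)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(paths, jp))
}
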