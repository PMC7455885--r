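# Study labeling and scan-selection rules: radiographic-or-visual
# progression labels, severe-vision-loss and biopsy exclusions, and the
# 2-year scan windows for cases and controls.

# logMAR equivalent of the 20/470 severe-loss floor
LOGMAR_SEVERE_LOSS <- log10(470 / 20)

#' Label a subject as progression or no progression
#'
#' Progression is any radiographic flag being true OR a worsening of
#' visual acuity of at least 0.2 logMAR in either eye between successive
#' examinations. Worsening is by default an increase (higher logMAR =
#' worse acuity); set `worsening_direction = "decrease"` to flip.
#'
#' @param record list/object with `va_series` (data frame with
#'   `time_years`, `logmar_od`, `logmar_os`) and `radiographic_flags`
#'   (logical vector per scan); [generate_cohort] subjects qualify
#' @param va_threshold logMAR change that counts as worsening (0.2)
#' @param worsening_direction "increase" (default) or "decrease"
#' @return `list(label, reason)`: label "progression"/"no_progression",
#'   reason a machine-readable string naming the trigger
#' @export
label_progression <- function(record, va_threshold = 0.2,
                              worsening_direction = c("increase", "decrease")) {
  worsening_direction <- match.arg(worsening_direction)
  va <- record$va_series
  flags <- record$radiographic_flags
  if (is.null(va) || nrow(va) == 0L || is.null(flags) || !length(flags))
    stop("insufficient-data error: record needs VA series and scan flags",
         call. = FALSE)
  if (any(flags))
    return(list(label = "progression",
                reason = sprintf("radiographic:scan%d", which(flags)[1L])))
  sgn <- if (worsening_direction == "increase") 1 else -1
  for (eye in c("logmar_od", "logmar_os")) {
    d <- sgn * diff(va[[eye]])
    # tolerance absorbs floating-point error in differences of decimal
    # logMAR readings (0.3 - 0.1 must count as a 0.2 change)
    hit <- which(d >= va_threshold - 1e-9)
    if (length(hit))
      return(list(label = "progression",
                  reason = sprintf("va:%s:exam%d-%d:delta%.2f",
                                   eye, hit[1L], hit[1L] + 1L, d[hit[1L]])))
  }
  list(label = "no_progression", reason = "no_trigger")
}

#' Apply study exclusion rules
#'
#' Excludes subjects with severe vision loss at baseline (20/470 or
#' worse, i.e. logMAR >= log10(470/20) ~ 1.371, a floor effect) or a
#' prior surgical biopsy (white-matter integrity confound). Always
#' returns a decision.
#'
#' @param record list with `baseline_logmar` (numeric, best eye; or a
#'   `va_series` whose first row is used) and optional `prior_biopsy`
#' @return `list(decision, reason)`: decision "include"/"exclude"
#' @export
apply_exclusions <- function(record) {
  if (isTRUE(record$prior_biopsy))
    return(list(decision = "exclude", reason = "prior_biopsy"))
  base <- record$baseline_logmar
  if (is.null(base) && !is.null(record$va_series))
    base <- min(record$va_series$logmar_od[1L], record$va_series$logmar_os[1L])
  if (is.null(base) || !is.finite(base))
    return(list(decision = "include", reason = "no_baseline_va"))
  if (base >= LOGMAR_SEVERE_LOSS)
    return(list(decision = "exclude",
                reason = sprintf("severe_loss:logmar%.3f", base)))
  list(decision = "include", reason = "passed")
}

#' Select the analyzable scans of a subject
#'
#' Cases keep the progression (index) scan plus up to 3 immediately
#' preceding scans within 2 years of it; controls keep their 3 most
#' recent scans, each within 2 years of the most recent. Scan times are
#' years relative to the index scan (index at 0, earlier negative).
#'
#' @param subject list with `scans` (each having `time_years`)
#' @param label "progression" or "no_progression"
#' @param window_years inclusion window (default 2)
#' @return integer indices of the kept scans in chronological order
#' @export
select_scans <- function(subject, label, window_years = 2) {
  times <- vapply(subject$scans, `[[`, 0, "time_years")
  ord <- order(times)
  times <- times[ord]
  n <- length(times)
  index_time <- times[n]
  in_window <- which(index_time - times <= window_years)
  if (label == "progression") {
    # index scan + up to 3 immediately preceding scans inside the window
    prev <- setdiff(in_window, n)
    keep <- c(utils::tail(prev, 3L), n)
  } else {
    keep <- utils::tail(in_window, 3L)
  }
  ord[keep]
}

#' Label, screen and window a whole cohort
#'
#' Runs [apply_exclusions], [label_progression] and [select_scans] over a
#' cohort, drops excluded subjects, restricts each remaining subject to
#' its selected scans, and relabels `group` as case/control from the
#' progression decision. Each decision carries its reason in the returned
#' manifest.
#'
#' @param cohort list of subjects ([generate_cohort] output or
#'   equivalently shaped records)
#' @param va_threshold,worsening_direction forwarded to
#'   [label_progression]
#' @return `list(cohort, manifest)`: the filtered cohort and a data frame
#'   of per-subject decisions (subject_id, decision, label, reasons,
#'   selected scan ids)
#' @export
apply_cohort_rules <- function(cohort, va_threshold = 0.2,
                               worsening_direction = "increase") {
  out <- list(); rows <- list()
  for (subj in cohort) {
    exc <- apply_exclusions(subj)
    if (exc$decision == "exclude") {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, decision = "exclude",
        label = NA_character_, reason = exc$reason, scans = "",
        stringsAsFactors = FALSE)
      next
    }
    lab <- label_progression(subj, va_threshold, worsening_direction)
    keep <- select_scans(subj, lab$label)
    if (!length(keep)) {
      warning(sprintf("subject %s dropped: no usable scans", subj$subject_id),
              call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, decision = "exclude",
        label = lab$label, reason = "no_usable_scans", scans = "",
        stringsAsFactors = FALSE)
      next
    }
    subj$scans <- subj$scans[keep]
    subj$masks <- subj$masks[keep]
    subj$streamlines <- subj$streamlines[keep]
    subj$radiographic_flags <- subj$radiographic_flags[keep]
    subj$group <- if (lab$label == "progression") "case" else "control"
    out[[length(out) + 1L]] <- subj
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subj$subject_id, decision = "include",
      label = lab$label, reason = paste(exc$reason, lab$reason, sep = ";"),
      scans = paste(keep, collapse = ","), stringsAsFactors = FALSE)
  }
  list(cohort = out, manifest = do.call(rbind, rows))
}

#' Read a clinical records CSV
#'
#' Expected columns: subject_id, scan_id, time_years, logmar_od,
#' logmar_os, radiographic_progression (0/1). Returns one record per
#' subject, shaped for [label_progression] / [apply_exclusions].
#'
#' @param path CSV path
#' @return named list of records
#' @export
read_clinical_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "scan_id", "time_years", "logmar_od", "logmar_os",
            "radiographic_progression")
  if (!all(need %in% colnames(df)))
    stop("clinical CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  recs <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$time_years), ]
    list(subject_id = d$subject_id[1L],
         va_series = data.frame(time_years = d$time_years,
                                logmar_od = d$logmar_od,
                                logmar_os = d$logmar_os),
         radiographic_flags = d$radiographic_progression != 0,
         scan_ids = d$scan_id)
  })
  recs[order(names(recs))]
}

#' Write the clinical records CSV for a cohort
#'
#' @param cohort list of subjects
#' @param path output CSV path
#' @export
write_clinical_records <- function(cohort, path) {
  rows <- lapply(cohort, function(subj) {
    n <- nrow(subj$va_series)
    data.frame(subject_id = subj$subject_id,
               scan_id = sprintf("%s_s%d", subj$subject_id, seq_len(n)),
               time_years = subj$va_series$time_years,
               logmar_od = subj$va_series$logmar_od,
               logmar_os = subj$va_series$logmar_os,
               radiographic_progression = as.integer(subj$radiographic_flags),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
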