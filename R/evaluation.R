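# Closeness-accuracy evaluation.
#
# The system's diagnosis set is compared with an expert's at three
# cumulative phases of a visit — first suspicions, initial diagnosis,
# final diagnosis.  With s = |system set|, e = |expert set|,
# c = |intersection| and D the size of the disease universe, the metric is
#
#     accuracy = (c / e) * ((D - |s - e|) / D)
#
# i.e. the recall of the expert's diagnoses, discounted by how far the two
# set sizes diverge relative to the universe.  It is 1 exactly when the
# sets coincide, and near zero when the system hedges with everything while
# the expert names one disease ((1/1) * (D - (D-1))/D = 1/D).

PHASES <- c("first_suspicions", "initial_diagnosis", "final_diagnosis")

#' Closeness accuracy of a system diagnosis set against an expert's
#'
#' @param s number of diseases the system considers possible.
#' @param e number of diseases the expert considers possible (must be
#'   at least 1: an empty expert set makes the comparison undefined).
#' @param c number of diseases common to the two sets.
#' @param D size of the disease universe.
#' @return a value in `[0, 1]`; equal to 1 iff `s == e == c`.
#' @examples
#' closeness_accuracy(s = 4, e = 5, c = 3, D = 137)
#' @export
closeness_accuracy <- function(s, e, c, D) {
  if (any(e < 1)) stop("expert diagnosis set is empty: comparison undefined")
  if (any(D < 1) || any(s < 0) || any(c < 0) ||
      any(c > pmin(s, e)) || any(s > D) || any(e > D)) {
    stop("invalid comparison input: need 0 <= c <= min(s, e), s <= D, e <= D, D >= 1")
  }
  (c / e) * ((D - abs(s - e)) / D)
}

#' Construct a phased patient case
#'
#' @param case_id identifier.
#' @param findings list of up to 3 character vectors (or [finding_set()]s)
#'   of condition terms, one per phase; findings are cumulative — each
#'   phase must contain the previous phase's findings.
#' @param expert list of character vectors of disease codes, the expert's
#'   diagnosis set per phase (may contain empty vectors for phases that are
#'   not evaluated).
#' @param group presentation group of the case (default `"other"`).
#' @param target optional ground-truth disease code (synthetic cases).
#' @return an object of class `patient_case`.
#' @export
patient_case <- function(case_id, findings, expert, group = "other", target = NULL) {
  stopifnot(is.list(findings), length(findings) >= 1L, length(findings) <= 3L,
            is.list(expert), length(expert) == length(findings))
  findings <- lapply(findings, as_finding_set)
  for (i in seq_along(findings)[-1L]) {
    if (!all(findings[[i - 1L]] %in% findings[[i]])) {
      stop("case ", case_id, ": findings are not cumulative (phase ", i,
           " does not contain phase ", i - 1L, ")")
    }
  }
  expert <- lapply(expert, function(x) sort(unique(toupper(canon_token(as.character(x))))))
  structure(
    list(case_id = as.character(case_id), group = canon_token(group),
         findings = findings, expert = expert,
         target = if (is.null(target)) NULL else toupper(canon_token(target))),
    class = "patient_case")
}

#' Evaluate one patient case against a knowledge base
#'
#' Runs [plausible_diagnoses()] on each phase's cumulative findings and
#' scores the system set against the expert's with
#' [closeness_accuracy()]; `D` is the size of the knowledge base's
#' registry.  Phases with an empty expert set are skipped with a warning.
#'
#' @param kb a [knowledge_base()].
#' @param case a [patient_case()].
#' @return data.frame of accuracy records, one row per evaluated phase:
#'   `case_id`, `group`, `phase` (ordinal), `phase_name`, `s`, `e`, `c`,
#'   `D`, `accuracy`.
#' @export
evaluate_case <- function(kb, case) {
  stopifnot(inherits(case, "patient_case"))
  out <- list()
  for (i in seq_along(case$findings)) {
    e_set <- case$expert[[i]]
    if (length(e_set) == 0L) {
      warning("case ", case$case_id, ": empty expert set at phase ", i,
              " — phase skipped")
      next
    }
    sys <- plausible_diagnoses(kb, case$findings[[i]])$plausible
    s <- length(sys); e <- length(e_set); c <- length(intersect(sys, e_set))
    out[[length(out) + 1L]] <- data.frame(
      case_id = case$case_id, group = case$group, phase = i,
      phase_name = PHASES[i], s = s, e = e, c = c, D = kb$D,
      accuracy = closeness_accuracy(s, e, c, kb$D),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(case_id = character(), group = character(),
                      phase = integer(), phase_name = character(),
                      s = integer(), e = integer(), c = integer(),
                      D = integer(), accuracy = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Evaluate a whole cohort
#' @param kb a [knowledge_base()].
#' @param cohort list of [patient_case()]s.
#' @return the row-bound accuracy records of [evaluate_case()].
#' @export
evaluate_cohort <- function(kb, cohort) {
  do.call(rbind, lapply(cohort, evaluate_case, kb = kb))
}

#' Summarize accuracy records over a cohort
#'
#' @param records accuracy records ([evaluate_case()] output, row-bound
#'   over cases); every case must have all three phases.
#' @return a `cohort_summary`: list with `n_cases`; `phase_means` (named
#'   numeric, mean accuracy per phase); `group_phase_means` (data.frame
#'   `group`, `phase`, `mean_accuracy`); `frac_ge_0.8_all_phases`
#'   (fraction of cases at or above 0.8 in every phase);
#'   `frac_case_mean_gt_0.5` and `frac_case_mean_gt_0.9` (fractions of
#'   cases whose three-phase average exceeds 0.5 / 0.9).
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("empty cohort")
  per_case <- table(records$case_id)
  if (any(per_case != 3L)) {
    stop("every case must carry records for all three phases; offending case(s): ",
         paste(names(per_case)[per_case != 3L], collapse = ", "))
  }
  phase_means <- tapply(records$accuracy, records$phase_name, mean)
  phase_means <- stats::setNames(as.numeric(phase_means[PHASES]), PHASES)
  gp <- stats::aggregate(accuracy ~ group + phase, data = records, FUN = mean)
  names(gp)[names(gp) == "accuracy"] <- "mean_accuracy"
  gp <- gp[order(gp$group, gp$phase), , drop = FALSE]
  rownames(gp) <- NULL
  by_case_min <- tapply(records$accuracy, records$case_id, min)
  by_case_mean <- tapply(records$accuracy, records$case_id, mean)
  structure(list(
    n_cases = length(per_case),
    phase_means = phase_means,
    group_phase_means = gp,
    frac_ge_0.8_all_phases = mean(by_case_min >= 0.8),
    frac_case_mean_gt_0.5 = mean(by_case_mean > 0.5),
    frac_case_mean_gt_0.9 = mean(by_case_mean > 0.9)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort summary> ", x$n_cases, " case(s)\n", sep = "")
  cat(sprintf("  mean accuracy: %s\n",
              paste(sprintf("%s %.3f", names(x$phase_means), x$phase_means),
                    collapse = ", ")))
  cat(sprintf("  cases >= 0.8 in all phases: %.0f%%\n",
              100 * x$frac_ge_0.8_all_phases))
  cat(sprintf("  case-average > 0.5: %.0f%%; > 0.9: %.0f%%\n",
              100 * x$frac_case_mean_gt_0.5, 100 * x$frac_case_mean_gt_0.9))
  invisible(x)
}

#' Cohort summary as JSON
#' @param summary a `cohort_summary`.
#' @return a length-one JSON string.
#' @export
summary_to_json <- function(summary) {
  jsonlite::toJSON(unclass(summary), auto_unbox = TRUE, dataframe = "rows",
                   digits = NA, pretty = TRUE)
}

#' Write a cohort as JSON Lines (one case per line)
#' @param cohort list of [patient_case()]s.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  lines <- vapply(cohort, function(case) {
    jsonlite::toJSON(list(
      case_id = case$case_id, group = case$group,
      findings = lapply(case$findings, unclass),
      expert = case$expert,
      target = case$target
    ), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort from JSON Lines
#' @param path file path.
#' @return list of [patient_case()]s.
#' @export
read_cohort <- function(path) {
  lapply(readLines(path), function(line) {
    doc <- jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    patient_case(
      case_id = doc$case_id,
      findings = lapply(doc$findings, as.character),
      expert = lapply(doc$expert, as.character),
      group = doc$group %||% "other",
      target = doc$target)
  })
}
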