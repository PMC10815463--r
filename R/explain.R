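# Explanations: unravel the arguments behind a diagnosis.
#
# For a plausible disease, the explanation is the winning scenario row —
# its effective conditions are all satisfied by the findings — plus the
# strengtheners: conditions in deeper, not-yet-matched descendant rows that
# still select the disease, i.e. information that would make the case more
# specific.  For a disease argued for but overridden, the explanation
# points at the maximal matched row carrying the deeper scenario that its
# own arguments could not match.

#' Explain the verdict for one disease
#'
#' @param kb a [knowledge_base()].
#' @param findings the [finding_set()] the result was computed from.
#' @param result the [plausible_diagnoses()] result for those findings.
#' @param disease a disease code present in the knowledge-base registry.
#' @return an `explanation`: list with `disease`; `verdict` one of
#'   `"plausible"`, `"defeated"`, `"no-evidence"`; `supporting` (records of
#'   `table_id`, `row_id`, `conditions` — the winning row's effective
#'   condition groups, all satisfied when plausible); `strengtheners`
#'   (records of `table_id`, `row_id`, `conditions` — unsatisfied groups in
#'   deeper rows still selecting the disease); `defeated_by` (for excluded
#'   diseases: the maximal matched row and its conditions).
#' @export
explain <- function(kb, findings, result, disease) {
  disease <- toupper(canon_token(disease))
  if (!disease %in% kb$registry$code) stop("unknown disease code: ", disease)
  findings <- as_finding_set(findings)
  empty <- structure(list(disease = disease, verdict = "no-evidence",
                          supporting = list(), strengtheners = list(),
                          defeated_by = list()),
                     class = "explanation")
  if (disease %in% result$plausible) {
    wins <- result$winning_arguments[[disease]]
    supporting <- lapply(seq_len(nrow(wins)), function(i) {
      tab <- kb$tables[[wins$table_id[i]]]
      row <- tab$rows[[wins$row_id[i]]]
      list(table_id = tab$table_id, row_id = row$row_id,
           conditions = row$effective)
    })
    strengtheners <- list()
    for (i in seq_len(nrow(wins))) {
      tab <- kb$tables[[wins$table_id[i]]]
      matched <- result$matched_rows[[tab$table_id]]$matched
      for (id in row_descendants(tab, wins$row_id[i])) {
        r <- tab$rows[[id]]
        if (id %in% matched || !disease %in% r$select) next
        groups <- Filter(function(g) !group_satisfied(g, findings), r$adds)
        if (length(groups)) {
          strengtheners[[length(strengtheners) + 1L]] <-
            list(table_id = tab$table_id, row_id = id, conditions = groups)
        }
      }
    }
    out <- empty
    out$verdict <- "plausible"
    out$supporting <- supporting
    out$strengtheners <- strengtheners
    return(out)
  }
  hit <- result$defeats[result$defeats$disease == disease, , drop = FALSE]
  if (nrow(hit)) {
    out <- empty
    out$verdict <- "defeated"
    out$defeated_by <- lapply(seq_len(nrow(hit)), function(i) {
      tab <- kb$tables[[hit$table_id[i]]]
      row <- tab$rows[[hit$row_id[i]]]
      list(table_id = tab$table_id, row_id = row$row_id,
           conditions = row$effective)
    })
    return(out)
  }
  empty
}

# all descendant row ids of `row_id`, in table order
row_descendants <- function(tab, row_id) {
  out <- character()
  frontier <- row_id
  while (length(frontier)) {
    kids <- names(tab$rows)[vapply(tab$rows, function(r) {
      !is.na(r$parent) && r$parent %in% frontier
    }, logical(1))]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' @export
format.explanation <- function(x, ...) {
  fmt_conds <- function(recs) {
    paste(vapply(recs, function(rec) {
      paste0(paste(vapply(rec$conditions, format_group, character(1)),
                   collapse = " & "),
             " (", rec$table_id, "/", rec$row_id, ")")
    }, character(1)), collapse = "; ")
  }
  switch(x$verdict,
    plausible = {
      line <- paste0("PLAUSIBLE: ", x$disease, " because ", fmt_conds(x$supporting))
      if (length(x$strengtheners)) {
        line <- paste0(line, "; would be strengthened by ", fmt_conds(x$strengtheners))
      }
      line
    },
    defeated = paste0("DEFEATED: ", x$disease,
                      " — overridden by the more specific scenario ",
                      fmt_conds(x$defeated_by)),
    paste0("NO EVIDENCE: ", x$disease,
           " — no matched scenario argues for this disease"))
}

#' @export
print.explanation <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' Rank the conditions worth establishing next
#'
#' Lists every condition group that (a) is not satisfied by the current
#' findings and (b) appears in a not-yet-matched descendant of a maximal
#' matched row — i.e. the questions that could push some table to a more
#' specific scenario.  Each candidate is scored by its discrimination: the
#' current plausible-set size minus the worst-case (largest) plausible-set
#' size over the group's alternatives when established, floored at zero.
#' Ranked by discrimination descending, ties broken lexicographically by
#' the group's canonical rendering.  Empty when every matched table is
#' already matched at a leaf.
#'
#' @param kb a [knowledge_base()].
#' @param findings a [finding_set()] or character vector of terms.
#' @return data.frame with columns `condition` (canonical group
#'   rendering), `tables_affected` (comma-separated table ids),
#'   `discrimination`, `rank`.
#' @export
candidate_queries <- function(kb, findings) {
  findings <- as_finding_set(findings)
  base <- plausible_diagnoses(kb, findings)
  cand <- list()  # key -> list(group, tables)
  for (tid in names(base$matched_rows)) {
    tab <- kb$tables[[tid]]
    mr <- base$matched_rows[[tid]]
    for (top in mr$maximal) {
      for (id in row_descendants(tab, top)) {
        if (id %in% mr$matched) next
        for (g in tab$rows[[id]]$adds) {
          if (group_satisfied(g, findings)) next
          key <- format_group(g)
          if (is.null(cand[[key]])) cand[[key]] <- list(group = g, tables = character())
          cand[[key]]$tables <- union(cand[[key]]$tables, tid)
        }
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(condition = character(), tables_affected = character(),
                      discrimination = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  n_now <- length(base$plausible)
  rows <- lapply(cand, function(x) {
    worst <- max(vapply(unclass(x$group), function(alt) {
      length(plausible_diagnoses(kb, finding_set(c(unclass(findings), alt)))$plausible)
    }, integer(1)))
    data.frame(condition = format_group(x$group),
               tables_affected = paste(sort(x$tables), collapse = ","),
               discrimination = max(0L, n_now - worst),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$discrimination, out$condition), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
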