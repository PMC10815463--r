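# The argumentation engine.
#
# Matching a scenario row means every one of its effective condition groups
# is satisfied by the current findings.  Each (matched row, selected
# disease) pair yields an argument; within one table, arguments from deeper
# rows are stronger than arguments from rows above them, while arguments
# from different tables are incomparable.  Arguments for different diseases
# are counterarguments of each other.  The dialectic selection keeps, per
# table, the diseases whose strongest supporting argument is not overridden
# by a strictly stronger counterargument; because cross-table arguments are
# incomparable, a multi-complaint patient gets the union of the per-table
# verdicts.

#' Match the rows of a table against a finding set
#'
#' A row is matched iff every condition group in its effective conditions
#' is satisfied by the findings.  Maximal rows are matched rows with no
#' matched descendant — the most specific scenarios the current information
#' reaches.  Matching of an ancestor is implied by any matched descendant
#' (effective conditions only grow down the tree).
#'
#' @param table a [diagnostic_table()].
#' @param findings a [finding_set()] (or character vector of terms).
#' @return list with `matched` and `maximal`: character vectors of row ids
#'   in table order.
#' @export
match_rows <- function(table, findings) {
  findings <- as_finding_set(findings)
  matched <- names(table$rows)[vapply(table$rows, function(r) {
    all(vapply(r$effective, group_satisfied, logical(1), findings = findings))
  }, logical(1))]
  # ancestor closure sanity: a matched row's parent must be matched
  for (id in matched) {
    p <- table$rows[[id]]$parent
    stopifnot(is.na(p) || p %in% matched)
  }
  has_matched_child <- vapply(matched, function(id) {
    any(vapply(table$rows[matched], function(r) identical(r$parent, id), logical(1)))
  }, logical(1))
  list(matched = matched, maximal = matched[!has_matched_child])
}

as_finding_set <- function(findings) {
  if (inherits(findings, "finding_set")) findings else finding_set(findings)
}

#' Build all arguments supported by the current findings
#'
#' One argument per (matched row, selected disease) pair across every table
#' of the knowledge base; rows that are not matched contribute nothing.
#' The argument's strength rank within its table is the row depth.
#'
#' @param kb a [knowledge_base()].
#' @param findings a [finding_set()] or character vector of terms.
#' @return data.frame with columns `disease`, `table_id`, `row_id`, `depth`.
#' @export
build_arguments <- function(kb, findings) {
  findings <- as_finding_set(findings)
  out <- list()
  for (tab in kb$tables) {
    matched <- match_rows(tab, findings)$matched
    for (id in matched) {
      r <- tab$rows[[id]]
      if (length(r$select)) {
        out[[length(out) + 1L]] <- data.frame(
          disease = r$select, table_id = tab$table_id, row_id = id,
          depth = r$depth, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(disease = character(), table_id = character(),
                      row_id = character(), depth = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Compare the strength of two arguments
#'
#' Within one table, the deeper argument is stronger and equal depths are
#' equal; arguments from different tables are incomparable.  The relation
#' is antisymmetric and transitive within a table.
#'
#' @param a,b arguments: lists or one-row data.frames with at least
#'   `table_id` and `depth`.
#' @return one of `"stronger"`, `"weaker"`, `"equal"`, `"incomparable"`
#'   (the verdict for `a` relative to `b`).
#' @export
compare_strength <- function(a, b) {
  if (!identical(as.character(a$table_id), as.character(b$table_id))) {
    return("incomparable")
  }
  if (a$depth > b$depth) "stronger" else if (a$depth < b$depth) "weaker" else "equal"
}

#' Dialectic selection of the plausible diagnosis set
#'
#' Per table with at least one matched row: every disease selected in a
#' matched row is argued for at the depth of that row; a disease's case is
#' overridden when some other disease is argued at a strictly greater
#' depth, i.e. the table's verdict is the set of diseases whose best
#' supporting depth equals the table's maximum supported depth.  Diseases
#' argued for in a table but absent from its verdict are recorded as
#' defeated there, with reason `"outranked"` — or `"overridden-elsewhere"`
#' when another table's verdict keeps them plausible anyway (cross-table
#' arguments being incomparable).  The global plausible set is the union of
#' the per-table verdicts.  Deterministic for fixed inputs.
#'
#' @param kb a [knowledge_base()].
#' @param findings a [finding_set()] or character vector of terms.
#' @return a `diagnosis_result`: list with
#'   \describe{
#'     \item{plausible}{sorted character vector of disease codes;}
#'     \item{winning_arguments}{named list, disease to data.frame of the
#'       strongest supporting arguments in each table whose verdict
#'       includes it;}
#'     \item{defeats}{data.frame `disease`, `table_id`, `row_id` (a maximal
#'       matched row carrying the overriding scenario), `reason`;}
#'     \item{matched_rows}{per table id, the `matched` and `maximal` row
#'       sets.}
#'   }
#' @export
plausible_diagnoses <- function(kb, findings) {
  findings <- as_finding_set(findings)
  verdicts <- list()       # table_id -> character
  best_depths <- list()    # table_id -> named integer (per disease)
  matched_rows <- list()
  defeat_rows <- list()
  for (tab in kb$tables) {
    mr <- match_rows(tab, findings)
    if (!length(mr$matched)) next
    matched_rows[[tab$table_id]] <- mr
    depths <- integer(0)
    for (id in mr$matched) {
      r <- tab$rows[[id]]
      for (d in r$select) {
        depths[d] <- max(depths[d], r$depth, na.rm = TRUE)
      }
    }
    if (!length(depths)) next
    top <- max(depths)
    verdicts[[tab$table_id]] <- sort(names(depths)[depths == top])
    best_depths[[tab$table_id]] <- depths
  }
  plausible <- sort(unique(as.character(unlist(verdicts, use.names = FALSE))))
  # defeat records, each anchored at a maximal matched row that carries
  # (on its root path) the deepest supported scenario of the table
  defeats <- list()
  for (tid in names(verdicts)) {
    depths <- best_depths[[tid]]
    losers <- names(depths)[depths < max(depths)]
    if (!length(losers)) next
    anchor <- defeat_anchor(kb$tables[[tid]], matched_rows[[tid]], max(depths))
    for (d in sort(losers)) {
      defeats[[length(defeats) + 1L]] <- data.frame(
        disease = d, table_id = tid, row_id = anchor,
        reason = if (d %in% plausible) "overridden-elsewhere" else "outranked",
        stringsAsFactors = FALSE)
    }
  }
  defeats <- if (length(defeats)) do.call(rbind, defeats) else
    data.frame(disease = character(), table_id = character(),
               row_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  winning <- lapply(stats::setNames(plausible, plausible), function(d) {
    out <- list()
    for (tid in names(verdicts)) {
      if (!d %in% verdicts[[tid]]) next
      depth <- best_depths[[tid]][[d]]
      tab <- kb$tables[[tid]]
      rows <- names(tab$rows)[vapply(tab$rows, function(r) {
        r$depth == depth && d %in% r$select
      }, logical(1))]
      rows <- intersect(rows, matched_rows[[tid]]$matched)
      out[[length(out) + 1L]] <- data.frame(
        disease = d, table_id = tid, row_id = rows, depth = depth,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  structure(
    list(plausible = plausible, winning_arguments = winning,
         defeats = defeats, matched_rows = matched_rows),
    class = "diagnosis_result")
}

# a maximal matched row whose root path passes through a matched row of
# depth `top` with a non-empty selection (the overriding scenario)
defeat_anchor <- function(tab, mr, top) {
  deep <- mr$matched[vapply(mr$matched, function(id) {
    r <- tab$rows[[id]]
    r$depth == top && length(r$select) > 0L
  }, logical(1))]
  target <- deep[[1L]]
  for (id in mr$maximal) {
    cur <- id
    while (!is.na(cur)) {
      if (cur == target) return(id)
      cur <- tab$rows[[cur]]$parent
    }
  }
  target  # unreachable in a well-formed table; defensive
}

#' @export
print.diagnosis_result <- function(x, ...) {
  cat("<diagnosis> plausible: ",
      if (length(x$plausible)) paste(x$plausible, collapse = ", ") else "(none)",
      "\n", sep = "")
  if (nrow(x$defeats)) {
    cat("  defeated: ",
        paste(unique(x$defeats$disease[x$defeats$reason == "outranked"]),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export a diagnosis result as JSON
#' @param result a `diagnosis_result`.
#' @return a length-one JSON string.
#' @export
diagnosis_to_json <- function(result) {
  jsonlite::toJSON(list(
    plausible = result$plausible,
    winning_arguments = lapply(result$winning_arguments, function(df) {
      df[, c("table_id", "row_id", "depth")]
    }),
    defeats = result$defeats,
    matched_rows = result$matched_rows
  ), auto_unbox = FALSE, dataframe = "rows", pretty = TRUE)
}
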