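# Knowledge-base data model: disease registry, scenario rows, diagnostic
# tables, and the knowledge base that bundles them.
#
# A diagnostic table is rooted at a presenting complaint (its trigger
# group).  Rows form a tree of increasingly specific scenarios: each row
# contributes its own condition groups ("adds") on top of everything its
# ancestors require, and marks the subset of the table's disease columns
# still supported in that scenario.  Effective conditions (own plus all
# ancestors') are resolved once, at construction time.

#' Construct a disease registry
#'
#' The registry is the disease universe of a knowledge base; its size is
#' the `D` of the closeness-accuracy metric.
#'
#' @param code character vector of short unique uppercase codes (e.g. `BV`).
#' @param label human-readable names (recycled to `""` if missing).
#' @param group presentation group of each disease (one of the seven
#'   presentation groups, or `"other"`).
#' @return a `data.frame` with columns `code`, `label`, `group`.
#' @export
disease_registry <- function(code, label = NULL, group = NULL) {
  code <- toupper(canon_token(code))
  if (any(!nzchar(code))) stop("disease codes must be non-empty")
  if (anyDuplicated(code)) {
    stop("duplicate disease codes: ",
         paste(unique(code[duplicated(code)]), collapse = ", "))
  }
  n <- length(code)
  if (is.null(label)) label <- rep("", n)
  if (is.null(group)) group <- rep("other", n)
  data.frame(code = code, label = as.character(label),
             group = canon_token(as.character(group)),
             stringsAsFactors = FALSE)
}

#' Construct a scenario row
#'
#' @param row_id identifier, unique within its table.
#' @param parent identifier of the parent row, or `NA` for the root.
#' @param adds list of condition groups (or strings parsed by
#'   [parse_group()]): the conditions this row adds to its ancestors'.
#' @param select character vector of disease codes marked as supported in
#'   this scenario (may be empty).
#' @return an object of class `scenario_row`; `effective` and `depth` are
#'   filled in by [diagnostic_table()].
#' @export
scenario_row <- function(row_id, parent = NA_character_, adds, select = character()) {
  if (!is.list(adds)) adds <- as.list(adds)
  adds <- lapply(adds, function(g) if (inherits(g, "cond_group")) g else parse_group(g))
  structure(
    list(row_id = as.character(row_id),
         parent = if (is.null(parent) || is.na(parent)) NA_character_ else as.character(parent),
         adds = adds,
         effective = NULL,
         select = toupper(canon_token(as.character(select))),
         depth = NA_integer_),
    class = "scenario_row"
  )
}

#' Construct a diagnostic table
#'
#' Resolves the row hierarchy: checks parent references, rejects cycles,
#' computes each row's depth (root = 1) and its effective conditions (its
#' own groups united with all ancestors').
#'
#' @param table_id identifier, unique within the knowledge base.
#' @param trigger the presenting-complaint condition group (string or
#'   `cond_group`) that heads the table.
#' @param columns ordered character vector of disease codes (the table's
#'   disease columns).
#' @param rows list of [scenario_row()]s.
#' @return an object of class `diagnostic_table`.
#' @export
diagnostic_table <- function(table_id, trigger, columns, rows) {
  if (!inherits(trigger, "cond_group")) trigger <- parse_group(trigger)
  columns <- toupper(canon_token(columns))
  ids <- vapply(rows, function(r) r$row_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in table ", table_id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(rows) <- ids
  parents <- vapply(rows, function(r) r$parent, character(1))
  bad <- !is.na(parents) & !(parents %in% ids)
  if (any(bad)) {
    stop("table ", table_id, ": unknown parent row ",
         paste(parents[bad], collapse = ", "))
  }
  # depth + effective conditions by walking up; cycle check via path length
  n <- length(rows)
  for (id in ids) {
    path <- character()
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% path || length(path) > n) {
        stop("table ", table_id, ": cyclic parent references at row ", id)
      }
      path <- c(cur, path)  # root first
      cur <- rows[[cur]]$parent
    }
    rows[[id]]$depth <- length(path)
    eff <- list()
    seen <- character()
    for (p in path) {
      for (g in rows[[p]]$adds) {
        key <- format_group(g)
        if (!key %in% seen) { eff[[length(eff) + 1L]] <- g; seen <- c(seen, key) }
      }
    }
    rows[[id]]$effective <- eff
  }
  structure(
    list(table_id = as.character(table_id), trigger = trigger,
         columns = columns, rows = rows),
    class = "diagnostic_table"
  )
}

#' Construct a knowledge base
#'
#' @param registry a [disease_registry()] (the disease universe; `D` is its
#'   number of rows).
#' @param tables list of [diagnostic_table()]s.
#' @return an object of class `knowledge_base` with fields `registry`,
#'   `tables` (named by table id) and `D`.
#' @export
knowledge_base <- function(registry, tables = list()) {
  stopifnot(is.data.frame(registry), all(c("code", "label", "group") %in% names(registry)))
  ids <- vapply(tables, function(t) t$table_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate table ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(tables) <- ids
  structure(
    list(registry = registry, tables = tables, D = nrow(registry)),
    class = "knowledge_base"
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge base> ", length(x$tables), " table(s), D = ", x$D,
      " disease(s)\n", sep = "")
  for (t in x$tables) {
    cat("  ", t$table_id, ": trigger ", format_group(t$trigger), ", ",
        length(t$rows), " row(s), ", length(t$columns), " column(s)\n", sep = "")
  }
  invisible(x)
}

#' Validate a knowledge base
#'
#' Mechanical consistency checks.  Errors: duplicate or unregistered
#' disease codes, rows selecting codes absent from their table's columns,
#' multiple roots, unreachable rows, a root that does not require the
#' table's trigger, or effective conditions that disagree with the union of
#' the root path.  Warnings: a child row whose selected set is not a subset
#' of its parent's (permitted, but the printed exemplars shrink
#' monotonically down the hierarchy).
#'
#' @param kb a [knowledge_base()].
#' @return a `validation_report`: list with `ok` (no errors) and `issues`
#'   (data.frame of severity, table_id, row_id, message).
#' @export
validate_kb <- function(kb) {
  issues <- list()
  add <- function(severity, table_id, row_id, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, table_id = table_id, row_id = row_id,
      message = message, stringsAsFactors = FALSE)
  }
  if (nrow(kb$registry) < 1L) add("error", NA, NA, "empty disease registry")
  if (anyDuplicated(kb$registry$code)) {
    add("error", NA, NA, "duplicate codes in registry")
  }
  for (tab in kb$tables) {
    tid <- tab$table_id
    unknown <- setdiff(tab$columns, kb$registry$code)
    if (length(unknown)) {
      add("error", tid, NA, paste0("disease columns not in registry: ",
                                   paste(unknown, collapse = ", ")))
    }
    roots <- names(tab$rows)[vapply(tab$rows, function(r) is.na(r$parent), logical(1))]
    if (length(roots) != 1L) {
      add("error", tid, NA, paste0("expected exactly one root row, found ",
                                   length(roots)))
    }
    for (r in tab$rows) {
      stray <- setdiff(r$select, tab$columns)
      if (length(stray)) {
        add("error", tid, r$row_id,
            paste0("selected codes not among table columns: ",
                   paste(stray, collapse = ", ")))
      }
      if (is.na(r$parent)) {
        keys <- vapply(r$adds, format_group, character(1))
        if (!(format_group(tab$trigger) %in% keys)) {
          add("error", tid, r$row_id,
              "root row does not require the table's presenting trigger")
        }
      } else {
        parent <- tab$rows[[r$parent]]
        if (r$depth != parent$depth + 1L) {
          add("error", tid, r$row_id, "depth inconsistent with parent")
        }
        if (!all(r$select %in% parent$select)) {
          add("warning", tid, r$row_id,
              "selected set is not a subset of the parent row's")
        }
        # effective must equal own ∪ ancestors' (recomputed)
        want <- unique(c(vapply(parent$effective, format_group, character(1)),
                         vapply(r$adds, format_group, character(1))))
        got <- vapply(r$effective, format_group, character(1))
        if (!setequal(want, got)) {
          add("error", tid, r$row_id,
              "effective conditions do not equal the union over the root path")
        }
      }
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), table_id = character(),
               row_id = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation> ", if (x$ok) "OK" else "FAILED", " — ",
      sum(x$issues$severity == "error"), " error(s), ",
      sum(x$issues$severity == "warning"), " warning(s)\n", sep = "")
  if (nrow(x$issues)) print(x$issues)
  invisible(x)
}

#' Revise one table of a knowledge base locally
#'
#' Applies a single-table edit and returns a new knowledge base in which
#' only the named table differs; every other table object is untouched.
#' The edit is rejected (with the validation report attached to the error)
#' if the result would not validate.
#'
#' @param kb a [knowledge_base()].
#' @param table_id the table to edit.
#' @param edit a list with `op` one of `"add_row"`, `"edit_selection"`,
#'   `"edit_conditions"`, plus: for `add_row` a `row` ([scenario_row()] or
#'   the list of its fields); for the other two a `row_id` and the new
#'   `select` / `adds`.
#' @return the revised `knowledge_base`.
#' @export
revise_table <- function(kb, table_id, edit) {
  if (!table_id %in% names(kb$tables)) stop("unknown table id: ", table_id)
  stopifnot(is.list(edit), !is.null(edit$op))
  tab <- kb$tables[[table_id]]
  rows <- unname(tab$rows)
  if (edit$op == "add_row") {
    row <- edit$row
    if (!inherits(row, "scenario_row")) {
      row <- scenario_row(row$row_id, row$parent, row$adds, row$select)
    }
    rows <- c(rows, list(row))
  } else if (edit$op %in% c("edit_selection", "edit_conditions")) {
    if (!edit$row_id %in% names(tab$rows)) {
      stop("unknown row id in table ", table_id, ": ", edit$row_id)
    }
    rows <- lapply(rows, function(r) {
      if (r$row_id == edit$row_id) {
        if (edit$op == "edit_selection") {
          r <- scenario_row(r$row_id, r$parent, r$adds, edit$select)
        } else {
          r <- scenario_row(r$row_id, r$parent, edit$adds, r$select)
        }
      } else {
        r <- scenario_row(r$row_id, r$parent, r$adds, r$select)
      }
      r
    })
  } else {
    stop("unknown edit op: ", edit$op)
  }
  new_tab <- diagnostic_table(tab$table_id, tab$trigger, tab$columns, rows)
  tables <- kb$tables
  tables[[table_id]] <- new_tab
  out <- knowledge_base(kb$registry, unname(tables))
  rep <- validate_kb(out)
  if (!rep$ok) {
    cond <- simpleError(paste0("edit rejected: revised knowledge base is invalid (",
                               sum(rep$issues$severity == "error"), " error(s))"))
    cond$report <- rep
    stop(cond)
  }
  out
}

#' Structural equality of two knowledge bases
#'
#' Field-by-field comparison on canonical forms: registry rows, table ids,
#' triggers, columns, and per row (in stored order) id, parent, own and
#' effective condition groups, selected codes and depth.
#'
#' @param a,b knowledge bases.
#' @return logical scalar.
#' @export
kb_equal <- function(a, b) {
  reg_a <- a$registry[order(a$registry$code), ]
  reg_b <- b$registry[order(b$registry$code), ]
  rownames(reg_a) <- rownames(reg_b) <- NULL
  if (!identical(reg_a, reg_b)) return(FALSE)
  if (!identical(names(a$tables), names(b$tables))) return(FALSE)
  for (tid in names(a$tables)) {
    ta <- a$tables[[tid]]; tb <- b$tables[[tid]]
    if (!identical(unclass(ta$trigger), unclass(tb$trigger))) return(FALSE)
    if (!identical(ta$columns, tb$columns)) return(FALSE)
    if (!identical(names(ta$rows), names(tb$rows))) return(FALSE)
    for (rid in names(ta$rows)) {
      ra <- ta$rows[[rid]]; rb <- tb$rows[[rid]]
      if (!identical(ra$parent, rb$parent)) return(FALSE)
      if (!groups_equal(ra$adds, rb$adds)) return(FALSE)
      if (!groups_equal(ra$effective, rb$effective)) return(FALSE)
      if (!setequal(ra$select, rb$select)) return(FALSE)
      if (!identical(ra$depth, rb$depth)) return(FALSE)
    }
  }
  TRUE
}

#' Default disease registry
#'
#' The ~50 named diseases of the seven gynaecological presentation groups
#' (bleeding, endocrinology, cancer, pelvic pain, urogynaecology, sexually
#' transmitted infections, vulva pathology), shipped as a plain-text
#' fixture.  Useful as a realistic disease universe for examples and
#' synthetic cohorts; `D` is always the size of whatever registry a
#' knowledge base actually carries.
#'
#' @return a [disease_registry()] data frame.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "disease_registry.yaml", package = "argdx",
                      mustWork = TRUE)
  doc <- yaml::read_yaml(path)
  disease_registry(
    code = vapply(doc$registry, `[[`, character(1), "code"),
    label = vapply(doc$registry, `[[`, character(1), "label"),
    group = vapply(doc$registry, `[[`, character(1), "group"))
}
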