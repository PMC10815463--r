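# Knowledge-base document format: a small YAML dialect.
#
#   registry:
#   - {code: BV, label: bacterial vaginosis, group: sexually_transmitted_infections}
#   tables:
#   - id: sti_discharge
#     trigger: vaginal_discharge
#     columns: [BV, TM, VC, SP, NG, CM, HSV, AW]
#     rows:
#     - id: r1
#       parent: ~
#       adds: [vaginal_discharge]
#       select: [BV, TM, VC, NG, CM]
#     - id: r2
#       parent: r1
#       adds: ["quantity(vd,profuse)", "texture(vd,thin)", "colour(vd,green)"]
#       select: [BV, TM, NG]
#
# Rows list only their own additions ("adds"); effective conditions are
# resolved at parse time.  Disjunctive groups use the "+/" separator inside
# one string.  Parsing is lossless with respect to serialize_kb().

#' Parse a knowledge-base document
#'
#' @param text a length-one YAML string (see the format sketch in this
#'   file's source), or a character vector of lines.
#' @return a [knowledge_base()] with the `adds` shorthand resolved into
#'   effective conditions.  Schema violations name the offending table and
#'   row; cyclic parent references are structural errors.
#' @seealso [read_kb()] to parse from a file, [serialize_kb()] for the
#'   inverse.
#' @export
parse_kb <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  doc <- yaml::yaml.load(text)
  parse_kb_doc(doc)
}

#' Read a knowledge base from a YAML file
#' @param path file path.
#' @return a [knowledge_base()].
#' @export
read_kb <- function(path) parse_kb_doc(yaml::read_yaml(path))

parse_kb_doc <- function(doc) {
  if (!is.list(doc) || is.null(doc$registry)) {
    stop("KB document must have a top-level `registry` list")
  }
  get_str <- function(x, field, where) {
    v <- x[[field]]
    if (is.null(v)) stop("missing `", field, "` in ", where)
    as.character(v)
  }
  registry <- disease_registry(
    code = vapply(doc$registry, get_str, character(1), "code", "registry entry"),
    label = vapply(doc$registry, function(x) as.character(x$label %||% ""), character(1)),
    group = vapply(doc$registry, function(x) as.character(x$group %||% "other"), character(1)))
  tables <- lapply(doc$tables %||% list(), function(tdoc) {
    tid <- get_str(tdoc, "id", "table entry")
    where <- paste0("table ", tid)
    rows <- lapply(tdoc$rows %||% list(), function(rdoc) {
      rid <- get_str(rdoc, "id", paste0(where, " row entry"))
      adds <- rdoc$adds
      if (is.null(adds) || length(adds) == 0L) {
        stop(where, " row ", rid, ": `adds` must list at least one condition group")
      }
      scenario_row(
        row_id = rid,
        parent = if (is.null(rdoc$parent)) NA_character_ else as.character(rdoc$parent),
        adds = lapply(as.character(adds), parse_group),
        select = as.character(rdoc$select %||% character()))
    })
    diagnostic_table(
      table_id = tid,
      trigger = parse_group(get_str(tdoc, "trigger", where)),
      columns = as.character(tdoc$columns %||% character()),
      rows = rows)
  })
  knowledge_base(registry, tables)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Serialize a knowledge base to its document form
#'
#' The inverse of [parse_kb()]: `parse_kb(serialize_kb(kb))` is
#' structurally equal to `kb` (see [kb_equal()]).  Condition groups are
#' written in canonical rendering, so serialization is stable: serializing
#' twice yields byte-identical text.
#'
#' @param kb a [knowledge_base()].
#' @return a length-one YAML string.
#' @export
serialize_kb <- function(kb) {
  doc <- list(
    registry = lapply(seq_len(nrow(kb$registry)), function(i) {
      list(code = kb$registry$code[i], label = kb$registry$label[i],
           group = kb$registry$group[i])
    }),
    tables = lapply(unname(kb$tables), table_doc))
  yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
}

table_doc <- function(tab) {
  list(
    id = tab$table_id,
    trigger = format_group(tab$trigger),
    columns = as.list(tab$columns),
    rows = lapply(unname(tab$rows), function(r) {
      list(id = r$row_id,
           parent = if (is.na(r$parent)) NULL else r$parent,
           adds = lapply(r$adds, format_group),
           select = as.list(r$select))
    }))
}

#' Serialize a single diagnostic table
#'
#' Used to check revision locality: after a single-table edit, the
#' serialized form of every untouched table is byte-identical.
#'
#' @param tab a [diagnostic_table()].
#' @return a length-one YAML string.
#' @export
serialize_table <- function(tab) yaml::as.yaml(table_doc(tab), indent.mapping.sequence = TRUE)

#' Write a knowledge base to a YAML file
#' @param kb a [knowledge_base()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  writeLines(sub("\n$", "", serialize_kb(kb)), path)
  invisible(path)
}
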