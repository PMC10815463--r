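# Condition terms and disjunctive condition groups.
#
# A condition term is an atomic finding descriptor: a bare symptom token
# ("vaginal_discharge") or a predicate over a subject and value
# ("texture(vd,thin)").  Terms are canonicalized at parse time so that
# equality is purely syntactic: case-folded, whitespace collapsed to
# underscores.  A condition group is a non-empty disjunction of terms,
# written with the "+/" separator ("burning +/ itching"); it is satisfied
# by a finding set iff at least one alternative is present.

#' Canonicalize a token
#'
#' Lower-cases, trims, and replaces internal whitespace with underscores so
#' that `"Texture"` and `" texture "` compare equal.
#'
#' @param x character vector of raw tokens.
#' @return character vector of canonical tokens.
#' @keywords internal
canon_token <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", "_", x)
}

#' Construct a condition term
#'
#' @param value the value token (the only mandatory part; a bare symptom is
#'   a term with empty predicate and subject).
#' @param subject optional subject token (e.g. the body substance the
#'   predicate qualifies).
#' @param predicate optional predicate token (e.g. `texture`, `colour`).
#' @return an object of class `cond_term` with fields `predicate`,
#'   `subject`, `value` (canonical tokens, `""` when absent).
#' @examples
#' cond_term("thin", subject = "vd", predicate = "Texture")
#' cond_term("vaginal discharge")
#' @export
cond_term <- function(value, subject = "", predicate = "") {
  value <- canon_token(value)
  if (!nzchar(value)) stop("condition term requires a non-empty value token")
  structure(
    list(predicate = canon_token(predicate), subject = canon_token(subject),
         value = value),
    class = "cond_term"
  )
}

#' @export
format.cond_term <- function(x, ...) {
  if (!nzchar(x$predicate)) return(x$value)
  if (!nzchar(x$subject)) return(paste0(x$predicate, "(", x$value, ")"))
  paste0(x$predicate, "(", x$subject, ",", x$value, ")")
}

#' @export
print.cond_term <- function(x, ...) {
  cat("<condition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a single condition term from text
#'
#' Accepts the canonical renderings as well as the looser spellings seen in
#' printed tables: `"quantity (VD, profuse)"`, `"Texture(vd,thin)"`,
#' `"lumps(small_cauliflower)"` (predicate with a value but no subject) and
#' bare tokens such as `"Vaginal discharge"`.
#'
#' @param text a length-one character string.
#' @return a [cond_term()].
#' @export
parse_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  m <- regmatches(text, regexec("^([^()]+)\\(([^()]*)\\)$", text))[[1]]
  if (length(m) == 3L) {
    pred <- m[2]
    args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    args <- args[nzchar(args)]
    if (length(args) == 1L) return(cond_term(args[1], predicate = pred))
    if (length(args) == 2L) {
      return(cond_term(args[2], subject = args[1], predicate = pred))
    }
    stop("cannot parse condition term (expected 1 or 2 arguments): ", text)
  }
  cond_term(text)
}

#' Canonical string form of a term given in any accepted spelling
#' @keywords internal
canon_term <- function(text) format(parse_term(text))

#' Parse a condition group
#'
#' A group is one or more terms joined by the `+/` disjunction separator.
#' Alternatives are canonicalized and sorted, so two spellings of the same
#' disjunction compare equal.
#'
#' @param text a length-one character string, e.g. `"Burning +/ itching"`.
#' @return a character vector of canonical term strings, class `cond_group`.
#' @export
parse_group <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  alts <- trimws(strsplit(text, "+/", fixed = TRUE)[[1]])
  alts <- alts[nzchar(alts)]
  if (length(alts) == 0L) stop("empty condition group: ", sQuote(text))
  structure(sort(unique(vapply(alts, canon_term, character(1), USE.NAMES = FALSE))),
            class = "cond_group")
}

#' Render a condition group back to its textual form
#' @param group a `cond_group` (or plain character vector of canonical terms).
#' @return a length-one string using the `+/` separator.
#' @export
format_group <- function(group) paste(unclass(group), collapse = " +/ ")

#' Is a condition group satisfied by a finding set?
#'
#' Open-world semantics: a group is satisfied iff at least one alternative
#' is among the findings; absence of a term is never negation.
#'
#' @param group a `cond_group` or character vector of canonical terms.
#' @param findings a finding set (see [finding_set()]).
#' @return logical scalar.
#' @export
group_satisfied <- function(group, findings) any(unclass(group) %in% findings)

#' Construct a finding set
#'
#' A finding set is the current positive patient information: a set of
#' canonical condition terms.  Inputs may use any accepted spelling; they
#' are canonicalized and deduplicated.
#'
#' @param terms character vector of condition terms.
#' @return sorted character vector of canonical terms, class `finding_set`.
#' @examples
#' finding_set(c("Vaginal discharge", "Texture (VD, frothy)"))
#' @export
finding_set <- function(terms = character()) {
  if (length(terms) == 0L) {
    return(structure(character(), class = "finding_set"))
  }
  stopifnot(is.character(terms))
  structure(sort(unique(vapply(terms, canon_term, character(1), USE.NAMES = FALSE))),
            class = "finding_set")
}

# structural equality of two lists of groups (order-sensitive on groups,
# order-insensitive within a group because alternatives are sorted)
groups_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  all(mapply(function(x, y) identical(unclass(x), unclass(y)), a, b))
}
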