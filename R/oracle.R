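# Brute-force verification oracle.
#
# Recomputes the plausible set by explicit enumeration, on a code path
# independent of plausible_diagnoses(): row matching is redone from the raw
# parent links (effective conditions are re-derived from the root path, not
# read from the resolved field), every argument is materialized, the full
# attack relation is built, and admissibility is decided argument by
# argument.  An argument is strictly defeated when some counterargument is
# strictly stronger than it and than every comparable (same-table)
# co-argument for the same disease; since strength is only defined within a
# table, incomparable co-arguments cannot be overridden by that attacker
# and defend the disease on their own.

#' Brute-force plausible set (verification oracle)
#'
#' Enumerates all arguments and the full attack relation (arguments for
#' different diseases attack each other; within a table the strictly
#' stronger one defeats, equal strengths attack mutually without strict
#' defeat) and returns the diseases holding at least one argument that no
#' attacker strictly defeats.  Intended as an independent check of
#' [plausible_diagnoses()] on small inputs only.
#'
#' @param kb a [knowledge_base()] with at most 8 tables of at most 6 rows
#'   each (enforced).
#' @param findings a [finding_set()] or character vector of terms.
#' @return sorted character vector of plausible disease codes.
#' @export
oracle_plausible <- function(kb, findings) {
  if (length(kb$tables) > 8L ||
      any(vapply(kb$tables, function(t) length(t$rows), integer(1)) > 6L)) {
    stop("oracle_plausible is restricted to small knowledge bases ",
         "(<= 8 tables, <= 6 rows each)")
  }
  findings <- as_finding_set(findings)
  args <- list()
  for (tab in kb$tables) {
    for (r in tab$rows) {
      # re-derive the effective conditions from the parent chain
      groups <- list()
      cur <- r$row_id
      hops <- 0L
      while (!is.na(cur)) {
        groups <- c(tab$rows[[cur]]$adds, groups)
        cur <- tab$rows[[cur]]$parent
        hops <- hops + 1L
        if (hops > length(tab$rows)) stop("cyclic parent references")
      }
      ok <- all(vapply(groups, function(g) any(unclass(g) %in% findings), logical(1)))
      if (ok) {
        for (d in r$select) {
          args[[length(args) + 1L]] <- list(disease = d, table_id = tab$table_id,
                                            row_id = r$row_id, depth = hops)
        }
      }
    }
  }
  if (!length(args)) return(character())
  survives <- logical(length(args))
  for (i in seq_along(args)) {
    a <- args[[i]]
    co <- Filter(function(x) x$disease == a$disease &&
                   x$table_id == a$table_id, args)
    defeated <- FALSE
    for (b in args) {
      if (b$disease == a$disease) next
      if (compare_strength(b, a) != "stronger") next
      beats_all <- all(vapply(co, function(x) {
        compare_strength(b, x) == "stronger"
      }, logical(1)))
      if (beats_all) { defeated <- TRUE; break }
    }
    survives[i] <- !defeated
  }
  sort(unique(vapply(args[survives], `[[`, character(1), "disease")))
}
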