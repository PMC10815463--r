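# Seeded generators for synthetic knowledge bases and phased patient
# cohorts with known ground truth.
#
# Token namespaces are kept disjoint by construction: condition vocabulary
# c<k>, noise findings x<k>, synthetic disease codes D<k>.  Noise terms
# therefore never collide with any table's conditions, so a noisy case and
# its noise-free twin drive the engine identically and differ only through
# expert perturbation.

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

SEVEN_GROUPS <- c("bleeding", "endocrinology", "cancer", "pelvic_pain",
                  "urogynaecology", "sexually_transmitted_infections",
                  "vulva_pathology")

#' Parameters for the synthetic knowledge-base generator
#'
#' Emulates, at desk scale, the structure of a table-based diagnostic
#' knowledge base: presenting-complaint-rooted scenario trees over a fixed
#' condition vocabulary and disease registry.
#'
#' @param n_tables number of diagnostic tables.
#' @param rows_per_table length-2 range of rows per table.
#' @param p_branch probability that a new row attaches to a random earlier
#'   row instead of extending the current chain.
#' @param conds_per_row length-2 range of condition groups a non-root row
#'   adds.
#' @param p_disjunction probability that an added group carries two
#'   alternatives instead of one.
#' @param vocab_size size of the condition vocabulary (`c<k>` tokens).
#' @param n_diseases size of the synthetic registry (`D<k>` codes).
#' @param diseases_per_table length-2 range of disease columns per table.
#' @param subset_selection when `TRUE`, every child row selects a subset of
#'   its parent's selection (the shape of the printed exemplars).
#' @param seed RNG seed.
#' @return a `kb_gen_params` list.
#' @export
kb_gen_params <- function(n_tables = 3, rows_per_table = c(2, 4),
                          p_branch = 0.2, conds_per_row = c(1, 2),
                          p_disjunction = 0.2, vocab_size = 40,
                          n_diseases = 10, diseases_per_table = c(3, 6),
                          subset_selection = TRUE, seed = 1) {
  stopifnot(n_tables >= 1, length(rows_per_table) == 2, all(rows_per_table >= 1),
            p_branch >= 0, p_branch <= 1, length(conds_per_row) == 2,
            all(conds_per_row >= 1), p_disjunction >= 0, p_disjunction <= 1,
            vocab_size >= 1, n_diseases >= 1, length(diseases_per_table) == 2,
            all(diseases_per_table >= 1))
  if (diseases_per_table[2] > n_diseases) {
    stop("infeasible parameters: diseases_per_table exceeds the registry size")
  }
  structure(as.list(environment()), class = "kb_gen_params")
}

#' Generate a random knowledge base
#'
#' Deterministic for a given seed; the output always passes [validate_kb()]
#' with zero errors, and when `subset_selection` is set every child row's
#' selection is a subset of its parent's.
#'
#' @param params a [kb_gen_params()].
#' @return a [knowledge_base()].
#' @export
generate_kb <- function(params) {
  stopifnot(inherits(params, "kb_gen_params"))
  with_seed(params$seed, {
    codes <- sprintf("D%02d", seq_len(params$n_diseases))
    registry <- disease_registry(
      code = codes,
      label = paste("synthetic disease", seq_len(params$n_diseases)),
      group = SEVEN_GROUPS[(seq_len(params$n_diseases) - 1L) %% length(SEVEN_GROUPS) + 1L])
    vocab <- sprintf("c%03d", seq_len(params$vocab_size))
    tables <- lapply(seq_len(params$n_tables), function(i) {
      n_rows <- sample(params$rows_per_table[1]:params$rows_per_table[2], 1L)
      n_cols <- sample(params$diseases_per_table[1]:params$diseases_per_table[2], 1L)
      columns <- sort(sample(codes, n_cols))
      trigger <- sample(vocab, 1L)
      rows <- vector("list", n_rows)
      rows[[1L]] <- scenario_row(
        "r1", NA, adds = list(parse_group(trigger)),
        select = sort(sample(columns, sample.int(n_cols, 1L))))
      table_used <- trigger  # tokens are distinct across a table's rows
      for (j in seq_len(n_rows)[-1L]) {
        parent <- if (j > 2L && stats::runif(1) < params$p_branch) {
          sprintf("r%d", sample.int(j - 1L, 1L))
        } else sprintf("r%d", j - 1L)
        avail <- setdiff(vocab, table_used)
        n_groups <- min(sample(params$conds_per_row[1]:params$conds_per_row[2], 1L),
                        length(avail))
        if (n_groups == 0L) {
          stop("infeasible parameters: condition vocabulary exhausted on a root path")
        }
        adds <- list()
        for (k in seq_len(n_groups)) {
          width <- if (length(avail) > 1L && stats::runif(1) < params$p_disjunction) 2L else 1L
          terms <- sample(avail, width)
          avail <- setdiff(avail, terms)
          adds[[k]] <- parse_group(paste(terms, collapse = " +/ "))
        }
        parent_sel <- rows[[match(parent, sprintf("r%d", seq_len(j - 1L)))]]$select
        sel_pool <- if (params$subset_selection) parent_sel else columns
        select <- if (length(sel_pool)) {
          sort(sample(sel_pool, sample.int(length(sel_pool), 1L)))
        } else character()
        rows[[j]] <- scenario_row(sprintf("r%d", j), parent, adds, select)
        table_used <- c(table_used, unlist(lapply(adds, unclass), use.names = FALSE))
      }
      diagnostic_table(sprintf("t%02d", i), trigger, columns, rows)
    })
    knowledge_base(registry, tables)
  })
}

#' Parameters for the synthetic cohort generator
#'
#' Emulates phased finding accumulation over a visit (first suspicions,
#' initial diagnosis, final diagnosis) and controlled expert/system
#' disagreement.
#'
#' @param n_cases number of patient cases (default 50, a pilot-sized
#'   cohort).
#' @param noise_rates length-3 vector: per phase, the probability that one
#'   irrelevant extra finding (an `x<k>` token outside every table's
#'   vocabulary) is recorded.
#' @param expert_model `"exact"` (expert set equals the engine's output) or
#'   `"perturbed"` (controlled disagreement via `drop_rate` / `add_rate`).
#' @param drop_rate probability that the expert omits each disease the
#'   engine proposes.
#' @param add_rate probability that the expert adds one disease the engine
#'   did not propose.
#' @param seed RNG seed.
#' @return a `cohort_gen_params` list.
#' @export
cohort_gen_params <- function(n_cases = 50, noise_rates = c(0.1, 0.1, 0.1),
                              expert_model = c("exact", "perturbed"),
                              drop_rate = 0.15, add_rate = 0.1, seed = 1) {
  expert_model <- match.arg(expert_model)
  stopifnot(n_cases >= 1, length(noise_rates) == 3,
            all(noise_rates >= 0), all(noise_rates <= 1),
            drop_rate >= 0, drop_rate <= 1, add_rate >= 0, add_rate <= 1)
  structure(as.list(environment()), class = "cohort_gen_params")
}

#' Generate one synthetic patient case
#'
#' Picks a target disease and a root-to-leaf row path selecting it in some
#' table; phase-1 findings satisfy the root scenario, phase-2 findings the
#' middle of the path, phase-3 findings the leaf scenario (cumulative, one
#' alternative chosen per disjunctive group), plus optional noise tokens
#' drawn from a namespace disjoint from every table's vocabulary.  Expert
#' sets are derived from the engine's per-phase output according to the
#' expert model; a perturbed expert set is never allowed to become empty
#' (one engine-proposed disease is retained).
#'
#' @param kb a [knowledge_base()] with at least one table whose leaves
#'   select at least one disease.
#' @param params a [cohort_gen_params()].
#' @param case_id identifier for the case.
#' @param target optional disease code the scenario path must select; an
#'   error is raised if no table's leaf selects it.
#' @param seed optional seed; when `NULL` (the default) the current RNG
#'   state is used, so that [generate_cohort()] can draw a varied cohort
#'   under one seed.
#' @return a [patient_case()] whose `target` field carries the ground
#'   truth.
#' @export
generate_case <- function(kb, params, case_id = "case1", target = NULL,
                          seed = NULL) {
  stopifnot(inherits(params, "cohort_gen_params"), length(kb$tables) >= 1L)
  if (!is.null(seed)) return(with_seed(seed, generate_case(kb, params, case_id, target)))
  # candidate (table, leaf) pairs: leaves with a non-empty (target-bearing)
  # selection
  cand <- list()
  for (tab in kb$tables) {
    kids <- vapply(tab$rows, function(r) r$parent, character(1))
    for (r in tab$rows) {
      if (r$row_id %in% kids[!is.na(kids)]) next  # not a leaf
      sel <- if (is.null(target)) r$select else intersect(r$select, toupper(canon_token(target)))
      if (length(sel)) cand[[length(cand) + 1L]] <- list(tab = tab, leaf = r, sel = sel)
    }
  }
  if (!length(cand)) {
    stop(if (is.null(target)) "no table has a leaf selecting any disease"
         else paste0("no table selects the requested target ", target))
  }
  pick <- cand[[sample.int(length(cand), 1L)]]
  tab <- pick$tab
  tgt <- pick$sel[sample.int(length(pick$sel), 1L)]
  # root-to-leaf path and one satisfied alternative per group along it
  path <- character(); cur <- pick$leaf$row_id
  while (!is.na(cur)) { path <- c(cur, path); cur <- tab$rows[[cur]]$parent }
  terms_along <- lapply(path, function(id) {
    vapply(tab$rows[[id]]$adds, function(g) {
      alts <- unclass(g)
      alts[sample.int(length(alts), 1L)]
    }, character(1))
  })
  len <- length(path)
  anchors <- c(1L, max(1L, ceiling(len / 2)), len)
  findings <- lapply(anchors, function(a) unique(unlist(terms_along[seq_len(a)])))
  # cumulative noise from the disjoint x<k> namespace
  noise <- character()
  for (i in 1:3) {
    if (stats::runif(1) < params$noise_rates[i]) {
      noise <- c(noise, sprintf("x%04d", sample.int(9999L, 1L)))
    }
    findings[[i]] <- c(findings[[i]], noise)
  }
  expert <- lapply(findings, function(f) {
    sys <- plausible_diagnoses(kb, f)$plausible
    if (params$expert_model == "exact") return(sys)
    keep <- sys[stats::runif(length(sys)) >= params$drop_rate]
    if (!length(keep)) keep <- sys[sample.int(length(sys), 1L)]
    if (stats::runif(1) < params$add_rate) {
      extra <- setdiff(kb$registry$code, keep)
      if (length(extra)) keep <- c(keep, extra[sample.int(length(extra), 1L)])
    }
    sort(keep)
  })
  group <- kb$registry$group[match(tgt, kb$registry$code)]
  patient_case(case_id, findings, expert,
               group = if (is.na(group)) "other" else group, target = tgt)
}

#' Generate a synthetic cohort
#'
#' Draws `params$n_cases` cases under `params$seed`; reproducible from the
#' seed.
#'
#' @param kb a [knowledge_base()].
#' @param params a [cohort_gen_params()].
#' @return list of [patient_case()]s with ids `case001`, `case002`, ...
#' @export
generate_cohort <- function(kb, params) {
  stopifnot(inherits(params, "cohort_gen_params"))
  with_seed(params$seed, {
    lapply(seq_len(params$n_cases), function(i) {
      generate_case(kb, params, case_id = sprintf("case%03d", i))
    })
  })
}
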