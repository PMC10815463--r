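test_that("row matching follows effective conditions and maximality", {
  tab <- fixture_kb("sti_discharge")$tables$sti_discharge
  m <- match_rows(tab, finding_set("vaginal_discharge"))
  expect_identical(m$matched, "r1")
  expect_identical(m$maximal, "r1")
  expect_identical(match_rows(tab, finding_set(character()))$matched, character())
  m3 <- match_rows(tab, finding_set(discharge_phases$third))
  expect_identical(m3$matched, c("r1", "r2", "r3"))
  expect_identical(m3$maximal, "r3")
  # partial specifics: row 2 needs all three of its added conditions
  m_part <- match_rows(tab, finding_set(c("vaginal_discharge", "texture(vd,thin)")))
  expect_identical(m_part$matched, "r1")
})

test_that("arguments arise exactly from (matched row, selected disease) pairs", {
  kb <- fixture_kb("sti_discharge")
  a1 <- build_arguments(kb, "vaginal_discharge")
  expect_identical(nrow(a1), 5L)
  expect_setequal(a1$disease, c("BV", "TM", "VC", "NG", "CM"))
  expect_true(all(a1$depth == 1L))
  a3 <- build_arguments(kb, discharge_phases$third)
  expect_setequal(unique(a3$depth), 1:3)
  expect_setequal(a3$disease[a3$depth == 3L], c("BV", "TM"))
  empty <- knowledge_base(disease_registry("X"), list())
  expect_identical(nrow(build_arguments(empty, "anything")), 0L)
})

test_that("strength orders by depth within a table and is incomparable across tables", {
  arg <- function(tid, depth) list(table_id = tid, depth = depth)
  expect_identical(compare_strength(arg("t", 3), arg("t", 1)), "stronger")
  expect_identical(compare_strength(arg("t", 1), arg("t", 3)), "weaker")
  expect_identical(compare_strength(arg("t", 2), arg("t", 2)), "equal")
  expect_identical(compare_strength(arg("t1", 5), arg("t2", 1)), "incomparable")
  # antisymmetry and transitivity over random same-table triples
  withr::with_seed(42, {
    for (i in 1:200) {
      d <- sample(1:6, 3, replace = TRUE)
      ab <- compare_strength(arg("t", d[1]), arg("t", d[2]))
      ba <- compare_strength(arg("t", d[2]), arg("t", d[1]))
      expect_identical(ab, switch(ba, stronger = "weaker", weaker = "stronger",
                                  equal = "equal"))
      if (ab == "stronger" &&
          compare_strength(arg("t", d[2]), arg("t", d[3])) == "stronger") {
        expect_identical(compare_strength(arg("t", d[1]), arg("t", d[3])),
                         "stronger")
      }
    }
  })
})

test_that("the discharge worked example narrows across the three finding sets", {
  kb <- fixture_kb("sti_discharge")
  expect_setequal(plausible_diagnoses(kb, discharge_phases$first)$plausible,
                  c("BV", "TM", "VC", "NG", "CM"))
  r2 <- plausible_diagnoses(kb, discharge_phases$second)
  expect_setequal(r2$plausible, c("BV", "TM", "NG"))
  expect_setequal(r2$defeats$disease, c("VC", "CM"))
  r3 <- plausible_diagnoses(kb, discharge_phases$third)
  expect_setequal(r3$plausible, c("BV", "TM"))
  # the prose-variant root additionally supports anogenital warts
  prose <- fixture_kb("sti_discharge_prose")
  expect_setequal(plausible_diagnoses(prose, discharge_phases$first)$plausible,
                  c("BV", "TM", "VC", "NG", "CM", "AW"))
})

test_that("the burning/itching worked example converges on anogenital warts", {
  kb <- fixture_kb("sti_burning")
  f1 <- "itching"
  f2 <- c(f1, "postcoital_bleeding")
  f3 <- c(f2, "image(2,condyloma)")
  expect_setequal(plausible_diagnoses(kb, f1)$plausible,
                  c("BV", "TM", "VC", "NG", "CM", "HSV", "AW"))
  expect_setequal(plausible_diagnoses(kb, f2)$plausible,
                  c("VC", "NG", "CM", "AW"))
  expect_identical(plausible_diagnoses(kb, f3)$plausible, "AW")
})

test_that("defeat records reference maximal matched rows and tag cross-table survivors", {
  kb <- toy_kb()
  res <- plausible_diagnoses(kb, c("p1", "q1", "p2"))
  # in t1, C loses to the depth-2 row; but t2's verdict keeps C and D plausible
  expect_setequal(res$plausible, c("A", "B", "C", "D"))
  defeat_c <- res$defeats[res$defeats$disease == "C", ]
  expect_identical(defeat_c$reason, "overridden-elsewhere")
  expect_true(defeat_c$row_id %in% res$matched_rows$t1$maximal)
  # without the second complaint, C is simply outranked
  res1 <- plausible_diagnoses(kb, c("p1", "q1"))
  expect_identical(res1$defeats$reason[res1$defeats$disease == "C"], "outranked")
})

test_that("the engine agrees with the brute-force oracle on random small instances", {
  for (seed in 1:200) {
    kb <- random_small_kb(seed)
    findings <- random_findings(seed)
    expect_identical(plausible_diagnoses(kb, findings)$plausible,
                     oracle_plausible(kb, findings),
                     info = paste("seed", seed))
  }
})

test_that("the oracle refuses knowledge bases above its size bound", {
  kb <- generate_kb(kb_gen_params(n_tables = 9, seed = 1))
  expect_error(oracle_plausible(kb, "c001"), "small knowledge bases")
  expect_identical(oracle_plausible(toy_kb(), character()), character())
})

test_that("terms appearing in no table leave the result unchanged", {
  for (seed in c(2, 9, 17)) {
    kb <- random_small_kb(seed)
    findings <- random_findings(seed)
    res1 <- plausible_diagnoses(kb, findings)
    res2 <- plausible_diagnoses(kb, finding_set(c(unclass(findings), "zz_nowhere")))
    expect_identical(res1$plausible, res2$plausible)
    expect_identical(res1$defeats, res2$defeats)
  }
})

test_that("refinement along one scenario path is monotone", {
  # growing findings along a root-to-leaf path: the maximal matched row
  # descends, and (with subset selection) the plausible set never grows
  for (seed in 1:30) {
    kb <- generate_kb(kb_gen_params(n_tables = 1, rows_per_table = c(3, 5),
                                    p_branch = 0.3, subset_selection = TRUE,
                                    seed = seed))
    tab <- kb$tables[[1L]]
    kids <- vapply(tab$rows, `[[`, character(1), "parent")
    leaves <- setdiff(names(tab$rows), kids[!is.na(kids)])
    leaf <- leaves[[1L]]
    path <- character(); cur <- leaf
    while (!is.na(cur)) { path <- c(cur, path); cur <- tab$rows[[cur]]$parent }
    prev_max <- NULL
    prev_plausible <- NULL
    for (i in seq_along(path)) {
      terms <- unlist(lapply(path[seq_len(i)], function(id) {
        vapply(tab$rows[[id]]$adds, function(g) unclass(g)[1L], character(1))
      }))
      m <- match_rows(tab, finding_set(terms))
      expect_true(path[i] %in% m$matched)
      this_max <- m$maximal
      if (!is.null(prev_max)) {
        # every maximal row now is a descendant-or-self of a previous one
        anc <- function(id) {
          out <- character(); cur <- id
          while (!is.na(cur)) { out <- c(out, cur); cur <- tab$rows[[cur]]$parent }
          out
        }
        expect_true(all(vapply(this_max, function(id) {
          any(prev_max %in% anc(id))
        }, logical(1))))
      }
      plaus <- plausible_diagnoses(kb, finding_set(terms))$plausible
      if (!is.null(prev_plausible)) {
        expect_true(all(plaus %in% prev_plausible))
      }
      prev_max <- this_max
      prev_plausible <- plaus
    }
  }
})

test_that("results are deterministic and independent of table order", {
  kb <- random_small_kb(5)
  findings <- random_findings(5)
  r1 <- plausible_diagnoses(kb, findings)
  r2 <- plausible_diagnoses(kb, findings)
  expect_identical(r1, r2)
  kb_rev <- knowledge_base(kb$registry, rev(unname(kb$tables)))
  r3 <- plausible_diagnoses(kb_rev, findings)
  expect_identical(r1$plausible, r3$plausible)
})
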