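test_that("the vaginal-discharge fixture parses to the printed structure", {
  kb <- fixture_kb("sti_discharge")
  expect_length(kb$tables, 1L)
  tab <- kb$tables$sti_discharge
  expect_length(tab$columns, 8L)
  expect_identical(vapply(tab$rows, `[[`, integer(1), "depth"),
                   c(r1 = 1L, r2 = 2L, r3 = 3L))
  eff3 <- vapply(tab$rows$r3$effective, format_group, character(1))
  expect_setequal(eff3, c("vaginal_discharge", "quantity(vd,profuse)",
                          "texture(vd,thin)", "colour(vd,green)",
                          "texture(vd,frothy)"))
  expect_true(validate_kb(kb)$ok)
})

test_that("the burning/itching fixture parses to the printed structure", {
  kb <- fixture_kb("sti_burning")
  tab <- kb$tables$sti_burning
  expect_length(tab$columns, 9L)
  expect_length(tab$rows$r1$select, 7L)
  expect_identical(tab$rows$r3$select, "AW")
  expect_identical(unclass(tab$trigger), c("burning", "itching"))
})

test_that("a minimal KB (one disease, no tables) is valid with D = 1", {
  kb <- parse_kb("registry:\n- {code: X, label: x, group: other}\ntables: []")
  expect_identical(kb$D, 1L)
  expect_true(validate_kb(kb)$ok)
})

test_that("serialization round-trips fixtures and seeded KBs structurally", {
  for (name in c("sti_discharge", "sti_burning", "sti_discharge_prose")) {
    kb <- fixture_kb(name)
    expect_true(kb_equal(kb, parse_kb(serialize_kb(kb))), info = name)
  }
  for (seed in 1:25) {
    kb <- random_small_kb(seed)
    expect_true(kb_equal(kb, parse_kb(serialize_kb(kb))), info = seed)
  }
  # serialization is stable: serializing twice is byte-identical
  kb <- random_small_kb(3)
  expect_identical(serialize_kb(kb), serialize_kb(parse_kb(serialize_kb(kb))))
})

test_that("effective conditions equal the union of own conditions over the root path", {
  for (seed in 1:20) {
    kb <- random_small_kb(seed)
    for (tab in kb$tables) {
      for (r in tab$rows) {
        want <- character()
        cur <- r$row_id
        while (!is.na(cur)) {
          want <- union(want, vapply(tab$rows[[cur]]$adds, format_group, character(1)))
          cur <- tab$rows[[cur]]$parent
        }
        expect_setequal(vapply(r$effective, format_group, character(1)), want)
      }
    }
  }
})

test_that("the validator flags constructed invariant breaches", {
  reg <- disease_registry(c("A", "B"))
  # row selecting a code absent from the table's columns
  tab <- diagnostic_table("t1", "p1", "A", list(
    scenario_row("r1", NA, list("p1"), c("A", "B"))))
  rep <- validate_kb(knowledge_base(reg, list(tab)))
  expect_false(rep$ok)
  expect_identical(sum(rep$issues$severity == "error"), 1L)
  # unregistered disease column
  tab2 <- diagnostic_table("t1", "p1", c("A", "Z"), list(
    scenario_row("r1", NA, list("p1"), "A")))
  expect_false(validate_kb(knowledge_base(reg, list(tab2)))$ok)
  # root row not requiring the trigger
  tab3 <- diagnostic_table("t1", "p1", "A", list(
    scenario_row("r1", NA, list("q9"), "A")))
  expect_false(validate_kb(knowledge_base(reg, list(tab3)))$ok)
  # cyclic parent references are structural errors at construction
  expect_error(
    diagnostic_table("t1", "p1", "A", list(
      scenario_row("r1", "r2", list("p1"), "A"),
      scenario_row("r2", "r1", list("q1"), "A"))),
    "cyclic")
})

test_that("non-shrinking selection down the hierarchy is a warning, not an error", {
  reg <- disease_registry(c("A", "B"))
  tab <- diagnostic_table("t1", "p1", c("A", "B"), list(
    scenario_row("r1", NA, list("p1"), "A"),
    scenario_row("r2", "r1", list("q1"), c("A", "B"))))
  rep <- validate_kb(knowledge_base(reg, list(tab)))
  expect_true(rep$ok)
  expect_identical(sum(rep$issues$severity == "warning"), 1L)
  # the generator with the subset constraint disabled also only warns
  kb <- generate_kb(kb_gen_params(n_tables = 2, rows_per_table = c(3, 4),
                                  subset_selection = FALSE, seed = 11))
  rep <- validate_kb(kb)
  expect_true(rep$ok)
})

test_that("single-table revision is local and rejects invalid edits", {
  kb <- toy_kb()
  before <- vapply(kb$tables, serialize_table, character(1))
  revised <- revise_table(kb, "t1", list(
    op = "add_row",
    row = list(row_id = "r4", parent = "r3", adds = list("q9"), select = "A")))
  expect_true("r4" %in% names(revised$tables$t1$rows))
  expect_identical(revised$tables$t1$rows$r4$depth, 4L)
  after <- vapply(revised$tables, serialize_table, character(1))
  expect_identical(before[["t2"]], after[["t2"]])   # untouched table byte-identical
  expect_false(identical(before[["t1"]], after[["t1"]]))

  # removing a disease from a root selection changes subsequent diagnoses
  kb2 <- fixture_kb("sti_burning")
  expect_true("AW" %in% plausible_diagnoses(kb2, "burning")$plausible)
  kb2r <- revise_table(kb2, "sti_burning", list(
    op = "edit_selection", row_id = "r1",
    select = setdiff(kb2$tables$sti_burning$rows$r1$select, "AW")))
  expect_false("AW" %in% plausible_diagnoses(kb2r, "burning")$plausible)

  # edits referencing unknown diseases or tables are rejected
  expect_error(revise_table(kb, "t1", list(op = "edit_selection",
                                           row_id = "r1", select = "ZZ")),
               "rejected")
  expect_error(revise_table(kb, "nope", list(op = "add_row")), "unknown table")
})

test_that("the default disease registry covers the seven presentation groups", {
  reg <- default_registry()
  expect_gte(nrow(reg), 40L)
  expect_setequal(unique(reg$group),
                  c("bleeding", "endocrinology", "cancer", "pelvic_pain",
                    "urogynaecology", "sexually_transmitted_infections",
                    "vulva_pathology"))
  expect_true(all(c("HP", "HIV") %in% reg$code))
  expect_false(anyDuplicated(reg$code) > 0L)
})
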