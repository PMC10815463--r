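# Shared fixtures and small seeded generators for the tests.

fixture_kb <- function(name) {
  read_kb(system.file("extdata", paste0(name, ".yaml"), package = "argdx"))
}

# the three progressive finding sets of the vaginal-discharge worked example
discharge_phases <- list(
  first = c("vaginal_discharge"),
  second = c("vaginal_discharge", "quantity(vd,profuse)",
             "texture(vd,thin)", "colour(vd,green)"),
  third = c("vaginal_discharge", "quantity(vd,profuse)",
            "texture(vd,thin)", "colour(vd,green)", "texture(vd,frothy)"))

# small random KBs within the oracle's size bound (<= 8 tables, <= 6 rows)
random_small_kb <- function(seed, subset_selection = seed %% 2L == 0L) {
  generate_kb(kb_gen_params(
    n_tables = 1L + seed %% 3L, rows_per_table = c(2, 5), p_branch = 0.3,
    conds_per_row = c(1, 2), p_disjunction = 0.3, vocab_size = 24,
    n_diseases = 6, diseases_per_table = c(2, 4),
    subset_selection = subset_selection, seed = seed))
}

# a random finding set over the generator's condition vocabulary (plus the
# occasional out-of-vocabulary token), drawn under `seed`
random_findings <- function(seed, vocab_size = 24) {
  withr::with_seed(seed + 7919L, {
    vocab <- sprintf("c%03d", seq_len(vocab_size))
    n <- sample(0:10, 1L)
    terms <- sample(vocab, n)
    if (stats::runif(1) < 0.3) terms <- c(terms, "zz_unrelated")
    finding_set(terms)
  })
}

# a tiny hand-built two-table KB used by revision and engine tests
toy_kb <- function() {
  reg <- disease_registry(c("A", "B", "C", "D"))
  t1 <- diagnostic_table("t1", "p1", c("A", "B", "C"), list(
    scenario_row("r1", NA, list("p1"), c("A", "B", "C")),
    scenario_row("r2", "r1", list("q1"), c("A", "B")),
    scenario_row("r3", "r2", list("q2"), c("A"))))
  t2 <- diagnostic_table("t2", "p2", c("C", "D"), list(
    scenario_row("r1", NA, list("p2"), c("C", "D")),
    scenario_row("r2", "r1", list("q3 +/ q4"), c("D"))))
  knowledge_base(reg, list(t1, t2))
}
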