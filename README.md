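# argdx — argumentation-based differential diagnosis over scenario tables

`argdx` is an R implementation of a knowledge-based differential-diagnosis
engine for clinical decision support.  It is aimed at researchers who study
explainable, rule-based diagnostic reasoning: the medical knowledge lives in
human-editable *diagnostic tables*, the inference is a dialectic comparison
of arguments, every verdict comes with a traceable explanation, and the
system-versus-expert agreement is scored with a closeness-accuracy metric
over the phases of a patient visit.

## The model

A knowledge base is a disease registry (the universe of `D` diseases) plus a
set of diagnostic tables.  Each table is rooted at a presenting complaint
(e.g. *vaginal discharge*) and its rows form a hierarchy of increasingly
specific scenarios: a row inherits all of its ancestors' condition groups
and adds its own, and marks (√) the subset of the table's disease columns
still supported in that scenario.  Condition groups may be disjunctive
(`burning +/ itching`); findings are open-world — an unrecorded condition is
unknown, never false.

Given the current findings, a row is **matched** when every one of its
effective condition groups is satisfied.  Each (matched row, selected
disease) pair yields an **argument**; arguments for different diseases are
counterarguments of each other, and within one table arguments from deeper
(more specific) rows are strictly stronger, while arguments from different
tables are incomparable.  The **plausible set** is the union, over matched
tables, of the diseases whose strongest supporting argument survives every
strictly stronger counterargument.  A brute-force oracle
(`oracle_plausible()`) re-derives the same set by enumerating the full
attack relation, on an independent code path, and is tested against the
engine on thousands of random instances.

Agreement with an expert is scored per phase (first suspicions, initial
diagnosis, final diagnosis) by

```
accuracy = (c / e) * ((D - |s - e|) / D)
```

where `s` and `e` are the sizes of the system's and the expert's diagnosis
sets, `c` the size of their intersection, and `D` the registry size.  The
metric is 1 exactly when the sets coincide and near zero when the system
hedges with all `D` diseases against a decisive expert (`1/D`).

## Worked example

The shipped fixture `sti_discharge.yaml` is a three-row table for the
presenting complaint *vaginal discharge* over eight sexually transmitted
infections.  A profuse, thin, green discharge:

```r
library(argdx)
kb <- read_kb(system.file("extdata", "sti_discharge.yaml", package = "argdx"))
f  <- finding_set(c("vaginal_discharge", "quantity(vd,profuse)",
                    "texture(vd,thin)", "colour(vd,green)"))
res <- plausible_diagnoses(kb, f)
res
#> <diagnosis> plausible: BV, NG, TM
#>   defeated: CM, VC
```

The depth-2 scenario is matched, so bacterial vaginosis, gonorrhoea and
trichomoniasis remain plausible while candidiasis and chlamydia — supported
only by the shallower root row — are overridden.  Every verdict can be
unravelled:

```r
explain(kb, f, res, "TM")
#> PLAUSIBLE: TM because vaginal_discharge & quantity(vd,profuse) &
#>   texture(vd,thin) & colour(vd,green) (sti_discharge/r2);
#>   would be strengthened by texture(vd,frothy) (sti_discharge/r3)

candidate_queries(kb, f)
#>            condition tables_affected discrimination rank
#> 1 texture(vd,frothy)   sti_discharge              1    1
```

The guidance says the one question worth asking next is whether the
discharge is frothy: establishing it would shrink the plausible set by one
(to BV and TM).  Scoring the three phases of this visit against an expert
who suspects BV and TM throughout:

```r
case <- patient_case("visit1",
  findings = list("vaginal_discharge", f, c(unclass(f), "texture(vd,frothy)")),
  expert   = list(c("BV","TM"), c("BV","TM"), c("BV","TM")))
evaluate_case(kb, case)
#>   case_id group phase        phase_name s e c D accuracy
#> 1  visit1 other     1  first_suspicions 5 2 2 8    0.625
#> 2  visit1 other     2 initial_diagnosis 3 2 2 8    0.875
#> 3  visit1 other     3   final_diagnosis 2 2 2 8    1.000
```

The accuracy climbs as the visit accumulates information — at phase 1 the
system still carries five diseases against the expert's two, by phase 3 the
sets coincide.

A command-line wrapper ships in `inst/exec/argdx` with `validate`,
`diagnose`, `explain`, `guide`, `evaluate` and `simulate` subcommands, e.g.

```sh
Rscript inst/exec/argdx diagnose --kb sti_discharge.yaml \
    --find vaginal_discharge --find "texture(vd,frothy)" \
    --find "quantity(vd,profuse)" --find "texture(vd,thin)" \
    --find "colour(vd,green)"
```

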