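# JSON metabolic-model dialect

`read_model(..., format = "json")` and `write_model(..., format = "json")`
exchange a COBRA-style JSON object with these top-level keys:

| key | type | meaning |
|-----|------|---------|
| `id` | string | model name |
| `version` | string | free-text version |
| `metabolites` | array | one object per metabolite |
| `reactions` | array | one object per reaction |
| `genes` | array of strings | gene namespace (optional; derived from GPRs when absent) |

Each **metabolite** object:

| field | type | notes |
|-------|------|-------|
| `id` | string | unique |
| `name` | string | optional, defaults to `id` |
| `compartment` | string | optional, defaults to `"c"` |
| `boundary` | bool | optional; `true` marks a source/sink pool excluded from mass balance (SBML `boundaryCondition`) |

Each **reaction** object:

| field | type | notes |
|-------|------|-------|
| `id` | string | unique |
| `metabolites` | object | metabolite id -> stoichiometric coefficient (negative = consumed) |
| `lower_bound`, `upper_bound` | number | flux bounds; when absent, defaulted to `(-1000, 1000)` if `reversible` is true, `(0, 1000)` otherwise, with a warning |
| `gene_reaction_rule` | string | infix boolean rule (`and`/`or`, parentheses; `and` binds tighter); empty string = no gene association |
| `subsystem` | string | pathway label |
| `reversible` | bool | only consulted when bounds are absent |

The SBML route (`format = "sbml"`) writes/reads the same information as
SBML Level 3 with fbc-style flux-bound parameters, boundary-condition
species and `geneProductAssociation` trees; the two formats round-trip to
identical models.
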