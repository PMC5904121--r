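# Metabolic model JSON dialect, version 1.0

A single JSON object with the following fields. All ids are strings; flux
bounds are mmol gCDW^-1 h^-1; the conventional "unbounded" value is +/-1000.

| field            | type   | notes                                        |
|------------------|--------|----------------------------------------------|
| `schema_version` | string | `"1.0"`                                      |
| `id`             | string | model identifier                             |
| `objective`      | string | reaction id of the biomass objective         |
| `genes`          | array  | gene id strings (superset of all rule genes) |
| `metabolites`    | array  | metabolite objects, see below                |
| `reactions`      | array  | reaction objects, see below                  |

Metabolite object:

| field         | type    | notes                                             |
|---------------|---------|---------------------------------------------------|
| `id`          | string  | unique within the model                           |
| `name`        | string  | free text (optional, defaults to `id`)            |
| `compartment` | string  | tag, e.g. `"c"` / `"e"` (optional, default `"c"`) |
| `n_carbon`    | integer | >= 0; transferable backbone carbon atoms. Carrier |
|               |         | moieties (CoA, nicotinamide nucleotides, adenine  |
|               |         | of ATP) are not counted, so internal reactions    |
|               |         | balance in this column.                           |

Reaction object:

| field           | type    | notes                                            |
|-----------------|---------|--------------------------------------------------|
| `id`            | string  | unique within the model                          |
| `name`          | string  | optional                                         |
| `stoichiometry` | object  | metabolite id -> signed decimal coefficient      |
|                 |         | (negative = consumed); non-empty; every key must |
|                 |         | resolve to a metabolite                          |
| `lower_bound`   | number  | default -1000                                    |
| `upper_bound`   | number  | default 1000; must be >= `lower_bound`           |
| `gene_rule`     | string  | boolean expression over gene ids with `and`/`or` |
|                 |         | and parentheses; `""` = spontaneous / not gene   |
|                 |         | associated                                       |
| `is_exchange`   | boolean | boundary pseudo-reaction touching exactly one    |
|                 |         | metabolite; negative flux = uptake               |

The loader (`read_model_json()`) validates all invariants and reports the
offending field; `write_model_json()` emits this dialect and round-trips to
a flux-equivalent model (identical stoichiometric matrix and bounds).
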