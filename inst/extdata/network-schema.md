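# Credal-network JSON dialect

A network file is a single JSON object with the following keys.

## `name`, `description`

Free-text metadata strings.

## `variables`

Array of `{"name": <identifier>, "states": [<label>, ...]}`.
Every variable needs at least two unique state labels.  The order of
`states` is canonical: it fixes vector indexing, parent-configuration
indexing and argmax tie-breaking everywhere in the package.

## `arcs`

Array of `{"child": <variable>, "parents": [<variable>, ...]}`.
Variables without an entry are roots.  The graph must be acyclic.

## `tables`

Array of `{"variable": <name>, "provenance": <label>, "rows": [...]}`,
one entry per variable.  Each row is

```json
{"parent_config": {"<parent>": "<state>", ...},
 "lower": [l1, ...], "upper": [u1, ...],
 "orderings": [["state_a", "state_b"], ...]}
```

- `parent_config` may be **partial** (or `{}`): the row then applies to
  every matching parent configuration.  Rows are applied in file order
  and the **last matching row wins**, so a `{}` default row followed by
  increasingly specific exceptions is the idiomatic layout.  Every
  parent configuration must be covered by at least one row.
- `lower`/`upper` are per-state probability bounds in canonical state
  order; `orderings` are optional comparative constraints
  `p(state_a) >= p(state_b)`.
- Alternatively a row may carry a `judgments` array instead of explicit
  bounds; each judgment is one of

```json
{"kind": "interval", "state": "s", "lower": 0.1, "upper": 0.4}
{"kind": "verbal",   "state": "s", "term": "very probable"}
{"kind": "comparative", "greater": "a", "less": "b"}
```

  compiled through the verbal scale (`verbal-scale.json` by default).
- `provenance` records where the numbers come from (the packaged
  place-of-death model labels every table `"illustrative"`).

Serialisation (`write_network()`) writes the fully expanded form: one
row per parent configuration with explicit bounds.  Parsing then
serialising is therefore semantically loss-free, though not
byte-identical for files using partial rows or judgments.
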