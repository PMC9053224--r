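# published_cohort_margins.tsv

Sex-stratified endorsement counts and age summaries for the 25 side-effect
columns, transcribed from the printed demographic table of a large
Australian cohort of antidepressant users (N = 20,941: 5,111 males with mean
age 47.99 [sd 15], 15,830 females with mean age 41.41 [sd 14]).

Columns:

* `k_male`, `k_female` — pooled-across-medications endorsement counts;
  the denominators are the per-sex totals above.
* `p_sex_printed` — the two-sample Z proportion test p-value as printed
  (recomputable from the counts; see `two_prop_z()`).
* `age_endorsed_*`, `age_not_*` — mean (sd) age of endorsers and
  non-endorsers; the endorser n is `k_male + k_female`, the non-endorser n
  is the complement of 20,941.
* `p_age_printed` — the printed two-sample t-test p-value.

These published margins are used as fixed inputs by the acceptance checks;
no individual-level data is included or required.
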