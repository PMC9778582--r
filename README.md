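# bphpersist

Medication persistence and drug-survival analysis for BPH/BPO pharmacy
claims.

Men treated for benign prostatic hyperplasia / benign prostatic obstruction
(BPH/BPO) receive two reimbursed drug classes — alpha-1-adrenoceptor
antagonists (ABs: alfuzosin, doxazosin, silodosin, tamsulosin, terazosin)
and steroid 5-alpha-reductase inhibitors (5ARIs: finasteride, dutasteride).
Because therapy is chronic, the key question for pharmacoepidemiologists
and health-service researchers is *persistence*: how long after initiation
does a man keep refilling? `bphpersist` answers it from dispensing records
(one row per dispensation with dates, ATC code, packages and DDD content),
for people who analyze administrative claims and need the whole chain to be
reproducible and testable without the non-redistributable source data.

The pipeline implements:

* **Record I/O and validation** — CSV dispensing records with a rejects
  report; YAML study configuration.
* **New-user cohort selection** — age gate (>= 40 years at 1 April 2018),
  wash-out window (Jan-Mar 2018), 1-year database history, index date =
  first fill in the index period, >= 2 distinct fills for chronic use;
  every man accounted for in an exclusion ledger. Death during follow-up is
  retained as a cause of non-persistence.
* **Treatment episodes** — supply duration = packages x DDD per package; a
  refill continues an episode iff it arrives within a grace period of
  1.5 x the previous dispensation's supply; early refills stockpile.
  Persistence is the time from index to the first episode's supply end,
  censored at 365 days: the Kaplan-Meier survival function of the time to
  discontinuation, S(t) = prod over t_i <= t of (1 - d_i/n_i), with
  Greenwood variance, log(-log) confidence bands, Brookmeyer-Crowley-style
  median CIs, k-group log-rank tests and a tie-corrected Wilcoxon rank-sum
  test — all implemented in-package and cross-checked against `survival`
  and `stats` in the tests.
* **Drug-prescription networks** — per-pair counts of men prescribed both
  drugs (21 possible pairs over 7 drugs) and polypharmacy distributions by
  age group.
* **Synthetic claims generator** — seeded, with per-drug latent
  discontinuation distributions, refill jitter, within-class switching,
  deaths and contaminant subpopulations, plus a ground-truth table so every
  stage is testable exactly.

## Worked example

The `analysis/` drivers run the full workflow on a simulated population of
5000 men (seed 20180401):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cohort.R
Rscript analysis/03_persistence.R
Rscript analysis/04_networks.R
```

`02_cohort.R` prints the exclusion cascade and descriptives:

```
         status    n
       eligible 3129
      under_age  256
   washout_user  233
  short_history  235
  no_index_fill    0
     occasional 1147

cohort: 3129 men, median age 71 [IQR 63-78]
           category    n  pct
1   at_least_one_ab 2391 76.4
2 at_least_one_5ari 1142 36.5
3      both_classes  404 12.9
4  died_in_followup   97  3.1
```

i.e. of 5000 simulated men, 3129 survive the cascade; 76.4% of the cohort
received at least one AB and 3.1% died during follow-up. `03_persistence.R`
prints per-class and per-drug drug survival:

```
 level         key    n n_events median_days persistent_pct
 class        5ARI 1142      657         270           42.5
 class          AB 2391     1648         185           31.1
  drug   alfuzosin  561      273          NA           51.3
  drug dutasteride  884      494         274           44.1
  drug finasteride  427      377         124           11.7
  drug  tamsulosin 1325     1121         128           15.4
 ...
        comparison  chi_square df       p_value p_display
   AB_across_drugs 561.8504757  4 2.791601e-120    <0.001
```

Median time to discontinuation was 185 days for ABs overall (31.1% still
in treatment at 365 days) and 270 days for 5ARIs (42.5%); alfuzosin's
median is not reached (51.3% persistent), and the across-drug log-rank is
overwhelming — the per-drug medians recover the generator's latent ordering
(alfuzosin and dutasteride persist longest). `04_networks.R` reports all
21 of 21 possible drug pairs detected, with silodosin-tamsulosin the most
common pair (224 men, 7.2%). Note that observed medians sit above the
latent ones (e.g. tamsulosin 128 vs 101 days): the supply-end convention
discretizes events to the 30-day package grid and eligibility conditions on
surviving the first package — see the methods vignette.

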