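# clinicdes

Discrete-event simulation (DES) of patient flow through a specialist
Obstetrics & Gynaecology outpatient clinic operating a **dual-practice**
system: the same senior specialists serve free/nominal-fee public patients in
the morning and fee-paying private patients in the afternoon, with both
streams sharing rooms, counters and staff. The package is for health-services
and operations researchers who want to study how consultation start times and
appointment staggering affect wait times and waiting-room crowding when two
patient queues share one resource pool.

## The model

Patients are entities flowing through a queueing network of
capacity-constrained stations, each a FIFO multi-server queue with daily
opening windows:

```
public:  QMS -> revenue -> O&G counter -> vitals -> [lab] -> consultation -> nurses -> exit
private: private counter -> vitals -> [lab] -> specialist consultation -> private counter -> exit
general: QMS -> revenue -> exit        (the other clinics' load on the shared counters)
```

Service times at each station are right-skewed lognormals fitted to published
median/quartile triples by constrained least squares: the lognormal median
`exp(mu)` is pinned to the printed median and `sigma` minimises the squared
error of the 0.25/0.75 quantiles, so for a triple (Q1, m, Q3)

```
mu = log(m),   sigma = argmin_s [ (exp(mu - z75 s) - Q1)^2 + (exp(mu + z75 s) - Q3)^2 ]
```

with `z75 = qnorm(0.75)`. Arrivals follow either the observed *block* pattern
(weighted random slot draws peaking 08:00-10:00, capped per 30-minute slot)
or *staggered* appointments (even per-slot counts). Doctors work to finish —
queues are served past the session close — and private consultations cannot
start before the specialists' switch-over from public duty plus a one-hour
lunch. Waiting-room crowding counts registered, not-yet-departed,
not-in-service patients per clock minute.

The simulation engine itself is generic (event calendar ordered by time with
insertion-order tie-breaks, FIFO seize/release, schedule-driven resources,
secondary resource co-seizure for specialist case discussions) and is checked
against a brute-force next-event oracle on hundreds of randomized small
systems.

## Worked example

```r
library(clinicdes)

# a published process time: public obstetrics consultation, 13 (10-20) min
d <- fit_quantile_dist(quantile_spec(10, 13, 20))
d
#> <service_dist> lognormal(meanlog = 2.5649, sdlog = 0.5949)
#>   quartiles 8.70 / 13.00 / 19.42 (target 10 / 13 / 20)

# base case vs scenario 3 (staggered arrivals, consultation from 08:15)
cfg  <- clinic_config()            # calibrated defaults
base <- run_experiment("base", cfg, n_replications = 3, days = 5, master_seed = 1)
base
#> <replication_set> scenario base: 3 replications x 5 day(s), master seed 1
#>   public  median TT (reg/clinic/overall): 43 / 96 / 138 min
#>   private median TT (reg/clinic/overall): 5 / 62 / 71 min

s3 <- run_experiment("3", cfg, n_replications = 3, days = 5, master_seed = 1)
compare_scenarios(s3, base)
#> <scenario_comparison> scenario 3 vs base
#>   change in median overall TT (%):
#>     OBS     GYN  PUBLIC PRIVATE
#>   -35.2   -35.9   -35.7   -38.3
#>   ...
```

The base-case medians track the published time-motion study (registration TT
45 min and clinic TT 99 min for public obstetrics patients, clinic TT 66 min
for private patients); matching the consultation start to staggered arrivals
(scenario 3) cuts the public overall turnaround time by roughly a third while
leaving daily volumes and resources untouched. `run_full_study()` runs the
whole battery (base plus scenarios 1-7, 30 replications of 5 days each) and
writes per-scenario summaries, percent-change tables and a reproducibility
manifest; `inst/cli/clinicdes.R` exposes the same pipeline as a command-line
tool.

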