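Package: clinicdes
Title: Discrete-Event Simulation of a Dual-Practice Outpatient Clinic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of patient flow through a specialist
    outpatient clinic operating a dual-practice (public/private) system.
    Provides a general event-calendar simulation engine with
    capacity-constrained, schedule-driven resources and FIFO queues;
    right-skewed service-time distributions fitted to published
    median/quartile triples; block ("random") and staggered (even per-slot)
    arrival generators; a calibrated clinic model covering registration
    counters, vital signs, laboratory, consultation and appointment stations;
    a battery of scheduling scenarios; and outcome metrics (registration,
    clinic and overall turnaround times, hourly waiting-area crowding,
    percentage change versus a base case, and rank-based group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
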