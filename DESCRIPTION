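Package: pumptwin
Title: Desk-Scale Digital Twin of an Insulin Pump Delivery Stack
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the delivery accuracy of a plunger-driven insulin pump
    from prescription to motor shaft. Computes total daily insulin and
    basal/bolus infusion schedules, maps doses to screw-drive plunger travel
    and encoder pulses for one- and two-stage drives, simulates a brushless
    DC motor speed loop under fixed-gain incremental PID and a
    backpropagation-neural-network adaptive PID, scores infusion logs with
    single/mean/maximum and cumulative basal-rate deviation statistics and
    paired t-tests, and predicts cumulative infusion deviation with a long
    short-term memory network whose forecast is distributed uniformly across
    planned infusions as a feed-forward compensation. Seeded generators
    produce infusion logs and deviation series with realistic under-delivery
    bias, drift and weighing noise for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
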