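Package: spinalreflex
Title: Quantification of Spinal Hyperexcitability from Electrophysiological
    and Behavioral Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vitro and in vivo signatures of
    spasticity after neonatal spinal cord injury: threshold-based detection of
    spontaneous ventral-root bursts on rectified-integrated envelopes,
    peristimulus time histogram (PSTH) quantification of dorsal-root-evoked
    short-latency and long-lasting reflexes with spontaneous-activity
    correction, cross-correlation classification of left/right ventral-root
    coupling (synchronous vs locomotor-like alternation), IPSP reversal
    potential estimation by regression x-intercept, persistent sodium current
    extraction from slow voltage ramps with linear leak subtraction, and EMG
    response duration / mechanical threshold / myoclonic twitch scoring.
    Includes seeded synthetic-recording generators with ground-truth
    annotations so every stage is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
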