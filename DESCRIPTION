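Package: alarmdet
Title: Knowledge-Based Detection of Periodic Equipment Alarm Sounds in Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of periodic biomedical equipment alarms (as heard, for
    example, in a neonatal intensive care unit) in noisy single-channel audio.
    Implements class-specific frame features built either from statistical
    sinusoid detection on spectral peaks (magnitude-shape and phase-continuity
    features scored against sinusoid and noise Gaussian mixture models) or from
    supervised non-negative matrix factorisation with Kullback-Leibler
    divergence and a sparsity penalty in alarm-specific frequency bands;
    Gaussian and shallow neural-network frame classifiers; temporal aggregation
    of frame posteriors over the alarm period structure; frame-level (missing
    rate, false-alarm rate, DET/EER) and period-level (PB-ERR) evaluation; and
    a synthetic alarm-soundscape generator with annotations so the whole
    pipeline can be exercised without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
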