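Package: swdscore
Title: Wavelet-Based Scoring of Spike-Wave Discharges and Sleep States in Rodent EEG
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automatic detection of spike-wave discharges (SWDs), behavioral
    (NREM) sleep, wakefulness and micro-arousals in multichannel rodent
    epidural EEG. Detection is based on the continuous Morlet wavelet
    transform: band-limited instantaneous energies are smoothed and combined
    into an SWD energy-ratio characteristic and a sleep-band characteristic,
    which are segmented by per-recording adaptive hysteresis thresholds.
    Candidate SWDs are validated by comparing signal extrema amplitudes
    against a pre-onset baseline. Downstream sleep-fragmentation metrics
    (episode counts, per-hour SWD rates, sleep fragmentation index,
    dark-phase analysis windows, epi-phenotype grouping) are computed from
    the resulting hypnogram. A synthetic multichannel EEG generator with
    ground-truth state intervals supports validation without animal data.
    Includes EDF/EDF+ and delimited-text I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
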