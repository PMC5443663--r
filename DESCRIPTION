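Package: ormiasrm
Title: Simulation and Analysis of Spatial Release from Masking in
    Mechanically Coupled Ears
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying spatial release from masking in the
    mechanically coupled auditory system of the parasitoid fly Ormia
    ochracea, exercisable entirely on synthetic data. Provides calibrated
    synthesis of pulsed cricket-song trills and band-limited noise maskers;
    a generative model of direction-dependent tympanal vibration and
    onset-phasic auditory afferent spiking; laser-vibrometry style analysis
    of effective response amplitudes and interaural vibration amplitude
    differences with sigmoid directionality fitting and inversion to a
    predicted sound direction; signal-detection-theoretic masked thresholds
    based on the standard separation statistic; open-loop treadmill
    phonotaxis kinematics; an adaptive descending staircase for behavioural
    thresholds; and the circular statistics (Watson U2, Watson-Williams,
    paired Hotelling, Harrison-Kanji two-factor ANOVA) used on angular
    headings.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
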