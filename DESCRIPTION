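Package: calwave
Title: Simulation and Analysis of Calcium Transients in Zebrafish Embryo Muscle Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ground-truthed simulator and analysis pipeline for in vivo
    calcium imaging of zebrafish embryo skeletal muscle. The simulator renders
    photon-limited bioluminescence movies (GFP-aequorin photophysics with a
    2.5-power luminescence law and substrate consumption), two-channel
    split-field FRET movies (Twitch-style ratiometric response with
    channel-specific photobleaching and common-mode motion artifacts), and
    transmitted-light contraction movies, all from explicit spike schedules
    over a somite phantom. The analysis side implements a two-component
    background model (general plus embryo background) with per-frame
    detection thresholds, size-gated connected-component transient detection,
    integrated-density event traces, crossing-based event kinetics (rise time
    10-90%, decay 90-10%, half-width, duration), dual-ROI contraction
    detection, pixel-wise FRET/donor ratioing with split-field registration
    and bleaching quantification, and rostro-caudal wave-speed estimation by
    regression of event onset times on somite distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
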