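Package: eislope
Title: Theta-Cycle Spectral-Slope and Morphometric Quantification of
    Hippocampal Excitatory-Inhibitory Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the excitatory:inhibitory balance of
    hippocampal circuits from local field potential recordings and from
    structural microscopy measurements. The signal pipeline conditions a
    CA1 recording (downsampling, mains notch, z-scoring), decomposes it by
    empirical mode decomposition into low (<5 Hz), theta (5-12 Hz) and
    supra-theta (>12 Hz) components, detects individual theta cycles during
    locomotion, and fits the 30-50 Hz log-log slope of Welch power spectra
    as an aperiodic excitation:inhibition proxy, with group-level
    statistics (Welch's t, Shapiro-Wilk gate, Grubbs outlier screen,
    Mann-Whitney U). A morphometry toolbox implements dendritic-spine
    classification (stubby/mushroom/thin), en passant bouton criteria,
    3D Sholl analysis of SWC reconstructions, synaptic puncta densities
    and E/I ratios, perisomatic puncta rings, optical densitometry,
    Cavalieri volume, fractionator counts, isotope ratios and
    co-expression percentages. A synthetic-data generator with embedded
    ground truth (colored 1/f noise, movement-gated theta with coupled
    gamma, random neuron trees, class-conditional spines, puncta images)
    makes every stage verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    pracma,
    EBImage,
    tiff,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
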