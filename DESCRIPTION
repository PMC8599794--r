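Package: imclip
Title: Analysis of i-Motif-Clipped Parallel Purine Homoduplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for the computational analysis of GA-repeat parallel
    homoduplexes clamped by a tetramolecular i-motif: conversion and
    normalization of CD/UV melting curves with melting-temperature and
    hysteresis estimation, calibration of NOE buildup volumes into NMR
    distance and glycosidic-torsion restraints, classification of
    purine-purine base-pair geometries (sugar edge, Hoogsteen edge,
    Watson-Crick edge), hemiprotonated C.C pair detection and i-motif
    intercalation topology calls (3'E/5'E, extended/compact) from atomic
    coordinates, and trajectory-level observables (base-stacking overlap
    areas by polygon projection, helical twist, hydrogen-bond distance
    distributions, average structures). A synthetic-data module generates
    melting curves, NOE buildup tables, idealized tetramolecular
    coordinate models and jittered trajectories so every stage runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    bio3d,
    deSolve
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
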