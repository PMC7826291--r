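Package: gp32footprint
Title: Footprint Mapping of Cooperative gp32 Binding on 2-AP-Labeled ssDNA Lattices
Version: 0.1.0
Authors@R:
    person("gp32footprint", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for single-nucleotide-resolution footprint mapping of the
    bacteriophage T4 single-stranded DNA binding protein (gp32) on short
    oligo(dT) lattices carrying 2-aminopurine (2-AP) fluorescent probes.
    Implements the exact equilibrium statistics of nonoverlapping,
    cooperatively interacting large ligands on finite one-dimensional
    lattices (partition-function recursion with a brute-force enumeration
    oracle), mass-balance titration curves, and the three spectroscopic
    analysis stages used in such studies: fluorescence-titration
    stoichiometry and enhancement-ratio mapping, Stern-Volmer acrylamide
    quenching analysis, and circular-dichroism exciton-peak titration
    profiles for 2-AP dimer probes. A deterministic synthetic-data
    generator emulates instrument output so that every analysis stage can
    be exercised and validated without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
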