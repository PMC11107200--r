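Package: cblpocket
Title: Structural and Spectroscopic Analysis of Cobalamin Transport Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the vitamin B12 (cobalamin) transport
    proteins transcobalamin, intrinsic factor and haptocorrin recognise
    beta-axially substituted cobalamins such as glutathionylcobalamin.
    Implements corrin butterfly fold-angle and axial-coordination geometry,
    Kabsch rigid-body superposition and domain deviation profiles,
    Shrake-Rupley solvent-accessible surface areas with buried-interface
    ranking, polar-contact and disulfide enumeration, ligand-transplant
    steric-clash screening of binding pockets, area-normalised absorbance
    spectrum comparison, microscale-thermophoresis binding-isotherm fitting
    with probe-depletion and lower-limit detection, pairwise global sequence
    alignment with conservation mapping, and seeded synthetic-data
    generators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
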