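Package: venomtox
Title: Mature Venom Toxin Reconstruction, Validation and Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream computational toolkit for venom peptidomics and
    proteomics. Reconstructs mature cysteine-rich peptides and short venom
    peptides from multi-enzyme digest evidence, validates their presence in
    native precursor-ion maps by disulfide-corrected monoisotopic mass and
    charge-ladder matching at ppm tolerance, quantifies venom proteins by
    the Hi3 (top-three peptide) label-free method, profiles net charge,
    isoelectric point and amino-acid class composition of validated toxins,
    and applies threshold decision rules to external antimicrobial and
    anticancer predictor scores. A seeded synthetic-data generator emulates
    precursor architecture, digests with dropout and precursor-ion maps with
    ppm jitter and decoy ions so every stage is testable without raw mass
    spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
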