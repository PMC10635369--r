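Package: tmcontact
Title: Inter-Helical Residue Contact Prediction from Structural Features
    in Transmembrane Proteins
Version: 0.1.0
Authors@R:
    person("tmcontact", "developers", email = "tmcontact@example.org",
           role = c("aut", "cre"))
Description: Predicts inter-helical residue-residue contacts in alpha-helical
    transmembrane proteins from atomic structures. Geometric features
    (inter-helical tilt angle, relative residue distances and relative residue
    angle) are extracted from the 3x3 sequence neighborhood of a residue pair
    and fed to a small feed-forward neural classifier trained on
    experimentally determined structures; the trained classifier rescoring
    pairs of a predicted (e.g. AlphaFold-like) structure improves the contact
    map implied by the predicted coordinates alone. Includes PDB coordinate
    I/O, contact-map construction under the 5.5 Angstrom minimum heavy-atom
    distance rule, a raw-coordinate feature baseline, per-sequence average
    precision / AUC-ROC / top-L evaluation with grouped cross-validation, an
    ideal alpha-helix bundle simulator for end-to-end testing, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
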