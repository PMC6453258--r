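Package: fepscout
Title: Triage of Charge-Changing Interface Mutations Before Free Energy
    Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens proposed charge-changing point mutations at
    protein-protein interfaces before they are sent to expensive alchemical
    free energy perturbation (FEP) simulations.  Implements a side-chain
    placeability filter based on rotamer strain energy, burial
    classification by fractional solvent accessible surface area (fSASA)
    against tripeptide reference maxima using a deterministic
    Shrake-Rupley lattice, salt-bridge network detection for extended
    sampling flags, protonation-state planning for buried carboxylates
    with a pKa-based state penalty, and the benchmark statistics used to
    evaluate predicted binding free energy changes against experiment
    (RMSE, coefficient of determination with permutation p-values,
    bootstrap confidence intervals, experimental truncation analysis,
    per-subset slope rescaling, and data-set selection rules).  Synthetic
    fixture generators provide ideal-geometry peptides, toy two-chain
    complexes and prediction tables so that every stage is testable
    without external downloads.  FEP energies themselves are consumed as
    input numbers, never computed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
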