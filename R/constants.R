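# Physical constants and unit conventions used throughout.
# Coordinates: Angstrom. Energies: kcal/mol. Entropies: cal/(mol K).
# Charges: elementary charge e. Masses: amu.

.COULOMB_KCAL <- 332.0636          # kcal A / (mol e^2)
.R_CAL        <- 1.98720425864083  # gas constant, cal/(mol K)
.KB_KCAL      <- .R_CAL / 1000     # kcal/(mol K)
.HBAR_SI      <- 1.054571817e-34   # J s
.KB_SI        <- 1.380649e-23      # J/K
.AMU_SI       <- 1.66053906892e-27 # kg

# Default residue-name whitelists; PDB dialects vary so these are
# configurable wherever they are consumed.
.WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SPC", "SOL")
.ION_RESNAMES   <- c("CA", "NA", "CL", "MG", "K", "ZN", "MN", "CA2", "NA+", "CL-")

# Atom names retained by alanine truncation (backbone + C-beta + their H).
.ALA_KEEP <- c("N", "H", "HN", "H1", "H2", "H3", "CA", "HA",
               "C", "O", "OXT", "CB", "HB1", "HB2", "HB3")
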