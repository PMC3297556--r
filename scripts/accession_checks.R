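#!/usr/bin/env Rscript
# Accession-based crystallographic checks. These need local copies of the
# deposited PDB entries (they are NOT bundled and this script does not
# download anything):
#
#   1ZHK.pdb  unliganded pMHC, allele 1 (peptide chain C by default)
#   1ZHL.pdb  unliganded pMHC, allele 2
#   2AK4.pdb  ternary TCR-pMHC complex, two conformations in the
#             asymmetric unit (complex A chains K-P, complex B chains A-E)
#
# Checks:
#   a. peptide Calpha RMSD between 1ZHK and 1ZHL over 13 residues
#      (published reference: 0.24 A)
#   b. mean peptide B-factor of each structure (published: 23.1 / 15.8 A^2)
#   c. docking-angle difference between complexes A and B of 2AK4
#      (published: ~12 deg; convention-dependent - the TCR atom set used
#      here is every TCR-chain Calpha, so exact agreement is not claimed)
#
# usage: Rscript scripts/accession_checks.R <dir-with-pdbs> [out.json]
#
# NOTE: the default 2AK4 chain-role map below follows deposition
# convention for the stated chain ranges but is unverified against the
# deposited file; inspect your copy and adjust if needed.

suppressPackageStartupMessages(library(tcrdyn))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: accession_checks.R <dir-with-pdbs> [out.json]")
dir <- args[1]
out <- if (length(args) > 1) args[2] else "results/accession_checks.json"
need <- file.path(dir, c("1ZHK.pdb", "1ZHL.pdb", "2AK4.pdb"))
missing <- need[!file.exists(need)]
if (length(missing))
  stop("missing local structure file(s): ", paste(missing, collapse = ", "))

report <- list()
roles_pmhc <- default_chain_roles("1ZHK")
pep_ca <- selection(chain = roles_pmhc$peptide, res = 1:13, name = "CA")
pep_all <- selection(chain = roles_pmhc$peptide, res = 1:13)

zhk <- read_structure(need[1])
zhl <- read_structure(need[2])
report$peptide_ca_rmsd_A <- list(
  value = pairwise_rmsd(zhk, zhl, pep_ca, pep_ca, superpose = TRUE), n = 13L)
report$peptide_mean_bfactor_1ZHK_A2 <- list(
  value = mean_bfactor(zhk, pep_all), n = 13L)
report$peptide_mean_bfactor_1ZHL_A2 <- list(
  value = mean_bfactor(zhl, pep_all), n = 13L)

cplx <- read_structure(need[3])
roles <- default_chain_roles("2AK4")
msel <- function(r) selection(chain = r$mhc_heavy, res = 1:180, name = "CA")
tsel <- function(r) selection(chain = c(r$tcr_alpha, r$tcr_beta), name = "CA")
report$docking_angle_difference_deg <- list(
  value = docking_angle_difference(cplx, cplx,
                                   mhc_sel_a = msel(roles$complex_a),
                                   tcr_sel_a = tsel(roles$complex_a),
                                   mhc_sel_b = msel(roles$complex_b),
                                   tcr_sel_b = tsel(roles$complex_b)),
  n = NA)

dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
print(str(report))
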