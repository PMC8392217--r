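# Bundled library of ~200 drug-like, hand-curated SMILES used by the
# synthetic-data generator, split roughly half and half between
# nitrogen-containing and nitrogen-free scaffolds so molecule-side
# predicates have balanced pools to draw from. All strings parse with
# openbabel (asserted in the test suite).

#' Bundled small-molecule library
#'
#' A fixed list of drug-like SMILES used by the synthetic-data
#' generator, so the SMILES-to-graph path is exercised on real
#' chemistry without external downloads. Roughly half the molecules
#' contain nitrogen.
#'
#' @return Named character vector of SMILES (names `M001`...).
#' @examples
#' length(cpi_smiles_library())
#' @export
cpi_smiles_library <- function() {
  smi <- c(
    # --- nitrogen-containing -----------------------------------------
    "CCN(CC)CC", "NCCO", "NCCc1ccccc1", "CN1CCCC1", "C1CCNCC1",
    "c1ccncc1", "Cc1ccncc1", "c1ccc2[nH]ccc2c1", "c1ccc2ncccc2c1",
    "NC(=O)c1ccccc1", "CC(=O)Nc1ccccc1", "CNC(=O)c1ccccc1",
    "NC(=O)CCc1ccccc1", "Nc1ccccc1", "Nc1ccc(O)cc1", "Nc1ccc(Cl)cc1",
    "CN(C)c1ccccc1", "NCc1ccccc1", "NCCc1ccc(O)c(O)c1",
    "CC(N)Cc1ccccc1", "CC(CN)O", "NCCCN", "NCCN", "NCCCCN",
    "N[C@@H](C)C(=O)O", "N[C@@H](CC(C)C)C(=O)O",
    "N[C@@H](Cc1ccccc1)C(=O)O", "N[C@@H](CO)C(=O)O",
    "N[C@@H](CS)C(=O)O", "N[C@@H](Cc1c[nH]cn1)C(=O)O",
    "OC(=O)CN", "CC(=O)NCCO", "O=C1CCCCN1", "O=C1NC(=O)NC(=O)C1",
    "CN1C(=O)N(C)c2ncn(C)c2C1=O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "NC(=N)N", "NC(=N)NCCC", "NC(=O)N", "CNC(=O)N",
    "c1cnc2[nH]ccc2c1", "c1ccc(cc1)CN1CCCCC1", "C1CN(CCN1)c1ccccc1",
    "CN1CCN(CC1)c1ccccc1", "O=C(O)c1ccccc1N", "Nc1ncnc2[nH]cnc12",
    "Nc1ccn(c(=O)n1)C", "Cc1ncc(CO)c(CN)c1O", "NCC(=O)O",
    "CC(=O)NC1CCCCC1", "O=C(Nc1ccccc1)c1ccccc1",
    "CCOC(=O)c1ccccc1N", "CN(C)CCOc1ccccc1", "CN(C)CCc1ccccc1",
    "COc1ccc(CCN)cc1", "CCN(CC)CCNC(=O)c1ccccc1",
    "NS(=O)(=O)c1ccccc1", "NS(=O)(=O)c1ccc(N)cc1",
    "CC(C)NCC(O)COc1ccccc1", "CNCC(O)c1ccccc1",
    "c1ccc(nc1)c1ccccn1", "Clc1ccccc1CN1CCNCC1",
    "O=C(CN1CCCC1)Nc1ccccc1", "CCN1CCCC1=O", "CN1CCCC1=O",
    "O=C1CCCN1C", "Nc1nc2ccccc2[nH]1", "Nc1nc2ccccc2s1",
    "Nc1nc2ccccc2o1", "CSc1ccccc1N", "COc1ccc2[nH]cnc2c1",
    "CC(C)Cc1ccc(cc1)C(C)NC", "O=C(O)CNC(=O)c1ccccc1",
    "NCCS", "NCCSSCCN", "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O",
    "CN1CCC(CC1)=C1c2ccccc2CCc2ccccc21", "NCCc1c[nH]c2ccccc12",
    "COc1ccc2[nH]cc(CCN)c2c1", "CN(C)CCn1nnnc1",
    "O=c1[nH]cnc2[nH]cnc12", "Nc1ncnc2n(cnc12)C1OC(CO)C(O)C1O",
    "CC(=O)Nc1ccc(O)cc1", "CC(=O)Nc1ccc(OCC)cc1",
    "CCN(CC)C(=O)c1ccccc1", "CN(C)C(=O)c1ccccc1",
    "O=C(N1CCCCC1)c1ccccc1", "O=C(N1CCOCC1)c1ccccc1",
    "C1COCCN1", "CN1CCOCC1", "C1CNCCN1", "c1cnccn1", "c1ccnnc1",
    "Cc1cccnc1", "CCc1cccnc1", "Brc1ccc(CN)cc1",
    "Fc1ccc(cc1)C(=O)N1CCNCC1", "CC(NC(=O)C)c1ccccc1",
    "N#Cc1ccccc1", "N#CCc1ccccc1", "CC(=O)NC", "CCCCNC(=O)C",
    # --- nitrogen-free -----------------------------------------------
    "CCO", "CCCO", "CC(C)O", "CCCCO", "CC(C)(C)O", "OCCO", "OCC(O)CO",
    "CCOCC", "COC", "C1CCOC1", "C1CCOCC1", "CCOC(=O)C", "COC(=O)C",
    "CC(=O)C", "CCC(=O)C", "CC(=O)CC(=O)C", "O=C1CCCCC1", "O=C1CCCC1",
    "CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(C)C(=O)O",
    "OC(=O)CCC(=O)O", "OC(=O)C=CC(=O)O", "OC(=O)c1ccccc1",
    "COC(=O)c1ccccc1", "CCOC(=O)c1ccccc1", "OC(=O)c1ccccc1O",
    "CC(=O)Oc1ccccc1C(=O)O", "Oc1ccccc1", "Cc1ccccc1O",
    "Oc1ccc(O)cc1", "Oc1ccccc1O", "COc1ccccc1", "COc1ccc(C=O)cc1",
    "O=Cc1ccccc1", "CC(=O)c1ccccc1", "c1ccccc1", "Cc1ccccc1",
    "CCc1ccccc1", "CC(C)c1ccccc1", "Cc1ccccc1C", "Cc1cccc(C)c1",
    "Cc1ccc(C)cc1", "c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1",
    "c1ccc2c(c1)CCCC2", "C1CCCCC1", "CC1CCCCC1", "C1CCCC1",
    "C1CCCCCC1", "CCCCCC", "CCCCCCCC", "CC(C)CC(C)(C)C",
    "C=CC=C", "CC=CC", "C#CC", "CCC#C", "Clc1ccccc1", "Clc1ccc(Cl)cc1",
    "Brc1ccccc1", "Fc1ccccc1", "Fc1ccc(F)cc1", "FC(F)(F)c1ccccc1",
    "ClCCCl", "ClC(Cl)Cl", "BrCCBr", "CCBr", "CCCl", "CCI",
    "CS(=O)C", "CS(=O)(=O)C", "CSC", "CCSCC", "CCS", "c1ccsc1",
    "Cc1ccsc1", "c1ccoc1", "Cc1ccco1", "O=Cc1ccco1",
    "OCc1ccccc1", "OCCc1ccccc1", "CC(O)c1ccccc1", "OC1CCCCC1",
    "CC1CCC(C(C)C)CC1", "CC1=CCC(CC1)C(C)C", "CC(C)=CCCC(C)=CCO",
    "OC(=O)CCCCCCCC", "CCCCCCCC(=O)O", "CCCCCC(=O)O",
    "CCCCOC(=O)C", "CCCCCOC(=O)C", "O=C(OCC)CC(=O)OCC",
    "C1OC1C", "C1OC1c1ccccc1", "OCC1OC(O)C(O)C(O)C1O",
    "CC(=O)OC1CCCCC1", "O=C(Oc1ccccc1)C", "CC(C)(C)c1ccc(O)cc1",
    "Cc1cc(C)c(O)c(C)c1", "Oc1ccc2ccccc2c1", "CCCCCCO", "CCCCCCCO",
    "CC(C)CO", "CC(C)CCO", "OCC=C", "C=CCO", "CCC(C)O", "CC(O)CO",
    "O1CCOCC1", "CC1OCCO1", "CCOC(C)OCC", "COCCOC", "CCCOC",
    "CC(C)OC(C)C"
  )
  names(smi) <- sprintf("M%03d", seq_along(smi))
  smi
}
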