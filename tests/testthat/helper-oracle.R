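# Reference masses computed independently of the package: neutral
# monoisotopic masses assembled by esterifying the class backbone with the
# fatty acyl/alkyl/sphingoid chains (glycerophospho-head group + chains -
# H2O per ester bond) from IUPAC atomic masses, cross-checked against the
# LIPID MAPS entries for the species with database records (e.g. PE 34:1
# 717.5309, PI 38:4 886.5571, SM d34:1 702.5676).
oracle_masses <- function() {
  data.frame(
    species = c("PI 32:0", "PI 34:1", "PI 34:2", "PI 36:1", "PI 36:2",
                "PI 36:4", "PI 38:3", "PI 38:4",
                "PE 36:1", "PE 36:2", "PE 36:4", "PE 38:2", "PE 38:4",
                "PE 38:6", "PE 40:6",
                "PE P 36:1", "PE P 38:4", "PE P 38:6", "PE P 40:6",
                "PS 36:1", "PS 38:4", "PS 40:6",
                "SM d34:1", "SM d36:1", "SM d42:1", "SM d42:2"),
    neutral_mass = c(810.5258, 836.5415, 834.5258, 864.5728, 862.5571,
                     858.5258, 888.5728, 886.5571,
                     745.5622, 743.5465, 739.5152, 771.5778, 767.5465,
                     763.5152, 791.5465,
                     729.5672, 751.5516, 747.5203, 775.5516,
                     789.5520, 811.5363, 835.5363,
                     702.5676, 730.5989, 814.6928, 812.6771),
    # deprotonated [M-H]- for glycerophospholipids, acetate adduct for SM
    mz = c(809.5186, 835.5342, 833.5186, 863.5655, 861.5499,
           857.5186, 887.5655, 885.5499,
           744.5549, 742.5392, 738.5079, 770.5705, 766.5392,
           762.5079, 790.5392,
           728.5600, 750.5443, 746.5130, 774.5443,
           788.5447, 810.5291, 834.5291,
           761.5814, 789.6127, 873.7066, 871.6910),
    stringsAsFactors = FALSE
  )
}
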