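shift,class,assignment,enriched_group
441,Lipids,Sterols stretching,CTRL
471,Carbohydrates,Polysaccharides,CTRL
499,Carbohydrates,Glycogen,CTRL
524,Lipids,Phosphatidylserine,CTRL
543,Carbohydrates,Glucose/Saccharides,CTRL
560,Protein,Tryptophan,CTRL
587,Lipids,Phosphatidylinositol,CTRL
621,Protein,Phenylalanine,none
715,Lipids,C-N phospholipids,none
746,Nucleotides,Ring breathing DNA/RNA,none
778,Nucleotides,"Ring breathing C, U, T",none
812,Nucleotides,Phosphodiester bonds,none
924,Carbohydrates,Glucose/Glycogen,COPD
937,Protein,Proline,COPD
948,Protein,Proline and Valine,COPD
962,Nucleotides,Phosphate monoester groups,COPD
979,Lipids,C-H bending in lipids,COPD
1001,Protein,"Phenylalanine, Tryptophan",COPD
1051,Carbohydrates,Glycogen,COPD
1077,Lipids,C-C of lipids,COPD
1104,Protein,Phenylalanine,COPD
1126,Nucleotides,Stretching of acyl backbone,COPD
1161,Protein,Tyrosine,COPD
1195,Nucleotides,Nucleotides breathing,COPD
1242,Protein,Amide III,CTRL
1267,Protein,Amide III/Lipids,CTRL
1284,Protein,C-H bending,none
1301,Nucleotides,C-H vibration,none
1382,Protein,C-H rocking,none
1409,Protein,Bending of methyl groups,none
1450,Lipids,C-H deformations in lipids,CTRL
1454,Lipids,Phospholipids,none
1515,Nucleotides,Cytosine,COPD
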