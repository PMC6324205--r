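protein,temperature_C,protein_concentration_mg_ml,polymer,polymer_concentration_pct_wv,measurement_method,diffusion_coefficient_1e6_cm2_s
Fluorescein,25,0.0025-0.01,Hydroxyethylcellulose,2.7,Fluorescence intensity analysis,2.6
Chymotrypsin,37,0.06,Fibrillar collagen,3.5,Protein release from hydrogel,0.95
BSA,20,4,Free solution,NA,FRAP,0.57 +/- 0.02
BSA,20,4,Sulfated agarose,6,FRAP,0.27 +/- 0.04
BSA,37,2,Glycidyl methacrylate-hyaluronic acid + PEG,1-2,Protein release from hydrogel,0.454 +/- 0.042; 0.085 +/- 0.036
BSA,37,2,Collagen,1-4.5,FRAP,0.2-0.8
BSA,37,2,Free solution,NA,Protein release from hydrogel,0.914
IgG,37,1,Polyvinyl alcohol,3,Protein release from hydrogel,0.1
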