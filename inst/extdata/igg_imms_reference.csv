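subclass,theoretical_mass_kda,experimental_mass_da,experimental_mass_sd,experimental_charge,overall_hinge_length,hinge_disulfides,upper_hinge_residues,initial_model_ccs,sampling_min_ccs,sampling_delta_ccs,collapsed_ccs_model1,collapsed_range_model1,collapsed_ccs_model2,collapsed_range_model2,collapsed_ccs_model3,collapsed_range_model3,experimental_ccs,experimental_ccs_sd,deglycosylated_ccs,deglycosylated_ccs_sd
IgG1,150,149328,89,21,12,2,5,9532,8756,1102,7226,176,6988,196,7142,176,6827,81,6851,61
IgG2,150,154297,42,21,12,4,3,9747,8597,929,7396,201,7197,184,7309,213,7030,113,7087,56
IgG3,170,162123,4,22,62,11,12,10958,9170,1329,7284,173,7176,197,7588,202,7173,68,7202,43
IgG4,150,155758,62,21,12,2,7,9512,8484,1080,7017,204,6766,268,6644,179,7024,97,7095,51
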