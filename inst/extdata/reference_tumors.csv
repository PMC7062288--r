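# Transcription template for the published example-tumor parameter sets
# (nodular / intermediate / diffuse fit to size dynamics; heterogeneous fit
# to all data). The parameter values appear only in the source publication's
# supplementary table and are NOT bundled here: rows hold NA placeholders to
# be filled in by hand. The printed per-tumor metric targets that the
# reproduction is checked against live in reference_tumor_metrics.csv.
tumor,rho_R,sigma_theta,p0,D_p,r_d,r_s,r_c,p_a,K_p,K_m,beta_p,beta_m,tau_mean,sigma_tau,v_mean,sigma_v
nodular,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
intermediate,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
diffuse,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
heterogeneous,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
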