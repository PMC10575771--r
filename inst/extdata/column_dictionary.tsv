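column	mandatory	type	units	description
study_id	yes	text		publication identifier
cohort_id	no	text		clinical group within the study (defaults to study_id); multiple cohorts may share one control group
timepoint	no	integer		longitudinal timepoint; only timepoint 1 is analysed
region	yes	text		brain region, canonical code or any label in region_synonyms()
metabolite	yes	text		one of glutamate, glutamine, Glx
mean_p	yes	numeric	institutional units or ratio	patient group mean metabolite concentration
sd_p	yes	numeric	same as mean_p	patient group standard deviation
n_p	yes	count		patient group sample size
mean_c	yes	numeric	same as mean_p	control group mean
sd_c	yes	numeric	same as mean_p	control group standard deviation
n_c	yes	count		control group sample size as reported (adjusted for shared controls at ingest)
n_clinical_groups	no	count		number of clinical groups sharing the control group (default 1)
medication_status	no	text		antipsychotic_naive, medicated or mixed
acquisition	no	text		standard, j_edited or epsi
reference_scheme	no	text		cr_scaled, csf_corrected or other
scale_factor	no	numeric		1, 1000 or 100000; applied to J-edited/EPSI means and SDs for comparability
mean_age	no	numeric	years	combined patient+control mean age
prop_male	no	proportion		proportion of males in the combined sample
panss_total	no	score		mean PANSS total score of the patient group
panss_total_sd	no	score		SD of the PANSS total score
age_sd	no	years		SD of age
cpz	no	mg/day		mean chlorpromazine-equivalent antipsychotic dose
snr_ratio	no	ratio		patient/control signal-to-noise ratio
fwhm_ratio	no	ratio		patient/control linewidth (full width at half maximum) ratio
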