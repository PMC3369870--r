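file	column	description
stasis_times.csv	realization	1-based realization index within the ensemble
stasis_times.csv	stasis_time	generations until structural stasis (NA if unabsorbed)
stasis_times.csv	terminal_status	"stasis" or "max_generations"
ensemble_summary.csv	n	number of realizations
ensemble_summary.csv	absorbed	realizations that reached stasis
ensemble_summary.csv	mean_stasis	mean stasis time over absorbed realizations
ensemble_summary.csv	se	standard error of the mean stasis time
kimura (--out)	p0	initial allele frequency
kimura (--out)	n_realizations	Monte Carlo realizations per point
kimura (--out)	n_fixed	realizations reaching fixation
kimura (--out)	mean_t_fix	fixation-conditioned mean absorption time (generations)
kimura (--out)	se	standard error of mean_t_fix
kimura (--out)	theory_t1	Kimura-Ohta fixation-conditioned prediction
kimura (--out)	theory_t0	Kimura-Ohta deletion-conditioned prediction
ce_points.csv	realization	realization index
ce_points.csv	generation	generation index (0 = initial machine)
ce_points.csv	h_mu	allelic entropy, bits per allele
ce_points.csv	C_mu	allelic complexity, bits
ce_points.csv	signature	isostructural-subspace signature
ce_points.csv	class	subspace class label (FC/BC/AP/GM/EP or raw signature)
pathways.csv	pathway	ordered subspace classes visited, joined by "|"
pathways.csv	n	realizations on this pathway
pathways.csv	weight	empirical pathway probability
pathways.csv	mean_time	mean stasis time on this pathway
pathways.csv	se	standard error of mean_time
dwell_times.csv	pathway	pathway label
dwell_times.csv	step	position of the subspace within the pathway
dwell_times.csv	class	subspace class
dwell_times.csv	n	realizations contributing
dwell_times.csv	mean_dwell	mean generations spent in the subspace
dwell_times.csv	mean_entry_p	mean tracked-symbol probability at entry
entry_params.csv	realization	realization index
entry_params.csv	pathway	pathway label
entry_params.csv	class	subspace entered
entry_params.csv	entry_generation	generation of the jump
entry_params.csv	entry_p	stationary tracked-symbol probability at entry
trajectory records	generation	generation index (0 = initial machine)
trajectory records	n_states	number of machine states
trajectory records	n_edges	number of stored transitions
trajectory records	h_mu	allelic entropy, bits per allele
trajectory records	C_mu	allelic complexity, bits
trajectory records	p_tracked	stationary probability of the first alphabet symbol
trajectory records	signature	isostructural-subspace signature
trajectory records	event	none / innovation_accepted / loss_merge / subspace_jump
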