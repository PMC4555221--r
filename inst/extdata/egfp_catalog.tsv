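protein_change	nt_change	fluorescence	protein_level	conserved	category	sources	notes
W57*	G170A	no	no	na	PTC	this_study:16;prior_report
W57*	G171A	no	no	na	PTC	this_study:4
Q69*		no	no	na	PTC	prior_screen
Q94*		no	sterile	na	PTC	this_study:32
Q157*		no	no	na	PTC	prior_screen
Q177*		no	no	na	PTC	prior_screen
Q183*		no	no	na	PTC	prior_screen
Q184*		no	sterile	na	PTC	prior_screen
T65I		weak_to_moderate	weak	no	chromophore	this_study:35
G67S		no	weak	yes	chromophore	prior_screen
G67D		weak	weak	yes	chromophore	this_study:22;prior_screen;prior_report
T62I		negligible	no	no	chromophore_maturation	prior_screen;prior_report
R96C		no	wt	yes	chromophore_maturation	this_study:31
R96H		no	wt	yes	chromophore_maturation	this_study:12;prior_screen
S205F		weak	wt	no	chromophore_maturation	prior_screen;prior_report
E222K		weak_to_moderate	weak	yes	chromophore_maturation	this_study:17,18
G20D		no	no	yes	stability_lid	this_study:38
G91S		no	no	yes	stability_lid	this_study:9
G91D		no	no	yes	stability_lid	this_study:3;prior_screen
G127D		negligible	no	yes	stability_lid	this_study:6,17;prior_report
G31D		negligible	no	yes	stability_unknown	this_study:12,31;prior_screen;prior_report
G33D		negligible	no	yes	stability_unknown	this_study:3,28,44
G35S		weak	very_weak	yes	stability_unknown	this_study:23,27,28
G40D		negligible	no	yes	stability_unknown	this_study:34;prior_screen
P56L		negligible	no	no	stability_unknown	this_study:25
C70Y		weak	very_weak	no	stability_unknown	this_study:40
A110V		negligible	no	no	stability_unknown	this_study:47;prior_report
V112M		weak	weak	no	stability_unknown	this_study:15
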