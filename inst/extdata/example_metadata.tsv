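sample_id	subject_id	sex	body_site
M_s001	M_s001	M	synthetic_site
M_s002	M_s002	M	synthetic_site
M_s003	M_s003	M	synthetic_site
M_s004	M_s004	M	synthetic_site
M_s005	M_s005	M	synthetic_site
M_s006	M_s006	M	synthetic_site
F_s001	F_s001	F	synthetic_site
F_s002	F_s002	F	synthetic_site
F_s003	F_s003	F	synthetic_site
F_s004	F_s004	F	synthetic_site
F_s005	F_s005	F	synthetic_site
F_s006	F_s006	F	synthetic_site
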