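# Functional regions of the JAK2 JH1 kinase domain (author numbering,
# both ends inclusive). Bounds marked (approx.) are not fully established
# in the literature consulted; override with your own TSV if needed.
name	start	end
G-rich_loop	858	860
C-helix	882	897
hinge	929	934
E-helix-D-helix_loop	945	955
catalytic_loop	976	983
activation_loop	1010	1015
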