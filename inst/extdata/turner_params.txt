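# rnaprof nearest-neighbor parameter table, version 1.0
# Free energies in kcal/mol at 37 C.  Stacks are keyed by the outer pair
# (i,j) and the inner pair (i+1,j-1), each written 5'->3'.  Loop initiation
# tables are extrapolated beyond their largest tabulated size with the
# Jacobson-Stockmayer term 1.75*RT37*ln(size/max_size).
stack AU AU -0.9
stack AU UA -1.1
stack AU CG -2.2
stack AU GC -2.1
stack AU GU -0.6
stack AU UG -1.4
stack UA AU -1.3
stack UA UA -0.9
stack UA CG -2.4
stack UA GC -2.1
stack UA GU -1.0
stack UA UG -1.3
stack CG AU -2.1
stack CG UA -2.1
stack CG CG -3.3
stack CG GC -2.4
stack CG GU -1.4
stack CG UG -2.1
stack GC AU -2.4
stack GC UA -2.2
stack GC CG -3.4
stack GC GC -3.3
stack GC GU -1.5
stack GC UG -2.5
stack GU AU -1.3
stack GU UA -1.4
stack GU CG -2.1
stack GU GC -1.9
stack GU GU -0.5
stack GU UG 1.3
stack UG AU -1.0
stack UG UA -0.6
stack UG CG -1.4
stack UG GC -1.5
stack UG GU 0.3
stack UG UG -0.5
hairpin 3 5.4
hairpin 4 5.6
hairpin 5 5.7
hairpin 6 5.4
hairpin 7 6.0
hairpin 8 5.5
hairpin 9 6.4
bulge 1 3.8
bulge 2 2.8
bulge 3 3.2
bulge 4 3.6
bulge 5 4.0
bulge 6 4.4
internal 2 1.5
internal 3 1.6
internal 4 1.7
internal 5 1.8
internal 6 2.0
internal 7 2.2
internal 8 2.3
internal 9 2.4
multiloop_init 3.4
multiloop_branch 0.4
multiloop_unpaired 0.0
internal_asym 0.5
internal_asym_max 3.0
max_internal 30
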