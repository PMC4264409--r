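# Two worked redintegration scenarios: an intact five-feature cue and
# the same cue elaborated with three contextually unique features
# (Q R N) that no competitor shares.  The target is trace 2.

name: intact-cue
probe: C C 2 3 1
trace: C C 1 2 3
trace: C C 2 3 1
trace: C C 3 1 2
target: 2

name: elaborated-cue
probe: C C 2 3 1 Q R N
trace: C C 1 2 3
trace: C C 2 3 1 Q R N
trace: C C 3 1 2
target: 2
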