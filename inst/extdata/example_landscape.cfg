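# example four-step promoter landscape (energies in kBT)
# same format accepted by read_landscape_config()
states: R+P RP1 RP2 RPo
state_G: 0 -0.5 -1 -8
barrier_G: 2 1.5 6
final_barrier_G: -5
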