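# Brain-energetics feasibility tasks for the packaged toy network.
# ATP tasks are phrased as ADP -> ATP conversion (adp_c allowed in, atp_c
# required out) so the adenylate pool stays balanced at steady state.
# Required outputs equal the network's designed integer yields where noted.
- id: atp_from_glucose_aerobic
  description: full aerobic ATP yield from one glucose (designed yield 26)
  inputs: {glc_e: 1, o2_e: 10, adp_c: 26}
  outputs: {atp_c: 26, co2_e: 0}
- id: atp_from_glucose_anaerobic
  description: fermentative ATP yield from one glucose (designed yield 2)
  inputs: {glc_e: 1, adp_c: 2}
  outputs: {atp_c: 2, lac_e: 0}
- id: atp_from_fatty_acid
  description: aerobic ATP yield from one palmitate-like fatty acid (designed yield 83)
  inputs: {ffa_e: 1, o2_e: 30, adp_c: 83}
  outputs: {atp_c: 83, co2_e: 0}
- id: atp_from_glutamine
  description: aerobic ATP yield from one glutamine via anaplerosis (designed yield 17)
  inputs: {gln_e: 1, o2_e: 10, adp_c: 17}
  outputs: {atp_c: 17, co2_e: 0}
- id: nadh_reoxidation
  description: oxidise lactate to exported pyruvate, reoxidising cytosolic NADH through the shuttles and the chain
  inputs: {lac_e: 1, o2_e: 1}
  outputs: {pyr_e: 1}
- id: glucose_full_oxidation
  description: oxidise one glucose completely to CO2
  inputs: {glc_e: 1, o2_e: 10}
  outputs: {co2_e: 6}
- id: fatty_acid_full_oxidation
  description: oxidise one fatty acid completely to CO2
  inputs: {ffa_e: 1, o2_e: 30}
  outputs: {co2_e: 16}
- id: lactate_fermentation
  description: ferment one glucose to two lactate without oxygen
  inputs: {glc_e: 1}
  outputs: {lac_e: 2}
- id: glutamine_full_oxidation
  description: oxidise one glutamine completely to CO2 via anaplerotic entry into the TCA cycle
  inputs: {gln_e: 1, o2_e: 5}
  outputs: {co2_e: 5}
- id: oxygen_dependent_respiration
  description: consume oxygen while burning glucose (chain active)
  inputs: {glc_e: 1, o2_e: 6}
  outputs: {co2_e: 1}
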