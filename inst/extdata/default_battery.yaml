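tests:
- test_id: bvmt_learning
  display_name: BVMT-R Learning
  domain: learning_memory
  subdomain: visuospatial
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 25.0
  norm_sd: 5.0
- test_id: bvmt_recall
  display_name: BVMT-R Delayed Recall
  domain: learning_memory
  subdomain: visuospatial
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 9.5
  norm_sd: 2.0
- test_id: ravlt_learning
  display_name: RAVLT Learning
  domain: learning_memory
  subdomain: verbal
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 50.0
  norm_sd: 9.0
- test_id: ravlt_recall
  display_name: RAVLT Delayed Recall
  domain: learning_memory
  subdomain: verbal
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 10.5
  norm_sd: 3.0
- test_id: tmt_a
  display_name: Trail Making Test A
  domain: visuospatial_perceptual
  subdomain: speed
  polarity: lower_better
  rci_eligible: yes
  norm_mean: 30.0
  norm_sd: 10.0
- test_id: rey_cft_copy
  display_name: Rey CFT copy
  domain: visuospatial_perceptual
  subdomain: executive
  polarity: higher_better
  rci_eligible: no
  norm_mean: 33.0
  norm_sd: 3.0
- test_id: bnt
  display_name: Boston Naming Test
  domain: language
  subdomain: visuoperceptual
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 54.0
  norm_sd: 3.5
- test_id: phonemic_fluency
  display_name: Phonemic fluency
  domain: language
  subdomain: executive
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 40.0
  norm_sd: 11.0
- test_id: semantic_fluency
  display_name: Semantic fluency
  domain: language
  subdomain: speed
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 22.0
  norm_sd: 5.0
- test_id: cwit1
  display_name: CWIT 1
  domain: language
  subdomain: speed
  polarity: lower_better
  rci_eligible: yes
  norm_mean: 30.0
  norm_sd: 5.0
- test_id: cwit2
  display_name: CWIT 2
  domain: language
  subdomain: speed
  polarity: lower_better
  rci_eligible: yes
  norm_mean: 22.0
  norm_sd: 4.0
- test_id: cwit3
  display_name: CWIT 3
  domain: executive
  subdomain: language
  polarity: lower_better
  rci_eligible: yes
  norm_mean: 50.0
  norm_sd: 10.0
- test_id: cwit4
  display_name: CWIT 4
  domain: executive
  subdomain: language
  polarity: lower_better
  rci_eligible: yes
  norm_mean: 55.0
  norm_sd: 12.0
- test_id: tmt_b
  display_name: Trail Making Test B
  domain: executive
  subdomain: visuospatial
  polarity: lower_better
  rci_eligible: yes
  norm_mean: 70.0
  norm_sd: 25.0
- test_id: digit_span_backward
  display_name: Digit span backward
  domain: executive
  subdomain: attention
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 8.0
  norm_sd: 2.0
- test_id: digit_span_forward
  display_name: Digit span forward
  domain: speed_attention
  subdomain: attention
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 10.0
  norm_sd: 2.0
- test_id: coding
  display_name: Coding
  domain: speed_attention
  subdomain: speed
  polarity: higher_better
  rci_eligible: yes
  norm_mean: 65.0
  norm_sd: 13.0
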