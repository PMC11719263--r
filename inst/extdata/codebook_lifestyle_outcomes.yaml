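# 31-item pandemic lifestyle-change instrument: 18 lifestyle items (L) and
# 13 health outcomes (H), each rated 1 ("substantially reduced") to
# 5 ("substantially increased"). Items worded with a "Less" prefix are
# reverse coded so that, after loading, higher always means healthier.
items:
  - {id: L1,  community: lifestyle, description: "Food types in daily meals"}
  - {id: L2,  community: lifestyle, description: "Consumption of fruits and vegetables"}
  - {id: L3,  community: lifestyle, description: "Less consumption of frozen food/food products", reverse_coded: true}
  - {id: L4,  community: lifestyle, description: "Less consumption of snacks", reverse_coded: true}
  - {id: L5,  community: lifestyle, description: "Less soft drinks/juices/other sugary drinks", reverse_coded: true}
  - {id: L6,  community: lifestyle, description: "Having a meal at home"}
  - {id: L7,  community: lifestyle, description: "Cooking at home"}
  - {id: L8,  community: lifestyle, description: "Less eating takeout food", reverse_coded: true}
  - {id: L9,  community: lifestyle, description: "Taking alternative medicine or natural health products"}
  - {id: L10, community: lifestyle, description: "Taking oral supplements/vitamins"}
  - {id: L11, community: lifestyle, description: "Less smoking tobacco", reverse_coded: true}
  - {id: L12, community: lifestyle, description: "Less alcohol consumption", reverse_coded: true}
  - {id: L13, community: lifestyle, description: "Less duration of sitting", reverse_coded: true}
  - {id: L14, community: lifestyle, description: "Less duration of screen time", reverse_coded: true}
  - {id: L15, community: lifestyle, description: "Frequency of exercise"}
  - {id: L16, community: lifestyle, description: "Duration of exercise"}
  - {id: L17, community: lifestyle, description: "Type of exercise"}
  - {id: L18, community: lifestyle, description: "Overall amount of exercise"}
  - {id: H1,  community: outcome, description: "Lose weight"}
  - {id: H2,  community: outcome, description: "Appetite"}
  - {id: H3,  community: outcome, description: "Physical health"}
  - {id: H4,  community: outcome, description: "Sleep quality"}
  - {id: H5,  community: outcome, description: "Quality of life"}
  - {id: H6,  community: outcome, description: "Less mental burden", reverse_coded: true}
  - {id: H7,  community: outcome, description: "Less emotional distress", reverse_coded: true}
  - {id: H8,  community: outcome, description: "Family disputes"}
  - {id: H9,  community: outcome, description: "Social support provided"}
  - {id: H10, community: outcome, description: "Social support received"}
  - {id: H11, community: outcome, description: "Social activities"}
  - {id: H12, community: outcome, description: "Income"}
  - {id: H13, community: outcome, description: "Less economic burden", reverse_coded: true}
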