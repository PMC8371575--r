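# Partisan profile-hashtag lexicon (example entries; extend for real runs).
# Keys: left, right — lists of hashtags, case-insensitive, '#' optional.
left:
  - "#TheResistance"
  - "#VoteBlue"
  - "#Resist"
  - "#BlueWave"
right:
  - "#MAGA"
  - "#KAG"
  - "#Trump2020"
  - "#WWG1WGA"
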