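nodes:
  - name: AcEM
    states:
      - low
      - high
      - perfect
    parents: []
    cpt:
      - 1/3
      - 1/3
      - 1/3
  - name: AcRM
    states:
      - low
      - high
      - perfect
    parents: []
    cpt:
      - 1/3
      - 1/3
      - 1/3
  - name: TE
    states:
      - low
      - medium
      - high
    parents: []
    cpt:
      - 1/3
      - 1/3
      - 1/3
  - name: R
    states:
      - none
      - medium
      - strong
    parents: []
    cpt:
      - 1/2
      - 1/4
      - 1/4
  - name: TR
    states:
      - low
      - medium
      - high
    parents:
      - R
      - TE
    cpt:
      - given:
          - none
          - low
        p:
          - 1/3
          - 1/3
          - 1/3
      - given:
          - medium
          - low
        p:
          - 3/5
          - 3/10
          - 1/10
      - given:
          - strong
          - low
        p:
          - 9/10
          - 2/25
          - 1/50
      - given:
          - none
          - medium
        p:
          - 1/3
          - 1/3
          - 1/3
      - given:
          - medium
          - medium
        p:
          - 1/5
          - 3/5
          - 1/5
      - given:
          - strong
          - medium
        p:
          - 1/20
          - 9/10
          - 1/20
      - given:
          - none
          - high
        p:
          - 1/3
          - 1/3
          - 1/3
      - given:
          - medium
          - high
        p:
          - 1/10
          - 3/10
          - 3/5
      - given:
          - strong
          - high
        p:
          - 1/50
          - 2/25
          - 9/10
  - name: ME
    states:
      - low
      - medium
      - high
    parents:
      - AcEM
      - TE
    cpt:
      - given:
          - low
          - low
        p:
          - 1/2
          - 3/10
          - 1/5
      - given:
          - high
          - low
        p:
          - 4/5
          - 3/20
          - 1/20
      - given:
          - perfect
          - low
        p:
          - '1'
          - '0'
          - '0'
      - given:
          - low
          - medium
        p:
          - 1/4
          - 1/2
          - 1/4
      - given:
          - high
          - medium
        p:
          - 1/10
          - 4/5
          - 1/10
      - given:
          - perfect
          - medium
        p:
          - '0'
          - '1'
          - '0'
      - given:
          - low
          - high
        p:
          - 1/5
          - 3/10
          - 1/2
      - given:
          - high
          - high
        p:
          - 1/20
          - 3/20
          - 4/5
      - given:
          - perfect
          - high
        p:
          - '0'
          - '0'
          - '1'
  - name: MR
    states:
      - low
      - medium
      - high
    parents:
      - AcRM
      - TR
    cpt:
      - given:
          - low
          - low
        p:
          - 1/2
          - 3/10
          - 1/5
      - given:
          - high
          - low
        p:
          - 4/5
          - 3/20
          - 1/20
      - given:
          - perfect
          - low
        p:
          - '1'
          - '0'
          - '0'
      - given:
          - low
          - medium
        p:
          - 1/4
          - 1/2
          - 1/4
      - given:
          - high
          - medium
        p:
          - 1/10
          - 4/5
          - 1/10
      - given:
          - perfect
          - medium
        p:
          - '0'
          - '1'
          - '0'
      - given:
          - low
          - high
        p:
          - 1/5
          - 3/10
          - 1/2
      - given:
          - high
          - high
        p:
          - 1/20
          - 3/20
          - 4/5
      - given:
          - perfect
          - high
        p:
          - '0'
          - '0'
          - '1'
  - name: ERMatch
    states:
      - ll
      - lm
      - lh
      - ml
      - mm
      - mh
      - hl
      - hm
      - hh
    parents:
      - ME
      - MR
    cpt:
      - given:
          - low
          - low
        p:
          - '1'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
      - given:
          - medium
          - low
        p:
          - '0'
          - '0'
          - '0'
          - '1'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
      - given:
          - high
          - low
        p:
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '1'
          - '0'
          - '0'
      - given:
          - low
          - medium
        p:
          - '0'
          - '1'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
      - given:
          - medium
          - medium
        p:
          - '0'
          - '0'
          - '0'
          - '0'
          - '1'
          - '0'
          - '0'
          - '0'
          - '0'
      - given:
          - high
          - medium
        p:
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '1'
          - '0'
      - given:
          - low
          - high
        p:
          - '0'
          - '0'
          - '1'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
      - given:
          - medium
          - high
        p:
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '1'
          - '0'
          - '0'
          - '0'
      - given:
          - high
          - high
        p:
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '0'
          - '1'
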