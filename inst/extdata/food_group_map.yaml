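- item: milk_full
  group: dairy
  fermented: no
  fullfat: yes
  sugary: no
- item: milk_skim
  group: dairy
  fermented: no
  fullfat: no
  sugary: no
- item: yogurt_plain
  group: dairy
  fermented: yes
  fullfat: yes
  sugary: no
- item: yogurt_flavored
  group: dairy
  fermented: yes
  fullfat: yes
  sugary: yes
- item: cheese_regular
  group: dairy
  fermented: yes
  fullfat: yes
  sugary: no
- item: cheese_lowfat
  group: dairy
  fermented: yes
  fullfat: no
  sugary: no
- item: cream
  group: dairy
  fermented: no
  fullfat: yes
  sugary: yes
- item: butter
  group: dairy
  fermented: no
  fullfat: yes
  sugary: no
- item: dessert_sugary
  group: dairy
  fermented: no
  fullfat: yes
  sugary: yes
- item: dessert_lowfat
  group: dairy
  fermented: no
  fullfat: no
  sugary: yes
- item: vegetables
  group: vegetables
- item: fruits
  group: fruits
- item: fish_seafood
  group: fish_seafood
- item: meat
  group: meat
- item: eggs
  group: eggs
- item: grains
  group: grains
- item: alcohol
  group: alcohol
- item: sugary_processed
  group: sugary_processed
- item: high_fat
  group: high_fat
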