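# Keyword specifications for six commercially traded wildlife taxa:
# include terms cover binomials, common names and trade-language variants;
# exclude ("NOT") terms remove known confounders (e.g. "pangolin" is also
# the name of a fruit-fly gene, and "rhinoceros beetle" patents concern an
# agricultural pest, not rhinoceroses).
bear:
  include:
    - bear bile
    - bear farm
    - gall bladder
    - gall powder
    - gallbladder
    - fel ursi
    - ursodeoxycholic
    - ursus arctos
    - ursus thibetanus
    - xiongdan
    - "熊胆"
  exclude:
    - ma huang jia zhu tang
caterpillar_fungus:
  include:
    - cordyceps
    - caterpillar fungus
    - aweto
    - dongchongxiacao
    - dong chong xia cao
  exclude: []
horseshoe_crab:
  include:
    - horseshoe crab
    - polyphemus
    - tachypleus tridentatus
    - tachypleus gigas
    - carcinoscorpius rotundicauda
    - limulus
  exclude:
    - soft-shell
pangolin:
  include:
    - pangolin
    - squama manis
    - jia zhu
    - pao shan jia
    - chuan shan jia
    - squama manitis
    - "穿山甲"
    - "醋山甲"
  exclude:
    - drosophila
rhinoceros:
  include:
    - rhinoceros
    - rhino
    - diceros
    - ceratotherium
    - dicerorhinus
  exclude:
    - rhinoceros beetle
    - oryctes
    - polyporus rhinoceros
    - giraffe rhinoceros
    - game
    - toy
    - software
sturgeon:
  include:
    - sturgeon
    - acipenser
  exclude: []
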